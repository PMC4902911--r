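# A hand-authored miniature cohort: twelve SNV sites (plus one indel that
# must be skipped) over four samples, chosen so that every branch of the
# training-label cascade is taken and the genotype-filter boundary
# (GQ 40 / alt depth 5 / allele balance 10%) is exercised. Shipped with the
# expected labels so tests and documentation can assert against it.

#' Write the worked-example fixture
#'
#' Creates `example.vcf`, `kg.tsv`, `exac.tsv`, `dbsnp.tsv` and `truth.tsv`
#' in `dir`, together with the expected training label per site. The sites,
#' in order (positions 1001..1012 on chromosome 1; the indel sits at 2000):
#' clean sites labelled from a 1000G-style PASS, from dbSNP presence, and
#' from no resource at all; one-failure sites resolved by a 1000G-style
#' FAIL and by no resource; two-failure sites resolved by each resource
#' branch; a three-failure site; a low-call-rate site; and a site whose
#' only heterozygote sits exactly on the genotype-filter boundary.
#'
#' @param dir output directory (created if needed).
#' @return list with `paths` and `expected` (data.frame of `pos`, `label`,
#'   `reason`, `validated`).
#' @export
worked_example_fixture <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  samples <- c("S1", "S2", "S3", "S4")
  hr <- "0/0:60,0:99"            # clean hom-ref genotype
  het <- "0/1:30,30:99"          # balanced het, NAD 0, AD 30
  good <- "QD=20;MQ=60;MQRankSum=0;ReadPosRankSum=0;BaseQRankSum=0;FS=2;InbreedingCoeff=0;HaplotypeScore=1"
  fail1 <- sub("QD=20", "QD=2.9", good)                    # QD fails
  fail2 <- sub("MQ=60", "MQ=49", fail1)                    # QD + MQ fail
  rec <- function(pos, ref, alt, info, g1, g2 = hr, g3 = hr, g4 = hr)
    paste(c("1", pos, ".", ref, alt, ".", ".", info, "GT:AD:GQ",
            g1, g2, g3, g4), collapse = "\t")
  lines <- c(
    vcf_header_lines(samples, source = "tarsvm-example"),
    rec(1001, "A", "G", good, het),                 # 0 fail, kg PASS
    rec(1002, "C", "T", good, het),                 # 0 fail, dbSNP only
    rec(1003, "G", "A", good, het),                 # 0 fail, no resource
    rec(1004, "T", "C", fail1, het),                # 1 fail, kg FAIL
    rec(1005, "A", "C", fail1, het),                # 1 fail, no resource
    rec(1006, "C", "G", fail2, het),                # 2 fail, kg PASS
    rec(1007, "G", "T", fail2, het),                # 2 fail, exac FAIL
    rec(1008, "T", "A", fail2, het),                # 2 fail, dbSNP only
    rec(1009, "A", "T", fail2, het),                # 2 fail, nothing
    rec(1010, "C", "A", fail2, "0/1:45,5:99"),      # skewed het: >= 3 fail
    rec(1011, "G", "C", good, het, "./.:.:.", "./.:.:.", "./.:.:."),  # call rate 0.25
    rec(1012, "T", "G", good, "0/1:45,5:40"),       # step-D boundary het
    rec(2000, "AT", "A", good, het))                # indel: skipped on read
  vcf <- file.path(dir, "example.vcf")
  con <- file(vcf, "w"); writeLines(lines, con); close(con)

  tsv <- function(name, pos, ref, alt, status = NULL) {
    d <- data.frame(chrom = "1", pos = pos, ref = ref, alt = alt)
    if (!is.null(status)) d$status <- status
    p <- file.path(dir, name)
    utils::write.table(d, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- list(
    vcf = vcf,
    kg = tsv("kg.tsv", c(1001, 1004, 1006), c("A", "T", "C"),
             c("G", "C", "G"), c("PASS", "FAIL", "PASS")),
    exac = tsv("exac.tsv", 1007, "G", "T", "FAIL"),
    dbsnp = tsv("dbsnp.tsv", c(1002, 1008), c("C", "T"), c("T", "A")),
    truth = tsv("truth.tsv", 1001:1012,
                c("A", "C", "G", "T", "A", "C", "G", "T", "A", "C", "G", "T"),
                c("G", "T", "A", "C", "C", "G", "T", "A", "T", "A", "C", "G"),
                NULL))
  truth <- utils::read.table(paths$truth, header = TRUE, sep = "\t",
                             colClasses = "character")
  truth$validated <- as.integer(truth$pos %in% c(1001, 1002, 1003, 1012))
  utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  expected <- data.frame(
    pos = 1001:1012,
    label = c("LIKELY_TRUE", "LIKELY_TRUE", "UNKNOWN",
              "LIKELY_FALSE", "UNKNOWN",
              "UNKNOWN", "LIKELY_FALSE", "UNKNOWN", "LIKELY_FALSE",
              "LIKELY_FALSE", "LIKELY_FALSE", "LIKELY_FALSE"),
    reason = c("F0_KG_PASS", "F0_DBSNP", "F0_NOT_IN_DBSNP",
               "F1_KG_FAIL", "F1_NO_RESOURCE",
               "F2_KG_PASS", "F2_EXAC_FAIL", "F2_DBSNP", "F2_NOT_IN_DBSNP",
               "F3PLUS", "CALLRATE_LT_50", "F3PLUS"),
    stringsAsFactors = FALSE)
  list(paths = paths, expected = expected)
}
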