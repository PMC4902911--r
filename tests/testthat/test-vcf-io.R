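# VCF parsing, genotype-derived site features, and the write/read round trip.

good_info <- "QD=20;MQ=60;MQRankSum=0;ReadPosRankSum=0;BaseQRankSum=0;FS=2;InbreedingCoeff=0;HaplotypeScore=1"

test_that("a 3-sample VCF with 2 SNVs yields 2 sites x 3 genotypes", {
  p <- write_test_vcf(c(
    vrec("1", 100, "A", "G", good_info, "0/1:30,30:99", "0/0:60,0:99", "0/0:55,0:99"),
    vrec("1", 200, "C", "T", "QD=15;MQ=58", "1/1:0,80:99", "0/0:70,0:99", "./.:.:.")))
  x <- read_sites(p)
  expect_equal(nrow(x$sites), 2L)
  expect_equal(nrow(x$genotypes), 6L)
  expect_equal(x$sites$qd, c(20, 15))
  expect_true(is.na(x$sites$fs[2]))  # absent INFO key flagged missing
  g <- x$genotypes[x$genotypes$site_id == x$sites$site_id[2], ]
  expect_equal(g$call, c("HOM_ALT", "HOM_REF", "MISSING"))
  expect_equal(g$alt_depth, c(80L, 0L, 0L))
})

test_that("multi-allelic records decompose per ALT with per-allele depths", {
  p <- write_test_vcf(vrec("1", 300, "C", "A,T", good_info,
                           "0/1:30,25,0:99", "0/2:28,0,31:99", "1/2:5,20,22:99"))
  x <- read_sites(p)
  expect_equal(nrow(x$sites), 2L)
  expect_equal(x$sites$chrom, c("1", "1"))
  expect_equal(x$sites$pos, c(300L, 300L))
  expect_equal(x$sites$alt, c("A", "T"))
  g1 <- x$genotypes[x$genotypes$site_id == x$sites$site_id[1], ]
  expect_equal(g1$call, c("HET", "HOM_REF", "HET"))
  expect_equal(g1$alt_depth, c(25L, 0L, 20L))  # other-ALT depth excluded
  g2 <- x$genotypes[x$genotypes$site_id == x$sites$site_id[2], ]
  expect_equal(g2$call, c("HOM_REF", "HET", "HET"))
  expect_equal(g2$alt_depth, c(0L, 31L, 22L))
})

test_that("non-SNV records are skipped with a warning", {
  p <- write_test_vcf(c(
    vrec("1", 100, "A", "G", good_info, "0/1:30,30:99", "0/0:60,0:99", "0/0:55,0:99"),
    vrec("1", 400, "AT", "A", good_info, "0/1:30,30:99", "0/0:60,0:99", "0/0:55,0:99")))
  expect_warning(x <- read_sites(p), "non-SNV")
  expect_equal(nrow(x$sites), 1L)
})

test_that("a VCF without the AD FORMAT field is fatal", {
  p <- write_test_vcf(vrec("1", 100, "A", "G", good_info, "0/1:30,30:99",
                           "0/0:60,0:99", "0/0:55,0:99"),
                      drop_ad_header = TRUE)
  expect_error(read_sites(p), "AD")
})

test_that("call rate is called/assayed with its degenerate cases", {
  calls <- c(rep("HET", 3), rep("HOM_REF", 5), rep("MISSING", 2))
  expect_equal(compute_call_rate(calls, 10), 0.8)
  expect_equal(compute_call_rate(rep("MISSING", 10), 10), 0)
  expect_equal(compute_call_rate(rep("HOM_REF", 10), 10), 1)
  expect_error(compute_call_rate(calls, 0), "n_samples")
})

test_that("ABHet pools alt over total depth across heterozygotes", {
  r <- compute_abhet_and_mean_ad(c("HET", "HET"), c(30, 10), c(30, 30))
  expect_equal(r$ab_het, 0.6)
  expect_equal(r$mean_ad_het, 30)
  r1 <- compute_abhet_and_mean_ad("HET", 5, 5)
  expect_equal(r1$ab_het, 0.5)
  expect_equal(r1$mean_ad_het, 5)
  r2 <- compute_abhet_and_mean_ad(c("HOM_REF", "HOM_ALT"), c(50, 0), c(0, 60))
  expect_true(is.na(r2$ab_het) && is.na(r2$mean_ad_het))
  # mean-of-ratios mode differs when depths differ
  rm <- compute_abhet_and_mean_ad(c("HET", "HET"), c(30, 10), c(30, 30),
                                  mode = "mean_of_ratios")
  expect_equal(rm$ab_het, mean(c(0.5, 0.75)))
})

test_that("call_rate and ab_het stay in [0,1] and match an independent loop", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(2:12, 1)
    calls <- sample(c("MISSING", "HOM_REF", "HET", "HOM_ALT"), n, replace = TRUE)
    rd <- sample(0:80, n, replace = TRUE)
    ad <- sample(0:80, n, replace = TRUE)
    cr <- compute_call_rate(calls, n)
    expect_true(cr >= 0 && cr <= 1)
    r <- compute_abhet_and_mean_ad(calls, rd, ad)
    if (!is.na(r$ab_het)) {
      expect_true(r$ab_het >= 0 && r$ab_het <= 1)
      num <- 0; den <- 0
      for (i in seq_len(n)) if (calls[i] == "HET") {
        num <- num + ad[i]; den <- den + ad[i] + rd[i]
      }
      expect_equal(r$ab_het, num / den)
    }
  }
})

test_that("write -> read round trip preserves keys, features, and NAD", {
  fx <- worked_example_fixture(tempfile("fx"))
  x <- suppressWarnings(read_sites(fx$paths$vcf))
  feats <- site_features(x)
  dec <- data.frame(site_id = x$sites$site_id,
                    label = rep(c("PASS", "FILTERED"), length.out = nrow(x$sites)))
  out <- tempfile(fileext = ".vcf")
  write_filtered_vcf(x, dec, out, features = feats)
  y <- read_sites(out)
  expect_equal(site_key(y$sites$chrom, y$sites$pos, y$sites$ref, y$sites$alt),
               site_key(x$sites$chrom, x$sites$pos, x$sites$ref, x$sites$alt))
  for (col in c("qd", "mq", "mq_rank_sum", "rp_rank_sum", "bq_rank_sum"))
    expect_equal(y$sites[[col]], x$sites[[col]], tolerance = 1e-6)
  # FILTER column as decided, in order
  raw <- readLines(out)
  body <- raw[!grepl("^#", raw)]
  expect_equal(vapply(strsplit(body, "\t"), `[`, "", 7),
               ifelse(dec$label == "PASS", "PASS", "tarSVM"))
  # NAD written to 4 decimals round-trips
  nad_back <- suppressWarnings(as.numeric(vcfR::extract.info(
    vcfR::read.vcfR(out, verbose = FALSE), "NAD")))
  expect_equal(nad_back, round(feats$nad, 4), tolerance = 1e-9)
  # genotype masking writes missing calls
  keep <- rep(FALSE, nrow(x$genotypes))
  write_filtered_vcf(x, dec, out, genotype_keep = keep)
  z <- read_sites(out)
  expect_true(all(z$genotypes$call == "MISSING"))
})

test_that("an empty site list still writes a valid header-only VCF", {
  fx <- worked_example_fixture(tempfile("fx"))
  x <- suppressWarnings(read_sites(fx$paths$vcf))
  x$sites <- x$sites[0, ]; x$genotypes <- x$genotypes[0, ]
  out <- tempfile(fileext = ".vcf")
  write_filtered_vcf(x, data.frame(site_id = character(0), label = character(0)),
                     out)
  y <- read_sites(out)
  expect_equal(nrow(y$sites), 0L)
})
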