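# Training-label trichotomization. Sites become LIKELY_FALSE, LIKELY_TRUE or
# UNKNOWN from the hard-filter failure count, the call rate, and the site's
# status in external call sets (a 1000 Genomes-style and an ExAC-style
# PASS/FAIL resource, and a dbSNP-style presence list). Only the first two
# classes train the classifier.

#' Load an external site-status resource
#'
#' Accepts a TSV with columns `chrom`, `pos`, `ref`, `alt` and optionally
#' `status` (`PASS`/`FAIL`; absent column means every listed site is PASS,
#' the natural reading for a presence list such as dbSNP), or a VCF whose
#' FILTER column encodes the status (`PASS` or `.` maps to PASS, anything
#' else to FAIL). Keys are matched on (chrom, pos, ref, alt) after
#' uppercasing alleles and stripping a `chr` prefix; unlisted keys report
#' ABSENT at lookup time.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"tsv"` or `"vcf"`.
#' @return data.frame with columns `key` and `status`.
#' @export
load_reference_sites <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE, checkFile = FALSE)
    fix <- v@fix
    keys <- character(0); status <- character(0)
    for (i in seq_len(nrow(fix))) {
      alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
      keys <- c(keys, site_key(fix[i, "CHROM"],
                               rep(as.integer(fix[i, "POS"]), length(alts)),
                               rep(fix[i, "REF"], length(alts)), alts))
      flt <- fix[i, "FILTER"]
      status <- c(status, rep(if (is.na(flt) || flt %in% c("PASS", "."))
        "PASS" else "FAIL", length(alts)))
    }
    return(data.frame(key = keys, status = status, stringsAsFactors = FALSE))
  }
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = "character", quote = "")
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(d)))
    stop("resource TSV must have columns chrom, pos, ref, alt: ", path)
  pos <- suppressWarnings(as.integer(d$pos))
  bad <- which(is.na(pos) | d$ref == "" | d$alt == "")
  if (length(bad))
    stop(sprintf("malformed resource row at line %d of %s", bad[1] + 1L, path))
  status <- if ("status" %in% names(d)) toupper(d$status) else
    rep("PASS", nrow(d))
  if (nrow(d) && !all(status %in% c("PASS", "FAIL")))
    stop("resource status must be PASS or FAIL: ", path)
  data.frame(key = site_key(d$chrom, pos, d$ref, d$alt), status = status,
             stringsAsFactors = FALSE)
}

lookup_status <- function(keys, resource) {
  if (is.null(resource)) return(rep("ABSENT", length(keys)))
  s <- resource$status[match(keys, resource$key)]
  ifelse(is.na(s), "ABSENT", s)
}

#' Per-site status in the external resources
#'
#' @param features data.frame with `chrom`, `pos`, `ref`, `alt` (e.g. from
#'   [site_features()]).
#' @param kg,exac loaded resources ([load_reference_sites()]) or paths;
#'   `NULL` means everything ABSENT.
#' @param dbsnp presence resource or path; `NULL` means nothing present.
#' @return data.frame with `kg_status`, `exac_status`
#'   (`PASS`/`FAIL`/`ABSENT`) and `in_dbsnp` (logical).
#' @export
reference_status <- function(features, kg = NULL, exac = NULL, dbsnp = NULL) {
  as_res <- function(r) if (is.character(r)) load_reference_sites(r) else r
  kg <- as_res(kg); exac <- as_res(exac); dbsnp <- as_res(dbsnp)
  keys <- site_key(features$chrom, features$pos, features$ref, features$alt)
  out <- data.frame(kg_status = lookup_status(keys, kg),
                    exac_status = lookup_status(keys, exac),
                    in_dbsnp = lookup_status(keys, dbsnp) != "ABSENT",
                    stringsAsFactors = FALSE)
  if (!is.null(features$site_id))
    out <- cbind(site_id = features$site_id, out, stringsAsFactors = FALSE)
  out
}

# scalar cascade; the 1000G-style resource takes precedence, ExAC-style is a
# fall-through for ABSENT only (first definitive answer wins)
assign_label_one <- function(n_failed, call_rate, kg, exac, in_dbsnp) {
  if (n_failed >= 3) return(c("LIKELY_FALSE", "F3PLUS"))
  if (call_rate < 0.5) return(c("LIKELY_FALSE", "CALLRATE_LT_50"))
  res <- if (kg != "ABSENT") c("KG", kg) else
    if (exac != "ABSENT") c("EXAC", exac) else c("NONE", "ABSENT")
  if (n_failed == 2) {
    if (res[2] == "PASS") return(c("UNKNOWN", paste0("F2_", res[1], "_PASS")))
    if (res[2] == "FAIL") return(c("LIKELY_FALSE", paste0("F2_", res[1], "_FAIL")))
    if (in_dbsnp) return(c("UNKNOWN", "F2_DBSNP"))
    return(c("LIKELY_FALSE", "F2_NOT_IN_DBSNP"))
  }
  tag <- if (n_failed == 1) "F1_" else "F0_"
  if (res[2] == "PASS") return(c("LIKELY_TRUE", paste0(tag, res[1], "_PASS")))
  if (res[2] == "FAIL") return(c("LIKELY_FALSE", paste0(tag, res[1], "_FAIL")))
  if (n_failed == 1) return(c("UNKNOWN", "F1_NO_RESOURCE"))
  if (in_dbsnp) return(c("LIKELY_TRUE", "F0_DBSNP"))
  c("UNKNOWN", "F0_NOT_IN_DBSNP")
}

#' Assign LIKELY_TRUE / LIKELY_FALSE / UNKNOWN training labels
#'
#' The cascade: three or more hard-filter failures, or call rate below 50%,
#' marks a site LIKELY_FALSE. With two failures, a PASS in the 1000
#' Genomes-style resource gives UNKNOWN and a FAIL gives LIKELY_FALSE; an
#' ABSENT falls through to the ExAC-style resource, and if both are absent
#' dbSNP presence decides UNKNOWN vs LIKELY_FALSE. With one failure the site
#' takes its verdict from the first resource that lists it (PASS maps to
#' LIKELY_TRUE, FAIL to LIKELY_FALSE), UNKNOWN if listed in neither. With no
#' failures the same resource rule applies, except that a site in neither
#' resource is LIKELY_TRUE when present in dbSNP and UNKNOWN otherwise.
#'
#' @param n_failed integer vector of hard-filter failure counts.
#' @param call_rate numeric vector of call rates.
#' @param status data.frame from [reference_status()] (columns `kg_status`,
#'   `exac_status`, `in_dbsnp`).
#' @return data.frame with `label` and `reason` (a machine-readable code for
#'   the branch taken).
#' @export
assign_training_labels <- function(n_failed, call_rate, status) {
  stopifnot(length(n_failed) == length(call_rate),
            length(n_failed) == nrow(status))
  if (length(n_failed) == 0L)
    return(data.frame(label = character(0), reason = character(0)))
  res <- mapply(assign_label_one, n_failed, call_rate, status$kg_status,
                status$exac_status, status$in_dbsnp)
  out <- data.frame(label = res[1, ], reason = res[2, ],
                    stringsAsFactors = FALSE)
  if (!is.null(status$site_id))
    out <- cbind(site_id = status$site_id, out, stringsAsFactors = FALSE)
  out
}
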