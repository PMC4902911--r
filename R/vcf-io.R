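# VCF input: parse a multi-sample VCF into per-site records and per-sample
# genotype observations, decomposing multi-allelic records per ALT allele and
# skipping non-SNVs (the method is SNV-only).

INFO_FEATURES <- c(qd = "QD", mq = "MQ", mq_rank_sum = "MQRankSum",
                   rp_rank_sum = "ReadPosRankSum", bq_rank_sum = "BaseQRankSum",
                   fs = "FS", inbreeding_coeff = "InbreedingCoeff",
                   haplotype_score = "HaplotypeScore")

# canonical SiteKey string: "chr" prefix stripped, alleles uppercased
site_key <- function(chrom, pos, ref, alt) {
  sprintf("%s:%d:%s:%s", sub("^chr", "", as.character(chrom)),
          as.integer(pos), toupper(ref), toupper(alt))
}

#' Read a multi-sample VCF into site and genotype tables
#'
#' Parses a VCF v4.x (via \pkg{vcfR}), keeping biallelic SNV ALT alleles.
#' Multi-allelic records are decomposed into one record per ALT allele;
#' depths for the other ALT alleles are excluded from the ref + alt totals.
#' Non-SNV alleles (indels, MNPs, symbolic alleles) are skipped with a
#' warning. Caller INFO annotations (QD, MQ, MQRankSum, ReadPosRankSum,
#' BaseQRankSum, FS, InbreedingCoeff, HaplotypeScore) are harvested when
#' present and flagged missing (`NA`) otherwise.
#'
#' Genotype calls are classified relative to the considered ALT allele by
#' allele copy count: 0 copies = HOM_REF, 1 = HET, 2 = HOM_ALT; any missing
#' allele = MISSING. Missing AD sub-fields are read as depth 0; missing GQ
#' as `NA` (treated as 0 by the genotype-level filters).
#'
#' @param path path to a VCF (plain text or bgzip/gzip).
#' @param verbose passed to [vcfR::read.vcfR()].
#' @return an object of class `tarsvm_sites`: a list with `sites` (one row
#'   per decomposed SNV: `site_id`, `chrom`, `pos`, `ref`, `alt` and the
#'   INFO features), `genotypes` (one row per site x sample: `site_id`,
#'   `sample_id`, `call`, `ref_depth`, `alt_depth`, `gq`), and `samples`.
#' @export
read_sites <- function(path, verbose = FALSE) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = verbose, checkFile = FALSE)
  meta <- v@meta
  if (!any(grepl("^##FORMAT=<ID=AD[,>]", meta)))
    stop("FORMAT field AD is required: the method cannot run without allele depths")
  fix <- v@fix
  gt <- v@gt
  samples <- colnames(gt)[-1]
  n_rec <- nrow(fix)

  info_has <- vapply(INFO_FEATURES, function(key)
    any(grepl(sprintf("^##INFO=<ID=%s[,>]", key), meta)), logical(1))
  info_vals <- lapply(seq_along(INFO_FEATURES), function(i) {
    if (!info_has[i] || n_rec == 0L) return(rep(NA_real_, n_rec))
    suppressWarnings(as.numeric(vcfR::extract.info(v, INFO_FEATURES[i])))
  })
  names(info_vals) <- names(INFO_FEATURES)

  has_gq <- any(grepl("^##FORMAT=<ID=GQ[,>]", meta))
  gt_m <- if (n_rec) vcfR::extract.gt(v, "GT") else NULL
  ad_m <- if (n_rec) vcfR::extract.gt(v, "AD") else NULL
  gq_m <- if (n_rec && has_gq)
    suppressWarnings(vcfR::extract.gt(v, "GQ", as.numeric = TRUE)) else NULL

  sites <- list()
  genos <- list()
  skipped <- character(0)
  for (i in seq_len(n_rec)) {
    ref <- toupper(fix[i, "REF"])
    alts <- toupper(strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]])
    gts <- gt_m[i, ]
    alleles <- strsplit(ifelse(is.na(gts), ".", gts), "[/|]")
    ads <- strsplit(ifelse(is.na(ad_m[i, ]), ".", ad_m[i, ]), ",", fixed = TRUE)
    for (a in seq_along(alts)) {
      alt <- alts[a]
      if (nchar(ref) != 1L || nchar(alt) != 1L ||
          !ref %in% c("A", "C", "G", "T") || !alt %in% c("A", "C", "G", "T")) {
        skipped <- c(skipped, sprintf("%s:%s %s>%s", fix[i, "CHROM"],
                                      fix[i, "POS"], ref, alt))
        next
      }
      copies <- vapply(alleles, function(al) {
        if (any(al == ".") || all(al == "")) return(NA_integer_)
        sum(al == as.character(a))
      }, integer(1))
      call <- ifelse(is.na(copies), "MISSING",
                     c("HOM_REF", "HET", "HOM_ALT")[copies + 1L])
      ref_d <- vapply(ads, function(x) {
        d <- suppressWarnings(as.integer(x[1]))
        if (is.na(d)) 0L else d
      }, integer(1))
      alt_d <- vapply(ads, function(x) {
        d <- if (length(x) >= a + 1L)
          suppressWarnings(as.integer(x[a + 1L])) else NA_integer_
        if (is.na(d)) 0L else d
      }, integer(1))
      gq <- if (is.null(gq_m)) rep(NA_real_, length(samples)) else gq_m[i, ]
      sites[[length(sites) + 1L]] <- data.frame(
        chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
        ref = ref, alt = alt,
        as.data.frame(lapply(info_vals, `[`, i)),
        stringsAsFactors = FALSE)
      genos[[length(genos) + 1L]] <- data.frame(
        sample_id = samples, call = unname(call),
        ref_depth = unname(ref_d), alt_depth = unname(alt_d),
        gq = unname(as.numeric(gq)), stringsAsFactors = FALSE)
    }
  }
  if (length(skipped))
    warning("skipped ", length(skipped), " non-SNV allele(s): ",
            paste(utils::head(skipped, 5L), collapse = ", "),
            if (length(skipped) > 5L) ", ..." else "")

  sites <- if (length(sites)) do.call(rbind, sites) else
    data.frame(chrom = character(0), pos = integer(0), ref = character(0),
               alt = character(0),
               as.data.frame(lapply(info_vals, function(x) numeric(0))))
  ids <- make.unique(site_key(sites$chrom, sites$pos, sites$ref, sites$alt),
                     sep = "#")
  sites <- cbind(site_id = ids, sites, stringsAsFactors = FALSE)
  genotypes <- if (length(genos)) {
    cbind(site_id = rep(ids, each = length(samples)), do.call(rbind, genos),
          stringsAsFactors = FALSE)
  } else {
    data.frame(site_id = character(0), sample_id = character(0),
               call = character(0), ref_depth = integer(0),
               alt_depth = integer(0), gq = numeric(0))
  }
  rownames(sites) <- rownames(genotypes) <- NULL
  structure(list(sites = sites, genotypes = genotypes, samples = samples),
            class = "tarsvm_sites")
}

#' @export
#' @method print tarsvm_sites
print.tarsvm_sites <- function(x, ...) {
  cat("tarsvm_sites:", nrow(x$sites), "SNV site(s),",
      length(x$samples), "sample(s)\n")
  invisible(x)
}

#' Call rate of a site
#'
#' Proportion of samples with a non-missing genotype call.
#'
#' @param calls character vector of calls
#'   (`MISSING`/`HOM_REF`/`HET`/`HOM_ALT`).
#' @param n_samples number of samples assayed (>= 1).
#' @return fraction in \[0, 1\].
#' @export
compute_call_rate <- function(calls, n_samples) {
  if (length(n_samples) != 1L || is.na(n_samples) || n_samples < 1)
    stop("n_samples must be a single value >= 1")
  sum(calls != "MISSING") / n_samples
}

#' Heterozygote allele balance and mean alternate depth
#'
#' Restricted to HET calls: `ab_het` is the pooled alternate depth divided
#' by the pooled total depth across heterozygotes (the default), or the mean
#' of per-sample ratios when `mode = "mean_of_ratios"`; `mean_ad_het` is the
#' mean per-heterozygote alternate depth. Both are `NA` when the site has no
#' heterozygotes or the pooled depth is zero — missing is a value here, not
#' an error.
#'
#' @param calls,ref_depth,alt_depth parallel genotype vectors for one site.
#' @param mode `"pooled"` or `"mean_of_ratios"`.
#' @return list with `ab_het` and `mean_ad_het`.
#' @export
compute_abhet_and_mean_ad <- function(calls, ref_depth, alt_depth,
                                      mode = c("pooled", "mean_of_ratios")) {
  mode <- match.arg(mode)
  het <- calls == "HET"
  if (!any(het)) return(list(ab_het = NA_real_, mean_ad_het = NA_real_))
  a <- alt_depth[het]; r <- ref_depth[het]
  tot <- a + r
  ab <- if (mode == "pooled") {
    if (sum(tot) == 0) NA_real_ else sum(a) / sum(tot)
  } else {
    if (all(tot == 0)) NA_real_ else mean(a[tot > 0] / tot[tot > 0])
  }
  list(ab_het = ab, mean_ad_het = mean(a))
}
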