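# Site-level feature computation: genotype-derived summaries (call rate,
# heterozygote allele balance, mean het alt depth, NAD) joined to the
# caller-provided INFO annotations.

# the ten features the classifier consumes, in fixed order
SVM_FEATURES <- c("call_rate", "qd", "rp_rank_sum", "ab_het", "mean_ad_het",
                  "nad", "inbreeding_coeff", "haplotype_score",
                  "mq_rank_sum", "bq_rank_sum")

#' Names and order of the ten classifier features
#' @return character vector of length 10.
#' @export
svm_feature_names <- function() SVM_FEATURES

#' Compute per-site quality features
#'
#' Adds the genotype-derived features to the site table of a
#' [read_sites()] result: `call_rate`, `ab_het`, `mean_ad_het`,
#' `mean_ad_hom_alt`, `n_het`, and `nad` (the normalized allele dosage score
#' on depths pooled across heterozygotes, normalized by the mean
#' heterozygote alternate depth). `ab_het`, `mean_ad_het` and `nad` are `NA`
#' when the site has no heterozygotes; they are filled later by
#' [impute_features()].
#'
#' @param x a `tarsvm_sites` object.
#' @param abhet_mode `"pooled"` (default) or `"mean_of_ratios"`; see
#'   [compute_abhet_and_mean_ad()].
#' @return data.frame, one row per site, with the columns of `x$sites` plus
#'   the computed features.
#' @export
site_features <- function(x, abhet_mode = c("pooled", "mean_of_ratios")) {
  stopifnot(inherits(x, "tarsvm_sites"))
  abhet_mode <- match.arg(abhet_mode)
  sites <- x$sites
  g <- x$genotypes
  n_samples <- length(x$samples)
  f <- factor(g$site_id, levels = sites$site_id)

  called <- g$call != "MISSING"
  call_rate <- as.numeric(tapply(called, f, sum, default = 0)) / n_samples

  het <- g$call == "HET"
  hom_alt <- g$call == "HOM_ALT"
  n_het <- as.numeric(tapply(het, f, sum, default = 0))
  sum_alt_het <- as.numeric(tapply(ifelse(het, g$alt_depth, 0), f, sum, default = 0))
  sum_tot_het <- as.numeric(tapply(ifelse(het, g$ref_depth + g$alt_depth, 0),
                                   f, sum, default = 0))
  n_hom_alt <- as.numeric(tapply(hom_alt, f, sum, default = 0))
  sum_alt_hom <- as.numeric(tapply(ifelse(hom_alt, g$alt_depth, 0), f, sum, default = 0))

  mean_ad_het <- ifelse(n_het > 0, sum_alt_het / n_het, NA_real_)
  mean_ad_hom_alt <- ifelse(n_hom_alt > 0, sum_alt_hom / n_hom_alt, NA_real_)
  ab_het <- if (abhet_mode == "pooled") {
    ifelse(n_het > 0 & sum_tot_het > 0, sum_alt_het / sum_tot_het, NA_real_)
  } else {
    vapply(split(seq_len(nrow(g)), f), function(idx) {
      compute_abhet_and_mean_ad(g$call[idx], g$ref_depth[idx],
                                g$alt_depth[idx], "mean_of_ratios")$ab_het
    }, numeric(1))
  }

  nad <- rep(NA_real_, nrow(sites))
  ok <- n_het > 0 & sum_tot_het > 0 & mean_ad_het > 0
  if (any(ok))
    nad[ok] <- nad_score(sum_alt_het[ok], sum_tot_het[ok], mean_ad_het[ok])$nad

  cbind(sites,
        data.frame(call_rate = call_rate, ab_het = ab_het,
                   mean_ad_het = mean_ad_het, mean_ad_hom_alt = mean_ad_hom_alt,
                   n_het = n_het, nad = nad))
}

#' Extract the classifier feature matrix
#'
#' @param features data.frame from [site_features()] (possibly after
#'   imputation columns were filled).
#' @return numeric matrix, sites x the ten features of
#'   [svm_feature_names()], rownames = `site_id`.
#' @export
feature_matrix <- function(features) {
  missing_cols <- setdiff(SVM_FEATURES, names(features))
  if (length(missing_cols))
    stop("feature columns missing: ", paste(missing_cols, collapse = ", "))
  m <- as.matrix(features[, SVM_FEATURES])
  rownames(m) <- features$site_id
  m
}
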