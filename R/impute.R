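# Missing-feature imputation before classifier training. Scores can be
# missing when a site's call rate is very low (the caller omits annotations)
# or when a site has no heterozygotes (ABHet, mean het alt depth and NAD are
# undefined). The chain is: (1) regression-based ABHet from QD for
# heterozygote-free sites, (2) pseudo-reference-depth NAD for those sites,
# (3) inverse-normal transform of every column, (4) k-NN (k = 10) for all
# remaining missing cells. Observed cells are never altered.

#' Regression-based ABHet imputation from QD
#'
#' Ordinary least squares of observed ABHet on observed QD; missing ABHet is
#' replaced by the fitted value, clipped to \[0.01, 0.99\]. With fewer than
#' two complete pairs or zero QD variance the observed-ABHet mean is used
#' instead (with a warning).
#'
#' @param m numeric matrix with columns named as [svm_feature_names()]
#'   (missing cells `NA`).
#' @return the matrix with `ab_het` filled where it was missing.
#' @export
impute_abhet_from_qd <- function(m) {
  ab <- m[, "ab_het"]; qd <- m[, "qd"]
  miss <- is.na(ab)
  if (!any(miss)) return(m)
  obs <- !is.na(ab) & !is.na(qd)
  pred <- if (sum(obs) < 2L || stats::var(qd[obs]) == 0) {
    warning("too few complete (ABHet, QD) pairs for regression; ",
            "falling back to the observed ABHet mean")
    rep(mean(ab, na.rm = TRUE), sum(miss))
  } else {
    fit <- stats::lm(ab[obs] ~ qd[obs])
    coef(fit)[1] + coef(fit)[2] * qd[miss]
  }
  pred[is.na(pred)] <- mean(ab, na.rm = TRUE)  # sites with QD also missing
  m[miss, "ab_het"] <- pmin(0.99, pmax(0.01, pred))
  m
}

#' Pseudo-depth NAD for heterozygote-free sites
#'
#' For rows whose NAD is missing because the site had no heterozygotes, the
#' imputed ABHet and the mean homozygote-alternate depth yield a pseudo
#' reference depth from which the NAD is computed
#' ([nad_from_homozygotes()]); `mean_ad_het` is filled with the homozygote
#' depth. Rows with heterozygotes are untouched; het-free rows without a
#' homozygote-alternate depth fall through (with a warning) to k-NN.
#'
#' @param m feature matrix after [impute_abhet_from_qd()].
#' @param mean_ad_hom_alt per-row mean homozygote-alt depth (`NA` if none).
#' @param n_het per-row heterozygote count.
#' @return the matrix with `nad` and `mean_ad_het` filled where possible.
#' @export
impute_nad_for_no_het_sites <- function(m, mean_ad_hom_alt, n_het) {
  target <- n_het == 0 & is.na(m[, "nad"])
  can <- target & !is.na(mean_ad_hom_alt) & mean_ad_hom_alt > 0 &
    !is.na(m[, "ab_het"]) & m[, "ab_het"] > 0 & m[, "ab_het"] < 1
  if (any(target & !can))
    warning(sum(target & !can), " heterozygote-free site(s) lack a ",
            "homozygote-alt depth; their NAD falls through to k-NN")
  if (any(can)) {
    sc <- nad_from_homozygotes(mean_ad_hom_alt[can], m[can, "ab_het"])
    m[can, "nad"] <- sc$nad
    fill_ad <- can & is.na(m[, "mean_ad_het"])
    m[fill_ad, "mean_ad_het"] <- mean_ad_hom_alt[fill_ad]
  }
  m
}

#' Rank-based inverse normal transform
#'
#' Observed values are replaced by standard-normal quantiles of their
#' fractional ranks, `qnorm((rank - 0.5) / m)` with average ranks for ties
#' (`m` = number observed); missing cells stay missing. The transform is
#' rank-preserving.
#'
#' @param x numeric vector, possibly with `NA`.
#' @return transformed vector.
#' @export
inverse_normal_transform <- function(x) {
  obs <- !is.na(x)
  if (!any(obs)) return(x)
  r <- rank(x[obs], ties.method = "average")
  x[obs] <- qnorm((r - 0.5) / sum(obs))
  x
}

#' k-nearest-neighbour imputation
#'
#' Each missing cell is the mean of its column over the `k` rows nearest to
#' the target row, among rows observed in that column. Distance is Euclidean
#' over the mutually observed columns, scaled by the number of shared
#' columns (root mean squared difference) so rows with different missingness
#' are comparable; ties are broken by row index. Rows sharing no observed
#' column with a candidate exclude that candidate; if no candidate remains
#' (or the target row has no observed columns) the column mean is used. An
#' entirely missing column is an error.
#'
#' @param m numeric matrix (rows = sites, columns = features), typically
#'   already inverse-normal transformed.
#' @param k neighbourhood size (default 10); effectively
#'   `min(k, candidates)`.
#' @return the matrix with no missing cells.
#' @export
knn_impute <- function(m, k = 10) {
  all_missing <- colSums(!is.na(m)) == 0
  if (any(all_missing))
    stop("column(s) entirely missing: ",
         paste(colnames(m)[all_missing], collapse = ", "))
  obs <- !is.na(m)
  col_means <- colMeans(m, na.rm = TRUE)
  out <- m
  need <- which(rowSums(!obs) > 0)
  for (i in need) {
    oi <- obs[i, ]
    if (!any(oi)) {
      out[i, ] <- ifelse(oi, m[i, ], col_means)
      next
    }
    diffs <- sweep(m[, oi, drop = FALSE], 2, m[i, oi], `-`)
    shared <- rowSums(!is.na(diffs))
    d <- sqrt(rowSums(diffs^2, na.rm = TRUE) / shared)
    d[i] <- Inf
    d[shared == 0] <- Inf
    for (j in which(!oi)) {
      cand <- which(obs[, j] & is.finite(d))
      if (!length(cand)) {
        out[i, j] <- col_means[j]
        next
      }
      ord <- cand[order(d[cand], cand)]
      nb <- ord[seq_len(min(k, length(ord)))]
      out[i, j] <- mean(m[nb, j])
    }
  }
  out
}

#' Run the full imputation chain on a feature table
#'
#' Applies, in order: ABHet-from-QD regression, pseudo-depth NAD for
#' heterozygote-free sites (both on the raw scale, so the bespoke scheme
#' takes precedence), the inverse normal transform of each column, and k-NN
#' for every cell still missing. The classifier consumes the
#' inverse-normal scale by default; `transform = "raw"` skips the transform
#' and k-NN then runs on raw features.
#'
#' @param features data.frame from [site_features()].
#' @param k k-NN neighbourhood size.
#' @param transform `"inverse_normal"` (default) or `"raw"`.
#' @return list with `matrix` (fully imputed, sites x ten features) and
#'   `raw` (the matrix after the raw-scale steps, still possibly missing).
#' @export
impute_features <- function(features, k = 10,
                            transform = c("inverse_normal", "raw")) {
  transform <- match.arg(transform)
  m <- feature_matrix(features)
  m <- impute_abhet_from_qd(m)
  m <- impute_nad_for_no_het_sites(m, features$mean_ad_hom_alt, features$n_het)
  raw <- m
  if (transform == "inverse_normal")
    for (j in seq_len(ncol(m))) m[, j] <- inverse_normal_transform(m[, j])
  m <- knn_impute(m, k = k)
  list(matrix = m, raw = raw)
}
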