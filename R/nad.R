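#' Two-sided exact binomial p-value under a 50% null
#'
#' Exact two-sided p-value for observing `k` successes in `n` trials under
#' Binomial(n, 0.5), using the minimum-likelihood convention: the sum of
#' P(X = j) over all j whose probability does not exceed P(X = k). Because
#' the null pmf is symmetric and strictly unimodal, that set is exactly the
#' two mirror tails, so the p-value has the closed form
#' `min(1, 2 * pbinom(min(k, n - k), n, 0.5))`, which is numerically stable
#' at arbitrary depth. At this symmetric null the tail-doubling convention
#' gives the identical value, so the two conventions share one code path.
#'
#' @param k integer vector of successes, `0 <= k <= n`.
#' @param n integer vector of trials, `n >= 1`; recycled against `k`.
#' @return numeric vector of p-values in (0, 1].
#' @examples
#' binom_two_sided_p(5, 10)   # 1: the most likely outcome under the null
#' binom_two_sided_p(1, 10)   # 22/1024
#' @export
binom_two_sided_p <- function(k, n) {
  if (length(k) == 0L) return(numeric(0))
  kk <- rep_len(as.numeric(k), max(length(k), length(n)))
  nn <- rep_len(as.numeric(n), max(length(k), length(n)))
  if (any(is.na(kk)) || any(is.na(nn))) stop("k and n must be non-missing")
  if (any(nn < 1)) stop("n must be at least 1")
  if (any(kk < 0) || any(kk > nn)) stop("k must satisfy 0 <= k <= n")
  m <- pmin(kk, nn - kk)
  ifelse(2 * m == nn, 1, pmin(1, 2 * pbinom(m, nn, 0.5)))
}

#' NAD: normalized allele dosage score
#'
#' Site-level allele-balance statistic for heterozygotes. The null
#' hypothesis is a 50% allele balance; the alternative is any other balance.
#' The exact binomial p-value on the pooled heterozygote depths is placed on
#' the PHRED scale (-10 log10 p) and normalized by the mean heterozygote
#' alternate-allele depth, because at high depth the p-value shrinks for the
#' same allele balance. Low NAD is consistent with a true heterozygote.
#'
#' @param alt_total summed alternate-allele depth across heterozygotes.
#' @param total summed alternate + reference depth across heterozygotes.
#' @param norm_depth normalizing depth (> 0), by default the mean
#'   heterozygote alternate-allele depth.
#' @param p_floor p-values are floored here before the log so that the
#'   PHRED score stays finite (default `1e-300`, i.e. PHRED <= 3000).
#' @return data.frame with columns `p_value`, `phred`, `nad`.
#' @examples
#' nad_score(5, 10, 5)    # perfect balance: nad 0
#' nad_score(1, 10, 1)    # skewed singleton het
#' @seealso [binom_two_sided_p()], [nad_from_homozygotes()]
#' @export
nad_score <- function(alt_total, total, norm_depth, p_floor = 1e-300) {
  if (any(norm_depth <= 0, na.rm = TRUE) || any(is.na(norm_depth)))
    stop("norm_depth must be positive")
  p <- binom_two_sided_p(alt_total, total)
  phred <- -10 * log10(pmax(p, p_floor))
  data.frame(p_value = p, phred = phred, nad = phred / norm_depth)
}

# round half away from zero (values here are non-negative)
round_half_up <- function(x) floor(x + 0.5)

#' NAD for a site without heterozygotes, via a pseudo reference depth
#'
#' Sites carried only by homozygous-alternate samples have no heterozygote
#' depths to test. Given the mean homozygote alternate depth and an imputed
#' allele balance, a pseudo mean reference depth
#' `round(mean_ad_hom_alt * (1 - ab) / ab)` is constructed and the NAD is
#' computed on the pseudo counts, normalized by `mean_ad_hom_alt`.
#'
#' @param mean_ad_hom_alt mean alternate-allele depth over homozygous-alt
#'   genotypes (> 0).
#' @param ab_het_imputed imputed allele balance, strictly inside (0, 1).
#' @param p_floor see [nad_score()].
#' @return data.frame as [nad_score()]; `nad` is `NA` in the degenerate case
#'   where both rounded pseudo-counts are zero.
#' @examples
#' nad_from_homozygotes(20, 0.5)    # balanced pseudo-counts: nad 0
#' nad_from_homozygotes(30, 0.75)   # k = 30, n = 40
#' @export
nad_from_homozygotes <- function(mean_ad_hom_alt, ab_het_imputed,
                                 p_floor = 1e-300) {
  if (any(is.na(mean_ad_hom_alt)) || any(mean_ad_hom_alt <= 0))
    stop("mean_ad_hom_alt must be positive")
  if (any(is.na(ab_het_imputed)) ||
      any(ab_het_imputed <= 0) || any(ab_het_imputed >= 1))
    stop("ab_het_imputed must be strictly between 0 and 1")
  k <- round_half_up(mean_ad_hom_alt)
  pseudo_ref <- round_half_up(mean_ad_hom_alt * (1 - ab_het_imputed) / ab_het_imputed)
  n <- k + pseudo_ref
  out <- data.frame(p_value = NA_real_, phred = NA_real_,
                    nad = rep(NA_real_, length(n)))
  ok <- n >= 1
  if (any(ok)) {
    sc <- nad_score(k[ok], n[ok], mean_ad_hom_alt[ok], p_floor = p_floor)
    out[ok, ] <- sc
  }
  out
}
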