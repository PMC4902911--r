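# The nine site-level hard filters whose failure count drives training-label
# selection. All bounds are inclusive; a missing feature is NOT_EVALUABLE and
# never counts as a failure (low-call-rate sites are handled by the explicit
# call-rate rules instead).

HARD_FILTER_NAMES <- c("QD", "MQ", "MQRankSum", "RPRankSum", "ABHet", "AD",
                       "BQRankSum", "CallRate", "NAD")

#' Default thresholds for the nine hard filters
#'
#' GATK-best-practice-style thresholds adjusted for the high-duplicate
#' amplicon regime: QD >= 3, MQ >= 50, -3 <= MQRankSum <= 10,
#' ReadPosRankSum >= -20, 0.20 <= ABHet <= 0.80, mean heterozygote alt
#' depth >= 10, BaseQRankSum >= -40, call rate >= 0.80, NAD <= 5.
#' Every bound is overridable per run.
#'
#' @param qd_min,mq_min,mq_rank_sum_min,mq_rank_sum_max,rp_rank_sum_min
#'   numeric bounds.
#' @param ab_het_min,ab_het_max,ad_het_min,bq_rank_sum_min,call_rate_min,nad_max
#'   numeric bounds.
#' @return named list of thresholds.
#' @export
hard_filter_thresholds <- function(qd_min = 3, mq_min = 50,
                                   mq_rank_sum_min = -3, mq_rank_sum_max = 10,
                                   rp_rank_sum_min = -20,
                                   ab_het_min = 0.20, ab_het_max = 0.80,
                                   ad_het_min = 10, bq_rank_sum_min = -40,
                                   call_rate_min = 0.80, nad_max = 5) {
  list(qd_min = qd_min, mq_min = mq_min, mq_rank_sum_min = mq_rank_sum_min,
       mq_rank_sum_max = mq_rank_sum_max, rp_rank_sum_min = rp_rank_sum_min,
       ab_het_min = ab_het_min, ab_het_max = ab_het_max,
       ad_het_min = ad_het_min, bq_rank_sum_min = bq_rank_sum_min,
       call_rate_min = call_rate_min, nad_max = nad_max)
}

filter_outcome <- function(ok) {
  ifelse(is.na(ok), "NOT_EVALUABLE", ifelse(ok, "PASS", "FAIL"))
}

#' Evaluate the nine hard filters per site
#'
#' @param features data.frame from [site_features()] (needs columns `qd`,
#'   `mq`, `mq_rank_sum`, `rp_rank_sum`, `ab_het`, `mean_ad_het`,
#'   `bq_rank_sum`, `call_rate`, `nad`; `site_id` is carried through when
#'   present).
#' @param thresholds list from [hard_filter_thresholds()].
#' @return data.frame with one `PASS`/`FAIL`/`NOT_EVALUABLE` column per
#'   filter (`QD`, `MQ`, `MQRankSum`, `RPRankSum`, `ABHet`, `AD`,
#'   `BQRankSum`, `CallRate`, `NAD`) plus `n_failed`, the number of FAIL
#'   outcomes.
#' @export
hard_filter_report <- function(features, thresholds = hard_filter_thresholds()) {
  t <- thresholds
  out <- data.frame(
    QD = filter_outcome(features$qd >= t$qd_min),
    MQ = filter_outcome(features$mq >= t$mq_min),
    MQRankSum = filter_outcome(features$mq_rank_sum >= t$mq_rank_sum_min &
                               features$mq_rank_sum <= t$mq_rank_sum_max),
    RPRankSum = filter_outcome(features$rp_rank_sum >= t$rp_rank_sum_min),
    ABHet = filter_outcome(features$ab_het >= t$ab_het_min &
                           features$ab_het <= t$ab_het_max),
    AD = filter_outcome(features$mean_ad_het >= t$ad_het_min),
    BQRankSum = filter_outcome(features$bq_rank_sum >= t$bq_rank_sum_min),
    CallRate = filter_outcome(features$call_rate >= t$call_rate_min),
    NAD = filter_outcome(features$nad <= t$nad_max),
    stringsAsFactors = FALSE)
  out$n_failed <- rowSums(out == "FAIL")
  if (!is.null(features$site_id))
    out <- cbind(site_id = features$site_id, out, stringsAsFactors = FALSE)
  out
}
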