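# Independent oracles used across the suite. These deliberately do not share
# code with the package: the p-value oracle enumerates the binomial pmf, the
# label oracle re-derives the cascade from its verbal description, and the
# k-NN oracle is a plain double loop.

# minimum-likelihood two-sided p by brute-force pmf enumeration
enum_binom_p <- function(k, n) {
  d <- dbinom(0:n, n, 0.5)
  sum(d[d <= d[k + 1] * (1 + 1e-9)])
}

# label cascade re-stated independently
oracle_label <- function(n_failed, call_rate, kg, exac, dbsnp) {
  if (n_failed >= 3 || call_rate < 0.5) return("LIKELY_FALSE")
  verdict <- if (kg != "ABSENT") kg else if (exac != "ABSENT") exac else NA
  if (n_failed == 2) {
    if (!is.na(verdict))
      return(if (verdict == "PASS") "UNKNOWN" else "LIKELY_FALSE")
    return(if (dbsnp) "UNKNOWN" else "LIKELY_FALSE")
  }
  if (!is.na(verdict))
    return(if (verdict == "PASS") "LIKELY_TRUE" else "LIKELY_FALSE")
  if (n_failed == 0 && dbsnp) return("LIKELY_TRUE")
  "UNKNOWN"
}

# brute-force k-NN mean for one missing cell (same distance definition:
# root-mean-square difference over mutually observed columns)
oracle_knn_cell <- function(m, i, j, k = 10) {
  d <- rep(Inf, nrow(m))
  for (r in seq_len(nrow(m))) {
    if (r == i || is.na(m[r, j])) next
    shared <- !is.na(m[i, ]) & !is.na(m[r, ])
    if (!any(shared)) next
    d[r] <- sqrt(mean((m[i, shared] - m[r, shared])^2))
  }
  ord <- order(d, seq_along(d))
  nb <- ord[is.finite(d[ord])][seq_len(min(k, sum(is.finite(d))))]
  mean(m[nb, j])
}

# a baseline feature row comfortably inside every hard-filter bound
interior_features <- function(n = 1) {
  data.frame(qd = rep(10, n), mq = 60, mq_rank_sum = 0, rp_rank_sum = 0,
             ab_het = 0.5, mean_ad_het = 50, bq_rank_sum = 0,
             call_rate = 0.99, nad = 0)
}

# write a small VCF from record lines (header built by the package)
write_test_vcf <- function(records, samples = c("S1", "S2", "S3"),
                           path = tempfile(fileext = ".vcf"),
                           drop_ad_header = FALSE) {
  hdr <- tarsvm:::vcf_header_lines(samples)
  if (drop_ad_header) hdr <- hdr[!grepl("ID=AD", hdr)]
  writeLines(c(hdr, records), path)
  path
}

site_key <- tarsvm:::site_key

vrec <- function(chrom, pos, ref, alt, info, ...) {
  paste(c(chrom, pos, ".", ref, alt, ".", ".", info, "GT:AD:GQ", ...),
        collapse = "\t")
}
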