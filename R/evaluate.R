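# Evaluation harness: confusion counts and derived metrics of any site
# filter against a validation truth set (Sanger- or array-confirmed sites).
# Site-level truth: a site is true iff at least one variant at it validated.

#' Confusion counts of a filter against a truth set
#'
#' Counts are over truth-set keys only (sites outside the truth set are
#' ignored); a truth site absent from the decisions counts as FILTERED.
#'
#' @param decisions data.frame with `chrom`, `pos`, `ref`, `alt` and
#'   `decision` (`PASS`/`FILTERED`).
#' @param truth data.frame with `chrom`, `pos`, `ref`, `alt` and
#'   `validated` (logical or 0/1).
#' @return named integer vector `c(tp, fp, tn, fn)`.
#' @export
confusion_counts <- function(decisions, truth) {
  if (is.null(truth) || nrow(truth) == 0L) stop("truth set is empty")
  tk <- site_key(truth$chrom, truth$pos, truth$ref, truth$alt)
  dk <- site_key(decisions$chrom, decisions$pos, decisions$ref, decisions$alt)
  d <- decisions$decision[match(tk, dk)]
  pass <- !is.na(d) & d == "PASS"
  val <- as.logical(truth$validated)
  c(tp = sum(val & pass), fp = sum(!val & pass),
    tn = sum(!val & !pass), fn = sum(val & !pass))
}

#' Sensitivity, specificity, FDR and accuracy from confusion counts
#'
#' sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), FDR = FP/(FP+TP),
#' accuracy = (TP+TN)/(TP+FP+TN+FN). A ratio with a zero denominator is
#' `NA` (undefined), never 0. Raw fractions are kept unrounded;
#' [percent()] gives the round-half-up integer-percent presentation.
#'
#' @param tp,fp,tn,fn non-negative counts; `tp` may also be a named vector
#'   as returned by [confusion_counts()].
#' @return object of class `tarsvm_eval`: list with the counts and the four
#'   fractions.
#' @export
metrics <- function(tp, fp = NULL, tn = 0, fn = 0) {
  if (length(tp) == 4L && is.null(fp)) {
    fp <- tp[["fp"]]; tn <- tp[["tn"]]; fn <- tp[["fn"]]; tp <- tp[["tp"]]
  }
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || sum(counts) < 1) stop("counts must be non-negative with sum >= 1")
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = ratio(tp, tp + fn),
                 specificity = ratio(tn, tn + fp),
                 fdr = ratio(fp, fp + tp),
                 accuracy = ratio(tp + tn, sum(counts))),
            class = "tarsvm_eval")
}

#' Round-half-up integer percent
#' @param x fraction(s) in \[0, 1\].
#' @param digits decimal places of the percentage (default 0).
#' @return numeric percent value(s).
#' @export
percent <- function(x, digits = 0) {
  s <- 10^digits
  floor(x * 100 * s + 0.5) / s
}

#' @export
#' @method print tarsvm_eval
print.tarsvm_eval <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  TN %d  FN %d\n", x$tp, x$fp, x$tn, x$fn))
  show <- function(v) if (is.na(v)) "undefined" else
    sprintf("%g%% (%.4f)", percent(v), v)
  cat("  sensitivity:", show(x$sensitivity), "\n")
  cat("  specificity:", show(x$specificity), "\n")
  cat("  FDR:        ", show(x$fdr), "\n")
  cat("  accuracy:   ", show(x$accuracy), "\n")
  invisible(x)
}

#' Evaluate a filter strategy against a truth table
#'
#' Convenience wrapper: [confusion_counts()] then [metrics()].
#'
#' @inheritParams confusion_counts
#' @return a `tarsvm_eval` object.
#' @export
evaluate_filter <- function(decisions, truth) {
  metrics(confusion_counts(decisions, truth))
}
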