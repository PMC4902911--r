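# The site classifier: a C-support-vector machine (LIBSVM via e1071) with a
# radial-basis kernel on the ten standardized features, trained on the
# LIKELY_TRUE vs LIKELY_FALSE sites only, then used to label every site.

#' Train the site classifier
#'
#' Fits a C-classification SVM with a radial-basis kernel on the rows
#' labelled `LIKELY_TRUE` or `LIKELY_FALSE` (UNKNOWN rows are excluded from
#' fitting but are still classified by [tarsvm_predict()]). Features are
#' standardized inside the fit using training rows only. Defaults are the
#' LIBSVM defaults: cost 1, gamma 1 / (number of features), no class
#' weighting.
#'
#' @param m fully imputed feature matrix (sites x features, rownames =
#'   site ids), e.g. `impute_features(...)$matrix`.
#' @param labels character vector of training labels parallel to the rows.
#' @param seed integer seed (the fit itself is deterministic; the seed is
#'   recorded and set for reproducibility of any downstream randomness).
#' @param cost,gamma SVM hyperparameters.
#' @param class_weights optional named weights passed to [e1071::svm()].
#' @param min_per_class minimum training rows required in each class.
#' @return object of class `tarsvm_model`.
#' @export
tarsvm_train <- function(m, labels, seed = 13, cost = 1, gamma = 1 / ncol(m),
                         class_weights = NULL, min_per_class = 10) {
  stopifnot(nrow(m) == length(labels))
  if (any(is.na(m))) stop("feature matrix must be fully imputed before training")
  train <- labels %in% c("LIKELY_TRUE", "LIKELY_FALSE")
  n_true <- sum(labels == "LIKELY_TRUE")
  n_false <- sum(labels == "LIKELY_FALSE")
  if (n_true < min_per_class || n_false < min_per_class)
    stop(sprintf(paste0("insufficient training examples: %d LIKELY_TRUE and ",
                        "%d LIKELY_FALSE (need >= %d each)"),
                 n_true, n_false, min_per_class))
  set.seed(seed)
  y <- factor(labels[train], levels = c("LIKELY_FALSE", "LIKELY_TRUE"))
  fit <- e1071::svm(x = m[train, , drop = FALSE], y = y,
                    type = "C-classification", kernel = "radial",
                    cost = cost, gamma = gamma, scale = TRUE,
                    class.weights = class_weights)
  # orient decision values so positive = LIKELY_TRUE side
  dv <- attr(predict(fit, m[train, , drop = FALSE], decision.values = TRUE),
             "decision.values")[, 1]
  sign_flip <- if (mean(dv[y == "LIKELY_TRUE"]) >= mean(dv[y == "LIKELY_FALSE"]))
    1 else -1
  structure(list(fit = fit, features = colnames(m), sign = sign_flip,
                 n_true = n_true, n_false = n_false, seed = seed,
                 cost = cost, gamma = gamma),
            class = "tarsvm_model")
}

#' @export
#' @method print tarsvm_model
print.tarsvm_model <- function(x, ...) {
  cat("tarsvm_model: radial-basis SVM on", length(x$features), "features;",
      x$n_true, "LIKELY_TRUE /", x$n_false, "LIKELY_FALSE training sites;",
      "cost", x$cost, "gamma", signif(x$gamma, 4), "\n")
  invisible(x)
}

#' Classify every site PASS / FILTERED
#'
#' @param model a `tarsvm_model`.
#' @param m feature matrix with exactly the training-time columns, in the
#'   same order.
#' @param training_labels optional vector carried into the output for audit.
#' @return data.frame with `site_id`, `label` (`PASS`/`FILTERED`) and
#'   `decision_value` (signed distance to the boundary, positive on the
#'   PASS side).
#' @export
tarsvm_predict <- function(model, m, training_labels = NULL) {
  stopifnot(inherits(model, "tarsvm_model"))
  if (!identical(colnames(m), model$features))
    stop("feature columns do not match the training feature order")
  ids <- if (is.null(rownames(m))) as.character(seq_len(nrow(m))) else rownames(m)
  if (nrow(m) == 0L)
    return(data.frame(site_id = character(0), label = character(0),
                      decision_value = numeric(0)))
  if (any(is.na(m))) stop("feature matrix must be fully imputed")
  pr <- predict(model$fit, m, decision.values = TRUE)
  dv <- attr(pr, "decision.values")[, 1] * model$sign
  out <- data.frame(site_id = ids,
                    label = ifelse(pr == "LIKELY_TRUE", "PASS", "FILTERED"),
                    decision_value = unname(dv), stringsAsFactors = FALSE)
  if (!is.null(training_labels)) out$training_label <- training_labels
  out
}
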