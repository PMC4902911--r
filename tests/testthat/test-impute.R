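# The imputation chain: ABHet-from-QD regression, pseudo-depth NAD,
# inverse normal transform, k-NN.

blank_matrix <- function(n) {
  m <- matrix(0, n, length(svm_feature_names()),
              dimnames = list(NULL, svm_feature_names()))
  m
}

test_that("ABHet regression recovers the line through two training points", {
  m <- blank_matrix(3)
  m[, "qd"] <- c(10, 20, 15)
  m[, "ab_het"] <- c(0.5, 0.7, NA)
  out <- impute_abhet_from_qd(m)
  expect_equal(unname(out[3, "ab_het"]), 0.6)
  expect_equal(out[1:2, "ab_het"], c(0.5, 0.7))  # observed untouched
})

test_that("ABHet regression is a no-op when nothing is missing, clips wild predictions, and falls back on degenerate fits", {
  m <- blank_matrix(2); m[, "qd"] <- c(10, 20); m[, "ab_het"] <- c(0.5, 0.7)
  expect_identical(impute_abhet_from_qd(m), m)
  m2 <- blank_matrix(3)
  m2[, "qd"] <- c(10, 20, 60)   # fitted 0.02*60 + 0.3 = 1.5 -> clip
  m2[, "ab_het"] <- c(0.5, 0.7, NA)
  expect_equal(unname(impute_abhet_from_qd(m2)[3, "ab_het"]), 0.99)
  m3 <- blank_matrix(3)
  m3[, "qd"] <- c(10, 10, 15)   # zero QD variance
  m3[, "ab_het"] <- c(0.4, 0.6, NA)
  expect_warning(out <- impute_abhet_from_qd(m3), "falling back")
  expect_equal(unname(out[3, "ab_het"]), 0.5)
})

test_that("pseudo-depth NAD fills het-free sites and leaves others alone", {
  m <- blank_matrix(3)
  m[, "ab_het"] <- c(0.5, 0.5, 0.5)
  m[, "nad"] <- c(NA, 2, NA)
  m[, "mean_ad_het"] <- c(NA, 30, NA)
  expect_warning(
    out <- impute_nad_for_no_het_sites(m, mean_ad_hom_alt = c(20, NA, NA),
                                       n_het = c(0, 3, 0)),
    "falls through")
  expect_equal(unname(out[1, "nad"]), 0)          # balanced pseudo-counts
  expect_equal(unname(out[1, "mean_ad_het"]), 20)
  expect_equal(unname(out[2, "nad"]), 2)          # site with heterozygotes untouched
  expect_true(is.na(out[3, "nad"]))       # no hom-alt depth: falls through
})

test_that("inverse normal transform maps ranks to normal quantiles", {
  expect_equal(inverse_normal_transform(c(1, 2, 3)),
               qnorm(c(1, 3, 5) / 6))
  expect_equal(inverse_normal_transform(7), 0)
  expect_equal(inverse_normal_transform(c(5, 5)), c(0, 0))
  x <- c(3, NA, 1, 10)
  out <- inverse_normal_transform(x)
  expect_true(is.na(out[2]))
  expect_equal(order(out[-2]), order(x[-2]))  # rank preserving
})

test_that("k-NN imputation matches a brute-force oracle on a 12-row fixture", {
  set.seed(11)
  m <- matrix(rnorm(12 * 4), 12, 4, dimnames = list(NULL, paste0("f", 1:4)))
  m[1, 2] <- NA
  out <- knn_impute(m, k = 10)
  expect_equal(unname(out[1, 2]), oracle_knn_cell(m, 1, 2, k = 10))
  expect_equal(out[-1, ], m[-1, ])
})

test_that("k-NN handles the degenerate cases the contract names", {
  m <- matrix(rnorm(20), 5, 4, dimnames = list(NULL, paste0("f", 1:4)))
  expect_identical(knn_impute(m), m)             # complete: no-op
  m2 <- matrix(rep(c(1, 2, 3, 4), each = 3), 3, 4,
               dimnames = list(NULL, paste0("f", 1:4)))
  m2[2, 3] <- NA
  expect_equal(unname(knn_impute(m2)[2, 3]), 3)          # identical rows share value
  m3 <- m; m3[, 2] <- NA
  expect_error(knn_impute(m3), "f2")             # names the dead column
})

test_that("no observed cell is ever modified by the full chain", {
  set.seed(21)
  for (rep in 1:40) {
    n <- 15
    feats <- data.frame(site_id = as.character(1:n),
                        call_rate = runif(n), qd = rnorm(n, 10, 3),
                        rp_rank_sum = rnorm(n), ab_het = runif(n, 0.2, 0.8),
                        mean_ad_het = runif(n, 5, 50), nad = abs(rnorm(n)),
                        inbreeding_coeff = rnorm(n, 0, 0.1),
                        haplotype_score = abs(rnorm(n, 2)),
                        mq_rank_sum = rnorm(n), bq_rank_sum = rnorm(n),
                        mean_ad_hom_alt = runif(n, 5, 50), n_het = 1L)
    mask <- matrix(runif(n * 10) < 0.2, n, 10)
    mask[1, ] <- FALSE  # keep every column alive
    raw <- feature_matrix(feats)
    raw[mask] <- NA
    for (col in svm_feature_names()) feats[[col]] <- raw[, colnames(raw) == col]
    imp <- suppressWarnings(impute_features(feats))
    expect_false(anyNA(imp$matrix))
    # observed cells survive on the raw scale...
    expect_equal(imp$raw[!mask], raw[!mask])
    # ...and occupy the same rank-derived positions after the transform
    int_direct <- raw
    int_direct[, "ab_het"] <- imp$raw[, "ab_het"]
    int_direct[, "nad"] <- imp$raw[, "nad"]
    int_direct[, "mean_ad_het"] <- imp$raw[, "mean_ad_het"]
    for (j in seq_len(ncol(int_direct)))
      int_direct[, j] <- inverse_normal_transform(int_direct[, j])
    expect_equal(imp$matrix[!is.na(int_direct)],
                 int_direct[!is.na(int_direct)])
  }
})
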