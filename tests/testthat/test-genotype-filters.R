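# Genotype-level filters and the published site-level baseline.

test_that("the pipeline genotype filter keeps exactly the published boundary", {
  d <- tarsvm_genotype_filter(
    call = c("HET", "HET", "HOM_ALT", "HET", "HOM_REF", "MISSING"),
    ref_depth = c(45, 20, 0, 0, 50, 0),
    alt_depth = c(5, 20, 5, 0, 0, 0),
    gq = c(40, 39, 50, 45, NA, NA))
  expect_equal(d$action, c("KEEP", "SET_MISSING", "KEEP", "SET_MISSING",
                           "KEEP", "KEEP"))
  expect_equal(d$failed_criteria[2], "GQ")
  expect_equal(d$failed_criteria[4], "AD,AB")  # zero-depth het fails AB
})

test_that("missing GQ counts as zero for considered calls", {
  d <- tarsvm_genotype_filter("HET", 30, 30, NA)
  expect_equal(d$action, "SET_MISSING")
  expect_equal(d$failed_criteria, "GQ")
})

test_that("the genotype filter is idempotent", {
  call <- c("HET", "HET", "HOM_ALT")
  rd <- c(45, 20, 0); ad <- c(5, 20, 10); gq <- c(40, 10, 90)
  d <- tarsvm_genotype_filter(call, rd, ad, gq)
  call2 <- ifelse(d$action == "SET_MISSING", "MISSING", call)
  rd2 <- ifelse(call2 == "MISSING", 0, rd)
  ad2 <- ifelse(call2 == "MISSING", 0, ad)
  d2 <- tarsvm_genotype_filter(call2, rd2, ad2, gq)
  expect_true(all(d2$action[call2 == "MISSING"] == "KEEP"))
  expect_equal(d2$action[call2 != "MISSING"], d$action[call2 != "MISSING"])
})

test_that("default and stringent depth filters follow their thresholds", {
  expect_equal(default_genotype_filter("HET", 10, 10)$action, "PASS")
  expect_equal(default_genotype_filter("HET", 10, 9)$action, "FAIL")
  expect_equal(default_genotype_filter("HOM_ALT", 64, 15)$action, "FAIL")
  expect_equal(default_genotype_filter("HOM_ALT", 64, 15,
                                       ab_rule = "het")$action, "PASS")
  expect_equal(stringent_genotype_filter("HET", 30, 30)$action, "PASS")
  expect_equal(stringent_genotype_filter("HET", 30, 29)$action, "FAIL")
  expect_equal(stringent_genotype_filter("HET", 35, 35)$action, "PASS")
  # under the literal homozygous reading the AB clause binds HOM_ALT only
  expect_equal(default_genotype_filter("HOM_ALT", 64, 15,
                                       ab_rule = "hom")$action, "FAIL")
  expect_equal(default_genotype_filter("HET", 64, 15,
                                       ab_rule = "hom")$action, "PASS")
})

test_that("any genotype failing the default filter also fails the stringent", {
  set.seed(3)
  call <- sample(c("HET", "HOM_ALT"), 200, replace = TRUE)
  rd <- sample(0:100, 200, replace = TRUE)
  ad <- sample(0:100, 200, replace = TRUE)
  for (rule in c("both", "hom", "het")) {
    dflt <- default_genotype_filter(call, rd, ad, rule)$action
    strg <- stringent_genotype_filter(call, rd, ad, rule)$action
    expect_true(all(strg[dflt == "FAIL"] == "FAIL"))
  }
})

test_that("the GATK best-practice hard filter triggers per clause, inclusively", {
  f <- function(qd = 10, fs = 10, mq = 55, mqrs = 0, rprs = 0)
    data.frame(qd = qd, fs = fs, mq = mq, mq_rank_sum = mqrs,
               rp_rank_sum = rprs)
  expect_equal(gatk_default_hard_filter(f(qd = 1.9)), "FAIL")
  expect_equal(gatk_default_hard_filter(f(fs = 61)), "FAIL")
  expect_equal(gatk_default_hard_filter(f(mq = 39.9)), "FAIL")
  expect_equal(gatk_default_hard_filter(f(qd = 2, fs = 60, mq = 40,
                                          mqrs = -12.5, rprs = -8)), "PASS")
  expect_equal(gatk_default_hard_filter(f(qd = NA)), "PASS")  # missing can't trigger
})
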