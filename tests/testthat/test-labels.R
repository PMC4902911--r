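# Resource loading and the training-label cascade.

test_that("TSV resources load and unlisted keys report ABSENT", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tref\talt\tstatus",
               "1\t100\tA\tG\tPASS", "chr2\t200\tC\tT\tFAIL",
               "3\t300\tg\ta\tPASS"), p)
  res <- load_reference_sites(p)
  expect_equal(nrow(res), 3L)
  feats <- data.frame(chrom = c("1", "2", "3", "9"), pos = c(100, 200, 300, 1),
                      ref = c("A", "C", "G", "A"), alt = c("G", "T", "A", "T"))
  st <- reference_status(feats, kg = res)
  expect_equal(st$kg_status, c("PASS", "FAIL", "PASS", "ABSENT"))
  expect_equal(st$exac_status, rep("ABSENT", 4))
})

test_that("a malformed resource row is fatal with its line number", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tref\talt", "1\t100\tA\tG", "1\txx\tC\tT"), p)
  expect_error(load_reference_sites(p), "line 3")
})

test_that("VCF resources map FILTER to PASS/FAIL", {
  p <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               '##FILTER=<ID=VQSRTrancheSNP,Description="x">',
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", sep = "\t"),
               paste("1", "100", ".", "A", "G", ".", "PASS", ".", sep = "\t"),
               paste("1", "200", ".", "C", "T", ".", "VQSRTrancheSNP", ".",
                     sep = "\t")), p)
  res <- load_reference_sites(p)
  expect_equal(res$status, c("PASS", "FAIL"))
})

test_that("cascade examples follow the published rules", {
  st <- function(kg, exac, db)
    data.frame(kg_status = kg, exac_status = exac, in_dbsnp = db)
  lab <- function(nf, cr, kg, exac, db)
    assign_training_labels(nf, cr, st(kg, exac, db))$label
  expect_equal(lab(3, 0.9, "PASS", "PASS", TRUE), "LIKELY_FALSE")
  expect_equal(lab(2, 0.9, "PASS", "ABSENT", FALSE), "UNKNOWN")
  expect_equal(lab(0, 0.9, "ABSENT", "ABSENT", TRUE), "LIKELY_TRUE")
  expect_equal(lab(0, 0.4, "PASS", "PASS", TRUE), "LIKELY_FALSE")
  # 1000G-style precedence: present-and-failed there, ExAC not consulted
  expect_equal(lab(1, 0.9, "FAIL", "PASS", TRUE), "LIKELY_FALSE")
})

test_that("kg PASS -> FAIL never moves a label toward LIKELY_TRUE", {
  rank <- c(LIKELY_FALSE = 0, UNKNOWN = 1, LIKELY_TRUE = 2)
  grid <- expand.grid(nf = 0:4, cr = c(0.4, 0.9),
                      exac = c("PASS", "FAIL", "ABSENT"),
                      db = c(TRUE, FALSE), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    l_pass <- assign_training_labels(g$nf, g$cr, data.frame(
      kg_status = "PASS", exac_status = g$exac, in_dbsnp = g$db))$label
    l_fail <- assign_training_labels(g$nf, g$cr, data.frame(
      kg_status = "FAIL", exac_status = g$exac, in_dbsnp = g$db))$label
    expect_lte(rank[l_fail], rank[l_pass])
  }
})

test_that("the worked-example fixture is labelled as designed", {
  fx <- worked_example_fixture(tempfile("fx"))
  x <- suppressWarnings(read_sites(fx$paths$vcf))
  f <- site_features(x)
  rep <- hard_filter_report(f)
  st <- reference_status(f, fx$paths$kg, fx$paths$exac, fx$paths$dbsnp)
  lab <- assign_training_labels(rep$n_failed, f$call_rate, st)
  expect_equal(lab$label, fx$expected$label)
  expect_equal(lab$reason, fx$expected$reason)
})
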