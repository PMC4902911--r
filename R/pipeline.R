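# End-to-end driver: VCF in, filtered/annotated VCF out, with every
# intermediate table kept for audit.

#' Run the full variant quality filtering pipeline
#'
#' Reads a VCF, computes site features, evaluates the nine hard filters,
#' assigns training labels from the external resources, imputes missing
#' features, trains the SVM on the LIKELY_TRUE / LIKELY_FALSE sites,
#' classifies every site PASS / FILTERED, applies the genotype-level filter,
#' and (optionally) writes the annotated VCF.
#'
#' @param vcf path to the input VCF.
#' @param kg,exac,dbsnp paths to (or preloaded tables of) the site-status
#'   resources; any may be `NULL`.
#' @param out_vcf output VCF path, or `NULL` to skip writing.
#' @param seed integer seed for the SVM stage.
#' @param thresholds hard-filter thresholds ([hard_filter_thresholds()]).
#' @param abhet_mode ABHet aggregation ([compute_abhet_and_mean_ad()]).
#' @param knn_k k-NN neighbourhood size for imputation.
#' @param cost,gamma SVM hyperparameters (`NULL` gamma = 1/10).
#' @param transform feature scale for imputation and the SVM.
#' @param genotype_filter apply the genotype-level filter (step of the
#'   pipeline that masks low-quality genotypes to missing)?
#' @return invisibly, a list: `sites` (the `tarsvm_sites` object),
#'   `features`, `report`, `status`, `labels`, `imputed`, `model`,
#'   `decisions` (per-site PASS/FILTERED + decision value), `genotype_keep`
#'   (logical per genotype row), and `site_decisions` — the site-level
#'   verdict used for evaluation, where a PASS additionally requires that at
#'   least one alternate-carrying genotype survives the genotype filter.
#' @export
tarsvm_filter <- function(vcf, kg = NULL, exac = NULL, dbsnp = NULL,
                          out_vcf = NULL, seed = 13,
                          thresholds = hard_filter_thresholds(),
                          abhet_mode = "pooled", knn_k = 10,
                          cost = 1, gamma = NULL,
                          transform = "inverse_normal",
                          genotype_filter = TRUE) {
  x <- read_sites(vcf)
  feats <- site_features(x, abhet_mode = abhet_mode)
  report <- hard_filter_report(feats, thresholds)
  status <- reference_status(feats, kg, exac, dbsnp)
  labels <- assign_training_labels(report$n_failed, feats$call_rate, status)
  imp <- impute_features(feats, k = knn_k, transform = transform)
  if (is.null(gamma)) gamma <- 1 / ncol(imp$matrix)
  model <- tarsvm_train(imp$matrix, labels$label, seed = seed, cost = cost,
                        gamma = gamma)
  decisions <- tarsvm_predict(model, imp$matrix,
                              training_labels = labels$label)

  g <- x$genotypes
  keep <- if (genotype_filter) {
    tarsvm_genotype_filter(g$call, g$ref_depth, g$alt_depth, g$gq)$action == "KEEP"
  } else rep(TRUE, nrow(g))

  carrier <- g$call %in% c("HET", "HOM_ALT")
  has_carrier <- tapply(carrier & keep, factor(g$site_id,
                                              levels = x$sites$site_id),
                        any, default = FALSE)
  pass <- decisions$label == "PASS" & as.logical(has_carrier)
  site_decisions <- data.frame(
    chrom = x$sites$chrom, pos = x$sites$pos, ref = x$sites$ref,
    alt = x$sites$alt, site_id = x$sites$site_id,
    decision = ifelse(pass, "PASS", "FILTERED"), stringsAsFactors = FALSE)

  final <- data.frame(site_id = decisions$site_id,
                      label = ifelse(pass, "PASS", "FILTERED"),
                      decision_value = decisions$decision_value)
  if (!is.null(out_vcf))
    write_filtered_vcf(x, final, out_vcf, features = feats, labels = labels,
                       genotype_keep = keep)
  invisible(list(sites = x, features = feats, report = report,
                 status = status, labels = labels, imputed = imp,
                 model = model, decisions = decisions,
                 genotype_keep = keep, site_decisions = site_decisions,
                 out_vcf = out_vcf))
}

#' Site-level decisions under a baseline filter strategy
#'
#' For the per-genotype baseline filters a site passes iff at least one
#' alternate-carrying genotype passes; `"none"` passes any site with a
#' non-missing carrier; `"gatk-hard"` is the site-level GATK best-practice
#' hard filter.
#'
#' @param x a `tarsvm_sites` object.
#' @param strategy one of `"none"`, `"default"`, `"stringent"`,
#'   `"gatk-hard"`.
#' @param features required for `"gatk-hard"` ([site_features()] output).
#' @param ab_rule allele-balance clause attachment for the genotype
#'   baselines (see [default_genotype_filter()]).
#' @return data.frame with `chrom`, `pos`, `ref`, `alt`, `site_id`,
#'   `decision`.
#' @export
baseline_site_decisions <- function(x, strategy = c("none", "default",
                                                    "stringent", "gatk-hard"),
                                    features = NULL,
                                    ab_rule = c("both", "hom", "het")) {
  strategy <- match.arg(strategy)
  ab_rule <- match.arg(ab_rule)
  g <- x$genotypes
  carrier <- g$call %in% c("HET", "HOM_ALT")
  if (strategy == "gatk-hard") {
    if (is.null(features)) stop("gatk-hard needs the site features")
    pass <- gatk_default_hard_filter(features) == "PASS"
  } else {
    ok <- switch(strategy,
      none = carrier,
      default = carrier & default_genotype_filter(
        g$call, g$ref_depth, g$alt_depth, ab_rule)$action == "PASS",
      stringent = carrier & stringent_genotype_filter(
        g$call, g$ref_depth, g$alt_depth, ab_rule)$action == "PASS")
    pass <- as.logical(tapply(ok, factor(g$site_id, levels = x$sites$site_id),
                              any, default = FALSE))
  }
  data.frame(chrom = x$sites$chrom, pos = x$sites$pos, ref = x$sites$ref,
             alt = x$sites$alt, site_id = x$sites$site_id,
             decision = ifelse(pass, "PASS", "FILTERED"),
             stringsAsFactors = FALSE)
}
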