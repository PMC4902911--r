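# Synthetic cohort generator. Emulates the regime the filters presuppose in
# microfluidic PCR amplicon data: very high per-genotype depth (all reads are
# PCR duplicates, none removable), true heterozygotes binomially balanced at
# 50%, artifact sites with a skewed alternate fraction from early-cycle
# polymerase errors, a singleton-heavy site-frequency spectrum, and external
# resources in which true sites are often catalogued and artifact sites are
# mostly absent or failed.

#' Simulation configuration
#'
#' Every distribution the generator uses lives here. Defaults describe a
#' cohort of 100 samples and 2000 SNV sites, 40% of them artifacts:
#' per-genotype depth log-normal with median 300; true heterozygote
#' alternate reads Binomial(depth, 0.5); artifact sites draw a site-level
#' alternate fraction Uniform(0.03, 0.22); 70% of true sites are singletons
#' and a small fraction are carried only by homozygous-alternate samples (so
#' the pseudo-depth NAD path is exercised); caller annotations are drawn
#' from per-class normal models and go missing at a small rate; true sites
#' enter dbSNP with probability 0.6 and the 1000G-/ExAC-style resources
#' mostly as PASS, artifact sites are mostly ABSENT or FAIL.
#'
#' @param n_samples,n_sites cohort dimensions.
#' @param prop_false fraction of artifact sites.
#' @param depth_meanlog,depth_sdlog log-normal per-genotype depth model.
#' @param false_ab_min,false_ab_max range of the artifact alternate
#'   fraction.
#' @param singleton_prop fraction of true sites carried by one sample.
#' @param max_carriers maximum carriers at a non-singleton site.
#' @param hom_alt_site_prop fraction of true sites whose carriers are all
#'   homozygous-alternate.
#' @param missing_rate per-genotype missingness.
#' @param low_callrate_prop fraction of sites with very low call rate
#'   (missingness drawn from Uniform(0.5, 0.95)).
#' @param anno_missing_rate per-site missingness of rank-sum /
#'   InbreedingCoeff / HaplotypeScore annotations.
#' @param true_anno,false_anno per-class annotation models: named list of
#'   `c(mean, sd)` for qd, mq, mq_rank_sum, rp_rank_sum, bq_rank_sum, fs,
#'   inbreeding_coeff, haplotype_score.
#' @param true_kg,false_kg,true_exac,false_exac probabilities of
#'   `c(PASS, FAIL, ABSENT)` status in the two site-status resources.
#' @param true_dbsnp_prob,false_dbsnp_prob dbSNP presence probabilities.
#' @param error_rate per-read error rate generating stray alternate reads
#'   in HOM_REF genotypes.
#' @param seed integer seed; identical configs give byte-identical outputs.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 100, n_sites = 2000, prop_false = 0.4,
                       depth_meanlog = log(300), depth_sdlog = 0.5,
                       false_ab_min = 0.03, false_ab_max = 0.22,
                       singleton_prop = 0.7, max_carriers = 5,
                       hom_alt_site_prop = 0.03,
                       missing_rate = 0.02, low_callrate_prop = 0.02,
                       anno_missing_rate = 0.05,
                       true_anno = list(
                         qd = c(20, 4), mq = c(59, 1), mq_rank_sum = c(0, 1.5),
                         rp_rank_sum = c(0, 2), bq_rank_sum = c(0, 2),
                         fs = c(3, 2), inbreeding_coeff = c(0, 0.05),
                         haplotype_score = c(2, 1)),
                       false_anno = list(
                         qd = c(4, 2.5), mq = c(53, 3), mq_rank_sum = c(-2, 2.5),
                         rp_rank_sum = c(-4, 5), bq_rank_sum = c(-6, 6),
                         fs = c(10, 8), inbreeding_coeff = c(-0.1, 0.15),
                         haplotype_score = c(6, 3)),
                       true_kg = c(PASS = 0.45, FAIL = 0.05, ABSENT = 0.50),
                       false_kg = c(PASS = 0.02, FAIL = 0.13, ABSENT = 0.85),
                       true_exac = c(PASS = 0.45, FAIL = 0.05, ABSENT = 0.50),
                       false_exac = c(PASS = 0.02, FAIL = 0.13, ABSENT = 0.85),
                       true_dbsnp_prob = 0.6, false_dbsnp_prob = 0.1,
                       error_rate = 0.002, seed = 7) {
  cfg <- as.list(environment())
  if (cfg$n_samples < 2) stop("invalid config: n_samples must be >= 2")
  if (cfg$n_sites < 1) stop("invalid config: n_sites must be >= 1")
  if (cfg$prop_false < 0 || cfg$prop_false > 1)
    stop("invalid config: prop_false must be in [0, 1]")
  structure(cfg, class = "sim_config")
}

draw_anno <- function(model, n) {
  vals <- lapply(names(model), function(k) {
    x <- rnorm(n, model[[k]][1], model[[k]][2])
    if (k %in% c("qd", "fs", "haplotype_score")) x <- pmax(x, 0)
    if (k == "mq") x <- pmin(x, 60)
    x
  })
  names(vals) <- names(model)
  as.data.frame(vals)
}

#' Simulate a cohort: VCF, truth table and resource files
#'
#' Generates a multi-sample VCF v4.2 (GT/AD/GQ genotypes, the eight caller
#' INFO annotations), a truth table marking each site true or artifact, and
#' the three resource files (1000G-style and ExAC-style PASS/FAIL TSVs,
#' dbSNP-style presence TSV). All randomness flows from `config$seed`, so an
#' identical config reproduces the files byte for byte.
#'
#' @param config a [sim_config()].
#' @param out_dir directory to write into (created if needed); `NULL`
#'   returns the data without writing.
#' @return invisibly, a list with the data frames (`sites`, `truth`, `kg`,
#'   `exac`, `dbsnp`, genotype tables) and, when `out_dir` is given, the
#'   file `paths`.
#' @export
simulate_cohort <- function(config = sim_config(), out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_sites; ns <- cfg$n_samples
  samples <- sprintf("S%03d", seq_len(ns))
  bases <- c("A", "C", "G", "T")

  is_true <- runif(n) >= cfg$prop_false
  pos <- sort(sample.int(50000000L, n))
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))

  anno <- draw_anno(cfg$true_anno, n)
  anno_false <- draw_anno(cfg$false_anno, n)
  anno[!is_true, ] <- anno_false[!is_true, ]
  # rank sums etc. go missing at a small rate (caller omits annotations)
  for (k in c("mq_rank_sum", "rp_rank_sum", "bq_rank_sum",
              "inbreeding_coeff", "haplotype_score"))
    anno[[k]][runif(n) < cfg$anno_missing_rate] <- NA_real_

  site_missing <- ifelse(runif(n) < cfg$low_callrate_prop,
                         runif(n, 0.5, 0.95), cfg$missing_rate)
  n_carriers <- ifelse(runif(n) < cfg$singleton_prop, 1L,
                       1L + sample.int(cfg$max_carriers - 1L, n, replace = TRUE))
  hom_only <- is_true & runif(n) < cfg$hom_alt_site_prop
  false_ab <- runif(n, cfg$false_ab_min, cfg$false_ab_max)

  call_m <- matrix("HOM_REF", n, ns)
  ref_m <- matrix(0L, n, ns)
  alt_m <- matrix(0L, n, ns)
  gq_m <- matrix(0L, n, ns)
  for (i in seq_len(n)) {
    depth <- pmax(2L, as.integer(round(rlnorm(ns, cfg$depth_meanlog,
                                              cfg$depth_sdlog))))
    carriers <- sample.int(ns, min(n_carriers[i], ns))
    a <- rbinom(ns, depth, cfg$error_rate)
    calls <- rep("HOM_REF", ns)
    gq <- pmin(99L, pmax(0L, as.integer(round(rnorm(ns, 90, 10)))))
    if (is_true[i]) {
      if (hom_only[i]) {
        calls[carriers] <- "HOM_ALT"
        a[carriers] <- rbinom(length(carriers), depth[carriers], 0.99)
      } else {
        hom <- runif(length(carriers)) < 0.05
        calls[carriers] <- ifelse(hom, "HOM_ALT", "HET")
        a[carriers] <- rbinom(length(carriers), depth[carriers],
                              ifelse(hom, 0.99, 0.5))
      }
    } else {
      calls[carriers] <- "HET"
      a[carriers] <- rbinom(length(carriers), depth[carriers], false_ab[i])
      gq[carriers] <- pmin(99L, pmax(0L, as.integer(round(
        rnorm(length(carriers), 55, 25)))))
    }
    miss <- runif(ns) < site_missing[i]
    calls[miss] <- "MISSING"
    a[miss] <- 0L; depth[miss] <- 0L
    call_m[i, ] <- calls
    alt_m[i, ] <- a
    ref_m[i, ] <- depth - a
    gq_m[i, ] <- ifelse(miss, 0L, gq)
  }

  draw_status <- function(p_true, p_false)
    ifelse(is_true,
           sample(names(p_true), n, replace = TRUE, prob = p_true),
           sample(names(p_false), n, replace = TRUE, prob = p_false))
  kg_status <- draw_status(cfg$true_kg, cfg$false_kg)
  exac_status <- draw_status(cfg$true_exac, cfg$false_exac)
  in_dbsnp <- runif(n) < ifelse(is_true, cfg$true_dbsnp_prob,
                                cfg$false_dbsnp_prob)

  sites <- data.frame(chrom = "1", pos = pos, ref = ref, alt = alt, anno,
                      stringsAsFactors = FALSE)
  truth <- data.frame(chrom = "1", pos = pos, ref = ref, alt = alt,
                      validated = as.integer(is_true))
  kg <- data.frame(chrom = "1", pos = pos, ref = ref, alt = alt,
                   status = kg_status)[kg_status != "ABSENT", ]
  exac <- data.frame(chrom = "1", pos = pos, ref = ref, alt = alt,
                     status = exac_status)[exac_status != "ABSENT", ]
  dbsnp <- data.frame(chrom = "1", pos = pos, ref = ref,
                      alt = alt)[in_dbsnp, ]

  out <- list(sites = sites, truth = truth, kg = kg, exac = exac,
              dbsnp = dbsnp, samples = samples,
              call = call_m, ref_depth = ref_m, alt_depth = alt_m, gq = gq_m)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(vcf = file.path(out_dir, "sim.vcf"),
                  truth = file.path(out_dir, "truth.tsv"),
                  kg = file.path(out_dir, "kg.tsv"),
                  exac = file.path(out_dir, "exac.tsv"),
                  dbsnp = file.path(out_dir, "dbsnp.tsv"))
    write_sim_vcf(out, paths$vcf)
    for (nm in c("truth", "kg", "exac", "dbsnp"))
      utils::write.table(out[[nm]], paths[[nm]], sep = "\t", quote = FALSE,
                         row.names = FALSE)
    out$paths <- paths
  }
  invisible(out)
}

# VCF text for a simulate_cohort() result
write_sim_vcf <- function(sim, path) {
  n <- nrow(sim$sites)
  lines <- vcf_header_lines(sim$samples, source = "tarsvm-simulate")
  info_keys <- c(qd = "QD", mq = "MQ", mq_rank_sum = "MQRankSum",
                 rp_rank_sum = "ReadPosRankSum", bq_rank_sum = "BaseQRankSum",
                 fs = "FS", inbreeding_coeff = "InbreedingCoeff",
                 haplotype_score = "HaplotypeScore")
  recs <- vapply(seq_len(n), function(i) {
    vals <- lapply(names(info_keys), function(col)
      fmt_num(sim$sites[[col]][i], "%.4f"))
    names(vals) <- info_keys
    g <- data.frame(call = sim$call[i, ], ref_depth = sim$ref_depth[i, ],
                    alt_depth = sim$alt_depth[i, ], gq = sim$gq[i, ])
    paste(c(sim$sites$chrom[i], sim$sites$pos[i], ".", sim$sites$ref[i],
            sim$sites$alt[i], ".", ".", info_string(vals), "GT:AD:GQ",
            format_genotype_fields(g)), collapse = "\t")
  }, character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(lines, recs), con)
  invisible(path)
}
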