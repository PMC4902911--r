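# VCF output. Records are formatted directly so that identical inputs give
# byte-identical files (important for reproducible pipelines); reading back
# goes through read_sites().

fmt_num <- function(x, fmt = "%.8g") ifelse(is.na(x), NA, sprintf(fmt, x))

vcf_header_lines <- function(samples, extra_info = character(0),
                             extra_filter = character(0), with_gq = TRUE,
                             source = "tarsvm") {
  c("##fileformat=VCFv4.2",
    paste0("##source=", source),
    sprintf('##INFO=<ID=%s,Number=1,Type=Float,Description="%s">',
            c("QD", "MQ", "MQRankSum", "ReadPosRankSum", "BaseQRankSum",
              "FS", "InbreedingCoeff", "HaplotypeScore"),
            c("Variant quality by depth", "RMS mapping quality",
              "Mapping quality rank sum", "Read position rank sum",
              "Base quality rank sum", "Fisher strand score",
              "Inbreeding coefficient", "Haplotype score")),
    extra_info,
    extra_filter,
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allele depths (ref,alt)">',
    if (with_gq)
      '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

# INFO string from a named list of (possibly NA) formatted values
info_string <- function(values) {
  keep <- !vapply(values, is.na, logical(1))
  if (!any(keep)) return(".")
  paste(paste0(names(values)[keep], "=", unlist(values[keep])), collapse = ";")
}

gt_code <- c(HOM_REF = "0/0", HET = "0/1", HOM_ALT = "1/1", MISSING = "./.")

# one "GT:AD:GQ" string per genotype row; masked rows are written missing
format_genotype_fields <- function(g, keep = NULL, with_gq = TRUE) {
  call <- g$call
  if (!is.null(keep)) call[!keep] <- "MISSING"
  ad <- ifelse(call == "MISSING", ".", paste0(g$ref_depth, ",", g$alt_depth))
  gt <- unname(gt_code[call])
  if (!with_gq) return(paste(gt, ad, sep = ":"))
  gq <- ifelse(is.na(g$gq) | call == "MISSING", ".",
               as.character(as.integer(round(g$gq))))
  paste(gt, ad, gq, sep = ":")
}

#' Write an annotated, filtered VCF
#'
#' Writes one record per site of `x`, FILTER set to `PASS` for sites the
#' classifier passed and `tarSVM` for filtered sites. The INFO column
#' carries the caller annotations plus `NAD`, `ABHET`, `ADHET`, `CALLRATE`,
#' `TRAINLABEL` and `SVMSCORE`. Genotypes masked by the genotype-level
#' filter are written as missing (`./.`). The output round-trips through
#' [read_sites()].
#'
#' @param x a `tarsvm_sites` object.
#' @param decisions data.frame with `site_id` and `label`
#'   (`PASS`/`FILTERED`), optionally `decision_value`; one row per site.
#' @param out_path output path; a `.gz` suffix gzip-compresses.
#' @param features optional [site_features()] data.frame supplying the
#'   computed INFO keys.
#' @param labels optional data.frame with `site_id` and `label`
#'   (training labels) for the `TRAINLABEL` key.
#' @param genotype_keep optional logical vector parallel to `x$genotypes`
#'   rows; `FALSE` masks that genotype to missing.
#' @return `out_path`, invisibly.
#' @export
write_filtered_vcf <- function(x, decisions, out_path, features = NULL,
                               labels = NULL, genotype_keep = NULL) {
  stopifnot(inherits(x, "tarsvm_sites"))
  sites <- x$sites
  dec <- decisions[match(sites$site_id, decisions$site_id), , drop = FALSE]
  if (nrow(sites) && any(is.na(dec$label)))
    stop("every site needs a decision")
  extra_info <- c(
    '##INFO=<ID=NAD,Number=A,Type=Float,Description="Normalized allele dosage score">',
    '##INFO=<ID=ABHET,Number=A,Type=Float,Description="Pooled heterozygote allele balance">',
    '##INFO=<ID=ADHET,Number=A,Type=Float,Description="Mean heterozygote alt depth">',
    '##INFO=<ID=CALLRATE,Number=1,Type=Float,Description="Fraction of samples called">',
    '##INFO=<ID=TRAINLABEL,Number=A,Type=String,Description="Training label">',
    '##INFO=<ID=SVMSCORE,Number=A,Type=Float,Description="SVM decision value">')
  extra_filter <-
    '##FILTER=<ID=tarSVM,Description="Filtered by the tarSVM site classifier">'
  lines <- vcf_header_lines(x$samples, extra_info, extra_filter)

  if (nrow(sites)) {
    feat <- if (is.null(features)) NULL else
      features[match(sites$site_id, features$site_id), , drop = FALSE]
    lab <- if (is.null(labels)) NULL else
      labels$label[match(sites$site_id, labels$site_id)]
    gsplit <- split(seq_len(nrow(x$genotypes)), factor(x$genotypes$site_id,
                                                      levels = sites$site_id))
    recs <- vapply(seq_len(nrow(sites)), function(i) {
      vals <- list(
        QD = fmt_num(sites$qd[i]), MQ = fmt_num(sites$mq[i]),
        MQRankSum = fmt_num(sites$mq_rank_sum[i]),
        ReadPosRankSum = fmt_num(sites$rp_rank_sum[i]),
        BaseQRankSum = fmt_num(sites$bq_rank_sum[i]),
        FS = fmt_num(sites$fs[i]),
        InbreedingCoeff = fmt_num(sites$inbreeding_coeff[i]),
        HaplotypeScore = fmt_num(sites$haplotype_score[i]))
      if (!is.null(feat)) {
        vals$NAD <- fmt_num(feat$nad[i], "%.4f")
        vals$ABHET <- fmt_num(feat$ab_het[i], "%.6f")
        vals$ADHET <- fmt_num(feat$mean_ad_het[i], "%.4f")
        vals$CALLRATE <- fmt_num(feat$call_rate[i], "%.6f")
      }
      if (!is.null(lab)) vals$TRAINLABEL <- lab[i]
      if (!is.null(dec$decision_value))
        vals$SVMSCORE <- fmt_num(dec$decision_value[i], "%.6f")
      idx <- gsplit[[i]]
      keep <- if (is.null(genotype_keep)) NULL else genotype_keep[idx]
      paste(c(sites$chrom[i], sites$pos[i], ".", sites$ref[i], sites$alt[i],
              ".", if (dec$label[i] == "PASS") "PASS" else "tarSVM",
              info_string(vals), "GT:AD:GQ",
              format_genotype_fields(x$genotypes[idx, , drop = FALSE], keep)),
            collapse = "\t")
    }, character(1))
    lines <- c(lines, recs)
  }
  con <- if (grepl("\\.gz$", out_path)) gzfile(out_path, "w") else
    file(out_path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(out_path)
}
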