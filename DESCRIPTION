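Package: tarsvm
Title: Variant Quality Filtering for Microfluidic PCR Targeted Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Support-vector-machine based variant quality filtering for
    targeted amplicon sequencing experiments in which reads are PCR
    duplicates by design (for example microfluidic PCR panels) and
    allele-balance distortion is a principal false-positive mechanism.
    Computes site-level quality features from a multi-sample VCF including
    the normalized allele dosage (NAD) score, an exact binomial test of 50
    percent allele balance on the PHRED scale normalized by heterozygote
    alternate-allele depth; selects likely-true and likely-false training
    sites with nine hard filters plus external site-status resources;
    imputes missing features (regression, pseudo reference depth, and
    inverse-normal k-nearest-neighbour imputation); trains a radial-basis
    support vector classifier to label every site PASS or FILTERED; applies
    genotype-level filters; and evaluates any filter strategy against a
    validation truth set. Includes a seedable synthetic cohort generator so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    stats,
    utils,
    vcfR
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
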