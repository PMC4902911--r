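# tarsvm

Variant quality filtering for targeted amplicon sequencing in which every
read is a PCR duplicate by design — e.g. microfluidic PCR panels used for
monogenic disease screening. In such data duplicate marking is impossible
and early-cycle polymerase errors are amplified alongside the template, so
call sets carry many artifact sites whose signature is a skewed allele
balance at heterozygous calls. `tarsvm` separates true variant sites from
these artifacts with a support vector machine whose training labels are
derived from the data itself plus public call sets, rather than requiring a
curated truth set for the panel.

## Method

For every biallelic SNV site the package computes, from the VCF genotypes
and caller annotations, a set of site-level features: call rate, QD, MQ,
rank-sum statistics, the pooled heterozygote allele balance

    ABHet = sum(alt depth) / sum(alt + ref depth)   over heterozygotes,

the mean heterozygote alternate depth (AD), and the **normalized allele
dosage** (NAD) score

    p    = two-sided exact binomial p-value of Binomial(n, 0.5) at k,
           with k = pooled het alt depth, n = pooled het total depth
    NAD  = (-10 log10 p) / AD

i.e. a PHRED-scaled exact test of 50% allele balance, normalized by the
alternate depth because at these depths (median ≈ 300×) the p-value shrinks
for the same allele balance. A true heterozygote has NAD near 0; a PCR
artifact with 3–22% alternate reads has a very large NAD.

The pipeline then:

1. **Hard filters** — nine inclusive thresholds (QD ≥ 3, MQ ≥ 50,
   −3 ≤ MQRankSum ≤ 10, ReadPosRankSum ≥ −20, 0.20 ≤ ABHet ≤ 0.80,
   AD ≥ 10, BaseQRankSum ≥ −40, call rate ≥ 0.80, NAD ≤ 5).
2. **Training labels** — sites are trichotomized LIKELY_FALSE / UNKNOWN /
   LIKELY_TRUE from the failure count, the call rate, and the site's status
   in a 1000 Genomes-style and an ExAC-style PASS/FAIL resource plus a
   dbSNP-style presence list (the 1000G-style resource takes precedence).
3. **Imputation** — ABHet for heterozygote-free sites by regression on QD,
   NAD for those sites through a pseudo reference depth, then inverse-normal
   transform and k-NN (k = 10) for everything else.
4. **SVM** — a radial-basis C-SVM (LIBSVM via `e1071`) trained on the
   LIKELY_TRUE vs LIKELY_FALSE sites over ten features classifies *every*
   site `PASS` / `FILTERED`.
5. **Genotype filter** — individual calls are masked to missing unless
   GQ ≥ 40, alt depth ≥ 5 and (for heterozygotes) allele balance ≥ 10%.

Baselines (GATK best-practice hard filter; default / stringent per-genotype
depth filters) and a confusion-matrix evaluation harness (sensitivity,
specificity, FDR, accuracy) are included, along with a seedable synthetic
cohort generator that emulates the regime — so the whole pipeline is
testable without any external download.

## Worked example

```r
library(tarsvm)

dir <- tempfile("demo")
sim <- simulate_cohort(sim_config(n_samples = 40, n_sites = 400,
                                  prop_false = 0.4, seed = 7), dir)
res <- tarsvm_filter(sim$paths$vcf, kg = sim$paths$kg, exac = sim$paths$exac,
                     dbsnp = sim$paths$dbsnp,
                     out_vcf = file.path(dir, "filtered.vcf"), seed = 13)
res$model
#> tarsvm_model: radial-basis SVM on 10 features; 207 LIKELY_TRUE / 156 LIKELY_FALSE training sites; cost 1 gamma 0.1
table(res$labels$label)
#> LIKELY_FALSE  LIKELY_TRUE      UNKNOWN
#>          156          207           37

truth <- read.table(sim$paths$truth, header = TRUE, sep = "\t")
evaluate_filter(res$site_decisions, truth)
#> TP 244  FP 0  TN 151  FN 5
#>   sensitivity: 98% (0.9799)
#>   specificity: 100% (1.0000)
#>   FDR:         0% (0.0000)
#>   accuracy:    99% (0.9875)
```

Of the 400 simulated sites (40% artifacts), the trained filter passes 244
and rejects 156; against the generator's known truth that is 98%
sensitivity at zero false discoveries, versus a 40% FDR with no filter. The
annotated output VCF carries `PASS`/`tarSVM` in FILTER plus `NAD`, `ABHET`,
`ADHET`, `CALLRATE`, `TRAINLABEL` and `SVMSCORE` INFO keys.

The NAD score itself:

```r
nad_score(1, 10, 1)
#>      p_value    phred      nad
#> 1 0.02148438 16.67908 16.67908
```

A command-line front end over the same functions is installed at
`inst/cli/tarsvm.R` (subcommands `simulate`, `extract-features`, `filter`,
`evaluate`, `nad`).

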