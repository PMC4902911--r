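---
title: "Filtering microfluidic PCR variant calls with tarsvm: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Filtering microfluidic PCR variant calls with tarsvm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tarsvm)
```

## The problem

Microfluidic PCR target enrichment amplifies a gene panel in thousands of
simultaneous reactions and sequences the products. Every read is a PCR
duplicate of an early amplification cycle, so two of the usual defenses
against artifacts are unavailable: duplicates cannot be marked and removed,
and read-level evidence cannot be de-correlated. A polymerase error in an
early cycle is amplified like template and appears as a variant call —
typically a "heterozygote" whose alternate-allele fraction is well below
the 50% a true heterozygote produces. The practical consequence is a call
set in which a large fraction of sites fail orthogonal (Sanger) validation
unless aggressively filtered.

`tarsvm` filters such call sets at the site level. Its design premise is
that no curated truth set exists for an arbitrary panel, so training labels
must be manufactured from the data itself (hard filters on quality
features) plus public catalogues (PASS/FAIL status in 1000 Genomes-style
and ExAC-style releases, presence in a dbSNP-style catalogue).

## The NAD statistic

For one site, pool depths over its heterozygous genotypes: `k` alternate
reads out of `n` total. Under the true-heterozygote hypothesis
`k ~ Binomial(n, 1/2)`. The normalized allele dosage is

$$\mathrm{NAD} = \frac{-10\log_{10} p}{\overline{AD}}, \qquad
p = P_{\mathrm{two\ sided}}\{X = k \mid X \sim \mathrm{Bin}(n, 1/2)\},$$

where $\overline{AD}$ is the mean heterozygote alternate depth. The PHRED
scaling makes the score additive in evidence; the division by
$\overline{AD}$ compensates for depth — at 300× a 40% allele balance is
already wildly significant, but is not evidence of an artifact of the kind
this assay produces. Low NAD is consistent with a true heterozygote; the
hard filter requires NAD ≤ 5.

Numerical choices:

* **Two-sided convention.** We use the minimum-likelihood convention (sum
  of all outcome probabilities not exceeding the observed one). At the
  symmetric null $p_0 = 1/2$ the pmf is symmetric and strictly unimodal, so
  this set is exactly the two mirror tails and the p-value reduces to
  $\min(1,\, 2\,F(\min(k, n-k)))$ with $F$ the binomial CDF. The
  tail-doubling convention gives the identical value at this null, so the
  choice is cosmetic and one code path serves both. The closed form is
  numerically stable at any depth (no pmf enumeration), and the test suite
  checks it against brute-force enumeration for every $(k, n)$ with
  $n \le 100$ at $10^{-12}$ relative tolerance.
* **Floor.** p-values are floored at $10^{-300}$ before the logarithm, so
  PHRED ≤ 3000 and the score stays finite at extreme imbalance.
* **Pooling.** NAD is computed once per site on depths pooled across
  heterozygotes, consistent with ABHet and AD being site-level summaries
  (not an average of per-sample tests).
* **Heterozygote-free sites** get a NAD through a pseudo reference depth:
  with imputed allele balance $a$ and mean homozygote-alternate depth $d$,
  pseudo-ref $= \mathrm{round}(d(1-a)/a)$ and the test runs on
  $(\mathrm{round}(d),\ \mathrm{round}(d) + \mathrm{pseudo\ ref})$,
  normalized by $d$. Pseudo-counts are rounded half-up before the exact
  test.

## ABHet and the feature set

ABHet is the *pooled* alternate fraction across heterozygotes
($\sum \mathrm{alt} / \sum \mathrm{total}$), not the mean of per-sample
ratios; pooling weights each read equally and is the same aggregation NAD
uses. The mean-of-ratios variant is available
(`site_features(x, abhet_mode = "mean_of_ratios")`) because the verbal
definition "across heterozygotes" admits both readings; pooled is the
default and the two coincide when depths are equal.

The classifier consumes ten features per site: call rate, QD,
ReadPosRankSum, ABHet, AD (mean heterozygote alternate depth), NAD,
inbreeding coefficient, haplotype score, MQRankSum, BaseQRankSum. FS
(strand bias) is deliberately absent: only one strand is amplified in this
assay, so strand-balance scores carry no signal and would only add noise.
FS is still parsed because the GATK-style baseline hard filter uses it.

## Hard filters and training labels

The nine hard filters (inclusive bounds: QD ≥ 3, MQ ≥ 50, −3 ≤ MQRankSum
≤ 10, ReadPosRankSum ≥ −20, 0.20 ≤ ABHet ≤ 0.80, AD ≥ 10, BaseQRankSum ≥
−40, call rate ≥ 0.80, NAD ≤ 5) are threshold-configurable per run
(`hard_filter_thresholds()`). A missing feature yields `NOT_EVALUABLE`, not
`FAIL`: sites whose annotations are missing because almost nothing was
called there are handled by the explicit call-rate rules rather than by
incidental missingness.

Labels then follow a cascade on the failure count `n_failed`:

* `n_failed ≥ 3` or call rate < 50% → LIKELY_FALSE.
* `n_failed = 2`: PASS in the 1000G-style resource → UNKNOWN, FAIL →
  LIKELY_FALSE; if absent there, the same test on the ExAC-style resource;
  absent in both → dbSNP presence decides UNKNOWN vs LIKELY_FALSE.
* `n_failed = 1`: verdict of the first resource that lists the site
  (PASS → LIKELY_TRUE, FAIL → LIKELY_FALSE); listed in neither → UNKNOWN.
* `n_failed = 0`: as for one failure, except a site in neither resource is
  LIKELY_TRUE if in dbSNP and UNKNOWN otherwise.

Two points were genuinely open and are resolved as follows. First, when a
site is present-and-FAIL in the 1000G-style resource but PASS in the
ExAC-style one, we take the first definitive answer (1000G precedence) and
do not consult ExAC; the `reason` code emitted with every label makes the
branch auditable. Second, "status from the resource" for 0–1 failures is
read as the resource's own PASS/FAIL verdict mapped onto
LIKELY_TRUE/LIKELY_FALSE. The full cascade is tested exhaustively against
an independently written oracle over all 720 input combinations.

## Imputation

Features can be missing for two reasons: the caller omits annotations at
very low call rate, and heterozygote-dependent features are undefined at
sites with no heterozygotes. The chain is ordered so the bespoke schemes
take precedence and k-NN only sees what remains:

1. **ABHet ~ QD regression** (OLS on sites with both observed) fills ABHet
   for heterozygote-free sites; predictions are clipped to [0.01, 0.99].
   Degenerate fits (< 2 complete pairs, constant QD) fall back to the
   observed mean with a warning.
2. **Pseudo-depth NAD** (above) fills NAD and AD for those sites.
3. **Inverse normal transform** per column: observed values are replaced by
   $\Phi^{-1}((r - 0.5)/m)$ of their average ranks ($m$ observed values).
   The offset $-0.5$ is the standard rank-to-quantile choice; it is exposed
   only through this documented definition, and the transform is
   rank-preserving by construction.
4. **k-NN, k = 10**: each missing cell takes the mean of its column over
   the k nearest rows among those observed in that column. Distance is the
   root-mean-square difference over mutually observed columns — scaling by
   the number of shared columns keeps rows with different missingness
   comparable (plain Euclidean sums would favour rows that share fewer
   columns). Ties break deterministically by row index; a row with no
   usable neighbour falls back to the column mean; an entirely missing
   column aborts the run naming the column.

The SVM consumes the inverse-normal scale — the scale on which k-NN imputed
— which also makes the fit insensitive to the features' wildly different
units. Training on raw features is available
(`impute_features(..., transform = "raw")`).

## The classifier

A C-support-vector machine with radial-basis kernel (LIBSVM through
`e1071`), cost 1, gamma = 1/10 (one over the feature count), features
standardized from training rows, no class weights — the library defaults,
recorded as this package's choices since nothing forces others; all are
arguments of `tarsvm_train()`. Only LIKELY_TRUE / LIKELY_FALSE sites enter
the fit (at least 10 of each are required); every site, including UNKNOWN
ones and sites whose label the SVM overrules, is classified by the decision
boundary at decision value 0, with no probability calibration. Decision
values are re-oriented so positive is always the PASS side. Fitting is
deterministic: identical inputs and seed give byte-identical downstream
VCFs, and permuting rows only permutes decisions.

## Genotype-level filters

After site classification, individual genotypes are masked to missing
unless GQ ≥ 40 and alternate depth ≥ 5, plus allele balance ≥ 10% for
heterozygotes. Missing GQ counts as 0 (conservative). A site that passes
the SVM but retains no alternate-carrying genotype is reported FILTERED in
the site-level decisions.

The published *default* (alt depth ≥ 10) and *stringent* (≥ 30) baseline
filters carry an allele-balance ≥ 20% clause whose literal description
attaches it to homozygous calls, while the filter it originates from
applied it to heterozygotes — most likely a typo, but undecidable from the
text. Both behaviours plus their union are implemented
(`ab_rule = "hom" | "het" | "both"`); the function default is the safe
superset `"both"`, while the simulation benchmark in the acceptance suite
evaluates the baseline exactly as published (`"hom"`). Each run's choice is
recorded in its output.

## The synthetic cohort generator

`simulate_cohort()` generates the regime the filters presuppose, not reads:
per-genotype depth log-normal with median 300 (matching the assay's
reported depth scale); true heterozygote alternate reads Binomial(depth,
0.5); artifact sites draw a site-level alternate fraction from
Uniform(0.03, 0.22) — the band threshold filters historically targeted;
70% of true sites singletons (the dominant pattern in rare-disease
panels); 3% of true sites carried only by homozygotes, so the pseudo-depth
path is exercised; ~2% genotype missingness plus a 2% tail of
very-low-call-rate sites; caller annotations from per-class normal models
with 5% missingness; true sites catalogued in dbSNP with probability 0.6
and PASS in the resources with probability 0.45, artifact sites mostly
absent (85%) or FAIL. Every parameter lives in `sim_config()`; identical
configs give byte-identical files.

What it does **not** emulate: alignment artifacts, primer-primer
interaction chemistry, batch structure, indels, allele-frequency structure
beyond the singleton spectrum, or correlated annotation noise. Passing the
end-to-end recovery test therefore demonstrates that the machinery—feature
computation through SVM to genotype masking—recovers a planted
allele-balance/annotation signal; it does not certify performance on any
real cohort, where feature distributions are messier and the resources are
imperfectly correlated with truth.

## Problem sizes and verification

The test suite verifies each stage against independent oracles:
brute-force pmf enumeration for the exact test (all $n \le 100$),
exhaustive symmetry/monotonicity for NAD ($n \le 200$), a 720-row truth
table for the label cascade, closed-form OLS and brute-force k-NN for
imputation, and boundary point tests for every threshold. The end-to-end
check runs the full pipeline on a simulated 2000-site × 100-sample cohort
with 40% artifact sites and asserts the directional claims that motivate
the method: FDR far below the unfiltered FDR, specificity above the default
genotype filter's, sensitivity ≥ 0.85. These sizes keep the whole suite
under a minute on one CPU while leaving every code path exercised;
`scripts/acceptance.R` re-runs the same computation from scratch at an
arbitrary seed.

## Known limitations

* SNVs only; indel records are skipped on input by design.
* Site-status resources are matched on exact (chrom, pos, ref, alt) after
  allele uppercasing and `chr`-prefix stripping; no liftover.
* The hard-filter thresholds were tuned for high-duplicate amplicon data;
  on capture or WGS data they are inappropriate defaults.
* Training labels inherit the biases of the external resources: a
  panel-specific artifact that is PASS in a public release will pull the
  decision boundary the wrong way.
* With fewer than 10 LIKELY_TRUE or LIKELY_FALSE sites the SVM refuses to
  train; very small panels should rely on the hard filters directly.
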