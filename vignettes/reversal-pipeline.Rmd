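---
title: "Models and methods of the revsig reversal pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods of the revsig reversal pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(revsig)
```

# The scientific setting

`revsig` implements the analysis chain of a preclinical transcriptome
study: a disease model (e.g. a transgenic Huntington-disease mouse) is
crossed with treatment arms (vehicle, low dose, high dose), bulk RNA-seq
counts are collected per tissue, and the analysis asks whether the
treatment *reverses* the disease's transcriptional signature, whether that
reversal is dose-dependent, and whether exon/junction usage shifts
accompany it. Because such studies are rarely released with raw data, the
package carries a first-class synthetic-data module so that every claim
the pipeline makes can be checked against planted ground truth.

# Differential expression model

Counts are filtered (genes with mean raw count below 10 across all samples
of the tissue are dropped; a mean of exactly 10 is kept — the filter reads
"less than" literally), normalized by TMM, and transformed to
log2-CPM with a prior count of 0.5 and a +1 on the effective library size.
The filter is applied per tissue before any contrast; per-contrast
filtering would change the BH family between contrasts of one tissue.

**TMM.** The reference sample is the one whose 75th-percentile count
fraction is closest to the mean of those. For each sample, gene-wise log2
ratios of count fractions against the reference (M) and average log2
abundances (A) are formed over genes nonzero in both, the most extreme 30%
of M and 5% of A are trimmed symmetrically (ranks, as in the published
convention), and the factor is `2^` the precision-weighted mean of the
retained M values with binomial delta-method weights. Factors are rescaled
to geometric mean 1. A sample sharing no nonzero gene with the reference
gets factor 1 with a warning. The test suite checks this implementation
against both a naive re-implementation and `edgeR::calcNormFactors`, which
it matches to machine precision.

**Precision weights.** Gene-wise unweighted fits of the design give
residual standard deviations; their square roots are smoothed against
average log2 count by `lowess` with span 0.5 (the conventional default). Each observation's predicted
standard deviation — interpolated at its own fitted log-count — enters as
an inverse fourth-power weight. Residual standard deviations and
predictions are floored at 1e-4 so constant genes keep finite weights.

**Moderated t.** With gene variances `s2` on `df` residual degrees of
freedom, the scaled-F prior parameters `(d0, s0_sq)` are estimated by
matching the mean and variance of `log(s2)` through digamma/trigamma
identities; the trigamma function is inverted by Newton iteration. If the
observed log-variances are less dispersed than the sampling law permits,
`d0` is infinite and every posterior variance equals `s0_sq` (complete
shrinkage, with a warning path for non-convergent inversion). Posterior
variances `(d0*s0_sq + df*s2)/(d0 + df)` replace `s2` in the t-statistic,
referred to `df + d0` degrees of freedom. `d0 = 0` reproduces the ordinary
t exactly; both limits are asserted in the tests, and the estimated prior
agrees with `limma::squeezeVar` to three decimals on simulated data.
Zero residual variances are floored at 1e-8 before moderation.

Contrasts are differences of genotype-by-dose cell means (`A` disease vs
control at vehicle, `B`/`C` high/low dose vs vehicle within disease, `D`
high dose vs vehicle in controls, `E` the same comparison in blood — just
another tissue subset, no special-case code). Additional covariate columns
can be appended to the design; no particular covariate is hard-coded. The PCA
screen flags samples beyond 3 robust SDs (MAD) on either of the first two
principal components; it reports and never removes.

# Signatures, meta-analysis, reversal

A **signature** is the per-gene moderated-t vector of one contrast — the
field's standard ranking statistic, preferred over log2FC because it carries the
precision of each gene's estimate. DEG lists use the MAQC-style filter,
strict inequalities on both thresholds: linear fold change `2^|log2FC|`
above 1.25 and BH-adjusted p below 0.05.

**Two-study meta-analysis** converts each study's two-sided p and score
sign into a signed normal deviate and combines them by Stouffer's method
(unweighted by default, weights exposed). The combination is performed on
z-scores rather than effect sizes because the motivating use pools a
microarray and an RNA-seq cohort, whose effect scales are not comparable; the method of combination is a
declared design choice of this package. Genes absent from either
study are excluded (no imputation); fewer than 100 shared genes warns.

**Cosine reversal.** The cosine of the angle between disease and treatment
signatures over shared filtered genes (all of them, not DEGs only — the
statistic is defined on the full moderated-t vector; a restricted query is available by subsetting the signature). Significance
comes from permuting the treatment signature's gene-score assignment,
one-sided toward reversal, with add-one smoothing so the p-value floor is
`1/(n_perm + 1)`.

**Directional verdict.** Disease-up and disease-down DEG sets are tested
by preranked enrichment in the treatment ranking; the verdict "reversed"
requires *both* the up-set negatively enriched and the down-set positively
enriched at BH-adjusted p < 0.05 across the tested family; BH keeps the whole
pipeline's multiplicity control consistent.

## The shared-sample caveat

A subtle and, in our measurements, large effect: if the disease signature
(disease vs control) and the treatment signature (treated vs vehicle
disease) are computed from the *same* dataset, they share the
vehicle-disease samples, and the two contrasts' noise is correlated about
−0.5. Even a completely null treatment then shows a negative cosine
(≈ −0.36 at 1000–2000 genes, 8 per group, 10% disease genes). The
gene-permutation null does not know about this, so within-study queries
overstate reversal. Consequently:

* the calibration tests build the disease signature from an *independent*
  cohort carrying the same planted effects (`simulate_counts(truth = )`),
  which mirrors the package's intended headline use — an external disease
  signature (e.g. a human meta-analysis) queried against the treatment
  study;
* a dedicated property test asserts the bias exists, so it is documented
  behavior rather than a surprise;
* dose *comparisons* within one study remain valid — the bias is common to
  both doses and cancels in the comparison.

# Preranked enrichment and over-representation

The running-sum statistic walks the ranking ordered by decreasing score
(ties broken by gene id for determinism): a set hit at position *i* adds
`|score_i|^p / sum(|score_hits|^p)`, a miss subtracts `1/(N - n_hits)`;
the ES is the signed maximal deviation, with exact ties between a positive
and a negative extremum resolved to the earlier position (float tolerance
1e-9). The default weight is `p = 1`; `p = 0` gives the rank-only
statistic, invariant to monotone score rescaling. The null is gene-tag
permutation (a preranked input has no sample labels to permute): NES is
the ES over the mean absolute null ES of matching sign, and the p-value is
one-sided within the matching sign class with add-one smoothing, then
BH-adjusted across the sets of the call. The full ES-pooling FDR machinery
of the original enrichment tool is deliberately not reproduced.

Over-representation of a DEG list in GMT sets is a one-sided
hypergeometric tail against the filtered-gene universe with BH across
sets — a local, auditable stand-in for web-service enrichment tools, which
are out of scope (their rank-corrected z-score blend is not replicated).

# Differential exon/junction usage

For each feature (exon or junction) of a multi-feature gene, the counts of
the feature and of the rest of its gene are modeled as negative-binomial
with log link: per-sample intercepts (absorbing library size and the
gene's overall expression), a feature-vs-rest term, and a
feature-by-condition interaction tested by a 1-df likelihood ratio. This
feature-vs-rest factorization is the package's declared simplification of
full multi-feature GLMs: each test is 1-df and desk-checkable, at the cost
of features of one gene not being tested jointly.

Two numerical choices matter and were set by calibration *analysis* (not
by tuning to a test): the NB dispersion is estimated by method of moments
from the **tested feature's own observations** — pooling with the much
larger rest-of-gene counts underestimates usage noise several-fold and
inflates the false-positive rate — and squared residuals are rescaled by
`1/(1 - h_i)` (leverage from the working-weights hat matrix) because the
model spends many parameters on few observations. With both corrections
the pure-null gene-level discovery rate is below nominal and planted
logit-1 shifts are recovered with sensitivity above 0.9 at 8 samples per
group. Features with mean count below 5 and single-feature genes are
excluded and counted in the report. A gene is called positive if any of
its features passes the BH threshold (minimum adjusted p per gene).

Known limitation: in mixtures with many true shifts, the gene-level
false discovery proportion exceeds the feature-level BH target (planting a
shift on one feature necessarily shifts its siblings' proportions, and
feature-level control does not translate exactly to gene-level control).

# The synthetic world

Counts for gene *g*, sample *i* are NB with mean
`lib_i * mu_g * 2^lfc_gi / sum(mu)` and variance `mu + phi_g mu^2`.
Defaults, chosen once:

| parameter | default | why |
|---|---|---|
| baseline `mu_g` | lognormal(log 100, 1.5) | typical bulk dynamic range |
| dispersion `phi_g` | lognormal(−1.5, 0.5) | median 0.22, typical bulk RNA-seq |
| library sizes | lognormal(log 1e7, 0.3) | standard sequencing depth, ±2-fold spread |
| samples per cell | 8 | balanced version of a typical 9-vs-6 preclinical design |
| disease genes | 10% of genes, lfc ~ N(0, 1) | analytically convenient; includes sub-detectable effects |
| reversal | 80% of disease genes, treated mean `2^(lfc(1−κ))`, κ = 0.3 (low) / 0.8 (high) | κ = 1 full reversal, κ = 0 none; dose enters only through κ |
| feature usage | Dirichlet base (symmetric α = 5), concentration 50 | moderate sample-to-sample usage overdispersion |

`simulate_two_studies` draws two cohorts whose per-gene disease effects
are bivariate normal with a stated correlation — the meta-analysis
test-bed. `simulate_feature_counts` shifts one randomly chosen feature's
expected proportion on the logit scale in the treated condition, rescaling
the others, so gene totals are unchanged in expectation.

What the generator does **not** emulate: batch effects beyond library
size, GC/length biases, correlated genes, outlier samples, unbalanced
designs beyond `n_per_group2`, or read-level artifacts. A green test
therefore certifies the statistics under a clean NB world, not robustness
to real-data pathologies.

Determinism: every simulation and permutation flows from an explicit seed
through an RNG-state-preserving wrapper; identical config + seed gives
bit-identical output, and the pipeline's JSON report is byte-identical
across repeated runs.

# Numerical and boundary conventions

* Count filter boundary: mean exactly 10 is kept; DEG thresholds are
  strict (`> 1.25`, `< 0.05`).
* p-values are clamped to `(0, 1]`; BH input outside that range errors.
* Zero residual variances floored at 1e-8 (moderation) / 1e-4 (weights).
* ES tie-break: earlier extremum within 1e-9; ranking ties by gene id.
* Degenerate TMM pairs (no shared nonzero genes, all-identical libraries)
  return factor 1 rather than NaN.

# Observed operating characteristics

All of the following are computed by the shipped tests, not asserted from
memory: oracle equivalence for BH, ES, TMM and the linear fits on 200
random instances each; prior recovery within 20%/10% at d0 = 4,
s0² = 0.25; null DE and DUEJ discovery rates within the binomial band of
0.05; planted reversal (κ = 1) detected in ≥ 90% of 50 replicates with a
calibrated κ = 0 control; the high dose beating the low dose on both DEG
count and cosine in ≥ 80% of replicates; uniform preranked permutation
p-values under the null. One operating characteristic is weaker than one
might guess and is recorded in the tests themselves: at lfc sd = 1 and 8
per group the |t|-ranking AUC for disease genes is ≈ 0.77–0.83, not 0.9 — the
reference voom/limma chain attains the identical AUC on the same data, so
this reflects the effect-size law (many near-zero planted effects), not
lost power.
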