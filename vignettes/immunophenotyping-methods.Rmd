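---
title: "Immunofunctional phenotyping: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Immunofunctional phenotyping: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunophen)
```

This vignette is the package's own account of the statistical machinery
it implements: what each stage assumes, which knobs matter and why their
defaults are what they are, what the synthetic cohort generator does and
does not emulate, and where the design was genuinely open.

## The two-axis phenotype model

The package classifies tumors by separating immune *presence* from
immune *function*. Presence is the CD8+ T-cell fraction estimated
upstream by a 22-cell-type deconvolution of the bulk transcriptome (the
deconvolution itself is out of scope; its output table is an input
here). Function is the immune cytolytic activity (CYT) score,

$$\mathrm{CYT}_s = \sqrt{(\mathrm{GZMA}_s + \varepsilon)\,(\mathrm{PRF1}_s + \varepsilon)},$$

the geometric mean of granzyme A and perforin expression in TPM.
Granzyme and perforin are the effector molecules of T/NK-cell killing,
and the geometric mean demands that *both* be expressed: a tumor cannot
buy a high CYT with one gene alone, which an arithmetic mean would
allow. The pseudocount $\varepsilon$ (default 0.01 TPM, configurable)
exists because the geometric mean is zero — and its log undefined —
whenever either gene has a zero count; 0.01 TPM is far below any
meaningful expression level, so it regularizes without distorting. The
mean is computed in log space.

Three phenotypes follow from two per-cohort percentile cutoffs. CYT
above its cutoff defines **hot T-cell infiltrated (HTI)** regardless of
CD8 — measured killing activity is direct evidence of a functional
response. Otherwise CD8 above its cutoff defines **cold T-cell
infiltrated (CTI)** — the infiltrate is present but not killing — and
the remainder is **non-inflamed (NI)**. The labels are exhaustive and
mutually exclusive, so the three group sizes always partition the
cohort.

### Percentile semantics and the realized-fraction audit

"Top $X\%$" is implemented as the linear-interpolation empirical
quantile at probability $1 - X/100$ with a strict `>` membership test.
Two consequences matter:

- On tie-free data, the realized fraction above the cutoff equals the
  requested fraction to within $1/n$.
- A point mass at or below the cutoff — in practice, samples with an
  estimated CD8 fraction of exactly zero — falls below the strict
  inequality, so the realized fraction drops *under* the request. With
  a 15% zero mass and a requested top-85% cut the realized CD8-high
  fraction lands around 84–85% rather than exactly 85%, which is the
  behavior observed on real deconvolved cohorts.

Because the choice of quantile estimator and tie rule is invisible in
the labels alone, every assignment carries its cutoff values and the
realized strictly-above fractions (`glance()` on the assignment), making
the calibration auditable.

Cutoffs are calibrated on the cohort being classified and never
transferred between cohorts: percentiles of different platforms
(RNA-seq TPM vs microarray ranks) are not comparable. The CD8 fraction
default is 0.85; the CYT fraction has no universal default and is a
user parameter (the shipped example configurations use 0.40 for the
RNA-seq-like cohort and 0.08 for the microarray-like cohort). No formal
objective for choosing these fractions is defined — the calibration
target is that CD8 and CYT should be highest in HTI and lowest in NI —
so they are exposed as parameters rather than optimized internally.

### CYT on microarray z-score cohorts

The geometric mean is only defined for non-negative expression. Cohorts
distributed as per-gene z-scores (microarray exports) would need the
original intensities, which are often unavailable. The package's
declared surrogate is rank-based: each sample's score is the mean of
the two genes' within-cohort fractional ranks (mid-ranks for ties),
giving values in $(0, 1]$ that are invariant to any strictly increasing
per-gene transform. Since the phenotype assignment depends on CYT only
through its cohort percentile, replacing values by ranks preserves
exactly the information the classifier uses. This surrogate is a design
choice of this package, not a published procedure.

## Statistical contrasts

Phenotype-wise comparisons of immune fractions and immunogenomic
features use the two-sided Mann-Whitney U test over all three label
pairs: these quantities are bounded, skewed, often zero-inflated, and a
rank test needs no distributional assumption. The exact null is
enumerated when $n_1 n_2 \le 400$ and the data are tie-free; otherwise
the tie-corrected normal approximation is used (the two agree to well
under 0.01 in the transition region). Panels report per-comparison
star annotations (strict thresholds at 1e-4, 1e-3, 0.01, 0.05) without
multiplicity correction, matching how such per-feature panels are
conventionally read; a Benjamini-Hochberg column is available with
`adjust = "BH"` but off by default. Clinical contingency tables use the
Pearson chi-square test, switching to Fisher's exact test for 2×2
tables with any expected cell under 5; explicit `unknown` levels are
parsed and retained in the tables but excluded from the tests.

## Differential expression and ranking

Per-gene two-group comparisons use Welch's t statistic on a log-like
scale (TPM input is moved through $\log_2(x+1)$ first; z-score and log2
input is used as is). Welch's t was chosen over a moderated
(empirical-Bayes) t deliberately: variance moderation earns its
complexity at small group sizes, while the phenotype groups this
pipeline targets run to hundreds of samples, where the two converge;
the output metadata records the test used. Genes with zero variance in
both groups have no defined t statistic — they are flagged, excluded
from the ranking, and given p = 1 when their means are also equal.

Volcano categorization marks a gene `up` when $\log_2\mathrm{FC} >
\log_2 1.5$ and $p < 0.05$ (symmetrically `down`), on raw p-values by
default with a switch for BH-adjusted ones, since conventions differ on
which a volcano should display. The GSEA ranking uses the t statistic
(not the fold change) in descending order, because t carries both
effect size and precision; ties break alphabetically and are logged.

## Pre-ranked GSEA

The enrichment statistic is the classic weighted running sum: walking
down the ranked list, set members increment the sum by
$|s|^p / \sum_{hits} |s|^p$ and non-members decrement it by
$1/(N - N_h)$; the enrichment score (ES) is the signed maximum
deviation, and the leading edge collects the members up to (positive
ES) or after (negative ES) the extremum. The weight exponent defaults
to $p = 1$, the standard pre-ranked setting; $p = 0$ gives the
unweighted Kolmogorov-Smirnov walk, whose running sum returns exactly
to zero. An exact tie between the positive and negative extremum is
possible (both are rational in the miss counts) and resolves to the
positive side by convention.

The null distribution is built by **gene-set permutation**: a ranked
list has no sample labels left to permute, so `n_perm` (default 1000)
uniformly random same-size sets are scored. NES divides ES by the mean
|null ES| of the same sign; the nominal p is the same-sign null tail
fraction (floored at $1/(n_{perm}+1)$); and the FDR q follows the
standard sign-stratified construction — pooled normalized null NES tail
fraction over observed NES tail fraction, clipped to $[0,1]$ and made
monotone in |NES|. Null samples are cached per set size, and all
randomness flows from one seed, so a fixed seed reproduces NES and q
bit-identically. The significance filter keeps |NES| > 1.7 with
q < 0.01 by default (both configurable). Genes in a set but absent from
the ranking are dropped per set with counts reported.

## Survival

Kaplan-Meier curves use the product-limit estimator with Greenwood
standard errors; censored records reduce the risk set without a step,
and at tied event/censor times censoring is processed after events (the
standard convention). Group differences use the k-group log-rank test
(observed minus expected with hypergeometric variance at each distinct
event time), covering the three phenotypes directly. Both are computed
through the `survival` package and verified in the test suite against
hand-tabulated oracles on small fixtures. Receptor subtypes are
exclusive, with HER2+ taking precedence over hormone-receptor status
(so HR+HER2− requires HER2-negative, and TN requires all three
negative); recurrence-specific endpoints censor events of the other
recurrence type at their event time. No Cox model is fitted — the
pipeline reports estimates and log-rank p-values only, and p-values are
reported raw with no significance verdicts attached.

## The synthetic cohort generator

`simulate_cohort()` generates cohorts with the statistical structure
the analysis assumes, so every downstream stage is testable without any
external download. Its defaults are the package's declared study
conditions, chosen once:

- **n = 1075 samples** in phenotype proportions **0.40 / 0.46 / 0.14**
  (HTI / CTI / NI), the group structure of a large RNA-seq breast
  cancer cohort.
- **CD8 fractions**: zero-inflated Beta. The base zero-inflation rate
  is 0.15, scaled per phenotype (0.25 / 0.5 / 3.0 for HTI / CTI / NI,
  capped below 1) since an estimated-zero CD8 fraction is far likelier
  in a non-inflamed tumor. Beta parameters order the nonzero means
  HTI > CTI ≫ NI.
- **Effector genes**: GZMA and PRF1 are lognormal in TPM with
  label-dependent log2 means (6 / 3.5 / 3, SD 1), ordered HTI > CTI ≥ NI
  as the phenotype definition requires.
- **Latent immune axis**: one standard-normal latent variable per
  sample couples the CD8 copula and both effector genes with loading
  0.55, which lands the CD8-CYT Spearman correlation near 0.5 — a weak
  correlation, deliberately: if infiltration determined killing, the
  two-axis model would be redundant.
- **Expression**: 2000 background genes, lognormal on TPM (Gaussian in
  log2, noise SD 1.0), columns renormalized to sum to $10^6$ so the
  scoring module consumes them unmodified. Three planted 50-gene sets
  carry a +1.0 log2 shift: an interferon-response-like set up in HTI
  and two estrogen-response-like sets up in CTI and NI, mirroring the
  enrichment directions this phenotype split is expected to expose.
- **Survival**: exponential event times with hazards 0.004 / 0.006 /
  0.008 per month (hazard ratio 0.5 for HTI vs NI), censored by an
  independent uniform horizon on 0–240 months.
- **Features**: TMB, mutation rates, neoantigen counts and checkpoint
  gene expression, lognormal/Poisson with a +1 log2 HTI shift.

`null_cohort()` re-runs the same machinery with every label effect
zeroed (shared distributions, no planted shifts, equal hazards); labels
are still drawn, so it calibrates the type-I error of each downstream
test. `worked_fixture()` is a 12-sample, 30-gene cohort built from
fixed arithmetic — GZMA/PRF1 values are perfect products, so its CYT
scores are the integers 600…40 — whose labels, rank-sum statistics and
enrichment scores are hand-checkable.

**What the generator does not emulate** — and hence what passing tests
do not certify about real data: gene-gene correlation beyond the single
latent immune axis, batch or platform effects, realistic mutation
spectra, deconvolution estimation error in the fraction table (the
generated fractions are exact draws, not estimates), non-proportional
hazards, or informative censoring. Tests on synthetic cohorts verify
the *machinery*; they do not validate the biological claims on any real
cohort.

## Numerical and interface choices

- Quantiles use linear interpolation between order statistics (R type
  7), the common default in scientific software; the realized-fraction
  audit makes the choice inspectable.
- Degenerate inputs fail loudly and early: all-zero samples in TPM
  conversion, missing effector genes, empty sample intersections,
  constant vectors in correlation, zero-margin contingency tables and
  empty gene-set overlaps all raise errors (or flagged results) naming
  the offending item.
- Duplicate gene symbols in expression exports collapse to the
  maximal-variance row, deterministically, with a report of what was
  dropped.
- Every stochastic stage (gene-set permutation, simulation) takes an
  explicit seed, restores the caller's RNG state, and reproduces
  bit-identically; the pipeline refuses a configuration that enables
  GSEA without a seed.
- The pipeline (`run_pipeline()`) is driven by a single YAML or list
  configuration, stamps every output with the configuration hash and
  seed, and on any stage failure writes a partial-output manifest
  naming the failed stage. The package's interface is its exported
  functions plus this config-driven driver; no shell wrapper is
  shipped, since R users call the functions directly and the
  acceptance script shows the end-to-end, non-interactive invocation.

## Problem sizes used in validation

The shipped test suite validates the enrichment walk against a
brute-force oracle on 200 random lists of up to 50 genes, calibrates
nominal GSEA p-values with 200 random sets at 1000 permutations,
checks Mann-Whitney exact/normal agreement at group sizes 8–20 and
type-I error over 1000 label permutations, verifies KM/log-rank against
hand-tabulated oracles on fixtures of up to 20 records with 500
equal-hazard replicates for p-uniformity, exercises the classification
invariants on 1000 random cohorts, and runs the full
simulate → score → classify → rank → GSEA → survival chain at n = 1000
across a 20-seed grid, requiring all three planted sets at q < 0.01 and
a log-rank rejection at p < 0.01 in at least 18 of 20 seeds. These
sizes keep the complete suite within a few minutes on one CPU while
leaving each check statistically meaningful.

## Known limitations

- The CYT surrogate for z-score cohorts is rank-based and therefore
  not numerically comparable to TPM-based CYT across cohorts; only
  within-cohort percentiles are used, by design.
- No batch correction, cross-cohort harmonization, variance shrinkage
  or surrogate-variable adjustment is provided.
- FDR q-values from gene-set permutation are conditional on the
  supplied collection; a one-set collection has a degenerate pooled
  null, so collections should include enough sets (the pipeline's
  planted-plus-random default illustrates this).
- The contrast panel's star annotations are per-comparison; with many
  features the BH option should be turned on.
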