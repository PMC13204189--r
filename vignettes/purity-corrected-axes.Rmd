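---
title: "Purity-corrected prognostic axes: methods and design"
author: "gliomaAxes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Purity-corrected prognostic axes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliomaAxes)
```

## The problem

Bulk tumor molecular profiles are mixtures: a fraction of the material
(the *tumor purity*) comes from malignant cells, the rest from immune,
stromal and vascular admixture. Two consequences matter for prognostic
biomarker work in diffuse glioma. First, latent factors learned from
bulk data can simply re-describe cell-type composition, so an apparent
survival association may be a purity artifact. Second, signatures tuned
on one cohort often degrade on another when any parameter — even a
per-gene mean — is re-estimated on the validation data, which quietly
turns validation into refitting.

`gliomaAxes` addresses both with a fixed pipeline: learn a loading
matrix and per-gene scaling once, freeze them into a *projection
bundle*, score external cohorts by pure matrix multiplication, and
quantify how much of each factor's prognostic signal survives
regression on purity.

## Factor model and projection

### The stand-in factorization

The package's factorization (`fitFactorModel`) is a truncated singular
value decomposition of the column-concatenated, per-feature
standardized views, with factors pruned by variance explained. This is
a deliberate, documented stand-in for probabilistic multi-omics factor
models: those prune by automatic relevance determination inside a
variational inference loop that is a tool of its own, and this package
does not reimplement it. Two design points follow:

- **Imported loadings are first-class.** `importBundle()` accepts any
  externally fitted loading matrix with scaling parameters, so the
  projection, purity and survival machinery apply unchanged to loadings
  from a probabilistic model.
- **Training and projection coincide.** Training scores are defined as
  the least-squares projection of the training data onto the loadings.
  Because SVD loadings have orthonormal rows, this equals the linear
  map Z = XWᵀ used out-of-sample, so a cohort projected through its own
  bundle reproduces its training scores exactly. A probabilistic model
  does not guarantee this identity (posterior-mean scores need not
  equal XWᵀ); importers of such loadings should decide which convention
  downstream analyses use and apply it consistently to the training
  cohort too.

Variance explained is computed per (factor, view) as
`100 * (1 - ||Y - z_k w_k||^2 / ||Y||^2)` with the per-view
least-squares single-factor score, floored at 0 for reporting. Pruning
keeps factors whose *total* variance explained reaches `pruneMinVe`
(percent; default 1), ordered decreasingly.

### Harmonization and the frozen map

Projection of a new cohort has five fixed steps (`harmonizeFeatures` +
`projectScores`): map/collapse identifiers to symbols (duplicates by
arithmetic mean), intersect with the bundle's ordered feature list,
log2(count + 1), standardize each shared gene with the *frozen*
training μ/σ, and impute bundle genes absent from the cohort with 0 —
exactly the standardized training mean, so a missing gene contributes
the neutral value rather than a platform-specific one. A warning is
raised when the imputed fraction exceeds 10% (configurable); the
robustness tests in the suite exercise ~7%, where projected scores
change by well under 10% in root-mean-square. The feature order is
verified by a content hash stored in the bundle; projection refuses
shuffled or truncated matrices rather than silently multiplying
misaligned columns. Projection involves no randomness: identical
inputs give identical scores, and bundles serialize to plain text at 17
significant digits so a written-and-reread bundle projects bit-identically.

## Purity correction

Purity enters residualization linearly: per factor, ordinary least
squares of score on (intercept, purity), residuals kept
(`residualizeScores`). Sensitivity is summarized by
(`puritySensitivity`):

- **Attenuation** `(1 - HR_residualized / HR_raw) * 100`, on hazard
  ratios from continuous-score Cox fits (per-1-SD by default). Negative
  attenuation — the hazard strengthening after adjustment — is
  legitimate and reported as such.
- **Stratum concordance**: the percentage of samples on the same side
  of the median under raw and residualized scores, each split computed
  independently. Ties at the median go to the low stratum; this is
  arbitrary but deterministic and documented.

Partial Spearman correlation residualizes the *ranks* of both variables
on the ranks of purity and correlates the residuals; the p-value uses
the t approximation on n − 3 degrees of freedom, with a seeded
permutation option for small n. Complete-case handling applies
throughout, with dropped-sample counts reported, mirroring the
per-analysis denominators that purity availability induces in real
cohorts.

## Survival statistics

Cox models are fitted by the partial likelihood with Efron tie handling
(Breslow selectable) through the survival package, which is also what
the upstream analyses in this field use; the test suite checks the fits
against an independent grid-search maximization of the partial
likelihood and against simulation calibration rather than trusting the
dependency blindly. Continuous predictors can be standardized to unit
sd *within the analysis cohort* so hazard ratios read per 1-SD
increase; whether the sd should instead be frozen from training is
genuinely open, so it is a flag (`scalePerSd`) with the per-cohort
convention as default. Wald confidence intervals use z = 1.959964.
Proportional hazards are checked by scaled Schoenfeld residuals against
Kaplan–Meier-transformed time; covariates violating the assumption
should enter as strata (supported via `strata =`), the convention the
stratified-baseline machinery exists for.

The IDH-stratified table fits univariate per-1-SD Cox models in every
(cohort, IDH stratum, factor) cell and adjusts p-values by
Benjamini–Hochberg across the *full* family in one pass — all cohorts,
strata and factors together — matching the reporting convention the
pipeline targets; per-cohort families are selectable. Cells with an
empty stratum or fewer than 2 events yield reason-coded rows instead of
errors, so the table shape is always the full grid.

Survival extremes use strict inequalities (OS < 6 or > 15 months;
boundary values excluded), pre-specified cutoffs that keep the analysis
independent of the factor-score distribution. Mann–Whitney U uses exact
enumeration when the smaller sample has ≤ 8 untied values, a
tie-corrected normal approximation otherwise.

## Meta-analysis

DerSimonian–Laird pooling is implemented directly from the moment
formulas (fixed weights w = 1/SE², Q, τ² truncated at 0,
random-effects weights 1/(SE² + τ²), I² = max(0, (Q − df)/Q)·100),
because the package treats these quantities — including the k = 1 and
Q = 0 degeneracies and the exact truncation rule — as part of its
contract; metafor serves as an independent cross-check in the tests.
Standard errors can be reconstructed from printed confidence limits as
(ln hi − ln lo)/(2·1.959964), which assumes log-symmetric Wald
intervals; pooled results from reconstructed SEs inherit the rounding
of the printed limits, so two-decimal agreement is the right
expectation there, and heterogeneity statistics (I²) recovered from
rounded inputs can differ in the first decimal. Meta-regression uses
weighted least squares with the method-of-moments residual τ²; with k
cohorts and p coefficients the fit saturates at k = p (residual Q = 0
by construction) and is flagged as such rather than blocked, because a
saturated fit still reports coefficients. The Knapp–Hartung adjustment
is available behind a flag and off by default, matching plain Wald
reporting.

## Concordance benchmarking

Harrell's C counts pairs where the member with the shorter observed
time has an event (pairs tied in time with events on both sides are
unusable; a tied time with exactly one event counts the event member as
failing first), crediting 0.5 for tied scores. The implementation is a
vectorized exact pair enumeration — no approximation — and is checked
against both a brute-force loop and the survival package's concordance.
Bootstrap CIs are percentile intervals over patient resamples
(B = 1000 by default, seeded); ΔC contrasts use *paired* resamples so
the two scores face identical sampling noise. Optimism-corrected
refitting per resample is deliberately not the default: the benchmark
contrasts fixed scores, and refitting answers a different question.
Composite signatures score as direction-weighted mean z-scores over the
panel genes present, erroring past 50% missingness. The shipped
angiogenic panel contains six canonical members (VEGFA, FLT1, KDR,
ANGPT1, ANGPT2, PECAM1); the remaining fourteen are representative
angiogenesis-pathway placeholders users should replace with their own
panel definitions, which is why signature files are a user-facing TSV
format rather than hard-coded gene sets.

## The synthetic generator: what it emulates, and what it does not

`simConfig()` defaults define the reference conditions used across the
tests: two cohorts of 500 samples, 2000 genes, 12 factors with
contiguous sparse loading blocks (90% sparsity; blocks overlap at most
25% of a block), factor signal amplitudes decreasing from 6 to 2.5 log2
units, a dominant prognostic factor 1 with log-HR 0.5 per score unit,
IDH-mutant prevalence 0.55 with a −1 shift on factor 1 and a protective
log-hazard of −0.8, purity ~ Beta(8, 3) (right-shifted, matching bulk
purity ranges) admixing a stromal profile at weight 0.5, residual noise
sd 0.5, exponential baseline hazard with median ~15 months, 30%
censoring, external-cohort platform shifts of sd 0.1 (per-gene scale
and offset) and 6.8% missing genes.

Mechanistically: expression signal on the log2 scale is
`purity-weighted mixture of (tumor baseline + scores' x loadings) and a
stromal profile`, exponentiated and Poisson-sampled to counts (giving a
realistic mean–variance relation after log2(count + 1)); survival is
Weibull with log-hazard linear in the true scores, IDH status and
optionally purity itself; censoring is an independent exponential whose
rate is found by bisection against the realized event times, making the
target censoring fraction exact and reproducible. One master seed is
expanded into per-cohort, per-view substreams, so e.g. the gene-drop
set of cohort 2 does not depend on how many draws cohort 1 consumed.

Two scenario choices in the test suite deserve explicit statement.
In the *purity-independent* scenario the factor effect is 0.7 and the
admixture weight 0; in the *purity-driven* scenario the factor effect is
0, purity carries a log-hazard of −8 (about one log-hazard unit per
purity sd), the admixture weight is 1 and the latent program is made
weak (amplitude 0.3), so the leading expression factor is a purity
surrogate by construction. The projected factor is oriented to the
adverse hazard direction before computing attenuation, since an SVD
factor's sign is arbitrary.

What the generator does *not* emulate: probe-level methylation
annotation (the optional methylation view maps probes 1:1 onto genes),
chromosome-scale CNA segment geometry, batch structure within a cohort,
non-linear purity effects, informative censoring, or the correlation
between IDH status and purity (treated as independent unless the
scores' IDH shift induces one). Passing tests therefore demonstrate
correctness of the statistical machinery under a faithful but idealized
mixture model — they do not certify performance on real TCGA/CGGA data,
whose effect sizes, missingness patterns and platform differences are
messier.

## Numerical choices

- Standard deviations use the n − 1 denominator everywhere.
- Genome coordinates are 0-based half-open internally; 1-based
  inclusive inputs convert at the reader boundary (`oneBased = TRUE`).
  CNA segment-to-gene mapping weights overlapping segments' log2 ratios
  by overlap length in base pairs — the least surprising continuous
  choice for "intersecting" segments with genes, and the one that keeps
  each gene value inside the range of its covering segments.
- Methylation β-values are clipped to [1e−6, 1 − 1e−6] before the
  logit so M-values stay finite; clip counts are reported.
- Genes with zero training sd standardize to all-zero rows (flagged),
  not NaN.
- Bundle text serialization uses 17 significant digits (bit-exact
  round trip); feature order is hash-verified.
- Median-split ties go to the low stratum; Cox convergence uses the
  survival package's tightened control (eps 1e−9, 50 iterations);
  possible separation (|coef| > 15) warns.

## Problem sizes in the test suite

The suite runs module tests at small sizes (tens to hundreds of
samples) and property/calibration tests at the reference conditions
scaled to keep the whole suite around a minute on one core: projection
recovery at 500 samples × 2000 genes, purity scenarios at 20 replicates
of 800–1000 samples over 20–60 genes (the survival side does not need
wide matrices), Cox calibration at 100 replicates of n = 2000, and
type-I error checks at 200 null replicates of n = 200–300. The
acceptance script re-runs the same analyses from scratch under a
user-supplied seed.

## Known limitations

- The factorization stand-in shares only the *interface* with
  probabilistic multi-omics factor models; variance-explained pruning
  is not automatic relevance determination, and the 25 → 12 factor
  trajectory of an ARD fit is not reproducible here.
- Multiple imputation for missing covariates is out of scope;
  complete-case analysis with per-model accounting is the implemented
  strategy.
- Purity is an input column. The package neither computes ESTIMATE/CPE
  scores nor models their estimation error, which attenuates purity
  adjustment toward under-correction.
- No time-varying covariates, competing risks, frailty terms, or
  time-dependent discrimination measures.
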