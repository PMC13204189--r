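# gliomaAxes

Purity-corrected latent-factor prognostic analysis for diffuse glioma.

Bulk tumor profiles mix malignant cells with immune, stromal and
vascular admixture, so prognostic signatures discovered on bulk
multi-omics data can merely re-describe tumor purity, and rarely
transfer across cohorts. `gliomaAxes` implements the analysis framework
for validating a continuous multi-omics prognostic axis against both
problems:

- **Frozen-parameter projection.** A discovery cohort yields a loading
  matrix *W* (factors × genes) plus per-gene scaling parameters
  (μ, σ) and an ordered feature list, frozen into a portable
  *projection bundle*. A new RNA-seq cohort is scored as
  **Z = XWᵀ**, where *X* is the cohort's log2 expression standardized
  with the *frozen* μ/σ after intersecting with the bundle's feature
  list (bundle genes absent from the cohort are imputed with 0, the
  standardized training mean). Nothing is re-estimated, so external
  cohorts are genuine validation sets.
- **Purity correction.** Factor scores are residualized on a tumor
  purity estimate (OLS per factor); the sensitivity statistics are the
  attenuation percentage, (1 − HR<sub>residualized</sub>/HR<sub>raw</sub>) × 100,
  and the median-split stratum concordance before vs after adjustment.
  Partial Spearman correlation (ranks residualized on purity ranks) is
  provided for clinical covariates.
- **Survival machinery.** Cox proportional-hazards fits (Efron ties,
  per-1-SD scaling, stratified baselines), Kaplan–Meier with Greenwood
  variance, log-rank, nested-model and factor × IDH interaction
  likelihood-ratio tests, scaled-Schoenfeld proportional-hazards
  checks, IDH-stratified hazard tables with Benjamini–Hochberg FDR,
  survival-extremes phenotyping (OS < 6 or > 15 months, strict
  inequalities) and Mann–Whitney U.
- **Cross-cohort synthesis.** DerSimonian–Laird random-effects pooling
  with Cochran's Q, τ² and I², moment-based meta-regression with
  residual heterogeneity, and leave-one-cohort-out sensitivity;
  standard errors can be reconstructed from printed confidence limits.
- **Benchmarking.** Harrell's C with bootstrap percentile CIs, paired
  bootstrap ΔC contrasts against composite gene-panel signatures
  (mean z-score scoring; a default 20-gene angiogenic panel ships in
  `inst/extdata/`, of which six members are canonical and the rest are
  documented placeholders).
- **Synthetic multi-cohort generator.** Sparse block loadings, purity
  drawn Beta(8,3) admixing a stromal profile, IDH-linked factor shifts,
  Weibull survival with log-hazard linear in the true scores, censoring
  calibrated by bisection, per-cohort platform shifts and missing
  genes — every downstream stage is testable without downloads, with
  ground truth carried alongside.

The central data objects are S4 (`ProjectionBundle`, `FactorScores`,
`ExpressionMatrix` with an explicit counts → log2 → standardized scale
state, `SimulationConfig`), and simulated cohorts are
`SummarizedExperiment`s with clinical tables as `colData`.

## Worked example

```r
library(gliomaAxes)

cfg <- simConfig(nCohorts = 2, nSamplesPerCohort = 300, nGenes = 1000,
                 nFactors = 6, seed = 7)
cohorts <- simulateMulticohort(cfg)

# training cohort: preprocess, fit the stand-in factor model, freeze a bundle
lg  <- log2Transform(ExpressionMatrix(SummarizedExperiment::assay(cohorts$training)))
sp  <- zscoreFit(lg)
mod <- fitFactorModel(list(rna = zscoreApply(lg, sp)), kInit = 10,
                      pruneMinVe = 1, scaling = list(rna = sp))
bundle <- exportBundle(mod, "rna")
#> ProjectionBundle: 7 factors x 1000 genes; hash 4766a166

# external cohort: harmonize against the frozen bundle, then project
lgx <- log2Transform(ExpressionMatrix(SummarizedExperiment::assay(cohorts$external1)))
h   <- harmonizeFeatures(lgx, bundle)   # 932 shared, 68 imputed (fraction 0.068)
zx  <- projectScores(h$matrix, bundle, cohort = "external1")
#> FactorScores: 300 samples x 7 factors [ projected , external1 ]

# purity sensitivity of the leading factor
clx <- as.data.frame(SummarizedExperiment::colData(cohorts$external1))
puritySensitivity(zx, clx)
#> Purity sensitivity (n = 300)
#>   HR raw          1.878
#>   HR residualized 1.840
#>   attenuation     2.01%
#>   stratum concordance 92.0%
```

The attenuation near zero and stratum concordance near 100% say the
factor's hazard is not a purity artifact: adjusting for purity moves
the hazard ratio by ~2% and reassigns 8% of patients across the median
split. Concordance benchmarking of the projected score:

```r
s1 <- scoreMatrix(zx)[clx$sample_id, 1]
bootstrapC(s1, clx, B = 1000, seed = 7)
#> C-index 0.666 (95% CI 0.628-0.702; B = 1000, n = 300, 211 events)
```

Pooling per-cohort hazard estimates published only as HRs with 95% CIs:

```r
eff <- studyEffects(label = c("discovery", "validation1", "validation2"),
                    hr = c(1.23, 1.64, 1.20), ciLow = c(1.03, 1.35, 1.06),
                    ciHigh = c(1.46, 1.99, 1.36))
poolDL(eff)
#> Pooled HR 1.329 (95% CI 1.108-1.593), k = 3
#>   tau^2 = 0.0187, Q = 7.461 (df 2, p = 0.024), I^2 = 73.2%
leaveOneOut(eff)$minHr      # 1.21: floor of the sensitivity analysis
deltaCFromConcordances(0.797, 0.801)   # -0.004
```

A declarative end-to-end run (simulate → harmonize → bundle → project →
purity → stratified survival + meta → benchmark → extremes) is driven
by `runPipeline()` from a YAML or list configuration; it writes
per-stage TSV/JSON outputs, a per-cohort sample-attrition ledger and a
run manifest. See `?runPipeline` and the methods vignette
(`vignettes/purity-corrected-axes.Rmd`).

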