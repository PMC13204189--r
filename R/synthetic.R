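#' SimulationConfig: study conditions for the synthetic multi-cohort generator
#'
#' Encodes the data-generating conditions the pipeline is exercised under:
#' sparse block loadings shared across cohorts, standard-normal factor
#' scores with an IDH-linked shift, a Beta-distributed tumor purity that
#' admixes a stromal expression profile, Weibull event times whose
#' log-hazard is linear in the factor scores and IDH status, independent
#' exponential censoring calibrated to a target censoring fraction, and
#' per-cohort platform shifts plus missing genes for external cohorts.
#'
#' @slot nCohorts,nSamplesPerCohort,nGenes,nFactors integer dimensions.
#' @slot loadingSparsity fraction of genes with zero loading per factor.
#' @slot maxBlockOverlap largest tolerated pairwise overlap between factor
#'   blocks, as a fraction of the block length.
#' @slot factorStrength per-factor signal amplitude on the log2 scale.
#' @slot factorSurvivalBetas per-factor log-hazard coefficients.
#' @slot idhPrevalence fraction of IDH-mutant samples.
#' @slot idhFactorShift per-factor mean score shift in IDH-mutant samples.
#' @slot idhHazardBeta log-hazard coefficient of IDH-mutant status.
#' @slot purityHazardBeta log-hazard coefficient of tumor purity itself
#'   (0 by default: purity affects expression, not survival).
#' @slot purityBetaParams shape parameters (a, b) of the Beta purity law.
#' @slot purityConfoundStrength weight of the stromal-profile admixture
#'   (0 = expression independent of purity, 1 = full admixture).
#' @slot noiseSd residual log2-scale noise sd per view.
#' @slot baselineHazardRate,baselineHazardShape Weibull baseline hazard.
#' @slot censoringRate target fraction of censored samples.
#' @slot platformScaleSd,platformOffsetSd per-gene affine platform-shift
#'   magnitudes applied to external cohorts.
#' @slot missingGeneFraction fraction of genes dropped from each external
#'   cohort.
#' @slot withMethylation,withCna logical, emit the optional views.
#' @slot seed integer master seed; every stochastic stage derives its own
#'   substream from it.
#' @export
setClass("SimulationConfig",
  representation(
    nCohorts = "integer", nSamplesPerCohort = "integer",
    nGenes = "integer", nFactors = "integer",
    loadingSparsity = "numeric", maxBlockOverlap = "numeric",
    factorStrength = "numeric", factorSurvivalBetas = "numeric",
    idhPrevalence = "numeric", idhFactorShift = "numeric",
    idhHazardBeta = "numeric", purityHazardBeta = "numeric",
    purityBetaParams = "numeric",
    purityConfoundStrength = "numeric", noiseSd = "numeric",
    baselineHazardRate = "numeric", baselineHazardShape = "numeric",
    censoringRate = "numeric", platformScaleSd = "numeric",
    platformOffsetSd = "numeric", missingGeneFraction = "numeric",
    withMethylation = "logical", withCna = "logical", seed = "integer"),
  validity = function(object) {
    msg <- NULL
    frac01 <- function(x) all(x >= 0 & x <= 1)
    if (!frac01(c(object@loadingSparsity, object@idhPrevalence,
                  object@purityConfoundStrength, object@maxBlockOverlap)))
      msg <- c(msg, "fractions must lie in [0,1]")
    if (object@missingGeneFraction < 0 || object@missingGeneFraction >= 1)
      msg <- c(msg, "missingGeneFraction must lie in [0,1)")
    if (object@censoringRate < 0 || object@censoringRate >= 1)
      msg <- c(msg, "censoringRate must lie in [0,1)")
    if (object@nFactors > object@nGenes)
      msg <- c(msg, "nFactors must not exceed nGenes")
    if (object@baselineHazardRate <= 0 || object@baselineHazardShape <= 0)
      msg <- c(msg, "baseline hazard rate and shape must be positive")
    if (any(object@purityBetaParams <= 0) ||
        length(object@purityBetaParams) != 2L)
      msg <- c(msg, "purityBetaParams must be two positive shapes")
    k <- object@nFactors
    if (length(object@factorSurvivalBetas) != k ||
        length(object@idhFactorShift) != k ||
        length(object@factorStrength) != k)
      msg <- c(msg, "per-factor parameter vectors must have length nFactors")
    if (is.null(msg)) TRUE else msg
  })

#' Build a SimulationConfig
#'
#' Defaults mirror the cross-cohort validation setting the pipeline is
#' designed for: two cohorts of 500 samples, 2000 genes, 12 sparse latent
#' factors, a dominant prognostic factor 1 (log-HR 0.5) that is shifted
#' downward in IDH-mutant samples, a right-shifted Beta(8, 3) purity,
#' moderate stromal admixture, 6.8\% of genes missing from external
#' cohorts and mild per-gene platform shifts.
#'
#' @param nCohorts,nSamplesPerCohort,nGenes,nFactors dimensions.
#' @param loadingSparsity fraction of zero loadings per factor.
#' @param maxBlockOverlap tolerated pairwise block overlap fraction.
#' @param factorStrength per-factor log2-scale signal amplitude; recycled
#'   to \code{nFactors}.
#' @param factorSurvivalBetas per-factor log-hazard coefficients; recycled.
#' @param idhPrevalence IDH-mutant fraction.
#' @param idhFactorShift per-factor mutant mean shift; recycled.
#' @param idhHazardBeta log-hazard of IDH-mutant status (protective when
#'   negative).
#' @param purityHazardBeta log-hazard coefficient of purity itself
#'   (default 0).
#' @param purityBetaParams Beta(a, b) shapes of the purity distribution.
#' @param purityConfoundStrength stromal admixture weight in [0,1].
#' @param noiseSd residual noise sd (log2 units).
#' @param baselineHazardRate,baselineHazardShape Weibull baseline; shape 1
#'   is exponential.
#' @param censoringRate target censored fraction in [0,1).
#' @param platformScaleSd,platformOffsetSd external-cohort per-gene affine
#'   shift magnitudes.
#' @param missingGeneFraction fraction of genes absent per external cohort.
#' @param withMethylation,withCna emit the optional methylation/CNA views.
#' @param seed master seed.
#' @return A validated \linkS4class{SimulationConfig}.
#' @examples
#' cfg <- simConfig(nSamplesPerCohort = 50, nGenes = 200, nFactors = 3)
#' cfg
#' @export
simConfig <- function(nCohorts = 2L, nSamplesPerCohort = 500L,
                      nGenes = 2000L, nFactors = 12L,
                      loadingSparsity = 0.9, maxBlockOverlap = 0.25,
                      factorStrength = seq(6, 2.5,
                                           length.out = nFactors),
                      factorSurvivalBetas = c(0.5,
                                              rep(0, nFactors - 1L)),
                      idhPrevalence = 0.55,
                      idhFactorShift = c(-1, rep(0, nFactors - 1L)),
                      idhHazardBeta = -0.8,
                      purityHazardBeta = 0,
                      purityBetaParams = c(8, 3),
                      purityConfoundStrength = 0.5,
                      noiseSd = 0.5,
                      baselineHazardRate = log(2) / 15,
                      baselineHazardShape = 1,
                      censoringRate = 0.3,
                      platformScaleSd = 0.1, platformOffsetSd = 0.1,
                      missingGeneFraction = 0.068,
                      withMethylation = FALSE, withCna = FALSE,
                      seed = 1L) {
  new("SimulationConfig",
      nCohorts = as.integer(nCohorts),
      nSamplesPerCohort = as.integer(nSamplesPerCohort),
      nGenes = as.integer(nGenes), nFactors = as.integer(nFactors),
      loadingSparsity = loadingSparsity, maxBlockOverlap = maxBlockOverlap,
      factorStrength = rep_len(factorStrength, nFactors),
      factorSurvivalBetas = rep_len(factorSurvivalBetas, nFactors),
      idhPrevalence = idhPrevalence,
      idhFactorShift = rep_len(idhFactorShift, nFactors),
      idhHazardBeta = idhHazardBeta,
      purityHazardBeta = purityHazardBeta,
      purityBetaParams = as.numeric(purityBetaParams),
      purityConfoundStrength = purityConfoundStrength,
      noiseSd = noiseSd,
      baselineHazardRate = baselineHazardRate,
      baselineHazardShape = baselineHazardShape,
      censoringRate = censoringRate,
      platformScaleSd = platformScaleSd,
      platformOffsetSd = platformOffsetSd,
      missingGeneFraction = missingGeneFraction,
      withMethylation = withMethylation, withCna = withCna,
      seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nCohorts, "cohort(s) x",
      object@nSamplesPerCohort, "samples,", object@nGenes, "genes,",
      object@nFactors, "factors (seed", object@seed, ")\n")
})

#' Generate a sparse block-structured loading matrix
#'
#' Each factor loads on one contiguous block of genes (mimicking
#' coordinated programs such as an ECM/angiogenesis module dominating the
#' leading factor); block starts are spread evenly so that distinct
#' factors overlap by at most \code{maxBlockOverlap} of a block length.
#' Rows are scaled to unit Euclidean norm.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return factors x genes numeric matrix with unit-norm rows.
#' @examples
#' W <- generateLoadings(simConfig(nGenes = 100, nFactors = 2,
#'                                 loadingSparsity = 0.9))
#' rowSums(W != 0)  # 10 nonzeros per factor
#' @export
generateLoadings <- function(config) {
  k <- config@nFactors
  p <- config@nGenes
  m <- round((1 - config@loadingSparsity) * p)
  stopIfNot(m >= 1,
            "loadingSparsity ", config@loadingSparsity,
            " leaves a factor with zero nonzero loadings over ", p, " genes")
  starts <- if (k == 1L) 0L else
    round((seq_len(k) - 1L) * (p - m) / (k - 1L))
  if (k > 1L && m < p) {  # dense loadings necessarily share all genes
    overlap <- max(0, m - min(diff(starts)))
    stopIfNot(overlap / m <= config@maxBlockOverlap + 1e-9,
              "factor blocks overlap by ", round(overlap / m, 3),
              " of a block; exceeds maxBlockOverlap ",
              config@maxBlockOverlap)
  }
  set.seed(deriveSeed(config@seed, "loadings"))
  W <- matrix(0, k, p,
              dimnames = list(paste0("Factor", seq_len(k)),
                              sprintf("gene%04d", seq_len(p))))
  for (f in seq_len(k)) {
    idx <- starts[f] + seq_len(m)
    w <- rnorm(m)
    W[f, idx] <- w / sqrt(sum(w^2))
  }
  W
}

# Shared tumor/stromal baseline profiles; fixed by the master seed so that
# all cohorts of one configuration share them.
baselineProfiles <- function(config) {
  set.seed(deriveSeed(config@seed, "baselines"))
  list(tumor = rnorm(config@nGenes, mean = 6, sd = 1),
       stromal = rnorm(config@nGenes, mean = 6, sd = 1))
}

# Calibrate the exponential censoring rate so that the realized censored
# fraction hits the target; bisection on the rate against fixed Exp(1)
# draws keeps the calibration deterministic.
calibrateCensoring <- function(eventTimes, exp1Draws, targetRate) {
  if (targetRate <= 0) return(rep(Inf, length(eventTimes)))
  frac <- function(rate) mean(exp1Draws / rate < eventTimes)
  lo <- 1e-8; hi <- 1e4
  for (i in 1:200) {
    mid <- sqrt(lo * hi)
    if (frac(mid) < targetRate) lo <- mid else hi <- mid
  }
  exp1Draws / sqrt(lo * hi)
}

#' Simulate one cohort with known latent structure and factor-driven
#' survival
#'
#' Factor scores are standard normal with the configured mean shift added
#' for IDH-mutant samples. The log2 expression signal is a purity-weighted
#' admixture of the tumor program (baseline + scores' x loadings) and a
#' stromal profile, plus Gaussian noise; counts arise by Poisson sampling
#' of the exponentiated signal. Event times are Weibull with log-hazard
#' linear in the true scores and IDH status; censoring is independent
#' exponential calibrated to the target censoring fraction.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param loadings factors x genes matrix conforming to \code{config}
#'   (defaults to \code{generateLoadings(config)}).
#' @param cohortIndex integer; cohorts beyond 1 receive per-gene affine
#'   platform shifts and random gene dropout when simulated through
#'   \code{\link{simulateMulticohort}}.
#' @param platformShift,dropGenes internal switches used by
#'   \code{simulateMulticohort}; cohort 1 never receives either.
#' @return A \link[SummarizedExperiment]{SummarizedExperiment}: assay
#'   \code{counts} (genes x samples), \code{colData} with columns
#'   sample_id, os_months, event, idh_status, purity, age, grade, and
#'   \code{metadata(x)$truth} holding true scores, purity, loadings and
#'   hazard coefficients. Optional assays \code{methylation_beta} and
#'   \code{cna_log2} when enabled in the config.
#' @examples
#' cfg <- simConfig(nSamplesPerCohort = 40, nGenes = 100, nFactors = 2,
#'                  factorStrength = 4)
#' sc <- simulateCohort(cfg)
#' sc
#' @export
simulateCohort <- function(config, loadings = generateLoadings(config),
                           cohortIndex = 1L, platformShift = FALSE,
                           dropGenes = FALSE) {
  stopIfNot(nrow(loadings) == config@nFactors &&
              ncol(loadings) == config@nGenes,
            "loadings do not conform to the configuration")
  n <- config@nSamplesPerCohort
  p <- config@nGenes
  k <- config@nFactors
  prof <- baselineProfiles(config)

  set.seed(deriveSeed(config@seed, "cohort", cohortIndex, "clinical"))
  idh <- rbinom(n, 1L, config@idhPrevalence)
  purity <- rbeta(n, config@purityBetaParams[1], config@purityBetaParams[2])
  Z <- matrix(rnorm(n * k), n, k) +
    outer(idh, config@idhFactorShift)
  dimnames(Z) <- list(sprintf("C%d_S%03d", cohortIndex, seq_len(n)),
                      rownames(loadings))
  age <- pmax(18, round(rnorm(n, 55, 12)))
  grade <- sample(c(2L, 3L, 4L), n, replace = TRUE,
                  prob = c(0.25, 0.3, 0.45))

  # survival: Weibull cumulative hazard rate * t^shape * exp(eta)
  eta <- drop(Z %*% config@factorSurvivalBetas) +
    config@idhHazardBeta * idh +
    config@purityHazardBeta * (purity - mean(purity))
  u <- runif(n)
  eventTime <- (-log(u) /
                  (config@baselineHazardRate * exp(eta)))^
    (1 / config@baselineHazardShape)
  cens <- calibrateCensoring(eventTime, rexp(n), config@censoringRate)
  osMonths <- pmin(eventTime, cens)
  event <- as.integer(eventTime <= cens)

  # expression view
  set.seed(deriveSeed(config@seed, "cohort", cohortIndex, "expression"))
  signal <- matrix(prof$tumor, n, p, byrow = TRUE) +
    Z %*% (loadings * config@factorStrength)
  w <- config@purityConfoundStrength
  mix <- (1 - w * (1 - purity)) * signal +
    (w * (1 - purity)) %o% prof$stromal
  if (platformShift) {
    set.seed(deriveSeed(config@seed, "cohort", cohortIndex, "platform"))
    a <- rnorm(p, 1, config@platformScaleSd)
    b <- rnorm(p, 0, config@platformOffsetSd)
    mix <- sweep(sweep(mix, 2, a, `*`), 2, b, `+`)
  }
  mix <- mix + matrix(rnorm(n * p, 0, config@noiseSd), n, p)
  lambda <- pmin(2^mix, 2^20)
  counts <- matrix(rpois(n * p, lambda), n, p)
  dimnames(counts) <- list(rownames(Z), colnames(loadings))

  keep <- colnames(loadings)
  if (dropGenes && config@missingGeneFraction > 0) {
    set.seed(deriveSeed(config@seed, "cohort", cohortIndex, "genedrop"))
    nDrop <- round(config@missingGeneFraction * p)
    keep <- setdiff(keep, sample(colnames(loadings), nDrop))
  }

  assays <- list(counts = t(counts[, keep, drop = FALSE]))
  if (config@withMethylation) {
    set.seed(deriveSeed(config@seed, "cohort", cohortIndex, "methylation"))
    M <- Z %*% (loadings * (config@factorStrength / 2)) +
      matrix(rnorm(n * p, 0, config@noiseSd), n, p)
    beta <- 2^M / (1 + 2^M)
    beta <- pmin(pmax(beta, 1e-6), 1 - 1e-6)
    # probes map 1:1 onto genes in the synthetic design, so the view
    # shares the gene row space of the count assay
    dimnames(beta) <- list(rownames(Z), colnames(loadings))
    assays$methylation_beta <- t(beta)[keep, , drop = FALSE]
  }
  if (config@withCna) {
    set.seed(deriveSeed(config@seed, "cohort", cohortIndex, "cna"))
    cna <- 0.3 * (Z %*% loadings) +
      matrix(rnorm(n * p, 0, config@noiseSd / 2), n, p)
    dimnames(cna) <- list(rownames(Z), colnames(loadings))
    assays$cna_log2 <- t(cna)[keep, , drop = FALSE]
  }

  clinical <- S4Vectors::DataFrame(
    sample_id = rownames(Z),
    os_months = osMonths,
    event = event,
    idh_status = ifelse(idh == 1L, "mutant", "wildtype"),
    purity = purity, age = age, grade = grade,
    row.names = rownames(Z))

  SummarizedExperiment::SummarizedExperiment(
    assays = assays, colData = clinical,
    metadata = list(
      cohortIndex = cohortIndex,
      truth = list(trueScores = Z, truePurity = purity,
                   trueLoadings = loadings,
                   trueBetas = config@factorSurvivalBetas,
                   idhHazardBeta = config@idhHazardBeta,
                   droppedGenes = setdiff(colnames(loadings), keep)),
      config = config))
}

#' Simulate a training cohort plus platform-shifted external cohorts
#'
#' Cohort 1 is the training cohort with the full gene set; cohorts 2..K
#' share the same latent loading matrix but receive per-gene affine
#' platform shifts and lose \code{missingGeneFraction} of genes at random
#' (a different, seed-determined set per cohort), emulating projection
#' from a discovery study into independently profiled validation cohorts.
#'
#' @param config a \linkS4class{SimulationConfig} with
#'   \code{nCohorts >= 2}.
#' @return A named list of \code{SummarizedExperiment}s
#'   (\code{training}, \code{external1}, ...).
#' @examples
#' cfg <- simConfig(nCohorts = 2, nSamplesPerCohort = 30, nGenes = 100,
#'                  nFactors = 2)
#' names(simulateMulticohort(cfg))
#' @export
simulateMulticohort <- function(config) {
  stopIfNot(config@nCohorts >= 2L, "nCohorts must be at least 2")
  stopIfNot(config@missingGeneFraction < 1,
            "missingGeneFraction must be < 1")
  W <- generateLoadings(config)
  out <- vector("list", config@nCohorts)
  out[[1]] <- simulateCohort(config, W, cohortIndex = 1L)
  for (i in 2:config@nCohorts)
    out[[i]] <- simulateCohort(config, W, cohortIndex = i,
                               platformShift = TRUE, dropGenes = TRUE)
  names(out) <- c("training", paste0("external", seq_len(config@nCohorts - 1L)))
  out
}

#' Write a simulated cohort to delimited text
#'
#' Emits \code{expression.tsv} (genes x samples with a header row of
#' sample ids), \code{clinical.tsv}, \code{truth.tsv} (true factor
#' scores + purity) and the configuration echoed as \code{config.yaml}.
#'
#' @param cohort a SummarizedExperiment from \code{\link{simulateCohort}}.
#' @param dir output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  expr <- SummarizedExperiment::assay(cohort, "counts")
  paths <- file.path(dir, c("expression.tsv", "clinical.tsv", "truth.tsv",
                            "config.yaml"))
  write.table(data.frame(gene = rownames(expr), expr, check.names = FALSE),
              paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(SummarizedExperiment::colData(cohort)),
              paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- S4Vectors::metadata(cohort)$truth
  write.table(data.frame(sample_id = rownames(truth$trueScores),
                         truth$trueScores, purity = truth$truePurity,
                         check.names = FALSE),
              paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- S4Vectors::metadata(cohort)$config
  yaml::write_yaml(configAsList(cfg), paths[4])
  invisible(paths)
}

configAsList <- function(config) {
  nm <- slotNames(config)
  out <- lapply(nm, function(s) {
    v <- slot(config, s)
    if (is.numeric(v)) as.numeric(v) else v
  })
  names(out) <- nm
  out
}
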