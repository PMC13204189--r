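# Purity-correction toolkit: residualization of factor scores on tumor
# purity, hazard-ratio attenuation, stratum concordance across a median
# split, and partial Spearman correlation.

#' Residualize factor scores on tumor purity
#'
#' Per factor, ordinary least squares of score on (intercept, purity);
#' the residuals become the purity-adjusted scores. Samples without a
#' purity estimate are dropped (complete-case) and counted.
#'
#' @param scores a \linkS4class{FactorScores} object.
#' @param purity data.frame with columns \code{sample_id} and
#'   \code{purity} in [0,1] (NA allowed; those samples are dropped).
#' @return A \linkS4class{FactorScores} with provenance
#'   \code{"residualized"}, restricted to samples with purity.
#' @examples
#' z <- FactorScores(matrix(rnorm(40), 20, 2,
#'        dimnames = list(paste0("s", 1:20), NULL)))
#' pur <- data.frame(sample_id = paste0("s", 1:20),
#'                   purity = rbeta(20, 8, 3))
#' residualizeScores(z, pur)
#' @export
residualizeScores <- function(scores, purity) {
  z <- scoreMatrix(scores)
  pur <- purity$purity[match(rownames(z), purity$sample_id)]
  keep <- !is.na(pur)
  dropped <- sum(!keep)
  if (dropped > 0)
    axMsg(dropped, " sample(s) without purity dropped (complete-case)")
  stopIfNot(sum(keep) >= 10, "fewer than 10 samples with purity overlap")
  z <- z[keep, , drop = FALSE]
  pur <- pur[keep]
  stopIfNot(var(pur) > 0, "purity has zero variance; regression undefined")
  X <- cbind(1, pur)
  resid <- z - X %*% solve(crossprod(X), crossprod(X, z))
  FactorScores(resid, provenance = "residualized",
               cohort = scores@cohort)
}

#' Hazard-ratio attenuation after purity adjustment
#'
#' attenuation = (1 - HR_residualized / HR_raw) * 100. Negative values
#' mean the hazard ratio strengthened after adjustment.
#'
#' @param hrRaw,hrResidualized positive hazard ratios from the raw and
#'   purity-residualized models.
#' @return attenuation percentage.
#' @examples
#' attenuation(2, 1)        # 50
#' attenuation(3.57, 3.72)  # -4.20...
#' @export
attenuation <- function(hrRaw, hrResidualized) {
  stopIfNot(hrRaw > 0 && hrResidualized > 0,
            "hazard ratios must be positive")
  (1 - hrResidualized / hrRaw) * 100
}

#' Stratum concordance across two median splits
#'
#' Both score vectors are median-split independently (values exactly at
#' the median go to the low stratum); the statistic is the percentage of
#' samples assigned the same high/low stratum under both splits.
#'
#' @param scoresA,scoresB \linkS4class{FactorScores} on the same samples.
#' @param factor factor column (name or index), default 1.
#' @return concordance percentage in [0, 100].
#' @export
stratumConcordance <- function(scoresA, scoresB, factor = 1L) {
  a <- scoreMatrix(scoresA)[, factor]
  b <- scoreMatrix(scoresB)[, factor]
  stopIfNot(length(a) >= 2, "need at least 2 samples")
  stopIfNot(identical(rownames(scoreMatrix(scoresA)),
                      rownames(scoreMatrix(scoresB))),
            "score sets must cover the same samples in the same order")
  highA <- a > median(a)
  highB <- b > median(b)
  100 * mean(highA == highB)
}

#' Partial Spearman correlation
#'
#' Ranks of x and y are each residualized on the ranks of the covariate
#' (OLS with intercept); the statistic is the Pearson correlation of the
#' residuals. The p-value uses the t approximation with n - 3 degrees of
#' freedom, or a seeded permutation test on request.
#'
#' @param x,y numeric vectors.
#' @param covariate numeric vector (e.g. tumor purity).
#' @param method \code{"t"} (default) or \code{"permutation"}.
#' @param nPerm,permSeed permutation count and seed when
#'   \code{method = "permutation"}.
#' @return list with \code{rho} and \code{p}.
#' @export
partialSpearman <- function(x, y, covariate, method = c("t", "permutation"),
                            nPerm = 2000L, permSeed = 1L) {
  method <- match.arg(method)
  keep <- complete.cases(x, y, covariate)
  x <- x[keep]; y <- y[keep]; covariate <- covariate[keep]
  n <- length(x)
  stopIfNot(n >= 5, "need at least 5 complete cases")
  stopIfNot(var(x) > 0 && var(y) > 0, "constant input vector")
  partRho <- function(x, y, z) {
    rx <- rank(x); ry <- rank(y); rz <- rank(z)
    ex <- resid(lm(rx ~ rz))
    ey <- resid(lm(ry ~ rz))
    if (sd(ex) == 0 || sd(ey) == 0) return(NA_real_)
    cor(ex, ey)
  }
  rho <- partRho(x, y, covariate)
  stopIfNot(is.finite(rho),
            "residual ranks are constant; correlation undefined")
  if (method == "t") {
    df <- n - 3
    tval <- rho * sqrt(df / (1 - rho^2))
    p <- 2 * pt(-abs(tval), df)
  } else {
    set.seed(permSeed)
    null <- replicate(nPerm, partRho(x, sample(y), covariate))
    p <- (1 + sum(abs(null) >= abs(rho), na.rm = TRUE)) / (nPerm + 1)
  }
  list(rho = rho, p = p)
}

#' Purity sensitivity analysis for one factor
#'
#' Bundles the purity sensitivity workflow into one call: fits the raw
#' Cox model of survival on the chosen factor, refits on the
#' purity-residualized factor, and reports both hazard ratios, the
#' attenuation percentage and the median-split stratum concordance.
#'
#' @param scores \linkS4class{FactorScores} (raw, i.e. trained or
#'   projected).
#' @param clinical data.frame with sample_id, os_months, event and a
#'   purity column.
#' @param factor factor column to analyze (default 1).
#' @param perSd standardize the score to unit sd before fitting so both
#'   hazard ratios are per 1-SD increases (default TRUE).
#' @return list of class \code{"attenuationResult"}: hrRaw,
#'   hrResidualized, attenuationPercent, stratumConcordancePercent,
#'   nUsed.
#' @export
puritySensitivity <- function(scores, clinical, factor = 1L,
                              perSd = TRUE) {
  z <- scoreMatrix(scores)
  common <- intersect(rownames(z), clinical$sample_id)
  cl <- clinical[match(common, clinical$sample_id), ]
  keep <- !is.na(cl$purity)
  cl <- cl[keep, ]
  resid <- residualizeScores(
    FactorScores(z[cl$sample_id, , drop = FALSE],
                 provenance = scores@provenance, cohort = scores@cohort),
    data.frame(sample_id = cl$sample_id, purity = cl$purity))
  raw <- z[cl$sample_id, factor]
  adj <- scoreMatrix(resid)[, factor]
  dfRaw <- data.frame(sample_id = cl$sample_id, os_months = cl$os_months,
                      event = cl$event, score = raw)
  dfAdj <- transform(dfRaw, score = adj)
  fitRaw <- fitCox(dfRaw, "score", scalePerSd = perSd)
  fitAdj <- fitCox(dfAdj, "score", scalePerSd = perSd)
  hrRaw <- fitRaw$table["score", "hr"]
  hrAdj <- fitAdj$table["score", "hr"]
  conc <- stratumConcordance(
    FactorScores(z[cl$sample_id, , drop = FALSE],
                 provenance = "trained", cohort = scores@cohort),
    resid, factor = factor)
  structure(list(hrRaw = hrRaw, hrResidualized = hrAdj,
                 attenuationPercent = attenuation(hrRaw, hrAdj),
                 stratumConcordancePercent = conc,
                 nUsed = nrow(cl)),
            class = "attenuationResult")
}

#' @export
print.attenuationResult <- function(x, ...) {
  cat(sprintf(paste0("Purity sensitivity (n = %d)\n",
                     "  HR raw          %.3f\n",
                     "  HR residualized %.3f\n",
                     "  attenuation     %.2f%%\n",
                     "  stratum concordance %.1f%%\n"),
              x$nUsed, x$hrRaw, x$hrResidualized, x$attenuationPercent,
              x$stratumConcordancePercent))
  invisible(x)
}
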