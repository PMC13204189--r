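# Random-effects synthesis of per-cohort hazard estimates:
# DerSimonian-Laird pooling with Cochran's Q and I-squared, moment-based
# meta-regression with residual heterogeneity, and leave-one-cohort-out
# sensitivity.

#' Reconstruct a log-scale standard error from a hazard-ratio CI
#'
#' SE = (ln ciHigh - ln ciLow) / (2 * 1.959964), assuming a log-symmetric
#' Wald interval.
#'
#' @param hr hazard ratio.
#' @param ciLow,ciHigh 95\% confidence limits, 0 < ciLow <= hr <= ciHigh.
#' @return standard error of the log hazard ratio.
#' @examples
#' seFromCI(1.23, 1.03, 1.46)  # ~0.089
#' @export
seFromCI <- function(hr, ciLow, ciHigh) {
  stopIfNot(ciLow > 0 && ciLow <= hr && hr <= ciHigh,
            "need 0 < ciLow <= hr <= ciHigh")
  se <- (log(ciHigh) - log(ciLow)) / (2 * 1.959964)
  stopIfNot(se > 0, "degenerate interval: SE would be 0")
  se
}

#' Assemble a study-effect table
#'
#' @param label study labels.
#' @param hr hazard ratios.
#' @param ciLow,ciHigh 95\% CI limits (used to reconstruct SEs), or
#'   supply \code{se} directly.
#' @param se log-HR standard errors; overrides the CI reconstruction.
#' @param ... optional moderator columns (recycled).
#' @return data.frame with columns label, log_hr, se (+ moderators).
#' @export
studyEffects <- function(label, hr, ciLow = NULL, ciHigh = NULL,
                         se = NULL, ...) {
  if (is.null(se)) {
    stopIfNot(!is.null(ciLow) && !is.null(ciHigh),
              "supply either se or both CI limits")
    se <- mapply(seFromCI, hr, ciLow, ciHigh)
  }
  data.frame(label = label, log_hr = log(hr), se = se, ...,
             stringsAsFactors = FALSE)
}

#' DerSimonian-Laird random-effects pooling
#'
#' Moment estimator: with fixed weights w = 1/SE^2 and weighted mean
#' y_w, Q = sum w (y - y_w)^2 and
#' tau^2 = max(0, (Q - (k - 1)) / (sum w - sum w^2 / sum w)); the pooled
#' estimate uses random-effects weights 1/(SE^2 + tau^2) with a Wald CI.
#' I^2 = max(0, (Q - df)/Q) * 100 (0 when Q = 0 or k = 1, flagged).
#'
#' @param effects data.frame with columns \code{log_hr} and \code{se}
#'   (e.g. from \code{\link{studyEffects}}).
#' @param knappHartung apply the Knapp-Hartung small-sample adjustment
#'   (t-based CI with a scaled variance) instead of the plain Wald CI.
#' @return list of class \code{"pooledEffect"}: logHr, hr, ci, se, tau2,
#'   Q, df, Qp, I2, k, singleStudy flag.
#' @export
poolDL <- function(effects, knappHartung = FALSE) {
  k <- nrow(effects)
  stopIfNot(!is.null(k) && k >= 1, "no studies to pool")
  stopIfNot(all(effects$se > 0), "all SEs must be positive")
  y <- effects$log_hr
  w <- 1 / effects$se^2
  yw <- sum(w * y) / sum(w)
  Q <- sum(w * (y - yw)^2)
  df <- k - 1L
  tau2 <- if (k == 1L) 0 else
    max(0, (Q - df) / (sum(w) - sum(w^2) / sum(w)))
  wr <- 1 / (effects$se^2 + tau2)
  mu <- sum(wr * y) / sum(wr)
  seMu <- sqrt(1 / sum(wr))
  I2 <- if (k == 1L || Q <= 0) 0 else max(0, (Q - df) / Q) * 100
  if (knappHartung && k >= 2L) {
    seMu <- sqrt(sum(wr * (y - mu)^2) / (df * sum(wr)))
    crit <- stats::qt(0.975, df)
  } else {
    crit <- 1.959964
  }
  structure(list(
    logHr = mu, hr = exp(mu),
    ci = exp(mu + c(-1, 1) * crit * seMu), se = seMu,
    tau2 = tau2, Q = Q, df = df,
    Qp = if (df >= 1) pchisq(Q, df, lower.tail = FALSE) else NA_real_,
    I2 = I2, k = k, singleStudy = k == 1L,
    p = if (knappHartung && k >= 2L) 2 * pt(-abs(mu / seMu), df)
        else 2 * pnorm(-abs(mu / seMu))),
    class = "pooledEffect")
}

#' @export
print.pooledEffect <- function(x, ...) {
  cat(sprintf(paste0("Pooled HR %.3f (95%% CI %.3f-%.3f), k = %d\n",
                     "  tau^2 = %.4f, Q = %.3f (df %d, p = %s), ",
                     "I^2 = %.1f%%%s\n"),
              x$hr, x$ci[1], x$ci[2], x$k, x$tau2, x$Q, x$df,
              if (is.na(x$Qp)) "NA" else sprintf("%.3f", x$Qp), x$I2,
              if (x$singleStudy) " [single study]" else ""))
  invisible(x)
}

#' Moment-based random-effects meta-regression
#'
#' Weighted least squares of log effects on moderators with
#' method-of-moments residual between-study variance:
#' tau^2 = max(0, (Q_E - (k - p)) /
#' (tr(W) - tr((X'WX)^-1 X'W^2 X))) with fixed weights W = diag(1/SE^2),
#' then a refit with weights 1/(SE^2 + tau^2). Residual
#' I^2 = max(0, (Q_E - df)/Q_E) * 100. Saturated fits (residual df = 0)
#' are permitted but flagged.
#'
#' @param effects data.frame with \code{log_hr}, \code{se}.
#' @param moderators data.frame or matrix of moderators, rows aligned
#'   with \code{effects}; an intercept is added.
#' @return list: coefficients (with SE, z, p), tau2, residualQ, df,
#'   residualI2, saturated flag, k.
#' @export
metaRegression <- function(effects, moderators) {
  k <- nrow(effects)
  X <- cbind(intercept = 1,
             as.matrix(data.frame(moderators, check.names = FALSE)))
  storage.mode(X) <- "double"
  p <- ncol(X)
  stopIfNot(k >= p, "more coefficients than studies")
  qrX <- qr(X)
  stopIfNot(qrX$rank == p,
            "collinear moderators: design rank ", qrX$rank, " < ", p)
  y <- effects$log_hr
  w <- 1 / effects$se^2
  W <- diag(w, k)
  XtWX <- t(X) %*% W %*% X
  beta <- solve(XtWX, t(X) %*% (w * y))
  residQ <- sum(w * (y - X %*% beta)^2)
  df <- k - p
  trP <- sum(w) - sum(diag(solve(XtWX, t(X) %*% diag(w^2, k) %*% X)))
  tau2 <- if (df == 0) 0 else max(0, (residQ - df) / trP)
  wr <- 1 / (effects$se^2 + tau2)
  Wr <- diag(wr, k)
  XtWrX <- t(X) %*% Wr %*% X
  betaR <- solve(XtWrX, t(X) %*% (wr * y))
  seR <- sqrt(diag(solve(XtWrX)))
  z <- drop(betaR) / seR
  coefTab <- cbind(estimate = drop(betaR), se = seR, z = z,
                   p = 2 * pnorm(-abs(z)))
  rownames(coefTab) <- colnames(X)
  residI2 <- if (df == 0 || residQ <= 0) 0 else
    max(0, (residQ - df) / residQ) * 100
  if (df == 0)
    axMsg("meta-regression is saturated (residual df = 0); residual ",
          "heterogeneity is not estimable")
  list(coefficients = coefTab, tau2 = tau2, residualQ = residQ, df = df,
       residualI2 = residI2, saturated = df == 0, k = k)
}

#' Leave-one-cohort-out sensitivity pooling
#'
#' Re-pools with each study excluded in turn.
#'
#' @param effects data.frame with \code{label}, \code{log_hr},
#'   \code{se}; at least 2 studies.
#' @return list: \code{fits} (named list of \code{pooledEffect}s, one
#'   per excluded study), \code{minHr}, \code{maxHr}.
#' @export
leaveOneOut <- function(effects) {
  k <- nrow(effects)
  stopIfNot(k >= 2, "leave-one-out needs at least 2 studies")
  labels <- if ("label" %in% names(effects)) effects$label
            else paste0("study", seq_len(k))
  fits <- lapply(seq_len(k), function(i)
    poolDL(effects[-i, , drop = FALSE]))
  names(fits) <- paste0("excluding_", labels)
  hrs <- vapply(fits, function(f) f$hr, 0)
  list(fits = fits, minHr = min(hrs), maxHr = max(hrs))
}
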