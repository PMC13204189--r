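# Survival statistics behind the pipeline: Cox proportional-hazards
# fitting (Efron ties), Kaplan-Meier with Greenwood variance, log-rank,
# nested-model likelihood-ratio tests, Factor x IDH interaction,
# Schoenfeld proportional-hazards checks, IDH-stratified tables with
# BH-FDR, survival-extremes selection and Mann-Whitney U.

#' @importFrom survival coxph coxph.control Surv survfit survdiff cox.zph
#'   strata
NULL

#' Fit a Cox proportional-hazards model
#'
#' Complete-case partial-likelihood fit with Efron tie handling by
#' default; continuous predictors can be standardized to unit sd within
#' the analysis cohort so hazard ratios read per 1-SD increase.
#' Stratified baseline hazards are used when \code{strata} is given.
#'
#' @param clinical data.frame with columns \code{os_months},
#'   \code{event}, the predictors, and optionally \code{sample_id}.
#' @param predictors character vector of predictor column names.
#' @param strata optional character vector of stratification columns.
#' @param ties \code{"efron"} (default) or \code{"breslow"}.
#' @param scalePerSd divide each numeric predictor by its within-cohort
#'   sd before fitting (default FALSE).
#' @return list of class \code{"coxFitResult"}: \code{table} (coef, se,
#'   hr, ci_low, ci_high, p per coefficient), \code{loglik} (null,
#'   fitted), \code{n}, \code{events}, \code{ties}, \code{strata},
#'   \code{perSd}, \code{samples}, \code{separationFlag}, and the
#'   underlying \code{model}.
#' @examples
#' cl <- data.frame(os_months = rexp(60, 0.05), event = rbinom(60, 1, .7),
#'                  x = rnorm(60))
#' fitCox(cl, "x")$table
#' @export
fitCox <- function(clinical, predictors, strata = NULL,
                   ties = c("efron", "breslow"), scalePerSd = FALSE) {
  ties <- match.arg(ties)
  cols <- c("os_months", "event", predictors, strata)
  stopIfNot(all(cols %in% names(clinical)),
            "missing column(s): ",
            paste(setdiff(cols, names(clinical)), collapse = ", "))
  cc <- complete.cases(clinical[, cols, drop = FALSE])
  if (any(!cc)) axMsg(sum(!cc), " incomplete row(s) dropped")
  d <- clinical[cc, , drop = FALSE]
  stopIfNot(sum(d$event) >= 2, "fewer than 2 events")
  if (scalePerSd)
    for (p in predictors)
      if (is.numeric(d[[p]]) && sd(d[[p]]) > 0)
        d[[p]] <- d[[p]] / sd(d[[p]])
  rhs <- paste(predictors, collapse = " + ")
  if (!is.null(strata))
    rhs <- paste(rhs, "+", paste(sprintf("strata(%s)", strata),
                                 collapse = " + "))
  fml <- as.formula(paste("Surv(os_months, event) ~", rhs))
  fit <- coxph(fml, data = d, ties = ties,
               control = coxph.control(eps = 1e-9, iter.max = 50))
  if (!is.null(fit$info) || any(is.na(coef(fit))))
    stop("Cox model failed to converge", call. = FALSE)
  sep <- any(abs(coef(fit)) > 15)
  if (sep) warning("possible separation: coefficient diverging",
                   call. = FALSE)
  se <- sqrt(diag(vcov(fit)))
  tab <- cbind(coef = coef(fit), se = se, hr = exp(coef(fit)),
               ci_low = exp(coef(fit) - 1.959964 * se),
               ci_high = exp(coef(fit) + 1.959964 * se),
               p = 2 * pnorm(-abs(coef(fit) / se)))
  samples <- if ("sample_id" %in% names(d)) d$sample_id else rownames(d)
  structure(list(table = tab, loglik = fit$loglik, n = nrow(d),
                 events = sum(d$event), ties = ties,
                 strata = strata, perSd = scalePerSd,
                 samples = samples, separationFlag = sep, model = fit,
                 data = d),
            class = "coxFitResult")
}

#' @export
print.coxFitResult <- function(x, ...) {
  cat(sprintf("Cox fit: n = %d, events = %d, ties = %s%s\n", x$n,
              x$events, x$ties, if (x$perSd) ", per-1-SD" else ""))
  print(round(x$table, 4))
  invisible(x)
}

#' Kaplan-Meier curves per group
#'
#' Product-limit estimates with Greenwood variance at the event times of
#' each group.
#'
#' @param clinical data.frame with \code{os_months} and \code{event}.
#' @param groupLabels vector of group labels, one per row.
#' @return named list of data.frames (time, n_risk, n_event, surv,
#'   greenwood_var, lower, upper) per group.
#' @export
kmEstimate <- function(clinical, groupLabels) {
  stopIfNot(length(groupLabels) == nrow(clinical),
            "every sample must be labeled")
  stopIfNot(!anyNA(groupLabels), "every sample must be labeled")
  groups <- unique(as.character(groupLabels))
  out <- lapply(groups, function(g) {
    d <- clinical[groupLabels == g, , drop = FALSE]
    stopIfNot(nrow(d) > 0, "empty group '", g, "'")
    sf <- survfit(Surv(os_months, event) ~ 1, data = d, conf.type = "plain")
    keep <- sf$n.event > 0
    data.frame(time = sf$time[keep], n_risk = sf$n.risk[keep],
               n_event = sf$n.event[keep], surv = sf$surv[keep],
               greenwood_var = (sf$std.err[keep] * sf$surv[keep])^2,
               lower = sf$lower[keep], upper = sf$upper[keep],
               group = rep(g, sum(keep)))
  })
  names(out) <- groups
  out
}

#' Log-rank test
#'
#' Observed-minus-expected statistic with hypergeometric variance summed
#' over event times.
#'
#' @param clinical data.frame with \code{os_months} and \code{event}.
#' @param groupLabels vector of group labels.
#' @return list(chisq, df, p).
#' @export
logrankTest <- function(clinical, groupLabels) {
  g <- factor(groupLabels)
  stopIfNot(nlevels(g) >= 2, "log-rank needs at least 2 groups")
  d <- data.frame(os_months = clinical$os_months, event = clinical$event,
                  g = g)
  sd_ <- survdiff(Surv(os_months, event) ~ g, data = d)
  df <- nlevels(g) - 1L
  list(chisq = sd_$chisq, df = df,
       p = pchisq(sd_$chisq, df, lower.tail = FALSE))
}

#' Likelihood-ratio test between nested Cox fits
#'
#' @param nested,full \code{coxFitResult}s on identical samples with
#'   nested predictor sets.
#' @return list(stat, df, p).
#' @export
lrTest <- function(nested, full) {
  stopIfNot(identical(sort(as.character(nested$samples)),
                      sort(as.character(full$samples))),
            "models were fitted on different samples")
  df <- nrow(full$table) - nrow(nested$table)
  stopIfNot(df >= 0, "the 'full' model has fewer parameters")
  stat <- max(0, 2 * (full$loglik[2] - nested$loglik[2]))
  list(stat = stat, df = df,
       p = if (df == 0) 1 else pchisq(stat, df, lower.tail = FALSE))
}

#' Factor x IDH interaction likelihood-ratio test
#'
#' Compares Cox(score + IDH) against Cox(score + IDH + score:IDH) with a
#' 1-df likelihood-ratio test.
#'
#' @param clinical data.frame with \code{os_months}, \code{event} and
#'   \code{idh_status} (\code{"mutant"}/\code{"wildtype"}).
#' @param score numeric factor-score vector aligned with the clinical
#'   rows.
#' @return list(stat, df, p); errors if either IDH level lacks events or
#'   the score is constant.
#' @export
interactionLRT <- function(clinical, score) {
  d <- data.frame(os_months = clinical$os_months, event = clinical$event,
                  idh = factor(clinical$idh_status,
                               levels = c("wildtype", "mutant")),
                  score = score)
  d <- d[complete.cases(d), ]
  stopIfNot(sd(d$score) > 0, "degenerate predictor: score is constant")
  ev <- tapply(d$event, d$idh, sum)
  stopIfNot(all(!is.na(ev)) && all(ev > 0),
            "an IDH level has zero events; interaction test skipped")
  base <- coxph(Surv(os_months, event) ~ score + idh, data = d)
  inter <- coxph(Surv(os_months, event) ~ score * idh, data = d)
  stat <- max(0, 2 * (inter$loglik[2] - base$loglik[2]))
  list(stat = stat, df = 1L, p = pchisq(stat, 1, lower.tail = FALSE))
}

#' Proportional-hazards check via scaled Schoenfeld residuals
#'
#' Correlates scaled Schoenfeld residuals against Kaplan-Meier
#' transformed time, giving a score-type chi-square per covariate plus a
#' global test.
#'
#' @param fit a \code{coxFitResult}.
#' @return data.frame with rows per covariate plus GLOBAL: chisq, df, p.
#' @export
schoenfeldPhTest <- function(fit) {
  stopIfNot(fit$events > nrow(fit$table) + 1L,
            "fewer events than the test requires (need more than ",
            "covariates + 1); test undefined")
  zph <- cox.zph(fit$model, transform = "km")
  as.data.frame(zph$table)
}

#' IDH-stratified univariate Cox table with BH-FDR
#'
#' For every (cohort, IDH stratum, factor) cell, fits a univariate Cox
#' model of survival on the per-1-SD factor score within the stratum and
#' adjusts the p-values by Benjamini-Hochberg across the full family
#' (all cohorts x strata x factors together by default).
#'
#' @param cohorts named list; each element a list with \code{clinical}
#'   (data.frame with sample_id, os_months, event, idh_status) and
#'   \code{scores} (a \linkS4class{FactorScores}).
#' @param factors factor columns to test (indices or names); default all
#'   columns of the first cohort's scores.
#' @param family \code{"global"} (one BH family, default) or
#'   \code{"per-cohort"}.
#' @return data.frame: cohort, stratum, factor, n, events, hr, ci_low,
#'   ci_high, p, fdr, reason (NA unless the cell was skipped).
#' @export
stratifiedCoxTable <- function(cohorts, factors = NULL,
                               family = c("global", "per-cohort")) {
  family <- match.arg(family)
  if (is.null(factors))
    factors <- colnames(scoreMatrix(cohorts[[1]]$scores))
  rows <- list()
  for (cn in names(cohorts)) {
    cl <- cohorts[[cn]]$clinical
    z <- scoreMatrix(cohorts[[cn]]$scores)
    common <- intersect(cl$sample_id, rownames(z))
    cl <- cl[match(common, cl$sample_id), ]
    z <- z[common, , drop = FALSE]
    for (st in c("wildtype", "mutant")) {
      idx <- which(cl$idh_status == st)
      for (f in factors) {
        row <- data.frame(cohort = cn, stratum = st, factor = as.character(f),
                          n = length(idx), events = sum(cl$event[idx]),
                          hr = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, p = NA_real_,
                          fdr = NA_real_, reason = NA_character_)
        if (length(idx) == 0) {
          row$reason <- "empty stratum"
        } else if (sum(cl$event[idx]) < 2) {
          row$reason <- "fewer than 2 events"
        } else {
          d <- data.frame(os_months = cl$os_months[idx],
                          event = cl$event[idx], score = z[idx, f])
          fit <- fitCox(d, "score", scalePerSd = TRUE)
          row[c("hr", "ci_low", "ci_high", "p")] <-
            fit$table["score", c("hr", "ci_low", "ci_high", "p")]
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  tab <- do.call(rbind, rows)
  if (family == "global") {
    ok <- !is.na(tab$p)
    tab$fdr[ok] <- bhAdjust(tab$p[ok])
  } else {
    for (cn in unique(tab$cohort)) {
      ok <- tab$cohort == cn & !is.na(tab$p)
      tab$fdr[ok] <- bhAdjust(tab$p[ok])
    }
  }
  tab
}

#' Select survival-extreme phenotypes
#'
#' Retains ultra-short survivors (OS strictly below \code{low} months)
#' and long survivors (OS strictly above \code{high} months); boundary
#' values and the interior are excluded.
#'
#' @param clinical data.frame with \code{os_months}.
#' @param low,high cutoffs in months (defaults 6 and 15).
#' @return the extreme-phenotype subset, with an added column
#'   \code{extreme_group} (\code{"ultra_short"}/\code{"long"}).
#' @examples
#' cl <- data.frame(os_months = c(3, 6, 10, 15, 20))
#' selectExtremes(cl)$os_months  # 3 and 20
#' @export
selectExtremes <- function(clinical, low = 6, high = 15) {
  stopIfNot(low < high, "low must be strictly below high")
  short <- clinical$os_months < low
  long <- clinical$os_months > high
  out <- clinical[short | long, , drop = FALSE]
  out$extreme_group <- ifelse(out$os_months < low, "ultra_short", "long")
  axMsg(sum(short), " ultra-short and ", sum(long), " long survivor(s) ",
        "retained of ", nrow(clinical))
  if (nrow(out) == 0)
    warning("no samples outside [", low, ", ", high, "] months",
            call. = FALSE)
  out
}

#' Mann-Whitney U test
#'
#' Rank-sum test with exact enumeration when the smaller sample has at
#' most 8 values and no ties span the groups, tie-corrected normal
#' approximation otherwise.
#'
#' @param valuesA,valuesB numeric samples.
#' @param alternative \code{"two.sided"} (default), \code{"less"},
#'   \code{"greater"}.
#' @return list(U, p). When all values are tied across both samples the
#'   test is degenerate: p = 1 with a warning.
#' @export
mwuTest <- function(valuesA, valuesB,
                    alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  stopIfNot(length(valuesA) > 0 && length(valuesB) > 0,
            "both samples must be non-empty")
  if (length(unique(c(valuesA, valuesB))) == 1L) {
    warning("all values tied across both samples", call. = FALSE)
    return(list(U = length(valuesA) * length(valuesB) / 2, p = 1))
  }
  exact <- min(length(valuesA), length(valuesB)) <= 8 &&
    !any(duplicated(c(valuesA, valuesB)))
  wt <- suppressWarnings(wilcox.test(valuesA, valuesB, exact = exact,
                                     correct = !exact,
                                     alternative = alternative))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values, monotone and capped at 1.
#'
#' @param pValues numeric vector in [0, 1].
#' @return adjusted values in the input order.
#' @export
bhAdjust <- function(pValues) {
  stopIfNot(all(pValues >= 0 & pValues <= 1, na.rm = TRUE),
            "p-values must lie in [0, 1]")
  p.adjust(pValues, method = "BH")
}
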