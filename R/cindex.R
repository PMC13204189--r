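# Composite gene-panel signature scoring and bootstrap concordance-index
# benchmarking with paired delta-C comparisons.

#' Define a composite gene-panel signature
#'
#' @param name signature name.
#' @param genes character vector of unique gene symbols.
#' @param direction +1 or -1 per gene (scalar recycled): the sign each
#'   gene's z-score contributes with.
#' @return list of class \code{"signatureDefinition"}.
#' @export
signatureDefinition <- function(name, genes, direction = 1) {
  stopIfNot(length(genes) > 0, "empty gene panel")
  stopIfNot(!anyDuplicated(genes), "panel genes must be unique")
  direction <- rep_len(direction, length(genes))
  stopIfNot(all(direction %in% c(-1, 1)), "direction must be +1 or -1")
  structure(list(name = name, genes = genes, direction = direction),
            class = "signatureDefinition")
}

#' Read signature definitions from a TSV file
#'
#' Expected columns: name, gene, direction. The package ships a default
#' 20-gene angiogenic panel in
#' \code{system.file("extdata", "angiogenic_panel_default.tsv",
#' package = "gliomaAxes")}; only six of its members (VEGFA, FLT1, KDR,
#' ANGPT1, ANGPT2, PECAM1) are canonical, the remaining genes are
#' representative angiogenesis-pathway placeholders that users should
#' review against their own panel definitions.
#'
#' @param path TSV file.
#' @return named list of \code{signatureDefinition}s.
#' @export
readSignatures <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopIfNot(all(c("name", "gene", "direction") %in% names(df)),
            "signature file needs columns name, gene, direction")
  out <- lapply(split(df, df$name), function(d)
    signatureDefinition(d$name[1], d$gene, d$direction))
  out[unique(df$name)]
}

#' Score samples on a composite signature
#'
#' Direction-weighted arithmetic mean of the panel genes' z-scores.
#' Panel genes absent from the matrix are skipped (listed via message);
#' more than half missing is an error.
#'
#' @param expr standardized \linkS4class{ExpressionMatrix} (z-scores per
#'   gene within the scoring cohort).
#' @param signature a \code{signatureDefinition}.
#' @return named numeric vector, one score per sample.
#' @export
compositeSignatureScore <- function(expr, signature) {
  stopIfNot(scaleState(expr) == "standardized",
            "signature scoring expects standardized expression")
  v <- exprValues(expr)
  present <- signature$genes %in% rownames(v)
  stopIfNot(any(present), "no panel gene present in the matrix")
  missingGenes <- signature$genes[!present]
  if (length(missingGenes))
    axMsg("panel '", signature$name, "': ", length(missingGenes),
          " gene(s) missing: ",
          paste(head(missingGenes, 10), collapse = ", "))
  stopIfNot(mean(present) > 0.5,
            "more than 50% of panel genes missing from the matrix")
  g <- signature$genes[present]
  d <- signature$direction[present]
  colMeans(v[g, , drop = FALSE] * d)
}

#' Restrict benchmarking to the common complete-case subset
#'
#' Head-to-head concordance comparisons are only meaningful on samples
#' with every predictor available; this intersection step reports how
#' many samples each predictor excludes.
#'
#' @param predictorList named list of named numeric score vectors (names
#'   are sample ids; NA marks unavailable).
#' @return character vector of sample ids complete across all
#'   predictors; per-predictor exclusion counts are reported via
#'   message.
#' @export
commonCompleteSamples <- function(predictorList) {
  stopIfNot(length(predictorList) >= 1, "no predictors supplied")
  univ <- Reduce(union, lapply(predictorList, names))
  keep <- univ
  for (nm in names(predictorList)) {
    s <- predictorList[[nm]]
    ok <- names(s)[!is.na(s)]
    excluded <- length(setdiff(keep, ok))
    if (excluded > 0)
      axMsg("predictor '", nm, "' excludes ", excluded, " sample(s)")
    keep <- intersect(keep, ok)
  }
  stopIfNot(length(keep) > 0, "no sample complete across all predictors")
  keep
}

#' Harrell's concordance index
#'
#' Over usable pairs (the member with the shorter observed time has an
#' event; pairs tied in time with events on both sides are unusable),
#' the fraction in which the earlier-failing member carries the higher
#' risk score, with 0.5 credit for tied scores.
#'
#' @param riskScores numeric vector, higher = higher risk.
#' @param clinical data.frame with \code{os_months} and \code{event},
#'   rows aligned with \code{riskScores}.
#' @return concordance in [0, 1].
#' @examples
#' cl <- data.frame(os_months = c(1, 2, 3, 4), event = 1)
#' harrellC(c(4, 3, 2, 1), cl)  # perfect ordering: 1
#' @export
harrellC <- function(riskScores, clinical) {
  t_ <- clinical$os_months
  e <- clinical$event
  stopIfNot(length(riskScores) == length(t_),
            "scores must align with clinical rows")
  lt <- outer(t_, t_, `<`)
  eq <- outer(t_, t_, `==`)
  # first[i, j]: subject i demonstrably fails before subject j
  first <- (lt & e == 1) | (eq & (e == 1) & outer(e, e,
              function(a, b) a == 1 & b == 0))
  stopIfNot(any(first), "no usable pair")
  gtR <- outer(riskScores, riskScores, `>`)
  eqR <- outer(riskScores, riskScores, `==`)
  (sum(first & gtR) + 0.5 * sum(first & eqR)) / sum(first)
}

#' Bootstrap-validated concordance index
#'
#' Resamples patients with replacement; the point estimate is the
#' full-sample C, the interval the percentile 95\% CI of the resampled
#' values. Resamples with fewer than 2 events are skipped and counted.
#'
#' @param riskScores numeric risk scores.
#' @param clinical aligned data.frame with \code{os_months},
#'   \code{event}.
#' @param B number of bootstrap resamples (default 1000).
#' @param seed RNG seed.
#' @return list of class \code{"cIndexResult"}: estimate, ci (length 2),
#'   B, skipped, seed, n, events.
#' @export
bootstrapC <- function(riskScores, clinical, B = 1000L, seed = 1L) {
  stopIfNot(B >= 1, "B must be at least 1")
  est <- harrellC(riskScores, clinical)
  set.seed(seed)
  n <- length(riskScores)
  vals <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    if (sum(clinical$event[idx]) < 2) next
    vals[b] <- harrellC(riskScores[idx], clinical[idx, , drop = FALSE])
  }
  skipped <- sum(is.na(vals))
  if (skipped > 0) axMsg(skipped, " resample(s) skipped (< 2 events)")
  vals <- vals[!is.na(vals)]
  stopIfNot(length(vals) >= 1, "all resamples degenerate")
  ci <- if (length(vals) == 1L) rep(vals, 2) else
    unname(quantile(vals, c(0.025, 0.975), type = 7))
  structure(list(estimate = est, ci = ci, B = B, skipped = skipped,
                 seed = seed, n = n, events = sum(clinical$event)),
            class = "cIndexResult")
}

#' @export
print.cIndexResult <- function(x, ...) {
  cat(sprintf("C-index %.3f (95%% CI %.3f-%.3f; B = %d, n = %d, %d events)\n",
              x$estimate, x$ci[1], x$ci[2], x$B, x$n, x$events))
  invisible(x)
}

#' Delta C-index with paired bootstrap confidence interval
#'
#' Delta C = C(scoreA) - C(scoreB) on the full sample; the CI comes from
#' a paired bootstrap that evaluates both scores on the same resample.
#'
#' @param scoreA,scoreB risk scores on identical samples (checked via
#'   names when present).
#' @param clinical aligned data.frame with \code{os_months},
#'   \code{event}.
#' @param B paired bootstrap resamples (default 1000).
#' @param seed RNG seed.
#' @return list: deltaC, ci, cA, cB, B, seed.
#' @export
deltaC <- function(scoreA, scoreB, clinical, B = 1000L, seed = 1L) {
  stopIfNot(length(scoreA) == length(scoreB),
            "scores must cover identical samples")
  if (!is.null(names(scoreA)) && !is.null(names(scoreB)))
    stopIfNot(identical(names(scoreA), names(scoreB)),
              "scores must cover identical samples in identical order")
  cA <- harrellC(scoreA, clinical)
  cB <- harrellC(scoreB, clinical)
  set.seed(seed)
  n <- length(scoreA)
  vals <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    if (sum(clinical$event[idx]) < 2) next
    cl <- clinical[idx, , drop = FALSE]
    vals[b] <- harrellC(scoreA[idx], cl) - harrellC(scoreB[idx], cl)
  }
  vals <- vals[!is.na(vals)]
  ci <- if (length(vals) <= 1L) rep(cA - cB, 2) else
    unname(quantile(vals, c(0.025, 0.975), type = 7))
  list(deltaC = cA - cB, ci = ci, cA = cA, cB = cB, B = B, seed = seed)
}

#' Contrast two reported concordance indices
#'
#' The arithmetic of the delta C-index applied to already-computed
#' concordances: deltaC = cA - cB. Useful for contrasting published
#' C values when the underlying scores are not available.
#'
#' @param cA,cB concordance indices in [0, 1].
#' @return the difference cA - cB.
#' @examples
#' deltaCFromConcordances(0.797, 0.801)  # -0.004
#' @export
deltaCFromConcordances <- function(cA, cB) {
  stopIfNot(cA >= 0 && cA <= 1 && cB >= 0 && cB <= 1,
            "concordances must lie in [0, 1]")
  cA - cB
}
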