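# Latent-factor machinery: a truncated singular-value stand-in for
# multi-view factorization with variance-explained pruning, portable
# projection bundles, and the frozen-parameter out-of-sample projection
# Z = XW'.

#' Fit the stand-in multi-view factorization
#'
#' Truncated singular decomposition of the column-concatenated
#' standardized views, with variance-explained pruning in place of
#' automatic relevance determination. Loadings are the right singular
#' vectors (orthonormal rows), split back into per-view blocks; training
#' scores are the least-squares projection of the training data onto the
#' loadings, which for orthonormal loadings coincides with the linear map
#' Z = XW' used for out-of-sample projection.
#'
#' @param views named list of \linkS4class{ExpressionMatrix} objects in
#'   \code{standardized} state (genes x samples), all sharing the same
#'   sample order.
#' @param kInit number of initial factors (default 25).
#' @param pruneMinVe factors whose total variance explained (percent)
#'   falls below this are discarded; 0 keeps all \code{kInit}.
#' @param scaling optional named list of \linkS4class{ScalingParams}
#'   (one per view) recorded in the model for bundle export.
#' @return A \linkS4class{FactorModel}.
#' @export
fitFactorModel <- function(views, kInit = 25L, pruneMinVe = 1,
                           scaling = list()) {
  stopIfNot(length(views) >= 1L, "at least one view required")
  if (is.null(names(views)))
    names(views) <- paste0("view", seq_along(views))
  samp <- sampleIds(views[[1]])
  for (v in views)
    stopIfNot(identical(sampleIds(v), samp),
              "all views must share the same samples in the same order")
  blocks <- lapply(views, function(v) t(exprValues(v)))  # samples x feat
  Y <- do.call(cbind, blocks)
  kInit <- min(kInit, nrow(Y), ncol(Y))
  sv <- svd(Y, nu = kInit, nv = kInit)
  W <- t(sv$v)                      # factors x features, orthonormal rows
  Z <- Y %*% sv$v                   # = U D, least-squares scores
  totSS <- sum(Y^2)
  veTotal <- 100 * colSums(Z^2) / totSS
  viewSizes <- vapply(blocks, ncol, 0L)
  viewIdx <- rep(seq_along(blocks), viewSizes)
  veView <- vapply(seq_along(blocks), function(b) {
    cols <- viewIdx == b
    ssView <- sum(Y[, cols]^2)
    # per-factor view VE with per-view least-squares score
    vapply(seq_len(kInit), function(k) {
      wk <- W[k, cols]
      if (sum(wk^2) == 0) return(0)
      zk <- Y[, cols] %*% wk / sum(wk^2)
      100 * (1 - sum((Y[, cols] - zk %*% t(wk))^2) / ssView)
    }, 0)
  }, numeric(kInit))
  veView <- matrix(veView, nrow = kInit,
                   dimnames = list(NULL, names(views)))
  keep <- which(veTotal >= pruneMinVe)
  stopIfNot(length(keep) >= 1L, "pruning removed every factor")
  keep <- keep[order(veTotal[keep], decreasing = TRUE)]
  labels <- paste0("Factor", seq_along(keep))
  loadings <- lapply(seq_along(blocks), function(b) {
    m <- W[keep, viewIdx == b, drop = FALSE]
    dimnames(m) <- list(labels, colnames(blocks[[b]]))
    m
  })
  names(loadings) <- names(views)
  Zk <- Z[, keep, drop = FALSE]
  dimnames(Zk) <- list(samp, labels)
  new("FactorModel", loadings = loadings,
      varianceExplained = matrix(veView[keep, , drop = FALSE],
                                 nrow = length(keep),
                                 dimnames = list(labels, names(views))),
      scaling = scaling, trainingScores = Zk, factorLabels = labels)
}

#' Per-view, per-factor variance explained
#'
#' For each factor k and view Y the statistic is
#' 100 * (1 - ||Y - z_k w_k||^2 / ||Y||^2), with z_k the per-view
#' least-squares score for that single factor; values are floored at 0
#' for reporting.
#'
#' @param model a \linkS4class{FactorModel}.
#' @param views named list of standardized \linkS4class{ExpressionMatrix}
#'   objects matching the model's views.
#' @return matrix factors x views of percentages.
#' @export
varianceExplained <- function(model, views) {
  out <- vapply(names(model@loadings), function(nm) {
    stopIfNot(nm %in% names(views), "view '", nm, "' not supplied")
    Y <- t(exprValues(views[[nm]]))
    stopIfNot(sum(Y^2) > 0, "all-zero view '", nm, "'")
    Wv <- model@loadings[[nm]][, colnames(Y), drop = FALSE]
    vapply(seq_len(nrow(Wv)), function(k) {
      wk <- Wv[k, ]
      if (sum(wk^2) == 0) return(0)
      zk <- Y %*% wk / sum(wk^2)
      max(0, 100 * (1 - sum((Y - zk %*% t(wk))^2) / sum(Y^2)))
    }, 0)
  }, numeric(length(model@factorLabels)))
  matrix(out, nrow = length(model@factorLabels),
         dimnames = list(model@factorLabels, names(model@loadings)))
}

#' Export one view of a factor model as a projection bundle
#'
#' @param model a \linkS4class{FactorModel} whose \code{scaling} list
#'   contains parameters for \code{viewName}.
#' @param viewName which view's loadings to freeze (typically the RNA
#'   view, the one available in validation cohorts).
#' @return A \linkS4class{ProjectionBundle}.
#' @export
exportBundle <- function(model, viewName = names(model@loadings)[1]) {
  stopIfNot(viewName %in% names(model@loadings),
            "view '", viewName, "' not in model")
  stopIfNot(viewName %in% names(model@scaling),
            "model carries no scaling parameters for view '", viewName, "'")
  W <- model@loadings[[viewName]]
  sp <- model@scaling[[viewName]]
  stopIfNot(identical(colnames(W), sp@features),
            "loading columns and scaling features disagree")
  ProjectionBundle(W, mu = sp@mu, sigma = sp@sigma,
                   features = sp@features,
                   factorLabels = model@factorLabels)
}

#' Write a projection bundle to a directory
#'
#' Plain-text serialization: \code{header.json} (factor labels, ordered
#' feature-list hash, creation metadata), \code{loadings.tsv}
#' (factors x genes) and \code{scaling.tsv} (gene, mu, sigma).
#'
#' @param bundle a \linkS4class{ProjectionBundle}.
#' @param dir output directory.
#' @return Invisibly, \code{dir}.
#' @export
writeBundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  header <- list(factor_labels = bundle@factorLabels,
                 n_features = length(bundle@features),
                 feature_hash = bundle@featureHash,
                 created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(header, file.path(dir, "header.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  # 17 significant digits uniquely identify a double, making the text
  # round trip bit-exact
  fmt <- function(x) formatC(x, digits = 17, format = "g")
  W <- bundle@loadings
  wDf <- data.frame(factor = rownames(W),
                    apply(W, 2, fmt), check.names = FALSE)
  write.table(wDf, file.path(dir, "loadings.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(gene = bundle@features, mu = fmt(bundle@mu),
                         sigma = fmt(bundle@sigma)),
              file.path(dir, "scaling.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}

#' Import a projection bundle from a directory
#'
#' Exact inverse of \code{\link{writeBundle}}; inconsistent dimensions or
#' missing scaling entries are rejected with a message naming the
#' discrepancy.
#'
#' @param path directory written by \code{writeBundle}.
#' @return A \linkS4class{ProjectionBundle}.
#' @export
importBundle <- function(path) {
  header <- jsonlite::read_json(file.path(path, "header.json"),
                                simplifyVector = TRUE)
  lt <- read.delim(file.path(path, "loadings.tsv"), check.names = FALSE)
  W <- as.matrix(lt[, -1, drop = FALSE])
  rownames(W) <- lt[[1]]
  sc <- read.delim(file.path(path, "scaling.tsv"))
  features <- colnames(W)
  missingScale <- setdiff(features, sc$gene)
  stopIfNot(length(missingScale) == 0,
            "scaling entries missing for feature(s): ",
            paste(head(missingScale, 5), collapse = ", "))
  stopIfNot(!any(is.na(sc$mu)) && !any(is.na(sc$sigma)),
            "scaling table contains missing mu/sigma for feature(s): ",
            paste(head(sc$gene[is.na(sc$mu) | is.na(sc$sigma)], 5),
                  collapse = ", "))
  sc <- sc[match(features, sc$gene), ]
  stopIfNot(length(header$factor_labels) == nrow(W),
            "header lists ", length(header$factor_labels),
            " factors but loadings have ", nrow(W), " rows")
  b <- ProjectionBundle(W, mu = sc$mu, sigma = sc$sigma,
                        features = features,
                        factorLabels = as.character(header$factor_labels))
  stopIfNot(identical(b@featureHash, header$feature_hash),
            "feature-list hash mismatch: file order differs from header")
  b
}

#' Align and standardize a target cohort against a bundle
#'
#' The frozen-parameter harmonization of an external cohort: target genes
#' are intersected with the bundle's ordered feature list, each shared
#' gene is standardized with the bundle's training mu/sigma (no
#' re-estimation), and bundle genes absent from the target are imputed
#' with 0 -- the standardized training mean. A warning is raised when the
#' imputed fraction exceeds \code{warnThreshold}.
#'
#' @param target \linkS4class{ExpressionMatrix} in \code{log2} state with
#'   symbol gene ids.
#' @param bundle a \linkS4class{ProjectionBundle}.
#' @param warnThreshold imputed-fraction warning level (default 0.10).
#' @return list with \code{matrix} (standardized ExpressionMatrix in
#'   bundle feature order) and \code{report} (shared / imputed counts,
#'   imputed fraction, extra genes dropped).
#' @export
harmonizeFeatures <- function(target, bundle, warnThreshold = 0.10) {
  stopIfNot(scaleState(target) == "log2",
            "target must be on the log2 scale")
  v <- exprValues(target)
  shared <- intersect(bundle@features, rownames(v))
  stopIfNot(length(shared) > 0, "no features shared with the bundle")
  extras <- setdiff(rownames(v), bundle@features)
  imputed <- setdiff(bundle@features, rownames(v))
  z <- matrix(0, length(bundle@features), ncol(v),
              dimnames = list(bundle@features, colnames(v)))
  denom <- ifelse(bundle@sigma[shared] == 0, 1, bundle@sigma[shared])
  z[shared, ] <- (v[shared, , drop = FALSE] - bundle@mu[shared]) / denom
  z[shared, ][bundle@sigma[shared] == 0, ] <- 0
  report <- list(shared = length(shared), imputed = length(imputed),
                 imputedFraction = length(imputed) / length(bundle@features),
                 extraGenes = length(extras))
  if (report$imputedFraction > warnThreshold)
    warning(sprintf("imputed fraction %.3f exceeds threshold %.2f",
                    report$imputedFraction, warnThreshold), call. = FALSE)
  if (length(extras))
    axMsg(length(extras), " target gene(s) outside the bundle dropped")
  list(matrix = ExpressionMatrix(z, scaleState = "standardized"),
       report = report)
}

#' Project a harmonized cohort through a frozen bundle
#'
#' The no-retraining scoring map Z = XW': X is the standardized,
#' bundle-aligned expression matrix (samples x genes), W the frozen
#' loading matrix. The feature order is verified against the bundle's
#' content hash before multiplying; nothing is re-estimated and the map
#' involves no randomness.
#'
#' @param aligned standardized \linkS4class{ExpressionMatrix} in bundle
#'   feature order (as returned by \code{\link{harmonizeFeatures}}).
#' @param bundle a \linkS4class{ProjectionBundle}.
#' @param cohort cohort label carried into the result.
#' @return A \linkS4class{FactorScores} with provenance
#'   \code{"projected"}.
#' @export
projectScores <- function(aligned, bundle, cohort = "cohort") {
  stopIfNot(scaleState(aligned) == "standardized",
            "projection expects a standardized matrix")
  v <- exprValues(aligned)
  stopIfNot(identical(featureListHash(rownames(v)), bundle@featureHash),
            "feature order does not match the bundle (hash mismatch); ",
            "run harmonizeFeatures first")
  Z <- t(v) %*% t(bundle@loadings)
  colnames(Z) <- bundle@factorLabels
  FactorScores(Z, provenance = "projected", cohort = cohort)
}
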