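#' @import methods
#' @importFrom stats sd var median quantile rnorm runif rbinom rbeta rpois
#'   rexp lm resid cor cor.test pnorm pchisq pt qnorm complete.cases
#'   setNames p.adjust wilcox.test coef vcov as.formula predict optimize
#' @importFrom utils head read.delim write.table modifyList
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' ExpressionMatrix: a gene-by-sample expression matrix with scale tracking
#'
#' A thin container for expression values that records where the matrix
#' stands in the counts -> log2 -> standardized preprocessing chain, so
#' that operations can refuse inputs at the wrong stage. Genes are rows,
#' samples are columns (the Bioconductor convention); the projection
#' algebra transposes internally.
#'
#' @slot values numeric matrix, genes x samples, with unique dimnames.
#' @slot scaleState one of \code{"counts"}, \code{"log2"},
#'   \code{"standardized"}.
#' @export
setClass("ExpressionMatrix",
  representation(values = "matrix", scaleState = "character"),
  validity = function(object) {
    msg <- NULL
    v <- object@values
    if (is.null(rownames(v)) || is.null(colnames(v)))
      msg <- c(msg, "values must have gene rownames and sample colnames")
    if (!is.null(colnames(v)) && anyDuplicated(colnames(v)))
      msg <- c(msg, "duplicate sample ids")
    if (length(object@scaleState) != 1L ||
        !object@scaleState %in% c("counts", "log2", "standardized"))
      msg <- c(msg, "scaleState must be counts, log2 or standardized")
    if (is.null(msg)) TRUE else msg
  })

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix, genes x samples, with dimnames.
#' @param scaleState scale of the values; default \code{"counts"}.
#' @return An \linkS4class{ExpressionMatrix}.
#' @examples
#' m <- matrix(rpois(12, 10), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' ExpressionMatrix(m)
#' @export
ExpressionMatrix <- function(values, scaleState = "counts") {
  new("ExpressionMatrix", values = as.matrix(values), scaleState = scaleState)
}

#' @describeIn ExpressionMatrix-class numeric values (genes x samples)
#' @param x an ExpressionMatrix
#' @export
exprValues <- function(x) x@values

#' @describeIn ExpressionMatrix-class gene identifiers (rownames)
#' @export
geneIds <- function(x) rownames(x@values)

#' @describeIn ExpressionMatrix-class sample identifiers (colnames)
#' @export
sampleIds <- function(x) colnames(x@values)

#' @describeIn ExpressionMatrix-class preprocessing stage of the values
#' @export
scaleState <- function(x) x@scaleState

setMethod("show", "ExpressionMatrix", function(object) {
  cat("ExpressionMatrix:", nrow(object@values), "genes x",
      ncol(object@values), "samples [", object@scaleState, "]\n")
})

setMethod("dim", "ExpressionMatrix", function(x) dim(x@values))

#' MethylationMatrix: probe-by-sample methylation values
#'
#' @slot values numeric matrix, probes x samples.
#' @slot unit \code{"beta"} (values in (0,1)) or \code{"m"}
#'   (logit2-transformed).
#' @export
setClass("MethylationMatrix",
  representation(values = "matrix", unit = "character"),
  validity = function(object) {
    msg <- NULL
    if (!object@unit %in% c("beta", "m"))
      msg <- c(msg, "unit must be beta or m")
    if (object@unit == "beta" &&
        (any(object@values <= 0) || any(object@values >= 1)))
      msg <- c(msg, "beta values must lie strictly inside (0,1)")
    if (object@unit == "m" && any(!is.finite(object@values)))
      msg <- c(msg, "m values must be finite")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a MethylationMatrix
#' @param values probes x samples numeric matrix.
#' @param unit "beta" or "m".
#' @export
MethylationMatrix <- function(values, unit = "beta") {
  new("MethylationMatrix", values = as.matrix(values), unit = unit)
}

#' @describeIn MethylationMatrix-class numeric values (probes x samples)
#' @param x a MethylationMatrix
#' @export
methValues <- function(x) x@values

#' @describeIn MethylationMatrix-class value unit ("beta" or "m")
#' @export
methUnit <- function(x) x@unit

setMethod("show", "MethylationMatrix", function(object) {
  cat("MethylationMatrix:", nrow(object@values), "probes x",
      ncol(object@values), "samples [", object@unit, "]\n")
})

#' ScalingParams: frozen per-gene standardization parameters
#'
#' Per-gene mean and standard deviation learned once on a training matrix
#' and applied unchanged elsewhere; the portability device that makes
#' cross-cohort projection a frozen linear map.
#'
#' @slot mu named numeric, per-gene training mean.
#' @slot sigma named numeric, per-gene training sd (n-1 denominator).
#' @slot features ordered character vector of gene symbols.
#' @slot zeroSd logical, flags genes whose training sd was 0.
#' @export
setClass("ScalingParams",
  representation(mu = "numeric", sigma = "numeric",
                 features = "character", zeroSd = "logical"),
  validity = function(object) {
    msg <- NULL
    n <- length(object@features)
    if (length(object@mu) != n || length(object@sigma) != n ||
        length(object@zeroSd) != n)
      msg <- c(msg, "mu, sigma, zeroSd must match the feature list length")
    if (any(object@sigma < 0)) msg <- c(msg, "sigma must be >= 0")
    if (anyDuplicated(object@features)) msg <- c(msg, "duplicate features")
    if (is.null(msg)) TRUE else msg
  })

setMethod("show", "ScalingParams", function(object) {
  cat("ScalingParams for", length(object@features), "features (",
      sum(object@zeroSd), "with zero sd )\n")
})

#' @describeIn ScalingParams-class ordered feature list
#' @param x a ScalingParams object
#' @export
scalingFeatures <- function(x) x@features

#' ProjectionBundle: the frozen artifact for no-retraining validation
#'
#' Holds the fixed loading matrix W (factors x genes), the per-gene
#' training mean/sd, and the ordered feature list. Everything a new
#' cohort needs to be scored as Z = XW' with no re-estimation.
#'
#' @slot loadings factors x genes numeric matrix.
#' @slot mu,sigma named numeric scaling parameters per gene.
#' @slot features ordered character vector (must match loading columns).
#' @slot factorLabels character labels for the factor rows.
#' @slot featureHash content hash of the ordered feature list, used to
#'   detect silent column shuffles before projection.
#' @export
setClass("ProjectionBundle",
  representation(loadings = "matrix", mu = "numeric", sigma = "numeric",
                 features = "character", factorLabels = "character",
                 featureHash = "character"),
  validity = function(object) {
    msg <- NULL
    p <- length(object@features)
    if (ncol(object@loadings) != p)
      msg <- c(msg, "loading columns must match the feature list")
    if (nrow(object@loadings) != length(object@factorLabels))
      msg <- c(msg, "factorLabels must match loading rows")
    if (length(object@mu) != p || length(object@sigma) != p)
      msg <- c(msg, "mu/sigma must match the feature list")
    if (anyDuplicated(object@features))
      msg <- c(msg, "feature list contains duplicates")
    if (any(object@sigma < 0)) msg <- c(msg, "sigma must be >= 0")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a ProjectionBundle
#'
#' @param loadings factors x genes matrix.
#' @param mu,sigma per-gene scaling parameters, aligned with
#'   \code{features}.
#' @param features ordered feature list.
#' @param factorLabels optional factor labels; defaults to
#'   Factor1..FactorK.
#' @return A \linkS4class{ProjectionBundle}.
#' @export
ProjectionBundle <- function(loadings, mu, sigma, features,
                             factorLabels = NULL) {
  loadings <- as.matrix(loadings)
  if (is.null(factorLabels))
    factorLabels <- if (!is.null(rownames(loadings))) rownames(loadings)
                    else paste0("Factor", seq_len(nrow(loadings)))
  dimnames(loadings) <- list(factorLabels, features)
  new("ProjectionBundle", loadings = loadings,
      mu = setNames(as.numeric(mu), features),
      sigma = setNames(as.numeric(sigma), features),
      features = features, factorLabels = factorLabels,
      featureHash = featureListHash(features))
}

#' @describeIn ProjectionBundle-class the frozen loading matrix W
#' @param x a ProjectionBundle
#' @export
bundleLoadings <- function(x) x@loadings

#' @describeIn ProjectionBundle-class ordered feature list
#' @export
bundleFeatures <- function(x) x@features

setMethod("show", "ProjectionBundle", function(object) {
  cat("ProjectionBundle:", nrow(object@loadings), "factors x",
      length(object@features), "genes; hash", object@featureHash, "\n")
})

#' FactorModel: a fitted multi-view factorization
#'
#' @slot loadings named list of factors x features matrices, one per view.
#' @slot varianceExplained matrix, factors x views, percent of view
#'   variance explained by each single factor.
#' @slot scaling named list of \linkS4class{ScalingParams}, one per view.
#' @slot trainingScores samples x factors matrix of training scores
#'   (least-squares projection of the training data).
#' @slot factorLabels character labels for retained factors.
#' @export
setClass("FactorModel",
  representation(loadings = "list", varianceExplained = "matrix",
                 scaling = "list", trainingScores = "matrix",
                 factorLabels = "character"),
  validity = function(object) {
    msg <- NULL
    k <- length(object@factorLabels)
    if (any(vapply(object@loadings, nrow, 0L) != k))
      msg <- c(msg, "all view loadings must have one row per factor")
    if (nrow(object@varianceExplained) != k)
      msg <- c(msg, "varianceExplained rows must match factors")
    if (ncol(object@trainingScores) != k)
      msg <- c(msg, "trainingScores columns must match factors")
    if (is.null(msg)) TRUE else msg
  })

setMethod("show", "FactorModel", function(object) {
  ve <- rowSums(object@varianceExplained)
  cat("FactorModel:", length(object@factorLabels), "factors over",
      length(object@loadings), "view(s)\n")
  cat("  total variance explained (%):",
      paste(sprintf("%s=%.1f", object@factorLabels, ve), collapse = ", "),
      "\n")
})

#' @describeIn FactorModel-class per-view loading matrices
#' @param x a FactorModel
#' @export
modelLoadings <- function(x) x@loadings

#' @describeIn FactorModel-class training-sample factor scores
#' @export
trainingScores <- function(x) x@trainingScores

#' FactorScores: sample-level latent factor scores
#'
#' The pipeline's central currency: a samples x factors matrix with a
#' provenance tag recording whether scores came from training, from
#' frozen-parameter projection, or from purity residualization.
#'
#' @slot scores samples x factors numeric matrix.
#' @slot provenance one of \code{"trained"}, \code{"projected"},
#'   \code{"residualized"}.
#' @slot cohort cohort label.
#' @export
setClass("FactorScores",
  representation(scores = "matrix", provenance = "character",
                 cohort = "character"),
  validity = function(object) {
    msg <- NULL
    if (!object@provenance %in% c("trained", "projected", "residualized"))
      msg <- c(msg, "provenance must be trained, projected or residualized")
    if (any(is.na(object@scores))) msg <- c(msg, "scores contain NA")
    if (is.null(rownames(object@scores)))
      msg <- c(msg, "scores must carry sample rownames")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a FactorScores object
#' @param scores samples x factors matrix with sample rownames.
#' @param provenance "trained", "projected" or "residualized".
#' @param cohort cohort label.
#' @export
FactorScores <- function(scores, provenance = "trained", cohort = "cohort") {
  scores <- as.matrix(scores)
  if (is.null(colnames(scores)))
    colnames(scores) <- paste0("Factor", seq_len(ncol(scores)))
  new("FactorScores", scores = scores, provenance = provenance,
      cohort = cohort)
}

#' @describeIn FactorScores-class the samples x factors score matrix
#' @param x a FactorScores object
#' @export
scoreMatrix <- function(x) x@scores

#' @describeIn FactorScores-class provenance tag
#' @export
scoreProvenance <- function(x) x@provenance

setMethod("show", "FactorScores", function(object) {
  cat("FactorScores:", nrow(object@scores), "samples x",
      ncol(object@scores), "factors [", object@provenance, ",",
      object@cohort, "]\n")
})

setMethod("dim", "FactorScores", function(x) dim(x@scores))
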