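# Preprocessing and harmonization of the molecular views: log2 transform,
# duplicate-gene collapse, low-information filtering, beta->M conversion,
# segment-to-gene CNA mapping, and frozen per-gene standardization.

#' log2(x + 1) transform of a count matrix
#'
#' @param matrix an \linkS4class{ExpressionMatrix} in \code{counts} state
#'   with nonnegative values.
#' @return The matrix with values log2(x + 1) and state \code{log2}.
#' @examples
#' m <- ExpressionMatrix(matrix(c(0, 3, 1023, 7), 2, 2,
#'        dimnames = list(c("g1", "g2"), c("s1", "s2"))))
#' exprValues(log2Transform(m))
#' @export
log2Transform <- function(matrix) {
  stopIfNot(scaleState(matrix) == "counts",
            "log2Transform expects scale state 'counts', got '",
            scaleState(matrix), "'")
  v <- exprValues(matrix)
  if (any(v < 0)) {
    bad <- which(v < 0, arr.ind = TRUE)[1, ]
    stop("negative value at gene '", rownames(v)[bad[1]], "', sample '",
         colnames(v)[bad[2]], "'", call. = FALSE)
  }
  ExpressionMatrix(log2(v + 1), scaleState = "log2")
}

#' Collapse duplicate gene mappings by mean aggregation
#'
#' Maps raw identifiers to symbols and replaces rows that share a symbol
#' by their arithmetic mean; identifiers absent from the map are dropped
#' (count reported via message).
#'
#' @param matrix an \linkS4class{ExpressionMatrix} (counts or log2).
#' @param idMap named character vector: names are raw ids, values are
#'   symbols. Defaults to the identity map on the matrix's own ids.
#' @return An ExpressionMatrix with unique symbol rownames.
#' @export
collapseDuplicateGenes <- function(matrix,
                                   idMap = setNames(geneIds(matrix),
                                                    geneIds(matrix))) {
  stopIfNot(scaleState(matrix) %in% c("counts", "log2"),
            "collapse operates on counts or log2 matrices")
  v <- exprValues(matrix)
  mapped <- idMap[rownames(v)]
  dropN <- sum(is.na(mapped))
  if (dropN > 0) axMsg(dropN, " unmapped identifier(s) dropped")
  keep <- !is.na(mapped)
  stopIfNot(any(keep), "no identifiers could be mapped to symbols")
  v <- v[keep, , drop = FALSE]
  sym <- as.character(mapped[keep])
  collapsed <- rowsum(v, group = sym, reorder = FALSE) /
    as.vector(table(factor(sym, levels = unique(sym))))
  ExpressionMatrix(collapsed, scaleState = scaleState(matrix))
}

#' Remove low-information genes and keep the most variable
#'
#' Genes must reach both a minimum mean and a minimum variance on the
#' log2 scale; survivors are ranked by variance (descending) and
#' truncated to \code{topN}. The retained, ordered feature list defines
#' the training feature space for projection bundles.
#'
#' @param matrix an \linkS4class{ExpressionMatrix} in \code{log2} state.
#' @param meanMin,varMin thresholds on per-gene mean and variance
#'   (defaults 1 and 1.5).
#' @param topN cap on the number of retained genes (default 2000).
#' @return An ExpressionMatrix restricted to the retained genes, ordered
#'   by decreasing variance.
#' @export
filterLowInformation <- function(matrix, meanMin = 1, varMin = 1.5,
                                 topN = 2000L) {
  stopIfNot(scaleState(matrix) == "log2",
            "filter expects log2-scale values")
  v <- exprValues(matrix)
  mu <- rowMeans(v)
  s2 <- apply(v, 1, var)
  pass <- which(mu >= meanMin & s2 >= varMin)
  stopIfNot(length(pass) >= 2L,
            "fewer than 2 genes pass the information filter")
  ord <- pass[order(s2[pass], decreasing = TRUE)]
  ord <- head(ord, topN)
  ExpressionMatrix(v[ord, , drop = FALSE], scaleState = "log2")
}

#' Convert methylation beta-values to M-values
#'
#' Betas are clipped to [epsilon, 1 - epsilon] before the logit so the
#' M-values stay finite; the number of clipped entries is reported.
#'
#' @param matrix a \linkS4class{MethylationMatrix} in \code{beta} unit.
#' @param epsilon clipping margin, default 1e-6.
#' @return A MethylationMatrix in \code{m} unit, M = log2(beta/(1-beta)).
#' @examples
#' mm <- MethylationMatrix(matrix(c(0.5, 0.8, 0.2, 0.4), 2, 2,
#'         dimnames = list(c("p1", "p2"), c("s1", "s2"))))
#' methValues(betaToM(mm))
#' @export
betaToM <- function(matrix, epsilon = 1e-6) {
  stopIfNot(methUnit(matrix) == "beta", "betaToM expects beta values")
  b <- methValues(matrix)
  clipped <- sum(b < epsilon | b > 1 - epsilon)
  if (clipped > 0) axMsg(clipped, " beta value(s) clipped to [eps, 1-eps]")
  b <- pmin(pmax(b, epsilon), 1 - epsilon)
  MethylationMatrix(log2(b / (1 - b)), unit = "m")
}

#' Map copy-number segments onto genes by overlap-weighted mean
#'
#' Intersects segment coordinates with gene annotations (both 0-based
#' half-open) and assigns each gene the overlap-length-weighted mean of
#' the log2 ratios of the segments covering it. Genes with no overlapping
#' segment get NA.
#'
#' @param segments data.frame with columns sample_id, chromosome, start,
#'   end, log2_ratio (0-based half-open; see \code{oneBased}).
#' @param geneAnnotation data.frame with columns gene, chromosome, start,
#'   end.
#' @param oneBased set TRUE if the inputs use 1-based inclusive
#'   coordinates; they are converted at this boundary.
#' @return matrix genes x samples of weighted-mean log2 ratios.
#' @export
mapSegmentsToGenes <- function(segments, geneAnnotation, oneBased = FALSE) {
  need <- c("sample_id", "chromosome", "start", "end", "log2_ratio")
  stopIfNot(all(need %in% names(segments)),
            "segments must have columns: ", paste(need, collapse = ", "))
  bad <- which(segments$start >= segments$end |
                 segments$start < 0 | segments$end < 0)
  if (length(bad)) {
    axMsg("rejecting ", length(bad), " malformed segment record(s) at ",
          "line(s) ", paste(head(bad, 5), collapse = ", "))
    segments <- segments[-bad, , drop = FALSE]
  }
  stopIfNot(nrow(segments) > 0, "no valid segment records remain")
  shift <- if (oneBased) 0L else 1L  # GRanges is 1-based inclusive
  segGR <- GenomicRanges::GRanges(
    segments$chromosome,
    IRanges::IRanges(segments$start + shift, segments$end + shift - 1L))
  genGR <- GenomicRanges::GRanges(
    geneAnnotation$chromosome,
    IRanges::IRanges(geneAnnotation$start + shift,
                     geneAnnotation$end + shift - 1L))
  hits <- GenomicRanges::findOverlaps(genGR, segGR)
  ov <- IRanges::width(IRanges::pintersect(
    genGR[S4Vectors::queryHits(hits)], segGR[S4Vectors::subjectHits(hits)]))
  samples <- unique(segments$sample_id)
  out <- matrix(NA_real_, nrow(geneAnnotation), length(samples),
                dimnames = list(geneAnnotation$gene, samples))
  df <- data.frame(gene = S4Vectors::queryHits(hits),
                   sample = segments$sample_id[S4Vectors::subjectHits(hits)],
                   ratio = segments$log2_ratio[S4Vectors::subjectHits(hits)],
                   w = ov)
  agg <- stats::aggregate(cbind(wsum = w * ratio, w = w) ~ gene + sample,
                          data = df, FUN = sum)
  out[cbind(agg$gene, match(agg$sample, samples))] <- agg$wsum / agg$w
  out
}

#' Learn frozen per-gene standardization parameters
#'
#' Per-gene mean and sd (n - 1 denominator) computed on a training
#' matrix; genes with zero sd are flagged and later standardized to
#' all-zero columns rather than dividing by zero.
#'
#' @param matrix an \linkS4class{ExpressionMatrix} (log2 scale).
#' @return A \linkS4class{ScalingParams} in the matrix's gene order.
#' @export
zscoreFit <- function(matrix) {
  v <- exprValues(matrix)
  mu <- rowMeans(v)
  sigma <- apply(v, 1, sd)
  zero <- sigma == 0
  if (any(zero)) axMsg(sum(zero), " constant gene(s) flagged (sd = 0)")
  new("ScalingParams", mu = mu, sigma = sigma,
      features = rownames(v), zeroSd = zero)
}

#' Standardize a matrix with frozen parameters
#'
#' Applies (x - mu) / sigma per gene using parameters learned elsewhere;
#' the matrix's genes must exactly match the parameter feature list (use
#' \code{\link{harmonizeFeatures}} first for external cohorts). Zero-sd
#' genes become all-zero rows.
#'
#' @param matrix an \linkS4class{ExpressionMatrix} in \code{log2} state.
#' @param params a \linkS4class{ScalingParams}.
#' @return An ExpressionMatrix in \code{standardized} state, genes in
#'   parameter order.
#' @export
zscoreApply <- function(matrix, params) {
  v <- exprValues(matrix)
  stopIfNot(setequal(rownames(v), params@features) &&
              length(rownames(v)) == length(params@features),
            "matrix features do not match the scaling parameters; ",
            "harmonization must precede standardization")
  v <- v[params@features, , drop = FALSE]
  denom <- ifelse(params@zeroSd, 1, params@sigma)
  z <- (v - params@mu) / denom
  z[params@zeroSd, ] <- 0
  ExpressionMatrix(z, scaleState = "standardized")
}

#' Read a genes-by-samples expression table
#'
#' @param path delimited text file; first column gene ids, remaining
#'   columns one per sample.
#' @param sep field separator (default tab).
#' @param scaleState scale of the stored values.
#' @return An \linkS4class{ExpressionMatrix}.
#' @export
readExpression <- function(path, sep = "\t", scaleState = "counts") {
  df <- read.delim(path, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  ExpressionMatrix(m, scaleState = scaleState)
}

#' Write an expression matrix as delimited text
#' @param matrix an ExpressionMatrix.
#' @param path output file.
#' @export
writeExpression <- function(matrix, path) {
  v <- exprValues(matrix)
  write.table(data.frame(gene = rownames(v), v, check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probes-by-samples methylation table
#'
#' @param path delimited text; first column probe ids.
#' @param unit unit of the stored values ("beta" or "m").
#' @return A \linkS4class{MethylationMatrix}.
#' @export
readMethylation <- function(path, unit = "beta") {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  MethylationMatrix(m, unit = unit)
}

#' Read a SEG-style segment table
#' @param path delimited text with columns sample_id, chromosome, start,
#'   end, log2_ratio.
#' @return data.frame suitable for \code{\link{mapSegmentsToGenes}}.
#' @export
readSegments <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
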