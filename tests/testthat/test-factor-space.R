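# Fixture: a two-block single-view dataset whose factors are known by
# construction. Block 1 (genes 1:10) is driven by score u with twice the
# amplitude of block 2 (genes 11:20, driven by independent v), so the
# leading singular spaces are well separated.
makeTwoBlock <- function(n = 200, noise = 0, seed = 10) {
  set.seed(seed)
  u <- rnorm(n)
  v <- resid(lm(rnorm(n) ~ u))  # exactly orthogonal to u in-sample
  signal <- cbind(u %o% rep(2, 10), v %o% rep(1, 10))
  X <- signal + matrix(rnorm(n * 20, 0, noise), n, 20)
  Xt <- t(X)
  dimnames(Xt) <- list(paste0("g", 1:20), paste0("s", 1:n))
  list(m = ExpressionMatrix(Xt, scaleState = "standardized"),
       u = u, v = v,
       # construction oracle: each block's share of the total sum of squares
       veBlocks = 100 * c(sum(signal[, 1:10]^2), sum(signal[, 11:20]^2)) /
         sum(X^2))
}

test_that("stand-in factorization recovers exact low-rank structure", {
  set.seed(20)
  u <- rnorm(100)
  X <- u %o% rnorm(15)
  m <- ExpressionMatrix(t(X) |>
    (\(x) { dimnames(x) <- list(paste0("g", 1:15), paste0("s", 1:100)); x })(),
    scaleState = "standardized")
  fit <- fitFactorModel(list(rna = m), kInit = 5, pruneMinVe = 1)
  expect_equal(length(fit@factorLabels), 1L)
  expect_equal(unname(rowSums(fit@varianceExplained)), 100, tolerance = 1e-8)
  expect_gt(abs(cor(trainingScores(fit)[, 1], u)), 0.999)
})

test_that("orthogonal gene blocks yield separated factors with block-specific variance", {
  tb <- makeTwoBlock()
  fit <- fitFactorModel(list(rna = tb$m), kInit = 4, pruneMinVe = 1)
  expect_equal(length(fit@factorLabels), 2L)
  W <- modelLoadings(fit)$rna
  # cross-block loadings vanish
  expect_lt(max(abs(W["Factor1", paste0("g", 11:20)])), 1e-8)
  expect_lt(max(abs(W["Factor2", paste0("g", 1:10)])), 1e-8)
  expect_gt(abs(cor(trainingScores(fit)[, 1], tb$u)), 0.999)
  expect_gt(abs(cor(trainingScores(fit)[, 2], tb$v)), 0.999)
  # per-block construction oracle: each factor explains its own block
  ve <- varianceExplained(fit, list(rna = tb$m))
  expect_equal(unname(ve[, "rna"]), tb$veBlocks, tolerance = 1e-6)
})

test_that("pruning threshold zero retains all initial factors", {
  tb <- makeTwoBlock(noise = 0.5)
  fit <- fitFactorModel(list(rna = tb$m), kInit = 6, pruneMinVe = 0)
  expect_equal(length(fit@factorLabels), 6L)
  # retained order is by decreasing total variance explained
  tot <- rowSums(fit@varianceExplained)
  expect_true(all(diff(tot) <= 1e-9))
  expect_error(
    fitFactorModel(list(a = tb$m,
                        b = ExpressionMatrix(exprValues(tb$m)[, 1:10],
                                             scaleState = "standardized"))),
    "same samples")
})

test_that("variance explained hits its analytic anchors", {
  tb <- makeTwoBlock()
  fit <- fitFactorModel(list(rna = tb$m), kInit = 2, pruneMinVe = 0)
  ve <- varianceExplained(fit, list(rna = tb$m))
  expect_equal(sum(ve), 100, tolerance = 1e-6)
  # zero loadings explain nothing
  zeroed <- fit
  zeroed@loadings$rna["Factor2", ] <- 0
  ve0 <- varianceExplained(zeroed, list(rna = tb$m))
  expect_equal(unname(ve0["Factor2", "rna"]), 0)
  # known 70/30 split at n = 1000, noiseless
  set.seed(30)
  n <- 1000
  a <- rnorm(n); b <- rnorm(n)
  # block sizes tuned so factor shares are 70% and 30% of total variance
  X <- cbind(a %o% rep(sqrt(7), 10), b %o% rep(sqrt(3), 10))
  dimnames(X) <- list(paste0("s", 1:n), paste0("g", 1:20))
  mm <- ExpressionMatrix(t(X), scaleState = "standardized")
  f2 <- fitFactorModel(list(rna = mm), kInit = 2, pruneMinVe = 0)
  ve2 <- sort(varianceExplained(f2, list(rna = mm))[, "rna"],
              decreasing = TRUE)
  expect_equal(unname(ve2), c(70, 30), tolerance = 5)
  expect_error(varianceExplained(f2, list(rna = ExpressionMatrix(
    exprValues(mm) * 0, scaleState = "standardized"))), "all-zero")
})

test_that("bundle export/import is a lossless round trip with schema checks", {
  tb <- makeTwoBlock()
  sp <- quiet(zscoreFit(ExpressionMatrix(exprValues(tb$m),
                                         scaleState = "log2")))
  fit <- fitFactorModel(list(rna = tb$m), kInit = 2, pruneMinVe = 0,
                        scaling = list(rna = sp))
  b <- exportBundle(fit, "rna")
  dir <- tempfile("bundle")
  writeBundle(b, dir)
  back <- importBundle(dir)
  expect_equal(back@loadings, b@loadings, tolerance = 1e-12)
  expect_equal(back@mu, b@mu, tolerance = 1e-12)
  expect_equal(back@sigma, b@sigma, tolerance = 1e-12)
  expect_identical(back@features, b@features)
  expect_identical(back@featureHash, b@featureHash)

  # corrupt the scaling table: schema error names the feature
  sc <- read.delim(file.path(dir, "scaling.tsv"))
  write.table(sc[-3, ], file.path(dir, "scaling.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(importBundle(dir), "g3")

  # the full-scale bundle shape: 12 factors x 2000 genes
  big <- ProjectionBundle(matrix(0, 12, 2000), mu = rep(0, 2000),
                          sigma = rep(1, 2000),
                          features = sprintf("gene%04d", 1:2000))
  expect_equal(dim(bundleLoadings(big)), c(12L, 2000L))
})

test_that("feature harmonization intersects, standardizes frozen, and zero-imputes", {
  p <- 2000
  features <- sprintf("gene%04d", 1:p)
  b <- ProjectionBundle(matrix(rnorm(2 * p), 2, p), mu = rep(5, p),
                        sigma = rep(2, p), features = features)
  set.seed(40)
  shared <- sort(sample(features, 1864))
  target <- ExpressionMatrix(
    matrix(rnorm(length(shared) * 3, 5, 2), length(shared), 3,
           dimnames = list(shared, paste0("s", 1:3))),
    scaleState = "log2")
  h <- harmonizeFeatures(target, b)
  expect_equal(h$report$shared, 1864L)
  expect_equal(h$report$imputed, 136L)
  expect_equal(h$report$imputedFraction, 0.068)
  expect_identical(geneIds(h$matrix), features)
  missing <- setdiff(features, shared)
  expect_true(all(exprValues(h$matrix)[missing, ] == 0))
  expect_equal(exprValues(h$matrix)[shared[1], ],
               (exprValues(target)[shared[1], ] - 5) / 2)

  # warning above the imputation threshold
  tiny <- ExpressionMatrix(exprValues(target)[1:1000, , drop = FALSE],
                           scaleState = "log2")
  expect_warning(harmonizeFeatures(tiny, b), "exceeds threshold")

  # superset target: extras dropped and reported
  extra <- ExpressionMatrix(rbind(
    exprValues(target),
    matrix(rnorm(500 * 3), 500, 3,
           dimnames = list(paste0("novel", 1:500), paste0("s", 1:3)))),
    scaleState = "log2")
  h2 <- quiet(harmonizeFeatures(extra, b))
  expect_equal(h2$report$extraGenes, 500L)
  expect_error(harmonizeFeatures(ExpressionMatrix(
    matrix(1, 2, 2, dimnames = list(c("no1", "no2"), c("a", "b"))),
    scaleState = "log2"), b), "no features shared")
})

test_that("self-harmonization through a fitted bundle reproduces training scores", {
  set.seed(50)
  counts <- matrix(rpois(3000, 60), 30, 100,
                   dimnames = list(paste0("g", 1:30), paste0("s", 1:100)))
  lg <- log2Transform(ExpressionMatrix(counts))
  sp <- zscoreFit(lg)
  std <- zscoreApply(lg, sp)
  fit <- fitFactorModel(list(rna = std), kInit = 4, pruneMinVe = 0,
                        scaling = list(rna = sp))
  b <- exportBundle(fit, "rna")
  h <- harmonizeFeatures(lg, b)
  expect_equal(h$report$imputed, 0L)
  z <- projectScores(h$matrix, b, "self")
  # orthonormal stand-in loadings: projection equals the training scores
  expect_equal(unname(scoreMatrix(z)), unname(trainingScores(fit)),
               tolerance = 1e-8)
  expect_identical(scoreProvenance(z), "projected")
})

test_that("projection is the exact linear map Z = XW' with alignment guards", {
  features <- paste0("g", 1:4)
  b <- ProjectionBundle(diag(4), mu = rep(0, 4), sigma = rep(1, 4),
                        features = features)
  X <- matrix(rnorm(20), 4, 5,
              dimnames = list(features, paste0("s", 1:5)))
  mx <- ExpressionMatrix(X, scaleState = "standardized")
  z <- projectScores(mx, b)
  expect_equal(unname(scoreMatrix(z)), unname(t(X)))  # identity loadings

  # linearity
  X2 <- matrix(rnorm(20), 4, 5, dimnames = dimnames(X))
  za <- scoreMatrix(projectScores(ExpressionMatrix(2 * X + 3 * X2,
          scaleState = "standardized"), b))
  expect_equal(za, 2 * scoreMatrix(z) +
    3 * scoreMatrix(projectScores(ExpressionMatrix(X2,
          scaleState = "standardized"), b)), tolerance = 1e-12)

  # zeroing a gene column equals projecting a target lacking that gene
  Wr <- matrix(rnorm(8), 2, 4)
  br <- ProjectionBundle(Wr, mu = rep(1, 4), sigma = rep(2, 4),
                         features = features)
  full <- matrix(rnorm(12, 1, 2), 4, 3,
                 dimnames = list(features, paste0("s", 1:3)))
  lgFull <- ExpressionMatrix(full, scaleState = "log2")
  hFull <- harmonizeFeatures(lgFull, br)
  zeroed <- exprValues(hFull$matrix)
  zeroed["g2", ] <- 0
  zManual <- t(zeroed) %*% t(Wr)
  lgMissing <- ExpressionMatrix(full[-2, , drop = FALSE],
                                scaleState = "log2")
  zMissing <- scoreMatrix(projectScores(
    quiet(harmonizeFeatures(lgMissing, br))$matrix, br))
  expect_equal(unname(zMissing), unname(zManual), tolerance = 1e-12)

  # determinism and misalignment rejection
  expect_identical(scoreMatrix(projectScores(mx, b)), scoreMatrix(z))
  shuffled <- ExpressionMatrix(X[c(2, 1, 3, 4), ],
                               scaleState = "standardized")
  expect_error(projectScores(shuffled, b), "hash")
})

test_that("projected external-cohort scores track the simulated truth", {
  cfg <- simConfig(nCohorts = 2L, nSamplesPerCohort = 300L, nGenes = 500L,
                   nFactors = 4L, loadingSparsity = 0.8,
                   missingGeneFraction = 0.068, platformScaleSd = 0.1,
                   platformOffsetSd = 0.1, noiseSd = 0.5, seed = 60L)
  cohorts <- simulateMulticohort(cfg)
  tr <- cohorts$training
  lg <- log2Transform(ExpressionMatrix(SummarizedExperiment::assay(tr)))
  sp <- quiet(zscoreFit(lg))
  fit <- fitFactorModel(list(rna = zscoreApply(lg, sp)), kInit = 6,
                        pruneMinVe = 1, scaling = list(rna = sp))
  b <- exportBundle(fit, "rna")
  ex <- cohorts$external1
  lgx <- log2Transform(ExpressionMatrix(SummarizedExperiment::assay(ex)))
  z <- projectScores(quiet(harmonizeFeatures(lgx, b))$matrix, b, "ext")
  truth <- S4Vectors::metadata(ex)$truth$trueScores
  expect_gt(abs(cor(scoreMatrix(z)[, 1], truth[, 1])), 0.9)

  # robustness: dropping up to 7% of features changes scores < 10% RMS
  set.seed(61)
  keep <- sample(bundleFeatures(b),
                 round(0.93 * length(bundleFeatures(b))))
  lgDrop <- ExpressionMatrix(exprValues(lgx)[
    intersect(rownames(exprValues(lgx)), keep), , drop = FALSE],
    scaleState = "log2")
  zDrop <- projectScores(quiet(harmonizeFeatures(lgDrop, b))$matrix, b)
  rel <- sqrt(mean((scoreMatrix(zDrop)[, 1] - scoreMatrix(z)[, 1])^2)) /
    sd(scoreMatrix(z)[, 1])
  expect_lt(rel, 0.10)
})
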