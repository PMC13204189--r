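test_that("Cox fit matches a grid-search partial-likelihood oracle on a toy fixture", {
  toy <- data.frame(os_months = 1:6, event = 1L,
                    x = c(1, 0, 1, 0, 1, 0))
  fit <- fitCox(toy, "x")
  oracle <- optimize(function(b)
    -oraclePartialLoglik(b, toy$os_months, toy$event, toy$x),
    c(-5, 5), tol = 1e-10)$minimum
  expect_lt(abs(fit$table["x", "coef"] - oracle), 1e-4)
  expect_equal(fit$table["x", "hr"], exp(fit$table["x", "coef"]))
  expect_equal(unname(fit$table["x", c("ci_low", "ci_high")]),
               exp(fit$table["x", "coef"] +
                     c(-1, 1) * 1.959964 * fit$table["x", "se"]))
})

test_that("a null binary group gives a coefficient near zero with CI covering 1", {
  set.seed(1)
  d <- simSurv(rep(0, 400))
  d$g <- rep(0:1, 200)
  fit <- fitCox(d, "g")
  expect_lt(abs(fit$table["g", "coef"]), 0.3)
  expect_lte(fit$table["g", "ci_low"], 1)
  expect_gte(fit$table["g", "ci_high"], 1)
})

test_that("Cox coefficients are invariant to positive time rescaling", {
  set.seed(2)
  d <- simSurv(0.5 * rnorm(300), seed = 3)
  d$x <- rnorm(300)
  f1 <- fitCox(d, "x")
  d2 <- transform(d, os_months = os_months * 37.2)
  f2 <- fitCox(d2, "x")
  expect_equal(f1$table["x", "coef"], f2$table["x", "coef"],
               tolerance = 1e-8)
})

test_that("per-SD scaling and complete-case accounting work as documented", {
  set.seed(4)
  x <- rnorm(200, sd = 4)
  d <- simSurv(0.2 * x, seed = 5)
  d$x <- x
  raw <- fitCox(d, "x")
  sc <- fitCox(d, "x", scalePerSd = TRUE)
  expect_equal(sc$table["x", "coef"], raw$table["x", "coef"] * sd(x),
               tolerance = 1e-6)
  d$x[1:25] <- NA
  expect_message(f <- fitCox(d, "x"), "25 incomplete")
  expect_equal(f$n, 175)
  expect_error(fitCox(data.frame(os_months = 1:3, event = 0L,
                                 x = 1:3), "x"), "fewer than 2 events")
})

test_that("Kaplan-Meier estimates match a hand-computed product-limit table", {
  # staggered censoring fixture, computed by hand:
  # t=2 (d=1, n=6) S=5/6; t=4 (d=1, n=4) S=5/6*3/4=0.625;
  # t=6 (d=1, n=2) S=0.625*1/2=0.3125
  cl <- data.frame(os_months = c(2, 3, 4, 5, 6, 7),
                   event = c(1, 0, 1, 0, 1, 0))
  km <- kmEstimate(cl, rep("all", 6))$all
  expect_equal(km$time, c(2, 4, 6))
  expect_equal(km$surv, c(5 / 6, 0.625, 0.3125), tolerance = 1e-12)
  # Greenwood: S(t)^2 * sum d/(n(n-d))
  g2 <- (0.625)^2 * (1 / (6 * 5) + 1 / (4 * 3))
  expect_equal(km$greenwood_var[2], g2, tolerance = 1e-12)

  # one event among four subjects
  cl4 <- data.frame(os_months = c(5, 6, 7, 8), event = c(1, 0, 0, 0))
  expect_equal(kmEstimate(cl4, rep("a", 4))$a$surv, 0.75)

  # no events: the survival curve never drops
  cl0 <- data.frame(os_months = 1:5, event = 0L)
  expect_equal(nrow(kmEstimate(cl0, rep("a", 5))$a), 0L)

  # with no censoring, KM equals the empirical survival function
  set.seed(6)
  t_ <- sort(runif(40, 1, 100))
  kmAll <- kmEstimate(data.frame(os_months = t_, event = 1L),
                      rep("g", 40))$g
  expect_equal(kmAll$surv, 1 - seq_len(40) / 40, tolerance = 1e-12)
  expect_error(kmEstimate(cl, c(rep("a", 5), NA)), "labeled")
})

test_that("log-rank equals the hand-tabulated observed-minus-expected statistic", {
  # 8-subject fixture; oracle builds the 2x2 table at each event time
  cl <- data.frame(os_months = c(1, 3, 4, 6, 2, 5, 7, 9),
                   event = c(1, 1, 0, 1, 1, 1, 0, 1))
  g <- rep(c("A", "B"), each = 4)
  got <- logrankTest(cl, g)
  oracle <- local({
    O <- 0; E <- 0; V <- 0
    for (t_ in sort(unique(cl$os_months[cl$event == 1]))) {
      at <- cl$os_months >= t_
      d <- sum(cl$event == 1 & cl$os_months == t_)
      dA <- sum(cl$event == 1 & cl$os_months == t_ & g == "A")
      n <- sum(at); nA <- sum(at & g == "A")
      O <- O + dA
      E <- E + d * nA / n
      if (n > 1) V <- V + d * (nA / n) * (1 - nA / n) * (n - d) / (n - 1)
    }
    (O - E)^2 / V
  })
  expect_equal(got$chisq, oracle, tolerance = 1e-10)
  expect_equal(got$df, 1L)
  # symmetry under label swap
  swapped <- logrankTest(cl, ifelse(g == "A", "B", "A"))
  expect_equal(swapped$chisq, got$chisq, tolerance = 1e-12)
  # identical groups: statistic 0, p 1
  dup <- rbind(cl, cl)
  same <- logrankTest(dup, rep(c("A", "B"), each = 8))
  expect_equal(same$chisq, 0, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-9)
  expect_error(logrankTest(cl, rep("A", 8)), "2 groups")
})

test_that("log-rank agrees with the Cox score test for a binary predictor", {
  set.seed(7)
  x <- rep(0:1, 60)
  d <- simSurv(0.6 * x, censRate = 0, seed = 8)
  d$x <- x
  lr <- logrankTest(d, x)
  sc <- survival::coxph(survival::Surv(os_months, event) ~ x,
                        data = d)
  expect_equal(lr$chisq, sc$score, tolerance = 1e-6)
})

test_that("nested-model likelihood ratio test behaves at its anchors", {
  set.seed(9)
  d <- simSurv(0.5 * rnorm(500), seed = 10)
  d$x <- rnorm(500); d$z <- rnorm(500)
  base <- fitCox(d, "x")
  expect_equal(lrTest(base, base)$stat, 0)
  expect_equal(lrTest(base, base)$p, 1)
  full <- fitCox(d, c("x", "z"))
  lt <- lrTest(base, full)
  expect_equal(lt$df, 1L)
  expect_gte(lt$p, 0)
  other <- fitCox(d[1:400, ], c("x", "z"))
  expect_error(lrTest(base, other), "different samples")

  # power: adding the true driver is decisively detected
  ps <- vapply(1:11, function(r) {
    x <- rnorm(1000)
    dd <- simSurv(0.5 * x, seed = 100 + r)
    dd$x <- x
    dd$noise <- rnorm(1000)
    lrTest(fitCox(dd, "noise"), fitCox(dd, c("noise", "x")))$p
  }, numeric(1))
  expect_lt(median(ps), 1e-4)
})

test_that("the factor-by-IDH interaction test detects stratum-specific effects", {
  set.seed(11)
  n <- 1200
  idh <- rep(c("mutant", "wildtype"), each = n / 2)
  x <- rnorm(n)
  lp <- ifelse(idh == "mutant", 0.7 * x, 0)
  d <- simSurv(lp, seed = 12)
  d$idh_status <- idh
  got <- interactionLRT(d, x)
  expect_lt(got$p, 0.05)
  expect_error(interactionLRT(d, rep(1, n)), "constant")
  d0 <- d; d0$event[d0$idh_status == "mutant"] <- 0L
  expect_error(interactionLRT(d0, x), "zero events")
})

test_that("Schoenfeld test flags a time-reversing coefficient and guards its preconditions", {
  set.seed(13)
  n <- 1000
  x <- rnorm(n)
  # piecewise hazard: adverse early, protective late -> PH violation
  t1 <- rexp(n, 0.1 * exp(1.2 * x))
  t_ <- ifelse(t1 < 5, t1, 5 + rexp(n, 0.1 * exp(-1.2 * x)))
  d <- data.frame(os_months = t_, event = 1L, x = x)
  fit <- fitCox(d, "x")
  ph <- schoenfeldPhTest(fit)
  expect_lt(ph["x", "p"], 0.05)
  tiny <- fitCox(data.frame(os_months = c(1, 2, 3, 4),
                            event = c(1, 1, 0, 0), x = c(0, 1, 0, 1)), "x")
  expect_error(schoenfeldPhTest(tiny), "fewer events")
})

test_that("the IDH-stratified table has the full grid shape and one BH family", {
  cfg <- smallConfig(nSamplesPerCohort = 250L, nGenes = 40L,
                     loadingSparsity = 0.5, maxBlockOverlap = 0.6)
  cohorts <- quiet(simulateMulticohort(cfg))
  input <- lapply(cohorts, function(se) {
    truth <- S4Vectors::metadata(se)$truth
    list(clinical = as.data.frame(SummarizedExperiment::colData(se)),
         scores = FactorScores(truth$trueScores, "trained", "sim"))
  })
  tab <- quiet(stratifiedCoxTable(input))
  expect_equal(nrow(tab), 2 * 2 * 3)  # cohorts x strata x factors
  ok <- !is.na(tab$p)
  expect_equal(tab$fdr[ok], bhAdjust(tab$p[ok]))

  # empty stratum produces a reason-coded row, not an error
  input1 <- input[1]
  input1[[1]]$clinical$idh_status <- "wildtype"
  tab1 <- quiet(stratifiedCoxTable(input1, factors = "Factor1"))
  expect_equal(tab1$reason[tab1$stratum == "mutant"], "empty stratum")
  expect_true(is.na(tab1$hr[tab1$stratum == "mutant"]))
})

test_that("survival-extremes selection applies strict inequalities", {
  cl <- data.frame(sample_id = letters[1:5],
                   os_months = c(3, 6, 10, 15, 20))
  got <- quiet(selectExtremes(cl))
  expect_equal(got$os_months, c(3, 20))
  expect_equal(got$extreme_group, c("ultra_short", "long"))

  interior <- data.frame(os_months = c(6, 8, 12, 15))
  expect_warning(out <- suppressMessages(selectExtremes(interior)),
                 "no samples")
  expect_equal(nrow(out), 0L)

  onlyLong <- quiet(selectExtremes(cl, low = 0, high = 15))
  expect_equal(onlyLong$os_months, 20)
  expect_error(selectExtremes(cl, low = 15, high = 6), "strictly below")
})

test_that("Mann-Whitney U uses exact small-sample enumeration and handles ties", {
  r <- mwuTest(c(1, 2, 3), c(4, 5, 6), alternative = "less")
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.05)  # 1 / choose(6, 3)
  same <- mwuTest(c(1.2, 3.4, 5.6, 7.8), c(1.2, 3.4, 5.6, 7.8))
  expect_gt(same$p, 0.9)
  expect_warning(tied <- mwuTest(rep(2, 5), rep(2, 4)), "tied")
  expect_equal(tied$p, 1)
  expect_error(mwuTest(numeric(0), 1:3), "non-empty")

  # power at a 1-SD shift
  hits <- vapply(1:20, function(r) {
    set.seed(200 + r)
    mwuTest(rnorm(50), rnorm(50, 1))$p < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("BH adjustment is the step-up procedure with monotone output", {
  expect_equal(bhAdjust(0.04), 0.04)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(14)
  p <- sort(runif(50))
  adj <- bhAdjust(p)
  expect_true(all(diff(adj) >= 0))
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  expect_error(bhAdjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("partial likelihood is maximized: fitted loglik beats nearby coefficients", {
  set.seed(15)
  d <- simSurv(0.4 * rnorm(150), seed = 16)
  d$x <- rnorm(150)
  fit <- fitCox(d, "x")
  bHat <- fit$table["x", "coef"]
  llAt <- function(b) oraclePartialLoglik(b, d$os_months, d$event, d$x)
  expect_gte(llAt(bHat), llAt(bHat + 0.05))
  expect_gte(llAt(bHat), llAt(bHat - 0.05))
})
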