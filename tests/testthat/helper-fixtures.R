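# Shared fixtures: all built in code, deterministic under explicit seeds.

quiet <- function(expr) suppressMessages(suppressWarnings(expr))

# Tiny expression matrix with dimnames.
makeExpr <- function(values, genes = NULL, samples = NULL,
                     scaleState = "counts") {
  m <- as.matrix(values)
  rownames(m) <- if (is.null(genes)) paste0("g", seq_len(nrow(m))) else genes
  colnames(m) <- if (is.null(samples)) paste0("s", seq_len(ncol(m)))
                 else samples
  ExpressionMatrix(m, scaleState = scaleState)
}

# Survival-only simulation: exponential event times with log-hazard
# rate0 * exp(lp), independent exponential censoring. Used where a test
# needs survival draws without the expression machinery.
simSurv <- function(lp, rate0 = 0.05, censRate = 0.02, seed = 1) {
  set.seed(seed)
  n <- length(lp)
  t_ev <- rexp(n, rate0 * exp(lp))
  t_c <- if (censRate > 0) rexp(n, censRate) else rep(Inf, n)
  data.frame(os_months = pmin(t_ev, t_c),
             event = as.integer(t_ev <= t_c))
}

# Independent Efron/Breslow partial log-likelihood for a single covariate
# (used as a grid-search oracle against the fitted Cox model; with
# distinct event times the two tie conventions coincide).
oraclePartialLoglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# Small multicohort configuration used by several module tests.
smallConfig <- function(...) {
  args <- modifyList(list(nCohorts = 2L, nSamplesPerCohort = 120L,
                          nGenes = 150L, nFactors = 3L,
                          loadingSparsity = 0.8, seed = 7L), list(...))
  do.call(simConfig, args)
}
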