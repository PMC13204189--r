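# Internal helpers shared across modules.

# Deterministic polynomial rolling hash of an ordered character vector.
# Base-257 Horner evaluation modulo the Mersenne prime 2^31 - 1, carried in
# doubles (all intermediates < 2^53, so arithmetic is exact). Order-sensitive
# by construction: a permuted feature list hashes differently.
featureListHash <- function(features) {
  mod <- 2147483647
  h <- 0
  for (s in features) {
    for (b in utf8ToInt(s)) h <- (h * 257 + b) %% mod
    h <- (h * 257 + 31) %% mod  # separator so c("ab","c") != c("a","bc")
  }
  sprintf("%08x", h)
}

# Expand one user seed into named integer substreams, keeping every derived
# seed inside 32-bit integer range. Isolates stochastic stages so that, e.g.,
# the gene-drop pattern of cohort 2 does not depend on how many random draws
# cohort 1 consumed.
deriveSeed <- function(seed, ...) {
  tag <- paste(c(...), collapse = "/")
  mod <- 2147483647
  h <- seed %% mod
  for (b in utf8ToInt(tag)) h <- (h * 131 + b) %% mod
  as.integer(h %% .Machine$integer.max)
}

# Messaging helper: all informational logging funnels through here so tests
# can silence it uniformly.
axMsg <- function(...) message("[gliomaAxes] ", ...)

stopIfNot <- function(cond, ...) if (!isTRUE(cond)) stop(..., call. = FALSE)
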