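# Independent oracles used to freeze expected values.

# expectation of fn(K) under K ~ Geometric(p) (K >= 1), truncated where the
# geometric tail bound p*(1-p)^(k-1) summed beyond k_max drops below tol
enum_geometric <- function(p, fn, tol = 1e-12) {
  if (p == 1) {
    return(fn(1L))
  }
  k_max <- ceiling(log(tol * p) / log(1 - p)) + 1L
  k <- seq_len(k_max)
  w <- p * (1 - p)^(k - 1)
  sum(w * vapply(k, fn, numeric(1)))
}

# harmonic-sum oracle for the IBS point estimate
harmonic_estimate <- function(k) {
  if (k == 1L) 0 else -sum(1 / seq_len(k - 1L))
}

# truncated-series oracle for the dilogarithm on [0, 1)
dilog_series_oracle <- function(z, tol = 1e-16) {
  total <- 0
  j <- 1
  repeat {
    term <- z^j / j^2
    total <- total + term
    if (term < tol || j > 1e6) break
    j <- j + 1
  }
  total
}

# simulators for engine tests
always_match_sim <- function(stimulus, params) 1L
never_match_sim <- function(stimulus, params) 0L

bernoulli_sim <- function(stimulus, params) as.integer(runif(1) < params[["p"]])

# all-hit dataset of n trials (target response 1)
unit_data <- function(n) trial_data(rep(0, n), rep(1L, n))
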