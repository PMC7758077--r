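#' IBS point estimate of log p from a geometric hit count
#'
#' Under inverse binomial sampling, simulator draws are taken until the
#' first 'hit'; the (inclusive) number of draws `K` is geometric with
#' success probability `p`.  The unique uniformly unbiased estimator of
#' `log p` given `K` is
#' \deqn{\hat L(K) = \psi(1) - \psi(K) = -\sum_{j=1}^{K-1} 1/j,}
#' with the convention that the empty sum is 0 (so `K = 1` maps to 0).
#'
#' @param k positive integer vector of hit counts (`K >= 1`).
#' @return numeric vector of estimates of `log p`, all `<= 0` (nats).
#' @seealso [ibs_variance_estimate()], [ibs_variance_true()]
#' @examples
#' ibs_point_estimate(1)   # 0
#' ibs_point_estimate(2)   # -1
#' @export
ibs_point_estimate <- function(k) {
  check_sample_count(k)
  digamma(1) - digamma(k)
}

#' IBS variance estimate given a hit count
#'
#' Posterior variance of the trial log-likelihood given `K`, derived from
#' a Bayesian reading of the IBS estimator:
#' \eqn{\psi_1(1) - \psi_1(K) = \sum_{j=1}^{K-1} 1/j^2}, where
#' \eqn{\psi_1} is the trigamma function.  It is 0 for `K = 1`, strictly
#' increasing in `K`, and bounded above by \eqn{\pi^2/6}.
#'
#' @inheritParams ibs_point_estimate
#' @return numeric vector of non-negative variances (nats squared).
#' @export
ibs_variance_estimate <- function(k) {
  check_sample_count(k)
  trigamma(1) - trigamma(k)
}

#' Exact variance of the IBS estimator for known p
#'
#' \deqn{Var[\hat L_{IBS}] = \sum_{k \ge 1} (1-p)^k / k^2 = Li_2(1 - p),}
#' the dilogarithm of `1 - p`.  Decreasing in `p`, equal to 0 at `p = 1`,
#' and converging to \eqn{\pi^2/6} as `p` tends to 0: the IBS estimator has
#' uniformly bounded variance.
#'
#' @param p probability vector with `0 < p <= 1`.
#' @return numeric vector of variances in `[0, pi^2/6)`.
#' @export
ibs_variance_true <- function(p) {
  check_probability(p)
  dilog(1 - p)
}

#' Expected number of simulator draws per trial under IBS
#'
#' The hit count is geometric with success probability `p`, so IBS uses on
#' average `1/p` draws for a trial whose likelihood is `p`.
#'
#' @inheritParams ibs_variance_true
#' @return numeric vector `1/p`.
#' @export
ibs_expected_samples <- function(p) {
  check_probability(p)
  1 / p
}

#' Fixed-sampling estimators of log p
#'
#' With the fixed policy, exactly `M` draws are taken and the number of
#' hits `m` is a sufficient statistic for `p`.  `fixed_point_estimate()`
#' returns the regularized estimator `log((m + 1) / (M + 1))`, which is
#' finite for all `m` (including `m = 0`) but biased for every finite `M`.
#' `naive_point_estimate()` returns `log(m / M)`, which equals `-Inf`
#' whenever `m = 0` and therefore has infinite bias; it is provided only
#' as a documented reference and is never used by dataset-level code.
#'
#' @param m non-negative integer vector of hit counts, `0 <= m <= M`.
#' @param M positive integer vector of draws.
#' @return numeric vector of estimates of `log p`; `naive_point_estimate()`
#'   may contain `-Inf`.
#' @export
fixed_point_estimate <- function(m, M) {
  check_fixed_summary(m, M)
  log((m + 1) / (M + 1))
}

#' @rdname fixed_point_estimate
#' @export
naive_point_estimate <- function(m, M) {
  check_fixed_summary(m, M)
  ifelse(m == 0, -Inf, log(m / M))
}

#' Exact bias and variance of the fixed-sampling estimator
#'
#' The bias of an estimator \eqn{\hat L} of `log p` is
#' \eqn{E[\hat L] - \log p}.  For the fixed policy the distribution of the
#' hit count is Binomial(`M`, `p`), so bias and variance of
#' [fixed_point_estimate()] can be computed by exact enumeration over
#' `m = 0, ..., M`.  Binomial weights are evaluated in log space
#' ([stats::dbinom()] with `log = TRUE`) so the enumeration is stable up
#' to `M` of order 1e4.
#'
#' @param p scalar probability, `0 < p <= 1`.
#' @param M scalar positive integer number of draws.
#' @return `fixed_bias_exact()`: the scalar bias (nats), which tends to 0
#'   as `p * M` grows and diverges in magnitude as `p * M` tends to 0.
#'   `fixed_variance_exact()`: the scalar variance (nats squared).
#' @export
fixed_bias_exact <- function(p, M) {
  check_probability(p, scalar = TRUE)
  check_sample_count(M, scalar = TRUE)
  m <- 0:M
  w <- exp(dbinom(m, M, p, log = TRUE))
  sum(w * fixed_point_estimate(m, M)) - log(p)
}

#' @rdname fixed_bias_exact
#' @export
fixed_variance_exact <- function(p, M) {
  check_probability(p, scalar = TRUE)
  check_sample_count(M, scalar = TRUE)
  m <- 0:M
  w <- exp(dbinom(m, M, p, log = TRUE))
  est <- fixed_point_estimate(m, M)
  mu <- sum(w * est)
  sum(w * (est - mu)^2)
}

#' Combine independent repeats of an unbiased estimate
#'
#' `R` independent estimates with individual variances are combined by
#' averaging: the value is the mean of the values and the variance is
#' \eqn{(\sum_r v_r) / R^2}.  `combine_repeats()` folds a whole sequence;
#' `iterative_update()` absorbs one new estimate into a running
#' `(value, variance, repeats)` triple, requiring only constant storage,
#' and folding it over a sequence is algebraically identical to
#' `combine_repeats()`.
#'
#' @param values numeric vector of estimate values (length `R >= 1`).
#' @param variances numeric vector of non-negative variances, same length.
#' @return a `repeated_estimate`: list with `value`, `variance`, `repeats`.
#' @examples
#' combine_repeats(c(0, -1), c(0, 1))  # value -0.5, variance 0.25
#' @export
combine_repeats <- function(values, variances) {
  if (length(values) == 0L) stop("need at least one estimate", call. = FALSE)
  if (length(values) != length(variances) || any(variances < 0)) {
    stop("`variances` must be non-negative and match `values`", call. = FALSE)
  }
  R <- length(values)
  structure(
    list(value = mean(values), variance = sum(variances) / R^2, repeats = R),
    class = "repeated_estimate"
  )
}

#' @rdname combine_repeats
#' @param current a `repeated_estimate` (e.g. from `combine_repeats()`).
#' @param value,variance the new estimate to absorb.
#' @export
iterative_update <- function(current, value, variance) {
  stopifnot(inherits(current, "repeated_estimate"), current$repeats >= 1)
  if (variance < 0) stop("`variance` must be non-negative", call. = FALSE)
  R <- current$repeats
  structure(
    list(
      value = (R * current$value + value) / (R + 1),
      variance = (R^2 * current$variance + variance) / (R + 1)^2,
      repeats = R + 1L
    ),
    class = "repeated_estimate"
  )
}

#' @export
print.repeated_estimate <- function(x, ...) {
  cat(sprintf(
    "<repeated_estimate> value %.6g, variance %.6g, repeats %d\n",
    x$value, x$variance, x$repeats
  ))
  invisible(x)
}

# ---- argument checks ------------------------------------------------------

check_sample_count <- function(k, scalar = FALSE) {
  ok <- is.numeric(k) && length(k) >= 1 && !anyNA(k) &&
    all(k >= 1) && all(k == floor(k))
  if (scalar) ok <- ok && length(k) == 1L
  if (!ok) {
    stop("expected ", if (scalar) "a " else "", "positive integer count",
      if (!scalar) "s", " (>= 1)",
      call. = FALSE
    )
  }
  invisible(k)
}

check_probability <- function(p, scalar = FALSE) {
  ok <- is.numeric(p) && length(p) >= 1 && !anyNA(p) &&
    all(p > 0) && all(p <= 1)
  if (scalar) ok <- ok && length(p) == 1L
  if (!ok) stop("expected probabilities in (0, 1]", call. = FALSE)
  invisible(p)
}

check_fixed_summary <- function(m, M) {
  ok <- is.numeric(m) && is.numeric(M) && !anyNA(m) && !anyNA(M) &&
    all(m == floor(m)) && all(M == floor(M)) &&
    all(M >= 1) && all(m >= 0) && all(m <= M)
  if (!ok) stop("need integer hit counts with 0 <= m <= M, M >= 1", call. = FALSE)
  invisible(NULL)
}
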