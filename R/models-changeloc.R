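#' Change localization model
#'
#' An ideal-observer model of a change localization task.  On each trial
#' the observer sees 6 oriented patches, then a second display in which
#' exactly one patch (the change location `c`) has been rotated by an
#' amount drawn from a von Mises distribution with concentration
#' `kappa_s`.  The observer measures all 12 orientations with independent
#' von Mises noise of concentration `kappa` and reports the patch whose
#' two measurements differ most in absolute circular distance; with
#' probability `gamma` it guesses uniformly over the 6 patches.
#'
#' Sensory noise is parametrized as `eta = log(sigma)` with `sigma` in
#' degrees; since `kappa` lives on the radian circle,
#' `kappa = (180 / (pi * sigma))^2`, the usual Gaussian-limit
#' correspondence.  The parameter vector is `c(eta, gamma)`.
#'
#' The trial likelihood has no closed form.  Writing `f_k` for the
#' density of the circular difference of two measurements
#' ([vm_difference_density()]) and `G_k` for the CDF of the absolute
#' difference of an unchanged patch, the no-lapse probability of a
#' correct report given a true change `Delta` is the order-statistic
#' integral
#' \deqn{p_0(\Delta) = \int_{-\pi}^{\pi} f_\kappa(\delta - \Delta)\,
#'   G_\kappa(|\delta|)^5 \, d\delta,}
#' evaluated by adaptive quadrature with `G_k` precomputed on a
#' 2048-interval grid with monotone interpolation.  The full likelihood is
#' `(1-gamma) p0 + gamma/6` for the changed patch and
#' `(1-gamma)(1-p0)/5 + gamma/6` for each of the other five, so the six
#' response probabilities sum to one.
#'
#' @param eta log of the measurement noise SD in degrees.
#' @param gamma lapse rate in `(0, 1]`.
#' @name changeloc_model
NULL

#' @rdname changeloc_model
#' @export
changeloc_params <- function(eta, gamma) {
  stopifnot(is.finite(eta), gamma > 0, gamma <= 1)
  c(eta = eta, gamma = gamma)
}

# degrees <-> radian-circle concentration
kappa_from_sigma_deg <- function(sigma_deg) (180 / (pi * sigma_deg))^2
sigma_deg_from_kappa <- function(kappa) 180 / (pi * sqrt(kappa))

#' @rdname changeloc_model
#' @param n_trials number of trials (default 400).
#' @param n_patches number of patches (the likelihood machinery assumes
#'   the default 6).
#' @param kappa_s concentration of the change-magnitude distribution
#'   (default 1).
#' @export
changeloc_task <- function(n_trials = 400L, n_patches = 6L, kappa_s = 1) {
  stopifnot(n_trials >= 1, n_patches >= 2, kappa_s > 0)
  list(
    n_trials = as.integer(n_trials),
    n_patches = as.integer(n_patches), kappa_s = kappa_s
  )
}

#' @rdname changeloc_model
#' @param stimulus numeric vector of 12 orientations (degrees): the six
#'   first-display patches followed by the six second-display patches.
#' @param params named vector `c(eta, gamma)`.
#' @return `changeloc_simulate()`: one response in `1:6`.
#' @export
changeloc_simulate <- function(stimulus, params) {
  if (runif(1) < params[["gamma"]]) {
    return(sample.int(6L, 1L))
  }
  kappa <- kappa_from_sigma_deg(exp(params[["eta"]]))
  meas <- deg2rad(stimulus) + rvonmises(12L, 0, kappa)
  d <- abs(wrap_pi(meas[7:12] - meas[1:6]))
  which.max(d)
}

# one draw per stimulus record, vectorized across trials
changeloc_simulate_vec <- function(stimuli, params) {
  n <- length(stimuli)
  mat <- matrix(unlist(stimuli, use.names = FALSE), nrow = n, byrow = TRUE)
  lapse <- runif(n) < params[["gamma"]]
  kappa <- kappa_from_sigma_deg(exp(params[["eta"]]))
  noise <- matrix(rvonmises(12L * n, 0, kappa), nrow = n)
  meas <- deg2rad(mat) + noise
  d <- abs(wrap_pi(meas[, 7:12, drop = FALSE] - meas[, 1:6, drop = FALSE]))
  resp <- max.col(d, ties.method = "first")
  if (any(lapse)) resp[lapse] <- sample.int(6L, sum(lapse), replace = TRUE)
  resp
}

#' @rdname changeloc_model
#' @param cfg a [changeloc_task()] configuration.
#' @param seed integer seed; the caller's RNG state is preserved.
#' @return `changeloc_generate_dataset()`: a [trial_data()] object whose
#'   stimuli are 12-orientation records (named `s1...s12`) and whose
#'   responses are integers in `1:6`.
#' @export
changeloc_generate_dataset <- function(params, cfg = changeloc_task(),
                                       seed = 1L) {
  old <- preserve_rng()
  on.exit(restore_rng(old), add = TRUE)
  seed_rng(seed)
  stim <- vector("list", cfg$n_trials)
  resp <- integer(cfg$n_trials)
  for (i in seq_len(cfg$n_trials)) {
    o1 <- runif(cfg$n_patches, 0, 360)
    cc <- sample.int(cfg$n_patches, 1L)
    delta <- rad2deg(rvonmises(1L, 0, cfg$kappa_s))
    o2 <- o1
    o2[cc] <- (o1[cc] + delta) %% 360
    s <- c(o1, o2)
    names(s) <- paste0("s", seq_along(s))
    stim[[i]] <- s
    resp[i] <- changeloc_simulate(s, params)
  }
  trial_data(stim, resp)
}

#' @rdname changeloc_model
#' @return `changeloc_trial_info()`: list with the change location `c`
#'   and the signed change magnitude `delta` in degrees, recovered from
#'   the stimulus record (the unchanged patches are exact copies).
#' @export
changeloc_trial_info <- function(stimulus) {
  n <- length(stimulus) / 2
  o1 <- stimulus[seq_len(n)]
  o2 <- stimulus[n + seq_len(n)]
  cc <- which(o1 != o2)
  if (length(cc) != 1L) {
    stop("stimulus record must differ in exactly one patch", call. = FALSE)
  }
  list(c = cc, delta = wrap_180(o2[[cc]] - o1[[cc]]))
}

#' @rdname changeloc_model
#' @param delta signed change magnitude in degrees.
#' @param response_is_change logical: did the observer report the changed
#'   patch?
#' @return `changeloc_likelihood()`: the trial likelihood in `(0, 1)`.
#' @export
changeloc_likelihood <- function(delta, response_is_change, params) {
  p0 <- changeloc_p_correct_nolapse(delta, params)
  gamma <- params[["gamma"]]
  if (isTRUE(response_is_change)) {
    (1 - gamma) * p0 + gamma / 6
  } else {
    (1 - gamma) * (1 - p0) / 5 + gamma / 6
  }
}

# no-lapse probability that the changed patch has the largest absolute
# measured difference, by order-statistic quadrature
changeloc_p_correct_nolapse <- function(delta_deg, params) {
  kappa <- kappa_from_sigma_deg(exp(params[["eta"]]))
  G <- changeloc_abs_diff_cdf(kappa)
  d0 <- abs(wrap_pi(deg2rad(delta_deg)))
  integrand <- function(x) vm_difference_density(x - d0, kappa) * G(abs(x))^5
  # split at the density peak (x = d0) so adaptive quadrature cannot miss
  # a narrow mode at high kappa
  v <- integrate(integrand, -pi, d0, abs.tol = 1e-8, rel.tol = 1e-8,
    subdivisions = 400L
  )
  w <- integrate(integrand, d0, pi, abs.tol = 1e-8, rel.tol = 1e-8,
    subdivisions = 400L
  )
  if (v$message != "OK" || w$message != "OK") {
    stop("quadrature failed: ", v$message, " / ", w$message, call. = FALSE)
  }
  min(max(v$value + w$value, 0), 1)
}

# CDF of |X - Y| for an unchanged patch, precomputed on a fine grid with
# monotone spline interpolation, cached per kappa (likelihood calls sit
# inside optimization loops)
.changeloc_cdf_cache <- new.env(parent = emptyenv())

changeloc_abs_diff_cdf <- function(kappa, n_grid = 2048L) {
  key <- sprintf("%.15g", kappa)
  hit <- .changeloc_cdf_cache[[key]]
  if (!is.null(hit)) {
    return(hit)
  }
  t <- seq(0, pi, length.out = n_grid + 1L)
  f <- vm_difference_density(t, kappa)
  # absolute difference folds the symmetric density: density 2 f(t) on [0, pi]
  cum <- c(0, cumsum((f[-1] + f[-length(f)]) / 2 * diff(t))) * 2
  cum <- cum / cum[length(cum)] # normalize trapezoid tail error
  G <- splinefun(t, cum, method = "hyman")
  fn <- function(x) pmin(pmax(G(x), 0), 1)
  .changeloc_cdf_cache[[key]] <- fn
  fn
}

#' @rdname changeloc_model
#' @param data a [trial_data()] object from this task.
#' @return `changeloc_exact_loglik()`: the dataset log-likelihood by
#'   numerical quadrature, \eqn{\sum_i \log p_i} (nats).
#' @export
changeloc_exact_loglik <- function(data, params) {
  sum(log(changeloc_trial_probs(data, params)))
}

#' @rdname changeloc_model
#' @export
changeloc_trial_probs <- function(data, params) {
  vapply(seq_len(data$n_trials), function(i) {
    info <- changeloc_trial_info(data$stimuli[[i]])
    r <- data$responses[[i]][[1]]
    changeloc_likelihood(info$delta, r == info$c, params)
  }, numeric(1))
}
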