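#' Orientation discrimination model
#'
#' A signal-detection model of a left/right orientation discrimination
#' task.  On each trial the observer sees a patch at orientation `s`
#' (degrees from a vertical reference), makes a noisy measurement
#' `x ~ Normal(s, sigma)`, and responds 'rightward' (coded `1`) if
#' `x > mu`, 'leftward' (coded `0`) otherwise.  With probability `gamma`
#' (the lapse rate) the observer instead guesses uniformly.  The slope is
#' parametrized as `eta = log(sigma)`, so the parameter vector is
#' `c(eta, mu, gamma)` and the trial likelihood is the psychometric
#' function
#' \deqn{\Pr(r = 1 \mid s) = \gamma/2 + (1 - \gamma)\,\Phi((s - \mu)/\sigma).}
#'
#' @param eta log of the measurement noise SD (sigma in degrees).
#' @param mu response bias (degrees).
#' @param gamma lapse rate in `(0, 1]`.
#' @return `psychometric_params()`: a named numeric vector
#'   `c(eta, mu, gamma)` with validated ranges.
#' @name orientation_model
NULL

#' @rdname orientation_model
#' @export
psychometric_params <- function(eta, mu, gamma) {
  stopifnot(
    is.finite(eta), is.finite(mu),
    gamma > 0, gamma <= 1
  )
  c(eta = eta, mu = mu, gamma = gamma)
}

#' @rdname orientation_model
#' @param s stimulus orientation(s), degrees.
#' @param r response(s): `1` rightward, `0` leftward.
#' @param params named vector `c(eta, mu, gamma)`.
#' @return `orientation_likelihood()`: `Pr(r | s, params)`, vectorized
#'   over `s` and `r`.
#' @export
orientation_likelihood <- function(s, r, params) {
  stopifnot(all(r %in% c(0, 1)))
  p_right <- orientation_p_right(s, params)
  ifelse(r == 1, p_right, 1 - p_right)
}

orientation_p_right <- function(s, params) {
  sigma <- exp(params[["eta"]])
  gamma <- params[["gamma"]]
  gamma / 2 + (1 - gamma) * pnorm((s - params[["mu"]]) / sigma)
}

#' @rdname orientation_model
#' @return `orientation_simulate()`: one simulated response (`0` or `1`).
#' @export
orientation_simulate <- function(s, params) {
  if (runif(1) < params[["gamma"]]) {
    as.integer(runif(1) < 0.5)
  } else {
    x <- rnorm(1, mean = s, sd = exp(params[["eta"]]))
    as.integer(x > params[["mu"]])
  }
}

# one draw per stimulus, vectorized across trials (engine fast path)
orientation_simulate_vec <- function(stimuli, params) {
  s <- unlist(stimuli, use.names = FALSE)
  orientation_simulate_n(s, params, length(s))
}

# vectorized n-draw variant (one stimulus repeated, or one per draw)
orientation_simulate_n <- function(s, params, n) {
  lapse <- runif(n) < params[["gamma"]]
  x <- rnorm(n, mean = s, sd = exp(params[["eta"]]))
  resp <- as.integer(x > params[["mu"]])
  if (any(lapse)) resp[lapse] <- as.integer(runif(sum(lapse)) < 0.5)
  resp
}

#' @rdname orientation_model
#' @param n_trials number of trials (default 600).
#' @param stim_mean,stim_sd stimulus distribution: orientations are drawn
#'   `Normal(stim_mean, stim_sd)` degrees (defaults 0 and 3).
#' @return `orientation_task()`: task configuration list.
#' @export
orientation_task <- function(n_trials = 600L, stim_mean = 0, stim_sd = 3) {
  stopifnot(n_trials >= 1, stim_sd > 0)
  list(
    n_trials = as.integer(n_trials),
    stim_mean = stim_mean, stim_sd = stim_sd
  )
}

#' @rdname orientation_model
#' @param cfg an [orientation_task()] configuration.
#' @param seed integer seed; the caller's RNG state is preserved.
#' @return `orientation_generate_dataset()`: a [trial_data()] object with
#'   single-column numeric stimuli (degrees) and 0/1 responses.
#' @export
orientation_generate_dataset <- function(params, cfg = orientation_task(),
                                         seed = 1L) {
  old <- preserve_rng()
  on.exit(restore_rng(old), add = TRUE)
  seed_rng(seed)
  s <- rnorm(cfg$n_trials, cfg$stim_mean, cfg$stim_sd)
  r <- vapply(s, function(si) orientation_simulate(si, params), integer(1))
  trial_data(s, r)
}

#' @rdname orientation_model
#' @param data a [trial_data()] object from this task.
#' @return `orientation_exact_loglik()`: the exact dataset log-likelihood
#'   \eqn{\sum_i \log p_i} (nats); `orientation_trial_probs()`: the vector
#'   of exact per-trial likelihoods `p_i`.
#' @export
orientation_exact_loglik <- function(data, params) {
  sum(log(orientation_trial_probs(data, params)))
}

#' @rdname orientation_model
#' @export
orientation_trial_probs <- function(data, params) {
  s <- vapply(data$stimuli, function(x) x[[1]], numeric(1))
  r <- vapply(data$responses, function(x) x[[1]], numeric(1))
  orientation_likelihood(s, r, params)
}
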