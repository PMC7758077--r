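#' IBS-based estimators of entropy, cross-entropy and KL divergence
#'
#' `entropy_estimate()` draws `x` from a discrete sampler, then runs IBS
#' against `x` (sampling from the same distribution until the first match)
#' to obtain an unbiased estimate of `log Pr(x)`; the negated average over
#' repeats is an unbiased estimate of the Shannon entropy in nats.  This
#' is possible because the IBS sample size is stochastic — no fixed-size
#' sampling scheme admits an unbiased entropy estimator.
#'
#' `cross_entropy_estimate()` samples the target `x` from `sampler_p` and
#' matches with draws from `sampler_q`, estimating
#' \eqn{-\sum_x P(x)\log Q(x)}.  `kl_estimate()` is the difference of a
#' cross-entropy run and an independent entropy run, so its variance is
#' the sum of the two variances; its expectation is `KL(P || Q) >= 0`.
#'
#' Samplers are zero-argument functions returning one discrete response
#' record (they may close over a stimulus and parameters).  `Q` must give
#' nonzero probability to everything `P` can emit, otherwise only a
#' `max_samples` cap in `cfg` terminates the run.
#'
#' @param sampler,sampler_p,sampler_q zero-argument sampler functions.
#' @param cfg an [ibs_config()]; `repeats`, `max_samples` and `seed` are
#'   honoured.
#' @return list with `value`, `variance` and `repeats` (plus
#'   `capped` count when a cap triggered).
#' @export
entropy_estimate <- function(sampler, cfg = ibs_config()) {
  est <- ibs_self_match(sampler, sampler, cfg)
  list(
    value = -est$value, variance = est$variance,
    repeats = est$repeats, capped = est$capped
  )
}

#' @rdname entropy_estimate
#' @export
cross_entropy_estimate <- function(sampler_p, sampler_q, cfg = ibs_config()) {
  est <- ibs_self_match(sampler_p, sampler_q, cfg)
  list(
    value = -est$value, variance = est$variance,
    repeats = est$repeats, capped = est$capped
  )
}

#' @rdname entropy_estimate
#' @export
kl_estimate <- function(sampler_p, sampler_q, cfg = ibs_config()) {
  cross_cfg <- cfg
  cross_cfg$seed <- derive_seed(cfg$seed, 1L)
  ent_cfg <- cfg
  ent_cfg$seed <- derive_seed(cfg$seed, 2L)
  ce <- cross_entropy_estimate(sampler_p, sampler_q, cross_cfg)
  en <- entropy_estimate(sampler_p, ent_cfg)
  list(
    value = ce$value - en$value,
    variance = ce$variance + en$variance,
    repeats = cfg$repeats,
    capped = ce$capped + en$capped
  )
}

# shared core: per repeat, draw target from sampler_target, then count
# draws from sampler_match until the first exact match
ibs_self_match <- function(sampler_target, sampler_match, cfg) {
  old <- preserve_rng()
  on.exit(restore_rng(old), add = TRUE)
  set.seed(cfg$seed, kind = "L'Ecuyer-CMRG")
  values <- numeric(cfg$repeats)
  variances <- numeric(cfg$repeats)
  capped <- 0L
  for (r in seq_len(cfg$repeats)) {
    target <- canonical_key(sampler_target())
    k <- 1L
    while (!identical(canonical_key(sampler_match()), target)) {
      if (!is.null(cfg$max_samples) && k >= cfg$max_samples) {
        capped <- capped + 1L
        break
      }
      k <- k + 1L
    }
    values[r] <- ibs_point_estimate(k)
    variances[r] <- ibs_variance_estimate(k)
  }
  comb <- combine_repeats(values, variances)
  list(
    value = comb$value, variance = comb$variance,
    repeats = comb$repeats, capped = capped
  )
}

#' Approximate IBS configuration for continuous responses
#'
#' @param metric `function(a, b)` returning a non-negative distance
#'   between two responses, with `metric(r, r) = 0`.
#' @param epsilon positive tolerance: a simulator draw counts as a hit
#'   when its distance to the observed response is at most `epsilon`.
#' @param ball_volume `function(r, epsilon)` returning the positive
#'   volume of the epsilon-ball around `r` in response space (geometry is
#'   user-supplied, not derived from the metric).
#' @param cfg an [ibs_config()] with the usual estimation controls.
#' @return an `aibs_config` list.
#' @export
aibs_config <- function(metric, epsilon, ball_volume, cfg = ibs_config()) {
  stopifnot(
    is.function(metric), is.numeric(epsilon), epsilon > 0,
    is.function(ball_volume), inherits(cfg, "ibs_config")
  )
  structure(
    list(metric = metric, epsilon = epsilon, ball_volume = ball_volume,
      cfg = cfg),
    class = "aibs_config"
  )
}

#' Approximate IBS for continuous response spaces
#'
#' Runs the IBS machinery with hit test `D(r~, r_i) <= epsilon` instead
#' of exact equality, and corrects each trial estimate by
#' `- log |B_eps(r_i)|`, the log-volume of the tolerance ball.  The
#' result is an unbiased estimate of the epsilon-approximate
#' log-likelihood
#' \deqn{L_\epsilon(\theta) = \sum_i \log
#'   \frac{\Pr(D(\tilde r_i, r_i) \le \epsilon)}{|B_\epsilon(r_i)|},}
#' which tends to the smoothed (and, as `epsilon` shrinks, the true)
#' log-likelihood.  With the discrete 0/1 metric, `epsilon < 1`, and unit
#' ball volume it reduces exactly to [ibs_loglik()].
#'
#' @inheritParams ibs_loglik
#' @param acfg an [aibs_config()].
#' @return an `ibs_result` (see [ibs_loglik()]); `loglik` includes the
#'   ball-volume correction.
#' @export
aibs_loglik <- function(data, sim, params, acfg) {
  stopifnot(inherits(acfg, "aibs_config"))
  match_fn <- function(candidate, observed) {
    acfg$metric(candidate, observed) <= acfg$epsilon
  }
  res <- ibs_loglik(data, sim, params, acfg$cfg, match = match_fn)
  offset <- sum(vapply(
    data$responses,
    function(r) log(acfg$ball_volume(r, acfg$epsilon)), numeric(1)
  ))
  res$loglik <- res$loglik - offset
  res
}
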