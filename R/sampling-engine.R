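#' Estimation controls for dataset-level IBS
#'
#' @param repeats positive integer `R`: number of independent IBS repeats
#'   to average (default 1).
#' @param early_stop negative real or `NULL`: threshold `L_lower` on the
#'   running dataset log-likelihood estimate.  When, within a repeat, the
#'   total over completed trials plus the current trial's partial estimate
#'   falls below `L_lower`, estimation aborts and [ibs_loglik()] returns
#'   exactly `L_lower` with `early_stopped = TRUE` (the variance field is
#'   then flagged unreliable).  `NULL` (default) disables the check.
#' @param max_samples positive integer or `NULL`: hard cap on simulator
#'   draws per (repeat, trial).  A capped trial keeps its current count
#'   `K` (a lower bound on the true `K`), is marked incomplete, and
#'   increments `capped_trials`.  `NULL` (default) means no cap; combine
#'   with a model lapse rate or `early_stop` to avoid infinite loops.
#' @param execution `"sequential"` (trial-by-trial loop), `"batched"`
#'   (round-robin over not-yet-matched pairs), or `"vectorized"` (one
#'   vectorized simulator call per round over all not-yet-matched trials;
#'   requires the simulator to carry an `attr(sim, "simulate_vec")`
#'   variant and scalar responses).  Sequential and batched modes use
#'   independent per-(repeat, trial) random substreams derived from
#'   `seed` and return bit-identical results; vectorized mode consumes a
#'   single stream and is equivalent in distribution (every hit count is
#'   still geometric), trading the bitwise contract for large speedups
#'   inside optimization loops.
#' @param batch_size draws per active pair per round in batched mode.
#' @param seed non-negative integer root seed; every simulator draw flows
#'   from it through the substream scheme.
#' @return an `ibs_config` list.
#' @export
ibs_config <- function(repeats = 1L, early_stop = NULL, max_samples = NULL,
                       execution = c("sequential", "batched", "vectorized"),
                       batch_size = 1L, seed = 1L) {
  execution <- match.arg(execution)
  stopifnot(
    repeats >= 1, repeats == floor(repeats),
    is.null(early_stop) || (is.numeric(early_stop) && early_stop < 0),
    is.null(max_samples) || (max_samples >= 1 && max_samples == floor(max_samples)),
    batch_size >= 1, seed >= 0
  )
  structure(
    list(
      repeats = as.integer(repeats), early_stop = early_stop,
      max_samples = if (!is.null(max_samples)) as.integer(max_samples),
      execution = execution, batch_size = as.integer(batch_size),
      seed = as.integer(seed)
    ),
    class = "ibs_config"
  )
}

#' Early-stopping decision rule
#'
#' Returns `TRUE` when the running total of completed-trial estimates plus
#' the current trial's partial estimate has fallen below the threshold
#' `L_lower`.  Per-trial IBS estimates are non-positive, so once the rule
#' fires it fires for every continuation.
#'
#' @param partial_total total estimate over completed trials (<= 0).
#' @param trial_partial partial estimate for the trial in progress (<= 0).
#' @param L_lower negative threshold.
#' @return logical.
#' @export
early_stop_check <- function(partial_total, trial_partial, L_lower) {
  stopifnot(is.numeric(L_lower), L_lower < 0)
  (partial_total + trial_partial) < L_lower
}

#' Dataset log-likelihood by inverse binomial sampling
#'
#' For each repeat and trial, draws simulator responses until the first
#' exact match with the observed response, records the hit count `K`, and
#' converts counts to the unbiased dataset estimate
#' \eqn{\hat L = (1/R) \sum_r \sum_i \hat L(K_{r,i})} with variance
#' \eqn{(1/R^2) \sum_r \sum_i \hat V(K_{r,i})}.  Whenever neither early
#' stopping nor capping triggers, the expectation of `loglik` equals the
#' true total log-likelihood at `params`.
#'
#' The simulator contract is `sim(stimulus, params)` returning one
#' response record comparable to the data's responses.  If
#' `attr(sim, "uses_history")` is `TRUE` it is called as
#' `sim(stimulus, params, history)` where `history` is the list of
#' *observed* `(stimulus, response)` pairs preceding the trial, matching
#' the likelihood factorization that conditions each trial on the data's
#' past.  All randomness is drawn from per-(repeat, trial) L'Ecuyer-CMRG
#' substreams derived from `cfg$seed`; the caller's RNG state is left
#' untouched.
#'
#' @param data a [trial_data()] object.
#' @param sim simulator function (see Details).
#' @param params parameter vector passed through to `sim`.
#' @param cfg an [ibs_config()].
#' @param match optional predicate `function(candidate, observed)` used
#'   instead of exact canonical equality (used by [aibs_loglik()]).
#' @return an `ibs_result`: list with `loglik`, `variance`,
#'   `sample_counts` (`R x N` integer matrix), `completed` (logical
#'   matrix, `FALSE` for capped or unstarted pairs), `total_samples`,
#'   `early_stopped`, `capped_trials`, `variance_reliable`, `repeats`.
#' @export
ibs_loglik <- function(data, sim, params, cfg = ibs_config(), match = NULL) {
  stopifnot(inherits(data, "trial_data"), inherits(cfg, "ibs_config"))
  N <- data$n_trials
  R <- cfg$repeats
  uses_history <- isTRUE(attr(sim, "uses_history"))
  histories <- if (uses_history) observed_histories(data)

  old <- preserve_rng()
  on.exit(restore_rng(old), add = TRUE)

  K <- matrix(1L, nrow = R, ncol = N)
  completed <- matrix(FALSE, nrow = R, ncol = N)
  early_stopped <- FALSE

  # scalar responses admit a fast equality path that skips serialization
  scalar_resp <- is.null(match) &&
    all(lengths(data$responses) == 1L) &&
    all(vapply(data$responses, is.atomic, logical(1)))
  resp_scalar <- if (scalar_resp) {
    vapply(data$responses, function(x) x[[1]], data$responses[[1]][[1]])
  }

  draw_once <- function(i) {
    out <- if (uses_history) {
      sim(data$stimuli[[i]], params, histories[[i]])
    } else {
      sim(data$stimuli[[i]], params)
    }
    if (scalar_resp) {
      isTRUE(out == resp_scalar[i])
    } else if (is.null(match)) {
      identical(canonical_key(out), data$response_keys[[i]])
    } else {
      isTRUE(match(out, data$responses[[i]]))
    }
  }

  if (cfg$execution == "vectorized") {
    sim_vec <- attr(sim, "simulate_vec")
    if (is.null(sim_vec)) {
      stop("vectorized execution requires attr(sim, \"simulate_vec\")",
        call. = FALSE
      )
    }
    if (!scalar_resp) {
      stop("vectorized execution requires scalar responses", call. = FALSE)
    }
    set.seed(cfg$seed, kind = "L'Ecuyer-CMRG")
    for (r in seq_len(R)) {
      active <- seq_len(N)
      repeat {
        draws <- sim_vec(data$stimuli[active], params)
        hit <- draws == resp_scalar[active]
        completed[r, active[hit]] <- TRUE
        still <- active[!hit]
        if (!is.null(cfg$max_samples)) {
          still <- still[K[r, still] < cfg$max_samples]
        }
        K[r, still] <- K[r, still] + 1L
        active <- still
        if (length(active) == 0L) break
        if (!is.null(cfg$early_stop) &&
          sum(digamma(1) - digamma(K[r, ])) < cfg$early_stop) {
          early_stopped <- TRUE
          break
        }
      }
      if (early_stopped) break
    }
  } else if (cfg$execution == "sequential") {
    streams <- pair_streams(cfg$seed, R * N)
    for (r in seq_len(R)) {
      running <- 0
      for (i in seq_len(N)) {
        assign(".Random.seed", streams[[(r - 1L) * N + i]], envir = globalenv())
        k <- 1L
        partial <- 0 # -sum_{j=1}^{k-1} 1/j, updated incrementally
        repeat {
          if (draw_once(i)) {
            completed[r, i] <- TRUE
            break
          }
          if (!is.null(cfg$max_samples) && k >= cfg$max_samples) break
          partial <- partial - 1 / k
          k <- k + 1L
          if (!is.null(cfg$early_stop) &&
            (running + partial) < cfg$early_stop) {
            early_stopped <- TRUE
            break
          }
        }
        K[r, i] <- k
        if (early_stopped) break
        running <- running + partial
      }
      if (early_stopped) break
    }
  } else {
    # batched: one round of draws for every not-yet-matched pair; per-pair
    # substreams make the counts bit-identical to sequential mode
    streams <- pair_streams(cfg$seed, R * N)
    for (r in seq_len(R)) {
      state <- streams[(r - 1L) * N + seq_len(N)]
      active <- rep(TRUE, N)
      while (any(active)) {
        for (i in which(active)) {
          assign(".Random.seed", state[[i]], envir = globalenv())
          for (b in seq_len(cfg$batch_size)) {
            if (draw_once(i)) {
              completed[r, i] <- TRUE
              active[i] <- FALSE
              break
            }
            if (!is.null(cfg$max_samples) && K[r, i] >= cfg$max_samples) {
              active[i] <- FALSE
              break
            }
            K[r, i] <- K[r, i] + 1L
          }
          state[[i]] <- get(".Random.seed", envir = globalenv())
        }
        if (!is.null(cfg$early_stop)) {
          # running total uses current (partial or final) counts
          total <- sum(ibs_point_estimate(K[r, ]))
          if (total < cfg$early_stop) {
            early_stopped <- TRUE
            break
          }
        }
      }
      if (early_stopped) break
    }
  }

  capped_trials <- if (is.null(cfg$max_samples)) {
    0L
  } else {
    sum(!completed & K >= cfg$max_samples)
  }
  if (capped_trials > 0L) {
    warning(sprintf(
      "%d (repeat, trial) pair(s) hit max_samples = %d; their K is a lower bound",
      capped_trials, cfg$max_samples
    ), call. = FALSE)
  }

  per_repeat_value <- rowSums(matrix(ibs_point_estimate(K), nrow = R))
  per_repeat_var <- rowSums(matrix(ibs_variance_estimate(K), nrow = R))
  comb <- combine_repeats(per_repeat_value, per_repeat_var)

  structure(
    list(
      loglik = if (early_stopped) cfg$early_stop else comb$value,
      variance = comb$variance,
      variance_reliable = !early_stopped && capped_trials == 0L,
      sample_counts = K,
      completed = completed,
      total_samples = sum(K),
      early_stopped = early_stopped,
      capped_trials = capped_trials,
      repeats = R,
      seed = cfg$seed
    ),
    class = "ibs_result"
  )
}

#' @export
print.ibs_result <- function(x, ...) {
  cat(sprintf(
    "<ibs_result> loglik %.4f (variance %.4f%s), R = %d, total samples %d%s%s\n",
    x$loglik, x$variance,
    if (x$variance_reliable) "" else ", unreliable",
    x$repeats, x$total_samples,
    if (x$early_stopped) ", early-stopped" else "",
    if (x$capped_trials > 0) sprintf(", %d capped", x$capped_trials) else ""
  ))
  invisible(x)
}

#' Dataset log-likelihood by fixed sampling
#'
#' For every trial draws exactly `M` simulator responses, counts the hits
#' `m_i`, and returns \eqn{\sum_i \log((m_i + 1) / (M + 1))} — the
#' regularized fixed-sampling estimate, which is finite but biased.  Total
#' simulator calls are exactly `N * M`.  If the simulator carries a
#' vectorized variant (`attr(sim, "simulate_vec")` across trials, or
#' `attr(sim, "simulate_n")` for repeated draws at one stimulus) it is
#' used for speed; the vectorized and scalar paths agree in distribution
#' but consume the random stream differently.
#'
#' @inheritParams ibs_loglik
#' @param M positive integer draws per trial.
#' @param seed integer seed.
#' @return list with `loglik`, `hits` (per-trial hit counts), `M`,
#'   `total_samples`.
#' @export
fixed_loglik <- function(data, sim, params, M, seed = 1L) {
  stopifnot(inherits(data, "trial_data"), M >= 1, M == floor(M))
  M <- as.integer(M)
  old <- preserve_rng()
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed, kind = "L'Ecuyer-CMRG")
  sim_vec <- attr(sim, "simulate_vec")
  sim_n <- attr(sim, "simulate_n")
  N <- data$n_trials
  scalar_resp <- all(lengths(data$responses) == 1L) &&
    all(vapply(data$responses, is.atomic, logical(1)))
  if (!is.null(sim_vec) && scalar_resp) {
    # all N * M draws in one vectorized call
    idx <- rep(seq_len(N), each = M)
    draws <- sim_vec(data$stimuli[idx], params)
    resp <- vapply(data$responses, function(x) x[[1]], data$responses[[1]][[1]])
    hits <- as.integer(rowsum(as.numeric(draws == resp[idx]), idx)[, 1])
  } else {
    hits <- integer(N)
    for (i in seq_len(N)) {
      draws <- if (!is.null(sim_n)) {
        sim_n(data$stimuli[[i]], params, M)
      } else {
        replicate(M, sim(data$stimuli[[i]], params), simplify = FALSE)
      }
      keys <- vapply(draws, canonical_key, character(1))
      hits[i] <- sum(keys == data$response_keys[[i]])
    }
  }
  list(
    loglik = sum(fixed_point_estimate(hits, M)),
    hits = hits, M = M, total_samples = data$n_trials * M
  )
}

# ---- RNG plumbing ---------------------------------------------------------

preserve_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# independent L'Ecuyer-CMRG substreams, one per (repeat, trial) pair,
# derived deterministically from the root seed
pair_streams <- function(seed, n) {
  set.seed(seed, kind = "L'Ecuyer-CMRG")
  s <- get(".Random.seed", envir = globalenv())
  out <- vector("list", n)
  for (j in seq_len(n)) {
    s <- parallel::nextRNGStream(s)
    out[[j]] <- s
  }
  out
}

# observed (stimulus, response) pairs preceding each trial
observed_histories <- function(data) {
  lapply(seq_len(data$n_trials), function(i) {
    if (i == 1L) {
      list()
    } else {
      lapply(seq_len(i - 1L), function(j) {
        list(stimulus = data$stimuli[[j]], response = data$responses[[j]])
      })
    }
  })
}
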