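#' Maximum-likelihood fitting with a noisy or exact objective
#'
#' Maximizes a dataset log-likelihood over a bounded parameter space for
#' one of three estimator arms:
#' * `list(type = "ibs", repeats = R)` — IBS estimate with `R` repeats;
#' * `list(type = "fixed", M = M)` — fixed sampling with `M` draws/trial;
#' * `list(type = "exact")` — the model's exact/numerical likelihood.
#'
#' Parameters are mapped to an unconstrained scale by a logit transform
#' of their bounds and `n_screen` random points are scored first.  The
#' exact arm then runs a plain Nelder-Mead multistart.  Sampling arms
#' face a noisy objective, which direct search cannot handle naively, so
#' the search alternates two noise-aware devices: (1) Nelder-Mead on
#' *common-random-numbers* realizations — with the estimation seed
#' frozen, the objective is deterministic (and unbiased pointwise), but
#' each frozen realization carries noise-induced local maxima, so the
#' search is restarted under `n_crn` independent realizations and a move
#' is accepted only if it wins a comparison averaged over `n_avg` fresh
#' evaluations; (2) a stochastic trust-region stage ("polish" options),
#' which fits local quadratic response surfaces to re-randomized
#' evaluations around the incumbent and takes eigenvalue-floored Newton
#' steps, with growing design sizes so gradient precision improves as
#' the incumbent converges.  An early-stopping floor `L_lower`
#' (default twice the uniform-guessing log-likelihood) aborts hopeless
#' parameter vectors cheaply throughout.
#'
#' Because the optimizer returns the best *seen* value, which is biased
#' upward, sampling arms re-estimate the log-likelihood at the solution
#' with fresh randomness and `refit_factor` times the fitting repeats,
#' giving an unbiased final value with its variance.
#'
#' @param data a [trial_data()] object.
#' @param model a registered model name (see [register_model()]) or a
#'   model entry list.
#' @param arm estimator arm specification (see Details).
#' @param opts optimizer options: `n_screen` (default 48), `n_starts`
#'   (default 3), `maxit` Nelder-Mead iterations per start (default 150),
#'   `refit_factor` (default 10), `early_stop_mult` multiple of the
#'   uniform-guessing log-likelihood used as floor (default 2; `NULL`
#'   disables early stopping), `n_crn` refinement CRN restarts (default
#'   2), `n_avg`
#'   fresh evaluations per comparison (default 8), and the polish stage's
#'   `polish_rounds` (default 10; 0 disables), `polish_design` (default
#'   32 new points per round; all rounds' evaluations are pooled) and
#'   `polish_radius` (default 0.5 on the unconstrained scale, held
#'   fixed).
#' @param seed integer seed governing screening points, common random
#'   numbers and the final re-estimate.
#' @return list with `theta` (named vector), `loglik` and `variance`
#'   (final unbiased re-estimate; variance 0 for the exact arm), `arm`,
#'   `n_evals`, `avg_samples_per_trial` (sampling arms; simulator draws
#'   per trial averaged over all objective evaluations), `converged`.
#' @export
mle_fit <- function(data, model, arm = list(type = "exact"),
                    opts = list(), seed = 1L) {
  model <- resolve_model(model)
  o <- modifyList(
    list(
      n_screen = 48L, n_starts = 3L, maxit = 150L,
      refit_factor = 10L, early_stop_mult = 2
    ),
    opts
  )
  lower <- model$lower
  upper <- model$upper
  pn <- model$param_names
  N <- data$n_trials
  sim <- model_simulator(model)
  exec_mode <- if (is.null(attr(sim, "simulate_vec"))) {
    "sequential"
  } else {
    "vectorized"
  }

  floor_ll <- if (!is.null(o$early_stop_mult)) {
    -abs(o$early_stop_mult) * N * log(model$response_space_size)
  }

  eval_env <- new.env(parent = emptyenv())
  eval_env$n_evals <- 0L
  eval_env$total_samples <- 0

  crn_seed <- derive_seed(seed, 101L)
  # eval_seed = NULL: common random numbers (frozen realization, used by
  # the direct-search stage); an integer re-randomizes the estimate (used
  # by the surrogate polish stage, whose regression averages the noise out)
  objective <- switch(arm$type,
    exact = function(theta, eval_seed = NULL) model$exact_loglik(data, theta),
    ibs = function(theta, eval_seed = NULL) {
      cfg <- ibs_config(
        repeats = arm$repeats %||% 1L, seed = eval_seed %||% crn_seed,
        early_stop = floor_ll, execution = exec_mode
      )
      res <- ibs_loglik(data, sim, theta, cfg)
      eval_env$total_samples <- eval_env$total_samples + res$total_samples
      res$loglik
    },
    fixed = function(theta, eval_seed = NULL) {
      res <- fixed_loglik(data, sim, theta,
        M = arm$M,
        seed = eval_seed %||% crn_seed
      )
      eval_env$total_samples <- eval_env$total_samples + res$total_samples
      res$loglik
    },
    stop("unknown arm type '", arm$type, "'", call. = FALSE)
  )
  obj_raw <- function(u, eval_seed = NULL) {
    eval_env$n_evals <- eval_env$n_evals + 1L
    theta <- from_unconstrained(u, lower, upper)
    names(theta) <- pn
    val <- objective(theta, eval_seed)
    if (!is.finite(val)) val <- -1e10
    val
  }
  obj_u <- function(u) -obj_raw(u) # optim minimizes, CRN realization

  old <- preserve_rng()
  on.exit(restore_rng(old), add = TRUE)
  seed_rng(derive_seed(seed, 7L))
  D <- length(pn)
  screen <- matrix(runif(o$n_screen * D), ncol = D)
  # keep screening points in the interior of the box
  screen <- 0.02 + 0.96 * screen
  screen_u <- t(apply(screen, 1, function(q) stats::qlogis(q)))
  scores <- apply(screen_u, 1, obj_u)
  ord <- order(scores)
  starts <- screen_u[ord[seq_len(min(o$n_starts, nrow(screen_u)))], ,
    drop = FALSE
  ]

  converged <- FALSE
  failed <- FALSE
  if (arm$type == "exact") {
    # deterministic objective: plain Nelder-Mead multistart
    best <- NULL
    for (j in seq_len(nrow(starts))) {
      fit <- tryCatch(
        optim(starts[j, ], obj_u,
          method = "Nelder-Mead",
          control = list(maxit = o$maxit, reltol = 1e-7)
        ),
        error = function(e) NULL
      )
      if (is.null(fit)) next
      if (is.null(best) || fit$value < best$value) best <- fit
      if (fit$convergence == 0) converged <- TRUE
    }
    if (is.null(best)) {
      failed <- TRUE
    } else {
      u_hat <- best$par
    }
  } else {
    # Stochastic objective.  A single frozen-CRN realization has local
    # maxima of its own (amplitude = the estimator SD), so run Nelder-Mead
    # under several independent CRN realizations — spurious maxima do not
    # persist across realizations — accepting each move only if it wins an
    # averaged fresh-randomness comparison, then refine with local
    # quadratic response surfaces that regress the noise away.
    n_avg <- o$n_avg %||% 8L
    avg_counter <- new.env(parent = emptyenv())
    avg_counter$k <- 0L
    avg_eval <- function(u) {
      mean(vapply(seq_len(n_avg), function(i) {
        avg_counter$k <- avg_counter$k + 1L
        obj_raw(u, derive_seed(seed, 5000L + avg_counter$k))
      }, numeric(1)))
    }
    run_nm <- function(u_start, crn_k) {
      tryCatch(
        optim(u_start, function(u) -obj_raw(u, crn_k),
          method = "Nelder-Mead",
          control = list(maxit = o$maxit, reltol = 1e-7)
        ),
        error = function(e) NULL
      )
    }
    # explore: one NM run per screening start, each under its own CRN
    # realization; candidates are compared on averaged fresh evaluations
    u_cur <- starts[1, ]
    val_cur <- -Inf
    for (j in seq_len(nrow(starts))) {
      fit <- run_nm(starts[j, ], derive_seed(seed, 100L + j))
      if (is.null(fit)) next
      if (fit$convergence == 0) converged <- TRUE
      val_new <- avg_eval(fit$par)
      if (val_new > val_cur) {
        u_cur <- fit$par
        val_cur <- val_new
      }
    }
    # refine: extra NM restarts from the winner under fresh realizations
    for (k in seq_len(o$n_crn %||% 2L)) {
      fit <- run_nm(u_cur, derive_seed(seed, 150L + k))
      if (is.null(fit)) next
      val_new <- avg_eval(fit$par)
      if (val_new > val_cur) {
        u_cur <- fit$par
        val_cur <- val_new
      }
    }
    if ((o$polish_rounds %||% 8L) > 0L) {
      u_cur <- polish_surrogate(
        obj_raw, u_cur,
        rounds = o$polish_rounds %||% 10L,
        n_design = o$polish_design %||% 32L,
        radius = o$polish_radius %||% 0.5,
        seed = derive_seed(seed, 303L)
      )
    }
    u_hat <- u_cur
  }
  if (failed) {
    return(list(
      theta = NULL, loglik = NA_real_, variance = NA_real_, arm = arm,
      n_evals = eval_env$n_evals, avg_samples_per_trial = NA_real_,
      converged = FALSE, failed = TRUE
    ))
  }
  theta_hat <- from_unconstrained(u_hat, lower, upper)
  names(theta_hat) <- pn

  # unbiased re-estimate at the solution (fresh randomness)
  final_seed <- derive_seed(seed, 202L)
  final <- switch(arm$type,
    exact = list(loglik = -best$value, variance = 0),
    ibs = {
      cfg <- ibs_config(
        repeats = (arm$repeats %||% 1L) * o$refit_factor,
        seed = final_seed, execution = exec_mode
      )
      res <- ibs_loglik(data, sim, theta_hat, cfg)
      list(loglik = res$loglik, variance = res$variance)
    },
    fixed = {
      res <- fixed_loglik(data, sim, theta_hat, M = arm$M, seed = final_seed)
      list(loglik = res$loglik, variance = NA_real_)
    }
  )

  list(
    theta = theta_hat,
    loglik = final$loglik,
    variance = final$variance,
    arm = arm,
    n_evals = eval_env$n_evals,
    avg_samples_per_trial = if (arm$type == "exact") {
      NA_real_
    } else {
      eval_env$total_samples / (eval_env$n_evals * N)
    },
    converged = converged,
    failed = FALSE
  )
}

resolve_model <- function(model) {
  if (is.character(model)) get_model(model) else model
}

# Stochastic trust-region optimization by local quadratic response
# surfaces.  Each round draws a Gaussian design around the incumbent,
# evaluates every point with independent randomness, fits a full
# quadratic by least squares, and takes a Newton-type step with the
# fitted Hessian's eigenvalues floored away from zero (so flat or
# indefinite fits still yield a bounded ascent step, capped at 1.5x the
# trust radius).  The radius stays fixed — shrinking it would make the
# curvature estimate *noisier* (its SE scales as 1/radius^2) — and the
# design grows over rounds instead, so gradient precision improves as the
# incumbent converges.  Noisy point-wise accept/reject is avoided
# (selecting the max of noisy values is biased upward by the selection);
# a per-round guard only vetoes steps that look clearly worse, and a
# final heavily averaged comparison protects against a runaway surrogate.
polish_surrogate <- function(obj_raw, u0, rounds = 10L, n_design = 32L,
                             radius = 0.5, seed = 1L) {
  D <- length(u0)
  counter <- new.env(parent = emptyenv())
  counter$k <- 0L
  pool_u <- matrix(numeric(0), ncol = D)
  pool_y <- numeric(0)
  fresh <- function(u) {
    counter$k <- counter$k + 1L
    y <- obj_raw(u, derive_seed(seed, counter$k))
    pool_u <<- rbind(pool_u, as.numeric(u))
    pool_y <<- c(pool_y, y)
    y
  }
  avg <- function(u, n) mean(vapply(seq_len(n), function(i) fresh(u), numeric(1)))
  old <- preserve_rng()
  on.exit(restore_rng(old), add = TRUE)
  seed_rng(derive_seed(seed, 999L))
  u_start <- u0
  for (round in seq_len(rounds)) {
    Z <- matrix(rnorm(n_design * D, 0, radius), n_design, D)
    for (j in seq_len(n_design)) fresh(u0 + Z[j, ])
    fresh(u0)
    # locally weighted quadratic on the whole evaluation pool: every
    # evaluation ever made keeps informing the surrogate, so precision
    # near the optimum grows as the search settles
    Zc <- sweep(pool_u, 2, u0)
    d2 <- rowSums(Zc^2)
    w <- exp(-0.5 * d2 / radius^2)
    keep <- w > 0.02
    if (sum(keep) < 3 * quad_terms(D)) next
    sw <- sqrt(w[keep])
    X <- quad_design(Zc[keep, , drop = FALSE]) * sw
    beta <- tryCatch(qr.coef(qr(X), pool_y[keep] * sw), error = function(e) NULL)
    if (is.null(beta) || anyNA(beta)) next
    gh <- quad_grad_hess(beta, D)
    eg <- eigen(gh$H, symmetric = TRUE)
    # floor eigenvalues at a negative value: Newton step on the concave
    # part, steepest-ascent-like in flat/indefinite directions
    floor_ev <- -pmax(abs(eg$values), 0.05 * max(abs(eg$values)), 1e-3)
    step <- -eg$vectors %*% ((t(eg$vectors) %*% gh$g) / floor_ev)
    len <- sqrt(sum(step^2))
    cap <- 1.5 * radius
    if (len > cap) step <- step * (cap / len)
    cand <- u0 + as.numeric(step)
    # veto only clear regressions; symmetric accept/reject on noisy
    # values would inject selection noise
    if (avg(cand, 6L) > avg(u0, 6L) - 3) u0 <- cand
  }
  if (avg(u0, 24L) >= avg(u_start, 24L)) u0 else u_start
}

quad_terms <- function(D) 1L + 2L * D + D * (D - 1L) %/% 2L

# full quadratic design matrix: intercept, linear, squares, interactions
quad_design <- function(U) {
  D <- ncol(U)
  cols <- list(rep(1, nrow(U)), U, U^2)
  if (D > 1) {
    for (a in seq_len(D - 1)) {
      for (b in seq((a + 1), D)) {
        cols[[length(cols) + 1L]] <- U[, a] * U[, b]
      }
    }
  }
  do.call(cbind, cols)
}

# gradient and Hessian (at the origin) of the fitted quadratic
quad_grad_hess <- function(beta, D) {
  g <- beta[1 + seq_len(D)]
  H <- diag(2 * beta[1 + D + seq_len(D)], D)
  idx <- 1 + 2 * D
  if (D > 1) {
    for (a in seq_len(D - 1)) {
      for (b in seq((a + 1), D)) {
        idx <- idx + 1L
        H[a, b] <- H[b, a] <- beta[idx]
      }
    }
  }
  list(g = g, H = H)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# scaled-logit bijection between the bounded box and R^D
from_unconstrained <- function(u, lower, upper) {
  lower + (upper - lower) * stats::plogis(u)
}

to_unconstrained <- function(theta, lower, upper) {
  q <- (theta - lower) / (upper - lower)
  stats::qlogis(pmin(pmax(q, 1e-10), 1 - 1e-10))
}
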