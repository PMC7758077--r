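#' Calibration study of the IBS estimator (z-score normality)
#'
#' For each of `n_datasets` synthetic orientation-discrimination
#' datasets, runs IBS (one repeat) at the true generating parameters and
#' records three z-scores per dataset, exploiting that the exact trial
#' likelihoods `p_i` are available:
#' * `z_K` — total sample count, centred on \eqn{\sum_i 1/p_i} and scaled
#'   by \eqn{\sqrt{\sum_i (1 - p_i)/p_i^2}} (geometric mean/variance);
#' * `z_L_exact` — the IBS estimate, centred on \eqn{\sum_i \log p_i} and
#'   scaled by the exact estimator SD \eqn{\sqrt{\sum_i Li_2(1 - p_i)}};
#' * `z_L_est` — the same numerator scaled by the square root of the
#'   trigamma-based variance *estimate* reported by [ibs_loglik()].
#'
#' If the estimator is unbiased, Gaussian and its variance estimate
#' calibrated, all three are standard normal across datasets; the summary
#' reports mean, SD, skewness, and the coverage of the +/-1 and +/-2
#' credible intervals against `pnorm(1) - pnorm(-1)` etc.  Datasets with
#' zero estimator variance (every `p_i = 1`) admit no z-score and are
#' excluded with a diagnostic count.
#'
#' @param params true generating parameters (default
#'   `psychometric_params(log(2), 0.1, 0.1)`, the package's reference
#'   setting).
#' @param n_datasets number of synthetic datasets.
#' @param task an [orientation_task()] configuration.
#' @param seed root seed; dataset `d` uses seeds derived from it.
#' @return list with `records` (data frame of the three z-scores),
#'   `summary` (per-z mean/sd/skewness and coverage), `n_excluded`.
#' @export
calibration_experiment <- function(params = psychometric_params(log(2), 0.1, 0.1),
                                   n_datasets = 100L,
                                   task = orientation_task(),
                                   seed = 1L) {
  zk <- zle <- zlv <- rep(NA_real_, n_datasets)
  n_excluded <- 0L
  for (d in seq_len(n_datasets)) {
    data <- orientation_generate_dataset(params, task,
      seed = derive_seed(seed, 2L * d)
    )
    p <- orientation_trial_probs(data, params)
    var_L <- sum(ibs_variance_true(p))
    var_K <- sum((1 - p) / p^2)
    if (var_L <= 0 || var_K <= 0) {
      n_excluded <- n_excluded + 1L
      next
    }
    res <- ibs_loglik(
      data, model_simulator(get_model("orientation")), params,
      ibs_config(
        repeats = 1L, seed = derive_seed(seed, 2L * d + 1L),
        execution = "vectorized"
      )
    )
    L_true <- sum(log(p))
    zk[d] <- (res$total_samples - sum(1 / p)) / sqrt(var_K)
    zle[d] <- (res$loglik - L_true) / sqrt(var_L)
    zlv[d] <- (res$loglik - L_true) / sqrt(res$variance)
  }
  records <- data.frame(z_K = zk, z_L_exact = zle, z_L_est = zlv)
  records <- records[stats::complete.cases(records), , drop = FALSE]
  summarize_z <- function(z) {
    list(
      mean = mean(z), sd = sd(z), skewness = sample_skewness(z),
      coverage_1 = mean(abs(z) <= 1), coverage_2 = mean(abs(z) <= 2)
    )
  }
  list(
    records = records,
    summary = lapply(records, summarize_z),
    expected_coverage = c(
      coverage_1 = pnorm(1) - pnorm(-1),
      coverage_2 = pnorm(2) - pnorm(-2)
    ),
    n_excluded = n_excluded
  )
}

#' Parameter-recovery experiment configuration
#'
#' @param model registered model name.
#' @param settings data frame of true parameter settings (one row per
#'   setting, columns = the model's parameter names).  Default: `n_settings`
#'   rows drawn uniformly from a plausible sub-box of the model's bounds.
#' @param n_settings number of default settings to draw (ignored when
#'   `settings` is supplied).  Desk-scale default 4; full-scale studies of this kind
#'   use `40 * D` settings.
#' @param datasets_per_setting synthetic datasets per setting (desk-scale
#'   default 20; full-scale studies use 100).
#' @param arms list of estimator arms as in [mle_fit()].
#' @param task task configuration (default: the model's default task).
#' @param opts optimizer options passed to [mle_fit()].
#' @param seed root seed.
#' @return a `recovery_config` list.
#' @export
recovery_config <- function(model, settings = NULL, n_settings = 4L,
                            datasets_per_setting = 20L,
                            arms = list(list(type = "ibs", repeats = 1L)),
                            task = NULL, opts = list(), seed = 1L) {
  entry <- get_model(model)
  if (is.null(settings)) {
    old <- preserve_rng()
    on.exit(restore_rng(old), add = TRUE)
    seed_rng(derive_seed(seed, 55L))
    box <- plausible_box(entry)
    settings <- as.data.frame(lapply(seq_along(entry$param_names), function(j) {
      runif(n_settings, box$lower[j], box$upper[j])
    }))
    names(settings) <- entry$param_names
  }
  stopifnot(datasets_per_setting >= 1, length(arms) >= 1)
  structure(
    list(
      model = model, settings = settings,
      datasets_per_setting = as.integer(datasets_per_setting),
      arms = arms, task = task %||% entry$default_task(),
      opts = opts, seed = as.integer(seed)
    ),
    class = "recovery_config"
  )
}

# interior sub-box of the default bounds used for drawing true settings
plausible_box <- function(entry) {
  lo <- entry$lower
  hi <- entry$upper
  list(lower = lo + 0.25 * (hi - lo), upper = hi - 0.25 * (hi - lo))
}

#' Parameter-recovery experiment
#'
#' Loops over true-parameter settings, synthetic datasets and estimator
#' arms; fits each dataset with each arm by [mle_fit()]; and reports one
#' record per (setting, dataset, arm) plus per-arm RMSE and bias
#' summaries for every parameter.  Individual fit failures are flagged
#' and excluded from the summaries with a count.
#'
#' @param cfg a [recovery_config()].
#' @return list with `records` (tidy data frame: setting, dataset, arm
#'   label, `true_*` and `hat_*` parameter columns, `loglik`,
#'   `avg_samples_per_trial`, `failed`), `summary` (data frame of RMSE
#'   and bias per arm and parameter), `n_failed`.
#' @export
recovery_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "recovery_config"))
  entry <- get_model(cfg$model)
  pn <- entry$param_names
  rows <- list()
  for (s in seq_len(nrow(cfg$settings))) {
    theta_true <- as.numeric(cfg$settings[s, pn])
    names(theta_true) <- pn
    for (d in seq_len(cfg$datasets_per_setting)) {
      data_seed <- derive_seed(cfg$seed, s * 1000L + d)
      data <- entry$generate(theta_true, cfg$task, seed = data_seed)
      for (a in seq_along(cfg$arms)) {
        arm <- cfg$arms[[a]]
        fit <- tryCatch(
          mle_fit(data, entry,
            arm = arm, opts = cfg$opts,
            seed = derive_seed(cfg$seed, s * 100000L + d * 100L + a)
          ),
          error = function(e) list(failed = TRUE, theta = NULL)
        )
        failed <- isTRUE(fit$failed)
        row <- data.frame(
          model = cfg$model, setting = s, dataset = d,
          arm = arm_label(arm), failed = failed,
          loglik = if (failed) NA_real_ else fit$loglik,
          avg_samples_per_trial = if (failed) NA_real_ else fit$avg_samples_per_trial
        )
        for (p in pn) {
          row[[paste0("true_", p)]] <- theta_true[[p]]
          row[[paste0("hat_", p)]] <- if (failed) NA_real_ else fit$theta[[p]]
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  records <- do.call(rbind, rows)
  ok <- records[!records$failed, , drop = FALSE]
  summ <- do.call(rbind, lapply(split(ok, ok$arm), function(g) {
    do.call(rbind, lapply(pn, function(p) {
      err <- g[[paste0("hat_", p)]] - g[[paste0("true_", p)]]
      data.frame(
        arm = g$arm[1], parameter = p,
        rmse = sqrt(mean(err^2)), bias = mean(err),
        avg_samples_per_trial = mean(g$avg_samples_per_trial),
        n = nrow(g)
      )
    }))
  }))
  rownames(summ) <- NULL
  list(records = records, summary = summ, n_failed = sum(records$failed))
}

arm_label <- function(arm) {
  switch(arm$type,
    exact = "exact",
    ibs = sprintf("ibs_R%d", arm$repeats %||% 1L),
    fixed = sprintf("fixed_M%d", arm$M)
  )
}

#' Log-likelihood loss of a fitted solution
#'
#' The loss of a candidate solution `theta_hat` is the exact
#' log-likelihood at the best solution found by a multistart
#' exact-likelihood reference fit, minus the exact log-likelihood at
#' `theta_hat`.  A model-comparison-relevant loss is anything much above
#' one nat.  Negative values (the candidate beat the reference) are
#' clipped to zero with a diagnostic attribute.
#'
#' @param data a [trial_data()] object.
#' @param model registered model name or entry with an `exact_loglik`.
#' @param theta_hat named parameter vector to score.
#' @param n_starts number of reference multistart Nelder-Mead runs
#'   (default 10).
#' @param seed seed for the reference fit.
#' @return non-negative scalar loss in nats, with attributes
#'   `theta_ref` and `clipped`.
#' @export
loglik_loss <- function(data, model, theta_hat, n_starts = 10L, seed = 1L) {
  model <- resolve_model(model)
  ref <- mle_fit(data, model,
    arm = list(type = "exact"),
    opts = list(n_screen = max(4L * n_starts, 20L), n_starts = n_starts,
      maxit = 400L),
    seed = seed
  )
  l_ref <- model$exact_loglik(data, ref$theta)
  l_hat <- model$exact_loglik(data, theta_hat)
  loss <- l_ref - l_hat
  clipped <- loss < 0
  structure(max(loss, 0), theta_ref = ref$theta, clipped = clipped)
}
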