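test_that("a simulator that always reproduces the data gives loglik 0 with all K = 1", {
  d <- unit_data(10)
  res <- ibs_loglik(d, always_match_sim, NULL, ibs_config(seed = 3))
  expect_identical(res$loglik, 0)
  expect_identical(res$variance, 0)
  expect_true(all(res$sample_counts == 1L))
  expect_identical(res$total_samples, 10L)
  expect_false(res$early_stopped)
  expect_identical(res$capped_trials, 0L)
})

test_that("hit counts follow the geometric law (chi-square goodness of fit)", {
  p <- 0.3
  n <- 2e4
  for (mode in c("sequential", "batched")) {
    res <- ibs_loglik(
      unit_data(n), bernoulli_sim, c(p = p),
      ibs_config(seed = 7, execution = mode)
    )
    k <- as.vector(res$sample_counts)
    bins <- c(1:14, Inf)
    obs <- table(cut(k, breaks = c(0, bins)))
    probs <- diff(c(0, 1 - (1 - p)^bins))
    gof <- suppressWarnings(chisq.test(as.vector(obs), p = probs))
    expect_gt(gof$p.value, 0.01)
    expect_equal(mean(k), 1 / p, tolerance = 0.05)
  }
})

test_that("the dataset estimate is unbiased (Monte-Carlo, single Bernoulli trial)", {
  p <- 0.5
  n_runs <- 2e4
  d <- unit_data(1)
  vals <- vapply(
    seq_len(n_runs),
    function(s) ibs_loglik(d, bernoulli_sim, c(p = p), ibs_config(seed = s))$loglik,
    numeric(1)
  )
  se <- sqrt(ibs_variance_true(p) / n_runs)
  expect_lt(abs(mean(vals) - log(p)), 4 * se)
})

test_that("dataset-level unbiasedness against the exact orientation likelihood", {
  params <- psychometric_params(log(2), 0.1, 0.1)
  data <- orientation_generate_dataset(params, orientation_task(n_trials = 200), seed = 5)
  exact <- orientation_exact_loglik(data, params)
  p_i <- orientation_trial_probs(data, params)
  n_runs <- 400
  vals <- vapply(
    seq_len(n_runs),
    function(s) {
      ibs_loglik(data, orientation_simulate, params, ibs_config(seed = s))$loglik
    },
    numeric(1)
  )
  se <- sqrt(sum(ibs_variance_true(p_i)) / n_runs)
  expect_lt(abs(mean(vals) - exact), 4 * se)
  # and the reported variance is calibrated on average
  vars <- vapply(
    seq_len(n_runs),
    function(s) {
      ibs_loglik(data, orientation_simulate, params, ibs_config(seed = s))$variance
    },
    numeric(1)
  )
  expect_equal(mean(vars), sum(ibs_variance_true(p_i)), tolerance = 0.1)
})

test_that("sequential and batched execution are bit-identical under shared substreams", {
  m <- get_model("bernoulli")
  d <- m$generate(c(p = 0.6), list(n_trials = 40), seed = 2)
  for (cfg_args in list(
    list(repeats = 1L, seed = 9),
    list(repeats = 3L, seed = 10),
    list(repeats = 2L, seed = 11, batch_size = 4L),
    list(repeats = 1L, seed = 12, max_samples = 3L)
  )) {
    seqr <- do.call(ibs_config, c(cfg_args, list(execution = "sequential")))
    batr <- do.call(ibs_config, c(cfg_args, list(execution = "batched")))
    r1 <- suppressWarnings(ibs_loglik(d, m$simulate, c(p = 0.35), seqr))
    r2 <- suppressWarnings(ibs_loglik(d, m$simulate, c(p = 0.35), batr))
    expect_identical(r1$sample_counts, r2$sample_counts)
    expect_identical(r1$loglik, r2$loglik)
  }
})

test_that("identical seed and config give identical results; seeds differ otherwise", {
  d <- unit_data(30)
  cfg <- ibs_config(repeats = 2L, seed = 42)
  r1 <- ibs_loglik(d, bernoulli_sim, c(p = 0.4), cfg)
  r2 <- ibs_loglik(d, bernoulli_sim, c(p = 0.4), cfg)
  expect_identical(r1, r2)
  r3 <- ibs_loglik(d, bernoulli_sim, c(p = 0.4), ibs_config(repeats = 2L, seed = 43))
  expect_false(identical(r1$sample_counts, r3$sample_counts))
  # caller RNG state untouched
  set.seed(1)
  before <- .Random.seed
  invisible(ibs_loglik(d, bernoulli_sim, c(p = 0.4), cfg))
  expect_identical(before, .Random.seed)
})

test_that("an unreachable response is capped with loud diagnostics", {
  d <- unit_data(1)
  expect_warning(
    res <- ibs_loglik(
      d, never_match_sim, NULL,
      ibs_config(max_samples = 1000L, seed = 1)
    ),
    "lower bound"
  )
  expect_identical(res$capped_trials, 1L)
  expect_false(res$completed[1, 1])
  expect_identical(res$sample_counts[1, 1], 1000L)
  expect_false(res$variance_reliable)
  expect_false(res$early_stopped)
})

test_that("early stopping floors the estimate at L_lower", {
  expect_true(early_stop_check(-10, -2, -11))
  expect_false(early_stop_check(0, 0, -5))
  expect_error(early_stop_check(-1, -1, 2), "L_lower")
  # monotone: adding non-positive terms can never un-trigger the rule
  set.seed(13)
  for (i in 1:20) {
    partials <- -cumsum(rexp(50, rate = 2))
    L <- -10
    fired <- vapply(partials, function(tp) early_stop_check(0, tp, L), logical(1))
    expect_true(all(diff(fired) >= 0))
  }
  # engine integration: hopeless parameters return exactly L_lower
  d <- unit_data(20)
  res <- ibs_loglik(
    d, bernoulli_sim, c(p = 0.001),
    ibs_config(early_stop = -30, seed = 4)
  )
  expect_true(res$early_stopped)
  expect_identical(res$loglik, -30)
  expect_false(res$variance_reliable)
})

test_that("fixed sampling draws exactly N*M samples and matches closed forms", {
  d <- unit_data(10)
  res0 <- fixed_loglik(d, always_match_sim, NULL, M = 7, seed = 1)
  expect_identical(res0$loglik, 0)
  res1 <- fixed_loglik(d, never_match_sim, NULL, M = 9, seed = 1)
  expect_equal(res1$loglik, 10 * log(1 / 10))
  expect_identical(res1$total_samples, 90L)
  # Monte-Carlo mean matches exact enumeration bias at p = 0.5, M = 1
  d1 <- unit_data(1)
  vals <- vapply(
    seq_len(2e4),
    function(s) fixed_loglik(d1, bernoulli_sim, c(p = 0.5), M = 1, seed = s)$loglik,
    numeric(1)
  )
  target <- fixed_bias_exact(0.5, 1) + log(0.5) # = -0.346574
  se <- sqrt(fixed_variance_exact(0.5, 1) / length(vals))
  expect_lt(abs(mean(vals) - target), 3 * se)
})

test_that("fixed sampling vectorized and scalar simulator paths agree in law", {
  m <- get_model("bernoulli")
  d <- unit_data(300)
  sim_vec <- m$simulate
  attr(sim_vec, "simulate_n") <- m$simulate_n
  rv <- fixed_loglik(d, sim_vec, c(p = 0.5), M = 10, seed = 3)
  rs <- fixed_loglik(d, m$simulate, c(p = 0.5), M = 10, seed = 3)
  # same generator stream consumed differently: equality in distribution only
  expect_equal(mean(rv$hits), mean(rs$hits), tolerance = 0.1)
  expect_identical(rv$total_samples, rs$total_samples)
})

test_that("history-conditional simulators receive the observed past", {
  # responds 1 iff an even number of trials precede it: deterministic given
  # the observed history
  sim <- function(stimulus, params, history) {
    as.integer(length(history) %% 2L == 0L)
  }
  attr(sim, "uses_history") <- TRUE
  d <- trial_data(rep(0, 4), c(1L, 0L, 1L, 0L))
  res <- ibs_loglik(d, sim, NULL, ibs_config(seed = 1))
  expect_identical(res$loglik, 0)
  expect_true(all(res$sample_counts == 1L))
})

test_that("multi-part (tuple) responses are matched exactly", {
  resp <- data.frame(r1 = c(1L, 2L), r2 = c("a", "b"))
  d <- trial_data(c(0, 0), resp)
  sim <- function(stimulus, params) list(r1 = 1L, r2 = "a")
  res <- suppressWarnings(
    ibs_loglik(d, sim, NULL, ibs_config(seed = 2, max_samples = 50L))
  )
  expect_identical(res$sample_counts[1, 1], 1L) # first trial matches at once
  expect_identical(res$capped_trials, 1L) # second can never match
})
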