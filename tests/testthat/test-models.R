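test_that("psychometric function values and normalization", {
  p <- psychometric_params(log(2), 0.3, 0.12)
  # at the bias point, both responses are equiprobable for any lapse
  expect_equal(orientation_likelihood(0.3, 1, p), 0.5)
  # full lapse: flat at 0.5
  expect_equal(orientation_likelihood(5, 1, psychometric_params(0, 0, 1)), 0.5)
  # no lapse, one-sigma stimulus: Phi(1)
  p0 <- c(eta = log(2), mu = 0, gamma = 0)
  expect_equal(orientation_likelihood(2, 1, p0), pnorm(1))
  # response probabilities sum to 1 (machine precision)
  s <- seq(-8, 8, by = 0.5)
  tot <- orientation_likelihood(s, rep(1, length(s)), p) +
    orientation_likelihood(s, rep(0, length(s)), p)
  expect_equal(tot, rep(1, length(s)), tolerance = 1e-15)
})

test_that("orientation simulator frequencies match the psychometric function", {
  n <- 1e5
  # pure lapse
  set.seed(41)
  r <- ibsr:::orientation_simulate_n(3, c(eta = 0, mu = 0, gamma = 1), n)
  expect_lt(abs(mean(r) - 0.5), 3 * sqrt(0.25 / n))
  # noiseless limit
  r2 <- ibsr:::orientation_simulate_n(1, c(eta = log(1e-8), mu = 0, gamma = 0), n)
  expect_true(all(r2 == 1L))
  # generic grid: 4-SE band since nine comparisons share the test
  for (par in list(
    c(eta = log(2), mu = 0.1, gamma = 0.1),
    c(eta = log(0.5), mu = -0.5, gamma = 0.02),
    c(eta = log(4), mu = 1, gamma = 0.3)
  )) {
    for (s in c(-2, 0.5, 2)) {
      pr <- orientation_likelihood(s, 1, par)
      r3 <- ibsr:::orientation_simulate_n(s, par, n)
      expect_lt(abs(mean(r3) - pr), 4 * sqrt(pr * (1 - pr) / n))
    }
  }
})

test_that("orientation dataset generator is seeded and matches stated moments", {
  p <- psychometric_params(log(2), 0.1, 0.1)
  d1 <- orientation_generate_dataset(p, seed = 7)
  d2 <- orientation_generate_dataset(p, seed = 7)
  expect_identical(d1, d2)
  expect_identical(d1$n_trials, 600L)
  s <- vapply(d1$stimuli, `[[`, numeric(1), 1)
  # sd of a 600-sample Gaussian: SE ~ sd/sqrt(2n)
  expect_lt(abs(sd(s) - 3), 3 * 3 / sqrt(2 * 600))
  expect_lt(abs(mean(s) - 0), 3 * 3 / sqrt(600))
  expect_true(is.finite(orientation_exact_loglik(d1, p)))
})

test_that("von Mises difference density normalizes and matches simulation", {
  # kappa = 0: uniform difference
  expect_equal(vm_difference_density(c(-1, 0, 2), 0), rep(1 / (2 * pi), 3))
  # normalization over the circle for small to very large kappa
  for (kappa in c(0.5, 2, 34, 3000)) {
    z <- integrate(function(x) vm_difference_density(x, kappa), -pi, pi,
      rel.tol = 1e-10
    )$value
    expect_equal(z, 1, tolerance = 1e-6)
  }
  # periodicity
  x <- seq(-pi, pi, length.out = 11)
  expect_equal(
    vm_difference_density(x, 2),
    vm_difference_density(x + 2 * pi, 2),
    tolerance = 1e-12
  )
  # histogram of simulated differences matches the density
  set.seed(43)
  kappa <- 2
  d <- ibsr:::wrap_pi(rvonmises(2e5, 0, kappa) - rvonmises(2e5, 0, kappa))
  breaks <- seq(-pi, pi, length.out = 25)
  h <- hist(d, breaks = breaks, plot = FALSE)
  expected <- vapply(
    seq_len(length(breaks) - 1),
    function(j) {
      integrate(function(x) vm_difference_density(x, kappa),
        breaks[j], breaks[j + 1]
      )$value
    },
    numeric(1)
  )
  se <- sqrt(expected * (1 - expected) / 2e5)
  expect_true(all(abs(h$counts / 2e5 - expected) < 4 * se))
})

test_that("von Mises sampler has the right circular moments", {
  set.seed(47)
  for (kappa in c(1, 5)) {
    x <- rvonmises(1e5, 0, kappa)
    rbar <- sqrt(mean(cos(x))^2 + mean(sin(x))^2)
    expected_rbar <- besselI(kappa, 1) / besselI(kappa, 0)
    expect_equal(rbar, expected_rbar, tolerance = 0.01)
    expect_lt(abs(atan2(mean(sin(x)), mean(cos(x)))), 0.02)
  }
})

test_that("degree/kappa reparametrization round-trips", {
  for (sigma in c(0.5, 1, 17.2, 60)) {
    expect_equal(
      ibsr:::sigma_deg_from_kappa(ibsr:::kappa_from_sigma_deg(sigma)),
      sigma,
      tolerance = 1e-12
    )
  }
})

test_that("change localization dataset generator: shape, seeding, change statistics", {
  p <- changeloc_params(log(17.2), 0.1)
  d1 <- changeloc_generate_dataset(p, changeloc_task(n_trials = 200), seed = 3)
  d2 <- changeloc_generate_dataset(p, changeloc_task(n_trials = 200), seed = 3)
  expect_identical(d1, d2)
  expect_identical(d1$n_trials, 200L)
  expect_true(all(lengths(d1$stimuli) == 12L))
  expect_true(all(unlist(d1$responses) %in% 1:6))
  info <- lapply(d1$stimuli, changeloc_trial_info)
  deltas <- ibsr:::deg2rad(vapply(info, `[[`, numeric(1), "delta"))
  # change magnitudes ~ vonMises(0, kappa_s = 1): resultant length I1/I0(1)
  rbar <- sqrt(mean(cos(deltas))^2 + mean(sin(deltas))^2)
  expect_equal(rbar, besselI(1, 1) / besselI(1, 0), tolerance = 0.12)
  # change locations roughly uniform
  cc <- vapply(info, `[[`, integer(1), "c")
  expect_gt(suppressWarnings(chisq.test(table(factor(cc, 1:6)))$p.value), 0.01)
})

test_that("change localization simulator limits", {
  # full lapse: uniform over the six patches
  set.seed(51)
  p_lapse <- changeloc_params(log(17.2), 1)
  stim <- c(runif(6, 0, 360), runif(6, 0, 360))
  r <- replicate(6000, changeloc_simulate(stim, p_lapse))
  expect_gt(suppressWarnings(chisq.test(table(factor(r, 1:6)))$p.value), 0.01)
  # noiseless limit: always picks the changed patch
  p_sharp <- changeloc_params(log(1), 1e-9) # sigma = 1 degree
  o1 <- c(10, 50, 90, 130, 170, 210)
  o2 <- o1
  o2[4] <- o2[4] + 120
  r2 <- replicate(200, changeloc_simulate(c(o1, o2), p_sharp))
  expect_true(all(r2 == 4L))
})

test_that("change localization likelihood: symmetry points and normalization", {
  p <- changeloc_params(log(17.2), 0.1)
  # no change: all patches exchangeable
  expect_equal(changeloc_likelihood(0, TRUE, p), 1 / 6, tolerance = 1e-5)
  # full lapse
  expect_equal(
    changeloc_likelihood(90, TRUE, changeloc_params(log(17.2), 1)),
    1 / 6,
    tolerance = 1e-9
  )
  # six response probabilities sum to 1 by construction
  lik_c <- changeloc_likelihood(70, TRUE, p)
  lik_o <- changeloc_likelihood(70, FALSE, p)
  expect_equal(lik_c + 5 * lik_o, 1, tolerance = 1e-7)
  # monotone in the change magnitude
  pc <- vapply(
    c(5, 20, 45, 90, 150),
    function(d) changeloc_likelihood(d, TRUE, p), numeric(1)
  )
  expect_true(all(diff(pc) > 0))
  # symmetric in the sign of the change
  expect_equal(
    changeloc_likelihood(-60, TRUE, p),
    changeloc_likelihood(60, TRUE, p),
    tolerance = 1e-9
  )
})

test_that("change localization quadrature agrees with a Monte-Carlo oracle", {
  p <- changeloc_params(log(17.2), 0.1)
  n <- 1e5
  set.seed(53)
  base <- runif(6, 0, 360)
  for (delta in c(30, 90)) {
    o2 <- base
    o2[2] <- (o2[2] + delta) %% 360
    stim <- c(base, o2)
    hits <- sum(replicate(n, changeloc_simulate(stim, p)) == 2L)
    pr <- changeloc_likelihood(delta, TRUE, p)
    expect_lt(abs(hits / n - pr), 3 * sqrt(pr * (1 - pr) / n))
  }
})

test_that("exact change localization log-likelihood is finite and seeded-stable", {
  p <- changeloc_params(log(10), 0.05)
  d <- changeloc_generate_dataset(p, changeloc_task(n_trials = 60), seed = 9)
  ll <- changeloc_exact_loglik(d, p)
  expect_true(is.finite(ll))
  # worse parameters give a worse likelihood than the generating ones, on
  # average over a moderate dataset
  ll_bad <- changeloc_exact_loglik(d, changeloc_params(log(55), 0.4))
  expect_gt(ll, ll_bad)
})
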