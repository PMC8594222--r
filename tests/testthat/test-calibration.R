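test_that("NRMSE implements the first-observation-normalized formula", {
  expect_equal(nrmse(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5)), 0)
  expect_equal(nrmse(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 6)), 1)
  set.seed(42)
  for (i in 1:5) {
    obs <- stats::runif(5, 10, 500)
    pred <- obs * stats::runif(5, 0.5, 1.5)
    oracle <- sqrt(sum((obs - pred)^2) / obs[1]^2)  # direct re-evaluation
    expect_lt(rel_err(nrmse(obs, pred), oracle), 1e-12)
    # scale covariance: common rescaling leaves the error unchanged
    expect_equal(nrmse(3.7 * obs, 3.7 * pred), nrmse(obs, pred))
  }
  expect_error(nrmse(c(1, 2), c(1, 2, 3)), "equal length")
  expect_error(nrmse(c(0, 2), c(1, 2)), "nonzero")
})

test_that("observation container enforces its invariants", {
  expect_error(tis_observations(5, 10), "at least 2")
  expect_error(tis_observations(c(5, 5), c(1, 2)), "increasing")
  expect_error(tis_observations(c(5, 10), c(1, -2)), "positive")
  o <- tis_observations(c(5, 10), c(1, 2), arm = "fivefu")
  expect_s3_class(o, "tis_observations")
  expect_equal(o$arm, "fivefu")
})

test_that("synthetic observations are reproducible and noiseless when asked", {
  p <- tis_parameters()
  days <- tis_record_days("control")
  clean <- generate_synthetic_observations(p, sched_control(), days,
                                           noise_cv = 0, seed = 1)
  tr <- tis_simulate(params = p, t_end = 25, grid_step = 0.25)
  expect_equal(clean$volumes,
               stats::approx(tr$time, tr$volume_mm3, xout = days)$y,
               tolerance = 1e-10)
  a <- generate_synthetic_observations(p, sched_control(), days,
                                       noise_cv = 0.05, seed = 99)
  b <- generate_synthetic_observations(p, sched_control(), days,
                                       noise_cv = 0.05, seed = 99)
  expect_identical(a$volumes, b$volumes)
  expect_false(identical(a$volumes, clean$volumes))
  expect_error(generate_synthetic_observations(p, sched_control(), c(-1, 5)),
               "\\[0, t_end\\]")
})

test_that("multiplicative noise has the nominal coefficient of variation", {
  # Monte-Carlo check of the noise model itself (no simulation needed per
  # point beyond the shared mean curve)
  p <- tis_parameters()
  days <- c(5, 10)
  reps <- t(vapply(1:1000, function(s) {
    generate_synthetic_observations(p, sched_control(), days,
                                    noise_cv = 0.05, seed = s)$volumes
  }, numeric(2)))
  cv <- apply(reps, 2L, function(x) stats::sd(x) / mean(x))
  expect_true(all(cv > 0.04 & cv < 0.06))
})

test_that("an empty search space returns the base parameters unchanged", {
  p <- tis_parameters()
  obs <- generate_synthetic_observations(p, sched_control(),
                                         tis_record_days("control"),
                                         noise_cv = 0, seed = 1)
  pr <- tis_fit_problem(free = list(), base = p,
                        arms = list(list(observations = obs,
                                         schedule = sched_control())))
  fit <- fit_parameters(pr)
  expect_identical(fit$params, p)
  expect_lt(fit$total_nrmse, 1e-8)
})

test_that("the GA recovers the growth rate from noisy synthetic data", {
  p <- tis_parameters()
  obs <- generate_synthetic_observations(p, sched_control(),
                                         tis_record_days("control"),
                                         noise_cv = 0.05, seed = 3)
  pr <- tis_fit_problem(free = list(a1 = c(p$a1 / 2, p$a1 * 2)),
                        arms = list(list(observations = obs,
                                         schedule = sched_control())),
                        ga = list(pop = 20, generations = 30, seed = 5))
  fit <- fit_parameters(pr)
  expect_lt(rel_err(fit$estimates[["a1"]], p$a1), 0.10)
  # elitism: the best-so-far cost never worsens across generations
  expect_true(all(diff(fit$trace) <= 0))
  # determinism: the same seed reproduces the same estimate
  fit2 <- fit_parameters(pr)
  expect_identical(fit$estimates, fit2$estimates)
})

test_that("fit problems validate bounds and free-parameter names", {
  obs <- tis_observations(c(5, 10), c(1, 2))
  arms <- list(list(observations = obs, schedule = sched_control()))
  expect_error(tis_fit_problem(free = list(zz = c(1, 2)), arms = arms),
               "not in the model")
  expect_error(tis_fit_problem(free = list(a1 = c(2, 1)), arms = arms),
               "lower < upper")
})
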