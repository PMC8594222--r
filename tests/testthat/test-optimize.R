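test_that("schedule cost is the mean squared population ratio over arms", {
  C <- c(1e8, 2e8, 3e8)
  expect_equal(schedule_cost(C, C, C, C), 1)
  z <- rep(0, 3)
  expect_equal(schedule_cost(C, z, z, z), 0)
  set.seed(7)
  for (i in 1:5) {
    n <- sample(3:20, 1)
    ctrl <- stats::runif(n, 1e6, 1e9)
    a <- stats::runif(n, 0, 1e9); b <- stats::runif(n, 0, 1e9)
    d <- stats::runif(n, 0, 1e9)
    oracle <- mean(((a / ctrl)^2 + (b / ctrl)^2 + (d / ctrl)^2) / 3)
    expect_lt(rel_err(schedule_cost(ctrl, a, b, d), oracle), 1e-12)
  }
  expect_error(schedule_cost(C, C, C, C[1:2]), "equal")
  expect_error(schedule_cost(c(0, 1, 2), C, C, C), "positive")
})

test_that("a singleton search space returns its only schedule", {
  bounds <- tis_schedule_bounds(n_5fu = 1, n_cd25 = 1, day_min = 3,
                                day_max = 3, max_per_day = 1)
  opt <- optimize_schedules(bounds = bounds, t_end = 30, n_samples = 30,
                            ga = list(pop = 4, generations = 2), seed = 1)
  expect_equal(opt$t_5fu, 3)
  expect_equal(opt$t_cd25, 3)
  # cost equals its direct evaluation on the same sampling grid
  st <- seq(1, 30, length.out = 30)
  simC <- function(s) {
    tr <- tis_simulate(schedule = s, t_end = 30, grid_step = 1)
    stats::approx(tr$time, tr$C, xout = st)$y
  }
  direct <- schedule_cost(simC(tis_schedule()),
                          simC(tis_schedule(fivefu_days = 3)),
                          simC(tis_schedule(anticd25_days = 3)),
                          simC(tis_schedule(fivefu_days = 3,
                                            anticd25_days = 3)))
  expect_equal(opt$cost, direct, tolerance = 1e-10)
})

test_that("the GA matches exhaustive enumeration on a tiny problem", {
  bounds <- tis_schedule_bounds(n_5fu = 1, n_cd25 = 1, day_min = 1,
                                day_max = 5)
  st <- seq(1, 30, length.out = 30)
  simC <- function(s) {
    tr <- tis_simulate(schedule = s, t_end = 30, grid_step = 1)
    stats::approx(tr$time, tr$C, xout = st)$y
  }
  ctrl <- simC(tis_schedule())
  # brute-force oracle over all 25 (f, a) day pairs
  grid <- expand.grid(f = 1:5, a = 1:5)
  costs <- mapply(function(f, a) {
    schedule_cost(ctrl, simC(tis_schedule(fivefu_days = f)),
                  simC(tis_schedule(anticd25_days = a)),
                  simC(tis_schedule(fivefu_days = f, anticd25_days = a)))
  }, grid$f, grid$a)
  best <- grid[which.min(costs), ]
  opt <- optimize_schedules(bounds = bounds, t_end = 30, n_samples = 30,
                            ga = list(pop = 12, generations = 12), seed = 2)
  expect_equal(opt$t_5fu, best$f)
  expect_equal(opt$t_cd25, best$a)
  expect_equal(opt$cost, min(costs), tolerance = 1e-10)
})

test_that("optimization is repeatable and respects bounds and the day cap", {
  bounds <- tis_schedule_bounds(n_5fu = 2, n_cd25 = 3, day_min = 1,
                                day_max = 6, max_per_day = 2)
  run <- function() {
    optimize_schedules(bounds = bounds, t_end = 30, n_samples = 30,
                       ga = list(pop = 10, generations = 8), seed = 11)
  }
  a <- run(); b <- run()
  expect_identical(a$t_5fu, b$t_5fu)
  expect_identical(a$t_cd25, b$t_cd25)
  expect_identical(a$cost, b$cost)
  for (v in list(a$t_5fu, a$t_cd25)) {
    expect_true(all(v >= 1 & v <= 6))
    expect_true(all(v == sort(v)))
    expect_true(all(table(v) <= 2))
  }
})

test_that("the optimum never loses to the calibrated baseline schedule", {
  st <- seq(1, 100, length.out = 100)
  simC <- function(s) {
    tr <- tis_simulate(schedule = s, t_end = 100, grid_step = 1)
    stats::approx(tr$time, tr$C, xout = st)$y
  }
  baseline <- schedule_cost(simC(tis_schedule()), simC(sched_5fu()),
                            simC(sched_cd25()), simC(sched_comb()))
  opt <- optimize_schedules(ga = list(pop = 12, generations = 6), seed = 4)
  expect_lte(opt$cost, baseline + 1e-12)
})

test_that("infeasible bounds are rejected", {
  expect_error(tis_schedule_bounds(n_5fu = 5, day_min = 2, day_max = 3,
                                   max_per_day = 2), "infeasible")
})
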