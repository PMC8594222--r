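test_that("Latin hypercube samples are stratified one-per-bin", {
  rng <- list(a = c(0, 1), b = c(10, 30))
  x1 <- lhs_sample(1, rng, seed = 1)
  expect_true(x1[, "a"] >= 0 && x1[, "a"] <= 1)
  expect_true(x1[, "b"] >= 10 && x1[, "b"] <= 30)

  x <- lhs_sample(10, rng, seed = 2)
  for (j in colnames(x)) {
    u <- (x[, j] - rng[[j]][1]) / diff(rng[[j]])
    bins <- findInterval(sort(u), seq(0, 1, by = 0.1),
                         rightmost.closed = TRUE)
    expect_equal(bins, 1:10)  # exactly one point per decile
  }
  expect_error(lhs_sample(0, rng), "at least 1")
  expect_error(lhs_sample(5, list(a = c(2, 1))), "lower < upper")
})

test_that("default sensitivity ranges span half to twice the calibrated values", {
  p <- tis_parameters()
  rng <- tis_sensitivity_ranges(p)
  expect_equal(rng$a1, c(p$a1 / 2, p$a1 * 2))
  # treatment-only constants are excluded from the no-treatment screen
  expect_false(any(c("d1", "g1", "h1", "k1", "h6", "b4_5fu") %in% names(rng)))
  x <- lhs_sample(50, rng["a1"], seed = 3)
  expect_true(all(x >= 2.1996e-2 & x <= 8.7984e-2))
})

test_that("PRCC detects a perfectly dependent parameter and masks noise", {
  set.seed(10)
  n <- 200
  x <- cbind(p1 = stats::runif(n), p2 = stats::runif(n), p3 = stats::runif(n))
  y <- x[, "p1"]^3  # monotone in p1 only
  res <- tis_prcc(x, cbind(out = y))
  expect_gt(res$prcc["p1", "out"], 0.99)
  expect_lt(res$p_value["p1", "out"], 1e-10)
  expect_gt(min(res$p_value[c("p2", "p3"), "out"]), 0.05)
})

test_that("PRCC matches the brute-force residualization oracle", {
  set.seed(11)
  for (rep in 1:3) {
    n <- 150
    x <- cbind(x1 = stats::runif(n), x2 = stats::runif(n),
               x3 = stats::runif(n))
    y <- 2 * x[, "x1"] - x[, "x2"] + stats::rnorm(n, sd = 0.1)
    res <- tis_prcc(x, cbind(y = y))
    # oracle: explicit rank transform + residual correlation per parameter
    xr <- apply(x, 2L, rank); yr <- rank(y)
    for (j in 1:3) {
      rx <- stats::resid(stats::lm(xr[, j] ~ xr[, -j]))
      ry <- stats::resid(stats::lm(yr ~ xr[, -j]))
      expect_lt(abs(res$prcc[j, "y"] - stats::cor(rx, ry)), 1e-10)
    }
    expect_gt(res$prcc["x1", "y"], 0)
    expect_lt(res$prcc["x2", "y"], 0)
  }
})

test_that("PRCC is invariant under monotone transforms of single columns", {
  set.seed(12)
  n <- 120
  x <- cbind(a = stats::runif(n, 1, 2), b = stats::runif(n, 1, 2))
  y <- x[, "a"] + 0.5 * x[, "b"] + stats::rnorm(n, sd = 0.05)
  r1 <- tis_prcc(x, cbind(y = y))$prcc
  x2 <- x; x2[, "a"] <- exp(x[, "a"]); x2[, "b"] <- log(x[, "b"])
  r2 <- tis_prcc(x2, cbind(y = y^3))$prcc
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("Morris indices separate additive from interacting inputs", {
  lower <- c(x1 = 0, x2 = 0); upper <- c(x1 = 1, x2 = 1)
  lin <- morris_ee(function(x) 3 * x[["x1"]] + x[["x2"]],
                   lower, upper, levels = 10, r = 60, seed = 5)
  # a linear model has constant elementary effects
  expect_lt(max(lin$sigma), 1e-10)
  expect_equal(lin$mu_star[lin$parameter == "x1"] /
               lin$mu_star[lin$parameter == "x2"], 3, tolerance = 1e-10)
  expect_equal(lin$mu_star[lin$parameter == "x1"], 3, tolerance = 1e-10)

  inter <- morris_ee(function(x) x[["x1"]] * x[["x2"]],
                     lower, upper, levels = 10, r = 60, seed = 6)
  expect_gt(inter$sigma[inter$parameter == "x1"], 0.05)
  # EE of x1 equals the current x2 value: mu* approximates E[x2] ~ 0.5
  expect_equal(inter$mu_star[inter$parameter == "x1"], 0.5, tolerance = 0.15)
  expect_error(morris_ee(function(x) 1, lower, upper, r = 1), "trajectories")
  expect_error(morris_ee(function(x) 1, lower, upper, levels = 9, r = 4),
               "even")
})

test_that("replicated PRCC aggregates and masks across re-draws", {
  fn <- function(x) c(y = x[["a"]]^2 + 0.01 * x[["b"]])
  res <- tis_prcc_replicated(fn, list(a = c(1, 2), b = c(1, 2), c = c(1, 2)),
                             n = 80, replications = 3, seed = 9)
  expect_gt(res$mean["a", "y"], 0.99)
  expect_true(res$significant["a", "y"])
  expect_false(res$significant["c", "y"])
  expect_true(is.na(res$mean_masked["c", "y"]))
  expect_equal(dim(res$sd), dim(res$mean))
})
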