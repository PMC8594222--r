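test_that("quasi-steady-state cytokines match the published initial values", {
  p <- tis_parameters()
  cyt <- qss_cytokines(tis_initial_state(), p)
  # IL-2 and TGF-beta reproduce the printed values at printed precision
  expect_equal(signif(cyt[["I"]], 5), 2.5107e-6)
  expect_equal(signif(cyt[["S"]], 4), 5.363e-7)
  # IFN-gamma agrees to 0.02% (the printed value carries rounded ratios)
  expect_lt(rel_err(cyt[["F"]], 3.9348e-7), 2e-4)

  zero <- tis_initial_state(C = 0, N = 0, T = 0, M = 0, H = 0, R = 0)
  expect_equal(unname(qss_cytokines(zero, p)), c(0, 0, 0))
  expect_error(qss_cytokines(c(C = -1, N = 0, T = 0, H = 0), p), "non-negative")
})

test_that("simplified derivatives vanish and source correctly at the fixed points", {
  p <- tis_parameters()
  # tumor at carrying capacity with no effectors: growth exactly balances
  st <- tis_initial_state(C = p$Cmax, N = 0, T = 0, M = 0, H = 0, R = 0)
  d <- simplified_rhs(0, st, p)
  expect_equal(unname(d["C"]), 0)
  # no tumor, no MDSCs: the MDSC compartment fills at its production rate
  st2 <- tis_initial_state(C = 0, N = 0, T = 0, M = 0, H = 0, R = 0)
  expect_equal(unname(simplified_rhs(0, st2, p)["M"]), p$a4)
  expect_error(simplified_rhs(Inf, st2, p), "finite")
  expect_error(simplified_rhs(0, replace(st2, 1, NaN), p), "finite")
})

test_that("simplified derivatives match a term-by-term oracle at the standard state", {
  p <- tis_parameters()
  C <- 6e5; N <- 105840; T <- 21e4; M <- 3e3; H <- 564480; R <- 42336
  # independent straight-line evaluation of every printed term (control arm)
  acc <- C / (1 + C^(1 / 3) / 100)
  Fcy <- 4.4691e-13 * T + 4.4691e-13 * N + 4.4691e-13 * H
  rIa <- 2.2483e11
  dC <- 4.3992e-2 * C * log(1e10 / C) -
    3.23e-7 * N * acc -
    (1.1e-7 * T * acc) / ((1 + 0.345 * R) * (1 + 0.286 * 8.9382e-13 * C))
  dN <- 1.4e4 - 4.12e-2 * N + 0.125 * H * N / (0.3 * rIa + H) +
    0.125 * Fcy * N / (0.3 + Fcy) - 1e-9 * N * acc - 1e-10 * R * N
  dT <- -2e-2 * T + 8e-2 * T * C^2 / (2.02e14 + C^2) +
    1.1e-7 * N * acc * ((1 - 0.18) / (1 + 6e-3 * (M - 2.5e6)^2) + 0.18) -
    1.5e-10 * T * acc + 125e-5 * H * T / (0.3 * rIa + H) +
    12.5e-2 * Fcy * T / (0.3 + Fcy) - 1e-10 * R * T
  dM <- 1.25e6 - 3.25e-2 * M + 0.7e7 * C / (1e10 + C)
  dH <- 3.6e5 - 1.2e-3 * H + 0.125 * H^2 / (0.3 * rIa + H) +
    0.125 * Fcy * H / (0.3 + Fcy) - 1e-10 * R * H
  dR <- 5.6e5 - 2.3e-2 * R + 2e-4 * T + 4e-4 * H +
    0.125 * H * R / (0.3 * rIa + H) - 1e-11 * N * R

  got <- simplified_rhs(0, tis_initial_state(), p)
  oracle <- c(C = dC, N = dN, T = dT, M = dM, H = dH, R = dR, A = 0)
  for (nm in names(oracle)) {
    if (oracle[[nm]] == 0) expect_equal(got[[nm]], 0)
    else expect_lt(rel_err(got[[nm]], oracle[[nm]]), 1e-12)
  }
})

test_that("compiled and reference right-hand sides integrate identically", {
  p <- tis_parameters()
  sched <- sched_comb()
  t_end <- 12
  fast <- tis_simulate(params = p, schedule = sched, t_end = t_end,
                       grid_step = 0.5)
  # reference integration of the exported R right-hand side with the same
  # segment restarts at the treatment-window boundaries
  breaks <- sort(unique(pmin(c(0, t_end, sched$fivefu_days,
                               sched$fivefu_days + 1, sched$anticd25_days,
                               sched$anticd25_days + 1), t_end)))
  y <- unname(tis_initial_state())
  slow <- matrix(y, nrow = 1L)
  tt <- 0
  for (i in seq_len(length(breaks) - 1L)) {
    times <- unique(c(breaks[i], seq(breaks[i], breaks[i + 1L], by = 0.5),
                      breaks[i + 1L]))
    o <- deSolve::lsoda(
      y = y, times = times,
      func = function(t, y, parms) {
        list(unname(simplified_rhs(t, pmax(y, 0), p, sched)))
      }, parms = NULL, rtol = 1e-10,
      atol = c(rep(1e-8, 6), 1), maxsteps = 20000)
    keep <- o[, 1L] %in% seq(0, t_end, 0.5) & o[, 1L] > tt[length(tt)]
    slow <- rbind(slow, o[keep, -1L, drop = FALSE])
    tt <- c(tt, o[keep, 1L])
    y <- pmax(o[nrow(o), -1L], 0)
  }
  expect_equal(tt, fast$time)
  for (j in 1:6) {
    expect_lt(max(rel_err(fast[[j + 1L]] + 1, slow[, j] + 1)), 1e-5)
  }
})

test_that("full model collapses onto the quasi-steady-state structure", {
  p <- tis_parameters()
  r <- tis_absolute_rates(p)
  y0 <- tis_initial_state()
  cyt <- qss_cytokines(y0, p)
  st <- c(y0[c("C", "N", "T", "M", "H", "R")], cyt, A = 0)
  d <- full_rhs(0, st, p, r)
  # cytokines at their QSS values have (numerically) zero net production
  expect_lt(abs(d[["I"]]), 1e-12 * r$tau1 * cyt[["I"]])
  expect_lt(abs(d[["F"]]), 1e-9 * r$tau2 * cyt[["F"]])
  expect_lt(abs(d[["S"]]), 1e-9 * r$tau3 * cyt[["S"]])
  # no T helper source: IL-2 decays exponentially
  st2 <- st; st2[["H"]] <- 0
  expect_equal(full_rhs(0, st2, p, r)[["I"]], -r$tau1 * st2[["I"]])
  # inconsistent rates are rejected with the violated ratio named
  bad <- r; bad$beta2 <- bad$beta2 * 2
  expect_error(full_rhs(0, st, p, bad), "beta2/tau2")
})

test_that("the simplified model is the fast-cytokine limit of the full model", {
  p <- tis_parameters()
  fu <- tis_simulate_full(params = p,
                          absolute_rates = tis_absolute_rates(p, 50, 50, 50),
                          t_end = 25, grid_step = 0.5)
  si <- tis_simulate(params = p, t_end = 25, grid_step = 0.5)
  sel <- fu$time >= 5
  for (v in c("C", "N", "T", "M", "H", "R")) {
    expect_lt(max(rel_err(fu[[v]][sel], si[[v]][sel])), 0.01)
  }
})

test_that("immune-free tumor growth recovers the closed-form Gompertz curve", {
  eps <- 1e-30  # effectively removes the kill terms
  p <- tis_parameters(b1 = eps, c1 = eps, g1 = eps, h1 = eps)
  tr <- tis_simulate(params = p, t_end = 60, grid_step = 1)
  C0 <- tr$C[1L]
  expected <- p$Cmax * (C0 / p$Cmax)^exp(-p$a1 * tr$time)
  expect_lt(max(rel_err(tr$C, expected)), 1e-6)
})

test_that("trajectories respect non-negativity, the carrying capacity and volumes", {
  arms <- list(sched_control(), sched_5fu(), sched_cd25(), sched_comb())
  for (s in arms) {
    tr <- tis_simulate(schedule = s, t_end = 100, grid_step = 1)
    expect_true(all(as.matrix(tr[, c("C", "N", "T", "M", "H", "R", "A")]) >= 0))
    expect_true(all(tr$C <= tis_parameters()$Cmax))
    expect_equal(tr$volume_mm3, tr$C * 1e-6)
    # cumulative exposure never decreases
    expect_true(all(diff(tr$A) >= -1e-8 * max(tr$A, 1)))
  }
})

test_that("control-arm output ignores amplitude and duration settings", {
  a <- tis_simulate(schedule = tis_schedule(), t_end = 30, grid_step = 1)
  b <- tis_simulate(schedule = tis_schedule(fivefu_amplitude = 7,
                                            anticd25_amplitude = 3e12,
                                            fivefu_effect_days = 9,
                                            anticd25_effect_days = 2),
                    t_end = 30, grid_step = 1)
  expect_identical(as.data.frame(a)[names(a) != "time"],
                   as.data.frame(b)[names(b) != "time"])
})

test_that("solution accuracy is tolerance-controlled, not grid-controlled", {
  a <- tis_simulate(schedule = sched_comb(), t_end = 100, grid_step = 1)
  b <- tis_simulate(schedule = sched_comb(), t_end = 100, grid_step = 0.5)
  expect_lt(rel_err(a$C[nrow(a)], b$C[nrow(b)]), 1e-3)
})

test_that("combination therapy beats the untreated arm at day 25", {
  ctrl <- tis_simulate(schedule = sched_control(), t_end = 25, grid_step = 1)
  comb <- tis_simulate(schedule = sched_comb(), t_end = 25, grid_step = 1)
  expect_lt(comb$C[comb$time == 25], ctrl$C[ctrl$time == 25])
})
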