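# Right-hand sides and numerical integration of the tumor-immune system model.

#' Quasi-steady-state cytokine concentrations
#'
#' The cytokines equilibrate much faster than the cell populations, so their
#' concentrations are algebraic functions of the cell state: IL-2 is
#' proportional to T helper cells, IFN-gamma to CTLs, NK and T helper cells,
#' and TGF-beta to tumor cells, with the calibrated secretion/decay ratios.
#'
#' @param state named numeric vector with at least `C`, `N`, `T`, `H`
#'   components (cell counts), e.g. from [tis_initial_state()].
#' @param params a [tis_parameters()] object.
#' @return Named vector `c(I, F, S)` in ng/ml.
#' @examples
#' qss_cytokines(tis_initial_state(), tis_parameters())
#' @export
qss_cytokines <- function(state, params) {
  params <- validate_tis_parameters(params)
  need <- c("C", "N", "T", "H")
  if (!all(need %in% names(state))) {
    stop("state must contain components ", paste(need, collapse = ", "))
  }
  if (any(!is.finite(state[need])) || any(state[need] < 0)) {
    stop("state components must be finite and non-negative")
  }
  c(I = unname(state[["H"]] / params$ratio_tau1_alpha1),
    F = unname(params$ratio_beta1_tau2 * state[["T"]] +
               params$ratio_beta2_tau2 * state[["N"]] +
               params$ratio_beta3_tau2 * state[["H"]]),
    S = unname(params$ratio_lambda1_tau3 * state[["C"]]))
}

#' Right-hand side of the simplified six-equation model
#'
#' Reference implementation (plain R) of the derivatives of the six cell
#' populations plus the auxiliary cumulative anti-CD25 exposure A, with
#' cytokines eliminated by their quasi-steady-state expressions. The compiled
#' equivalent used by [tis_simulate()] is cross-checked against this function.
#'
#' Treatment enters through the pulsed forcing signals: while the 5-FU signal
#' is positive, tumor cells die at extra rate `g1` and the MDSC death rate is
#' `b4_5fu` (else `b4_normal`); the anti-CD25 signal u drives Treg depletion
#' (`h6*u*R`), releases the Treg block on CTL killing (`d1*u^2*R^3`), and
#' accumulates into A whose logarithm kills tumor cells (`h1*log(1+k1*A)`;
#' active only in arms that receive anti-CD25).
#'
#' @param t time (day).
#' @param state named vector `c(C, N, T, M, H, R, A)`.
#' @param params a [tis_parameters()] object.
#' @param schedule a [tis_schedule()].
#' @return Named vector of the seven derivatives.
#' @export
simplified_rhs <- function(t, state, params, schedule = tis_schedule()) {
  if (!is.finite(t)) stop("t must be finite")
  if (any(!is.finite(state))) stop("state must be finite")
  u5 <- drug_signal(schedule, "fivefu", t)
  ua <- drug_signal(schedule, "anticd25", t)
  sgn <- attr(ua, "sign")
  .simplified_rhs_num(state, params, u5 = as.numeric(u5),
                      ua = as.numeric(ua), sgn = sgn)
}

# Core arithmetic with precomputed segment signals; mirrors src/tis_rhs.c.
.simplified_rhs_num <- function(state, params, u5, ua, sgn) {
  p <- params
  C <- max(state[[1L]], 0); N <- max(state[[2L]], 0); T <- max(state[[3L]], 0)
  M <- max(state[[4L]], 0); H <- max(state[[5L]], 0); R <- max(state[[6L]], 0)
  A <- max(state[[7L]], 0)

  Cl <- max(C, 1)
  acc <- C / (1 + C^(1 / 3) / p$l1)
  Fcy <- p$ratio_beta1_tau2 * T + p$ratio_beta2_tau2 * N + p$ratio_beta3_tau2 * H
  treg <- (1 + p$e1 * R) / (1 + p$d1 * ua^2 * R^3)

  dC <- p$a1 * C * log(p$Cmax / Cl) -
    p$b1 * N * acc -
    (p$c1 * T * acc) / (treg * (1 + p$f1 * p$ratio_lambda1_tau3 * C)) -
    (if (u5 > 0) p$g1 * C else 0) -
    p$h1 * log1p(p$k1 * sgn * A) * C / (C + 1)
  if (state[[1L]] <= 0 && dC < 0) dC <- 0

  dN <- p$a2 - p$b2 * N +
    p$c2 * H * N / (p$d2 * p$ratio_tau1_alpha1 + H) +
    p$e2 * Fcy * N / (p$f2 + Fcy) -
    p$g2 * N * acc - p$h2 * R * N

  dT <- -p$a3 * T +
    p$b3 * T * C^2 / (p$c3 + C^2) +
    p$d3 * N * acc * ((1 - p$m3) / (1 + p$n3 * (M - p$p3)^2) + p$m3) -
    p$e3 * T * acc +
    p$f3 * H * T / (p$g3 * p$ratio_tau1_alpha1 + H) +
    p$h3 * Fcy * T / (p$k3 + Fcy) -
    p$l3 * R * T

  dM <- p$a4 - (if (u5 > 0) p$b4_5fu else p$b4_normal) * M +
    p$c4 * C / (p$d4 + C)

  dH <- p$a5 - p$b5 * H +
    p$c5 * H^2 / (p$d5 * p$ratio_tau1_alpha1 + H) +
    p$e5 * Fcy * H / (p$f5 + Fcy) -
    p$g5 * R * H

  dR <- p$a6 - p$b6 * R + p$c6 * T + p$d6 * H +
    p$e6 * H * R / (p$f6 * p$ratio_tau1_alpha1 + H) -
    p$g6 * N * R - p$h6 * ua * R

  c(C = dC, N = dN, T = dT, M = dM, H = dH, R = dR, A = ua * C)
}

#' Right-hand side of the full nine-equation model
#'
#' Derivatives of the six cell populations, the three cytokines (IL-2 `I`,
#' IFN-gamma `F`, TGF-beta `S`) with explicit secretion/decay dynamics, and
#' the auxiliary exposure A. The absolute cytokine rates must be consistent
#' with the calibrated ratios carried by `params` (relative tolerance 1e-9);
#' [tis_absolute_rates()] constructs such a set.
#'
#' @param t time (day).
#' @param state named vector `c(C, N, T, M, H, R, I, F, S, A)`.
#' @param params a [tis_parameters()] object.
#' @param absolute_rates list with `alpha1`, `tau1`, `beta1`, `beta2`,
#'   `beta3`, `tau2`, `lambda1`, `tau3`.
#' @param schedule a [tis_schedule()].
#' @return Named vector of the ten derivatives.
#' @export
full_rhs <- function(t, state, params, absolute_rates,
                     schedule = tis_schedule()) {
  if (!is.finite(t)) stop("t must be finite")
  if (any(!is.finite(state))) stop("state must be finite")
  params <- validate_tis_parameters(params)
  .check_rates(params, absolute_rates)
  u5 <- as.numeric(drug_signal(schedule, "fivefu", t))
  ua <- drug_signal(schedule, "anticd25", t)
  sgn <- attr(ua, "sign"); ua <- as.numeric(ua)
  .full_rhs_num(state, params, absolute_rates, u5, ua, sgn)
}

.check_rates <- function(params, r) {
  need <- c("alpha1", "tau1", "beta1", "beta2", "beta3", "tau2",
            "lambda1", "tau3")
  if (!all(need %in% names(r))) {
    stop("absolute_rates must contain ", paste(need, collapse = ", "))
  }
  chk <- function(val, ref, what) {
    if (abs(val - ref) > 1e-9 * abs(ref)) {
      stop("absolute rates inconsistent with calibrated ratio ", what,
           sprintf(" (implied %.6g, expected %.6g)", val, ref))
    }
  }
  chk(r$tau1 / r$alpha1, params$ratio_tau1_alpha1, "tau1/alpha1")
  chk(r$beta1 / r$tau2, params$ratio_beta1_tau2, "beta1/tau2")
  chk(r$beta2 / r$tau2, params$ratio_beta2_tau2, "beta2/tau2")
  chk(r$beta3 / r$tau2, params$ratio_beta3_tau2, "beta3/tau2")
  chk(r$lambda1 / r$tau3, params$ratio_lambda1_tau3, "lambda1/tau3")
  invisible(r)
}

.full_rhs_num <- function(state, params, r, u5, ua, sgn) {
  p <- params
  C <- max(state[[1L]], 0); N <- max(state[[2L]], 0); T <- max(state[[3L]], 0)
  M <- max(state[[4L]], 0); H <- max(state[[5L]], 0); R <- max(state[[6L]], 0)
  I <- max(state[[7L]], 0); Fc <- max(state[[8L]], 0); S <- max(state[[9L]], 0)
  A <- max(state[[10L]], 0)

  Cl <- max(C, 1)
  acc <- C / (1 + C^(1 / 3) / p$l1)
  treg <- (1 + p$e1 * R) / (1 + p$d1 * ua^2 * R^3)

  dC <- p$a1 * C * log(p$Cmax / Cl) -
    p$b1 * N * acc -
    (p$c1 * T * acc) / (treg * (1 + p$f1 * S)) -
    (if (u5 > 0) p$g1 * C else 0) -
    p$h1 * log1p(p$k1 * sgn * A) * C / (C + 1)
  if (state[[1L]] <= 0 && dC < 0) dC <- 0

  dN <- p$a2 - p$b2 * N +
    p$c2 * I * N / (p$d2 + I) +
    p$e2 * Fc * N / (p$f2 + Fc) -
    p$g2 * N * acc - p$h2 * R * N

  dT <- -p$a3 * T +
    p$b3 * T * C^2 / (p$c3 + C^2) +
    p$d3 * N * acc * ((1 - p$m3) / (1 + p$n3 * (M - p$p3)^2) + p$m3) -
    p$e3 * T * acc +
    p$f3 * I * T / (p$g3 + I) +
    p$h3 * Fc * T / (p$k3 + Fc) -
    p$l3 * R * T

  dM <- p$a4 - (if (u5 > 0) p$b4_5fu else p$b4_normal) * M +
    p$c4 * C / (p$d4 + C)

  dH <- p$a5 - p$b5 * H +
    p$c5 * I * H / (p$d5 + I) +
    p$e5 * Fc * H / (p$f5 + Fc) -
    p$g5 * R * H

  dR <- p$a6 - p$b6 * R + p$c6 * T + p$d6 * H +
    p$e6 * I * R / (p$f6 + I) -
    p$g6 * N * R - p$h6 * ua * R

  dI <- r$alpha1 * H - r$tau1 * I
  dF <- r$beta1 * T + r$beta2 * N + r$beta3 * H - r$tau2 * Fc
  dS <- r$lambda1 * C - r$tau3 * S

  c(C = dC, N = dN, T = dT, M = dM, H = dH, R = dR,
    I = dI, F = dF, S = dS, A = ua * C)
}

# Segment signals: piecewise-constant forcing evaluated at segment midpoints.
.segment_signals <- function(schedule, breaks) {
  mids <- (breaks[-length(breaks)] + breaks[-1L]) / 2
  list(u5 = as.numeric(drug_signal(schedule, "fivefu", mids)),
       ua = as.numeric(drug_signal(schedule, "anticd25", mids)),
       sgn = as.numeric(length(schedule$anticd25_days) > 0))
}

#' Simulate the simplified tumor-immune system model
#'
#' Integrates the six-equation model (plus the cumulative anti-CD25 exposure)
#' with a stiff-capable adaptive method (`deSolve::lsoda`, rtol 1e-8, atol
#' 1e-6 cells). The integrator is restarted at every treatment-window
#' boundary so the discontinuous forcing is resolved exactly; within a
#' segment the drug signals are constant. Non-negativity is enforced on the
#' returned grid; tumor volume uses 1e-6 mm^3 per cell.
#'
#' @param initial named state vector from [tis_initial_state()].
#' @param params a [tis_parameters()] object.
#' @param schedule a [tis_schedule()].
#' @param t_end simulation end time (day), > 0.
#' @param grid_step output grid spacing (day), > 0.
#' @param rtol,atol integrator tolerances.
#' @return A data frame of class `tis_trajectory` with columns `time`, the
#'   states `C`, `N`, `T`, `M`, `H`, `R`, `A`, the quasi-steady-state
#'   cytokines `I`, `F`, `S`, and `volume_mm3`; the schedule and parameters
#'   are attached as attributes.
#' @examples
#' tr <- tis_simulate(t_end = 25, grid_step = 1)
#' tail(tr[, c("time", "C", "volume_mm3")], 3)
#' @export
tis_simulate <- function(initial = tis_initial_state(),
                         params = tis_parameters(),
                         schedule = tis_schedule(),
                         t_end = 100, grid_step = 0.1,
                         rtol = 1e-8, atol = 1e-6) {
  params <- validate_tis_parameters(params)
  stopifnot(inherits(schedule, "tis_schedule"))
  if (!is.numeric(t_end) || t_end <= 0) stop("t_end must be positive")
  if (!is.numeric(grid_step) || grid_step <= 0) stop("grid_step must be positive")
  if (length(initial) != 7L || any(!is.finite(initial)) || any(initial < 0)) {
    stop("initial must be a non-negative 7-component state vector")
  }

  grid <- seq(0, t_end, by = grid_step)
  if (grid[length(grid)] < t_end) grid <- c(grid, t_end)
  breaks <- .schedule_breaks(schedule, t_end)
  sig <- .segment_signals(schedule, breaks)
  pvec <- .tis_param_vector(params)
  # the exposure state A is orders of magnitude larger than the cell counts
  # (it integrates signal x cells); give it a matching absolute tolerance
  atol_vec <- c(rep(atol, 6L), max(atol, 1e8))

  y <- unname(initial)
  rows <- matrix(NA_real_, nrow = length(grid), ncol = 7L)
  rows[1L, ] <- y
  filled <- 1L

  for (i in seq_len(length(breaks) - 1L)) {
    t0 <- breaks[i]; t1 <- breaks[i + 1L]
    seg_grid <- grid[grid > t0 & grid <= t1]
    times <- unique(c(t0, seg_grid, t1))
    parms <- c(pvec, u5 = sig$u5[i], ua = sig$ua[i], sgn = sig$sgn)
    out <- tryCatch(
      deSolve::lsoda(y = y, times = times, parms = parms,
                     func = "tis_derivs", initfunc = "tis_initmod",
                     dllname = "tisim", rtol = rtol, atol = atol_vec,
                     maxsteps = 50000),
      error = function(e) e)
    if (inherits(out, "error") || nrow(out) < length(times)) {
      stop(sprintf("integration failed in segment [%.4g, %.4g]; last valid time %.4g",
                   t0, t1, if (inherits(out, "error")) t0 else out[nrow(out), 1L]))
    }
    keep <- out[, 1L] %in% seg_grid
    if (any(keep)) {
      n_new <- sum(keep)
      rows[filled + seq_len(n_new), ] <- pmax(out[keep, -1L, drop = FALSE], 0)
      filled <- filled + n_new
    }
    y <- pmax(out[nrow(out), -1L], 0)
  }

  colnames(rows) <- c("C", "N", "T", "M", "H", "R", "A")
  cyt <- cbind(
    I = rows[, "H"] / params$ratio_tau1_alpha1,
    F = params$ratio_beta1_tau2 * rows[, "T"] +
        params$ratio_beta2_tau2 * rows[, "N"] +
        params$ratio_beta3_tau2 * rows[, "H"],
    S = params$ratio_lambda1_tau3 * rows[, "C"])
  traj <- data.frame(time = grid, rows, cyt,
                     volume_mm3 = rows[, "C"] * 1e-6)
  attr(traj, "schedule") <- schedule
  attr(traj, "params") <- params
  class(traj) <- c("tis_trajectory", "data.frame")
  traj
}

#' Simulate the full nine-equation model
#'
#' Integrates the parent model with explicit cytokine dynamics. Mainly used
#' to verify that the simplified model is the fast-cytokine limit of the full
#' one; the cytokine decay rates set the separation of time scales.
#'
#' @inheritParams tis_simulate
#' @param initial named 10-component state `c(C, N, T, M, H, R, I, F, S, A)`;
#'   by default the standard cell state with cytokines at quasi-steady state.
#' @param absolute_rates list from [tis_absolute_rates()].
#' @return A data frame with columns `time`, states, and `volume_mm3`.
#' @export
tis_simulate_full <- function(initial = NULL,
                              params = tis_parameters(),
                              absolute_rates = tis_absolute_rates(params),
                              schedule = tis_schedule(),
                              t_end = 100, grid_step = 0.1,
                              rtol = 1e-8, atol = 1e-6) {
  params <- validate_tis_parameters(params)
  .check_rates(params, absolute_rates)
  if (is.null(initial)) {
    y0 <- tis_initial_state()
    cyt <- qss_cytokines(y0, params)
    initial <- c(y0[c("C", "N", "T", "M", "H", "R")], cyt, A = 0)
  }
  if (length(initial) != 10L || any(!is.finite(initial)) || any(initial < 0)) {
    stop("initial must be a non-negative 10-component state vector")
  }
  grid <- seq(0, t_end, by = grid_step)
  if (grid[length(grid)] < t_end) grid <- c(grid, t_end)
  breaks <- .schedule_breaks(schedule, t_end)
  sig <- .segment_signals(schedule, breaks)
  # cell states, then ng/ml-scale cytokines, then the large exposure state
  atol_vec <- c(rep(atol, 6L), rep(min(atol, 1e-12), 3L), max(atol, 1e8))

  y <- unname(initial)
  res <- matrix(NA_real_, nrow = length(grid), ncol = 10L)
  res[1L, ] <- y
  filled <- 1L
  for (i in seq_len(length(breaks) - 1L)) {
    t0 <- breaks[i]; t1 <- breaks[i + 1L]
    seg_grid <- grid[grid > t0 & grid <= t1]
    times <- unique(c(t0, seg_grid, t1))
    fn <- local({
      u5 <- sig$u5[i]; ua <- sig$ua[i]; sgn <- sig$sgn
      function(t, y, parms) {
        list(unname(.full_rhs_num(y, params, absolute_rates, u5, ua, sgn)))
      }
    })
    out <- deSolve::lsoda(y = y, times = times, func = fn, parms = NULL,
                          rtol = rtol, atol = atol_vec, maxsteps = 50000)
    if (nrow(out) < length(times)) {
      stop(sprintf("integration failed in segment [%.4g, %.4g]", t0, t1))
    }
    keep <- out[, 1L] %in% seg_grid
    if (any(keep)) {
      n_new <- sum(keep)
      res[filled + seq_len(n_new), ] <- pmax(out[keep, -1L, drop = FALSE], 0)
      filled <- filled + n_new
    }
    y <- pmax(out[nrow(out), -1L], 0)
  }
  colnames(res) <- c("C", "N", "T", "M", "H", "R", "I", "F", "S", "A")
  data.frame(time = grid, res, volume_mm3 = res[, "C"] * 1e-6)
}

#' @export
print.tis_trajectory <- function(x, ...) {
  cat(sprintf("<tis_trajectory> %d time points over [%g, %g] days\n",
              nrow(x), x$time[1L], x$time[nrow(x)]))
  cat(sprintf("  final tumor burden: %.4g cells (%.4g mm^3)\n",
              x$C[nrow(x)], x$volume_mm3[nrow(x)]))
  invisible(x)
}
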