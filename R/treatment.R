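# Treatment efficacy, tumor-growth-inhibition curves, and Bliss synergy.

#' Treatment efficacy
#'
#' Relative tumor reduction at one time point:
#' `(C_control - C_treated) / C_control`. Zero when the treated arm equals
#' the control arm, one at eradication, negative if treatment worsens the
#' outcome.
#'
#' @param C_control tumor population of the untreated arm (> 0).
#' @param C_treated tumor population of the treated arm.
#' @return Dimensionless efficacy (vectorized).
#' @examples
#' efficacy(1e8, 2.5e7)  # 0.75
#' @export
efficacy <- function(C_control, C_treated) {
  if (any(C_control <= 0)) stop("C_control must be strictly positive")
  (C_control - C_treated) / C_control
}

#' Bliss combination index
#'
#' Compares the observed combination efficacy with the Bliss-independence
#' expectation of the two single-agent efficacies:
#' `CI = (E_a + E_5 - E_a*E_5) / E_comb`. CI < 1 indicates synergy, CI = 1
#' additivity, CI > 1 antagonism. When the combination has no effect
#' (`E_comb <= 0`) the index is undefined and reported as `NA`.
#'
#' @param E_a efficacy of anti-CD25 alone.
#' @param E_5 efficacy of 5-FU alone.
#' @param E_comb efficacy of the combination.
#' @return CI values (vectorized), `NA` where undefined.
#' @examples
#' bliss_ci(0.5, 0.5, 0.75)  # exactly additive -> 1
#' bliss_ci(0.5, 0.5, 1.0)   # synergy -> 0.75
#' @export
bliss_ci <- function(E_a, E_5, E_comb) {
  ci <- (E_a + E_5 - E_a * E_5) / E_comb
  ci[E_comb <= 0] <- NA_real_
  ci
}

.ci_class <- function(ci, tol = 1e-6) {
  cls <- rep(NA_character_, length(ci))
  ok <- !is.na(ci)
  cls[ok & abs(ci - 1) <= tol] <- "additive"
  cls[ok & ci < 1 - tol] <- "synergistic"
  cls[ok & ci > 1 + tol] <- "antagonistic"
  cls
}

# Running time-average by trapezoid rule; equals the instantaneous value at
# the first grid point.
.running_average <- function(t, x) {
  n <- length(t)
  if (n == 1L) return(x)
  cum <- c(0, cumsum(diff(t) * (x[-1L] + x[-n]) / 2))
  avg <- x
  pos <- t > t[1L]
  avg[pos] <- cum[pos] / (t[pos] - t[1L])
  avg
}

#' Inhibition and Bliss combination-index curves
#'
#' Simulates four arms sharing the initial state and parameters — control,
#' 5-FU alone, anti-CD25 alone, and their combination — and derives the
#' tumor-growth-inhibition percentage of each treated arm together with the
#' Bliss combination index, using both the instantaneous tumor size
#' (`ci_inst`) and the running time-average tumor size from treatment start
#' (`ci_ave`, trapezoid rule) as outcomes.
#'
#' @param params a [tis_parameters()] object.
#' @param sched_5fu schedule of the 5-FU monotherapy arm.
#' @param sched_cd25 schedule of the anti-CD25 monotherapy arm.
#' @param initial shared initial state.
#' @param t_end simulation horizon (day).
#' @param grid_step output grid spacing (day).
#' @return A data frame of class `tis_synergy` with columns `time`,
#'   `inh_5fu_pct`, `inh_cd25_pct`, `inh_comb_pct`, `ci_inst`, `ci_ave`,
#'   `class` (classification of `ci_inst`: synergistic / additive /
#'   antagonistic, `NA` where CI is undefined). The four arm trajectories are
#'   attached as the `trajectories` attribute.
#' @examples
#' \donttest{
#' syn <- tis_synergy(t_end = 30, grid_step = 0.5)
#' syn[syn$time == 25, ]
#' }
#' @export
tis_synergy <- function(params = tis_parameters(),
                        sched_5fu = tis_schedule(fivefu_days = 1:4),
                        sched_cd25 = tis_schedule(anticd25_days = c(3, 6, 10, 13, 17, 20)),
                        initial = tis_initial_state(),
                        t_end = 100, grid_step = 0.5) {
  comb <- tis_schedule(
    fivefu_days = sched_5fu$fivefu_days,
    anticd25_days = sched_cd25$anticd25_days,
    fivefu_effect_days = sched_5fu$fivefu_effect_days,
    anticd25_effect_days = sched_cd25$anticd25_effect_days,
    fivefu_amplitude = sched_5fu$fivefu_amplitude,
    anticd25_amplitude = sched_cd25$anticd25_amplitude)
  arms <- list(
    control = tis_schedule(),
    fivefu = sched_5fu,
    anticd25 = sched_cd25,
    comb = comb)
  tr <- lapply(arms, function(s) {
    tis_simulate(initial = initial, params = params, schedule = s,
                 t_end = t_end, grid_step = grid_step)
  })

  t <- tr$control$time
  Cc <- tr$control$C
  E5 <- efficacy(Cc, tr$fivefu$C)
  Ea <- efficacy(Cc, tr$anticd25$C)
  Ec <- efficacy(Cc, tr$comb$C)

  t0 <- min(c(sched_5fu$fivefu_days, sched_cd25$anticd25_days, 0))
  avg <- lapply(tr, function(x) .running_average(t, x$C))
  E5a <- efficacy(avg$control, avg$fivefu)
  Eaa <- efficacy(avg$control, avg$anticd25)
  Eca <- efficacy(avg$control, avg$comb)

  ci_inst <- bliss_ci(Ea, E5, Ec)
  ci_ave <- bliss_ci(Eaa, E5a, Eca)

  out <- data.frame(time = t,
                    inh_5fu_pct = 100 * E5,
                    inh_cd25_pct = 100 * Ea,
                    inh_comb_pct = 100 * Ec,
                    ci_inst = ci_inst,
                    ci_ave = ci_ave,
                    class = .ci_class(ci_inst))
  attr(out, "trajectories") <- tr
  class(out) <- c("tis_synergy", "data.frame")
  out
}
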