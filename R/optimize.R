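# GA optimization of 5-FU / anti-CD25 injection timings.

#' Bounds of the schedule search space
#'
#' @param n_5fu number of 5-FU doses (default 4).
#' @param n_cd25 number of anti-CD25 doses (default 6).
#' @param day_min,day_max earliest / latest allowed injection day; doses are
#'   given before day 20 to pre-empt the Treg/MDSC-mediated regrowth window.
#' @param max_per_day maximum doses of one drug on a single day (default 2,
#'   the toxicity cap); stacked doses add their signal amplitudes.
#' @return An object of class `tis_schedule_bounds`.
#' @export
tis_schedule_bounds <- function(n_5fu = 4, n_cd25 = 6, day_min = 1,
                                day_max = 20, max_per_day = 2) {
  stopifnot(n_5fu >= 1, n_cd25 >= 1, day_min <= day_max, max_per_day >= 1)
  n_slots <- (day_max - day_min + 1) * max_per_day
  if (n_5fu > n_slots || n_cd25 > n_slots) {
    stop("infeasible bounds: dose count exceeds available day slots")
  }
  structure(list(n_5fu = n_5fu, n_cd25 = n_cd25, day_min = day_min,
                 day_max = day_max, max_per_day = max_per_day),
            class = "tis_schedule_bounds")
}

#' Three-arm normalized tumor-burden cost
#'
#' The schedule-optimization objective: the mean over N sample times and the
#' three treated arms of the squared ratio of treated to control tumor
#' population, `cost = (1/(3N)) * sum((C_5F/C_ctrl)^2 + (C_CD/C_ctrl)^2 +
#' (C_comb/C_ctrl)^2)`. Equal to 1 when no treatment has any effect and 0
#' when all treated arms are eradicated at every sample.
#'
#' @param C_ctrl,C_5fu,C_cd25,C_comb tumor populations of the four arms at
#'   the same N sample times.
#' @return Dimensionless cost.
#' @export
schedule_cost <- function(C_ctrl, C_5fu, C_cd25, C_comb) {
  n <- length(C_ctrl)
  if (n < 1L || length(C_5fu) != n || length(C_cd25) != n ||
      length(C_comb) != n) {
    stop("all four series must have equal positive length")
  }
  if (any(C_ctrl <= 0)) stop("control population must be positive at every sample")
  sum((C_5fu / C_ctrl)^2 + (C_cd25 / C_ctrl)^2 + (C_comb / C_ctrl)^2) / (3 * n)
}

#' Optimize injection timings by genetic algorithm
#'
#' Searches over integer injection-day vectors for both drugs (jointly),
#' simulating for each candidate the three treated arms plus a shared
#' control arm and minimizing [schedule_cost()] sampled on an even time grid.
#' Day multisets are canonicalized sorted; at most `max_per_day` doses of a
#' drug may share a day, and doses sharing a day stack their signal.
#' Deterministic given `seed`; the best-ever candidate is returned.
#'
#' @param params a [tis_parameters()] object.
#' @param bounds a [tis_schedule_bounds()].
#' @param initial shared initial state.
#' @param t_end simulation horizon (day).
#' @param n_samples number of cost sample times, evenly spaced on
#'   `(0, t_end]`.
#' @param ga list of GA settings: `pop`, `generations`, `pcross`, `pmut`.
#' @param seed integer seed for the GA.
#' @param schedule_template a [tis_schedule()] providing effect durations and
#'   amplitudes for the candidate schedules.
#' @return An object of class `tis_optimization_result`: list with `t_5fu`,
#'   `t_cd25` (optimal day vectors), `cost`, `inhibition_pct` (final-day
#'   tumor-growth inhibition per arm), `trajectories` at the optimum, `trace`
#'   and `seed`.
#' @export
optimize_schedules <- function(params = tis_parameters(),
                               bounds = tis_schedule_bounds(),
                               initial = tis_initial_state(),
                               t_end = 100, n_samples = 100,
                               ga = list(), seed = 1,
                               schedule_template = tis_schedule()) {
  stopifnot(inherits(bounds, "tis_schedule_bounds"))
  ga_def <- list(pop = 40, generations = 80, pcross = 0.9, pmut = 0.15)
  ga_def[names(ga)] <- ga
  sample_t <- seq(t_end / n_samples, t_end, length.out = n_samples)

  mk_sched <- function(f_days, a_days) {
    tis_schedule(fivefu_days = f_days, anticd25_days = a_days,
                 fivefu_effect_days = schedule_template$fivefu_effect_days,
                 anticd25_effect_days = schedule_template$anticd25_effect_days,
                 fivefu_amplitude = schedule_template$fivefu_amplitude,
                 anticd25_amplitude = schedule_template$anticd25_amplitude)
  }
  simC <- function(sched) {
    tr <- tis_simulate(initial = initial, params = params, schedule = sched,
                       t_end = t_end, grid_step = t_end / n_samples)
    stats::approx(tr$time, tr$C, xout = sample_t)$y
  }
  C_ctrl <- simC(tis_schedule())

  n1 <- bounds$n_5fu
  fitness <- function(g) {
    f_days <- g[seq_len(n1)]
    a_days <- g[-seq_len(n1)]
    schedule_cost(C_ctrl,
                  simC(mk_sched(f_days, numeric(0))),
                  simC(mk_sched(numeric(0), a_days)),
                  simC(mk_sched(f_days, a_days)))
  }

  # seed the population with the calibrated experimental schedule whenever
  # the bounds admit it, so the optimum can never lose to the hand-picked
  # baseline
  init <- NULL
  base_f <- 1:4; base_a <- c(3, 6, 10, 13, 17, 20)
  if (bounds$n_5fu == length(base_f) && bounds$n_cd25 == length(base_a) &&
      all(c(base_f, base_a) >= bounds$day_min) &&
      all(c(base_f, base_a) <= bounds$day_max)) {
    init <- matrix(c(base_f, base_a), nrow = 1L)
  }

  if (!is.null(seed)) set.seed(seed)
  res <- .ga_integer(fitness,
                     genome_lengths = c(t_5fu = bounds$n_5fu,
                                        t_cd25 = bounds$n_cd25),
                     day_min = bounds$day_min, day_max = bounds$day_max,
                     cap = bounds$max_per_day,
                     pop = ga_def$pop, generations = ga_def$generations,
                     pcross = ga_def$pcross, pmut = ga_def$pmut,
                     init = init)

  t_5fu <- res$par$t_5fu; t_cd25 <- res$par$t_cd25
  arms <- list(control = tis_schedule(),
               fivefu = mk_sched(t_5fu, numeric(0)),
               anticd25 = mk_sched(numeric(0), t_cd25),
               comb = mk_sched(t_5fu, t_cd25))
  trajs <- lapply(arms, function(s) {
    tis_simulate(initial = initial, params = params, schedule = s,
                 t_end = t_end, grid_step = t_end / n_samples)
  })
  C_end <- vapply(trajs, function(tr) tr$C[nrow(tr)], numeric(1))
  inh <- 100 * (C_end[["control"]] - C_end[-1L]) / C_end[["control"]]

  structure(list(t_5fu = t_5fu, t_cd25 = t_cd25, cost = res$value,
                 inhibition_pct = inh, trajectories = trajs,
                 trace = res$trace, n_evaluated = res$n_evaluated,
                 seed = seed),
            class = "tis_optimization_result")
}

#' @export
print.tis_optimization_result <- function(x, ...) {
  cat("<tis_optimization_result>\n")
  cat("  5-FU days:      ", paste(x$t_5fu, collapse = ", "), "\n")
  cat("  anti-CD25 days: ", paste(x$t_cd25, collapse = ", "), "\n")
  cat(sprintf("  cost: %.6g\n", x$cost))
  cat(sprintf("  final inhibition (%%): 5-FU %.2f, anti-CD25 %.2f, combination %.2f\n",
              x$inhibition_pct[["fivefu"]], x$inhibition_pct[["anticd25"]],
              x$inhibition_pct[["comb"]]))
  invisible(x)
}
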