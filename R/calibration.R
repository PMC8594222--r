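# Goodness of fit, synthetic observations, and GA parameter estimation.

#' Tumor-volume observation series
#'
#' Container for (time, tumor volume) measurements of one experimental arm,
#' as used by the NRMSE fit: control, 5-FU and anti-CD25 arms with tumor
#' volume recorded at a handful of days.
#'
#' @param times measurement days, strictly increasing, at least 2.
#' @param volumes tumor volumes (mm^3), strictly positive.
#' @param arm arm label: `"control"`, `"fivefu"` or `"anticd25"`.
#' @return An object of class `tis_observations`.
#' @export
tis_observations <- function(times, volumes,
                             arm = c("control", "fivefu", "anticd25")) {
  arm <- match.arg(arm)
  times <- as.numeric(times); volumes <- as.numeric(volumes)
  if (length(times) < 2L) stop("at least 2 observation points required")
  if (length(times) != length(volumes)) stop("times and volumes differ in length")
  if (any(diff(times) <= 0)) stop("observation times must be strictly increasing")
  if (any(!is.finite(volumes)) || any(volumes <= 0)) {
    stop("volumes must be finite and strictly positive")
  }
  structure(list(times = times, volumes = volumes, arm = arm),
            class = "tis_observations")
}

#' Normalized root-mean-square error
#'
#' The calibration cost: the square root of the sum of squared residuals over
#' all points, normalized by the square of the first observation:
#' `sqrt(sum((T_i - That_i)^2) / T_1^2)`.
#'
#' @param observed a [tis_observations()] object or numeric vector of
#'   observed volumes.
#' @param predicted numeric vector of model-predicted volumes at the same
#'   time points.
#' @return Non-negative dimensionless error.
#' @examples
#' nrmse(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 6))  # sqrt(1 / 1^2) = 1
#' @export
nrmse <- function(observed, predicted) {
  obs <- if (inherits(observed, "tis_observations")) observed$volumes else observed
  if (length(obs) != length(predicted)) {
    stop("observed and predicted must have equal length")
  }
  if (obs[1L] == 0) stop("first observation must be nonzero")
  sqrt(sum((obs - predicted)^2) / obs[1L]^2)
}

#' Generate synthetic tumor-volume observations
#'
#' Simulates the model under a schedule and perturbs the volumes at the
#' requested days with independent multiplicative log-normal noise
#' (`volume * exp(eps)`, `eps ~ Normal(0, noise_cv)`). Stands in for in vivo
#' tumor-size series in calibration studies; with `noise_cv = 0` the series
#' is the exact model prediction.
#'
#' @param params a [tis_parameters()] object (the generating truth).
#' @param schedule a [tis_schedule()].
#' @param times measurement days.
#' @param noise_cv standard deviation of the log-scale noise (roughly the
#'   coefficient of variation for small values).
#' @param seed integer seed; the series is reproducible given the seed.
#' @param initial initial state, default [tis_initial_state()].
#' @param arm arm label recorded in the result.
#' @return A [tis_observations()] object.
#' @export
generate_synthetic_observations <- function(params, schedule, times,
                                            noise_cv = 0.05, seed = 1,
                                            initial = tis_initial_state(),
                                            arm = c("control", "fivefu",
                                                    "anticd25")) {
  arm <- match.arg(arm)
  if (noise_cv < 0) stop("noise_cv must be non-negative")
  if (any(times < 0)) stop("observation times must lie in [0, t_end]")
  t_end <- max(times)
  tr <- tis_simulate(initial = initial, params = params, schedule = schedule,
                     t_end = t_end, grid_step = min(0.25, min(diff(c(0, times)))))
  vol <- stats::approx(tr$time, tr$volume_mm3, xout = times)$y
  if (noise_cv > 0) {
    if (!is.null(seed)) set.seed(seed)
    vol <- vol * exp(stats::rnorm(length(times), mean = 0, sd = noise_cv))
  }
  tis_observations(times, vol, arm)
}

#' Define a parameter-estimation problem
#'
#' Bundles the free parameters with box bounds, the fixed base parameter set,
#' the fitted experimental arms (observations + schedule + initial state),
#' and the GA settings. The staged calibration protocol fits the control arm
#' first (growth rate), then the 5-FU arm (`g1`, `b4_5fu`) with the control
#' estimates frozen, then the anti-CD25 arm (`d1`, `h1`, `k1`, `h6`).
#'
#' @param free named list mapping each free parameter name to `c(lower,
#'   upper)` bounds (finite, lower < upper).
#' @param base the fixed [tis_parameters()] base set.
#' @param arms list of arms; each arm is a list with elements `observations`
#'   (a [tis_observations()]), `schedule` (a [tis_schedule()]) and optionally
#'   `initial`.
#' @param ga list of GA settings: `pop`, `generations`, `pcross`, `pmut`,
#'   `seed`.
#' @return An object of class `tis_fit_problem`.
#' @export
tis_fit_problem <- function(free, base = tis_parameters(), arms,
                            ga = list()) {
  base <- validate_tis_parameters(base)
  if (length(free)) {
    if (is.null(names(free))) stop("free must be a named list of bounds")
    unknown <- setdiff(names(free), .tis_param_names)
    if (length(unknown)) {
      stop("free parameter(s) not in the model: ", paste(unknown, collapse = ", "))
    }
    for (nm in names(free)) {
      b <- free[[nm]]
      if (length(b) != 2L || any(!is.finite(b)) || b[1L] >= b[2L] || b[1L] <= 0) {
        stop("bounds for '", nm, "' must be finite positive with lower < upper")
      }
    }
  }
  for (arm in arms) {
    stopifnot(inherits(arm$observations, "tis_observations"),
              inherits(arm$schedule, "tis_schedule"))
  }
  ga_def <- list(pop = 60, generations = 120, pcross = 0.9, pmut = 0.1,
                 seed = 1)
  ga_def[names(ga)] <- ga
  structure(list(free = free, base = base, arms = arms, ga = ga_def),
            class = "tis_fit_problem")
}

#' Estimate model parameters by genetic algorithm
#'
#' Minimizes the summed per-arm NRMSE between simulated and observed tumor
#' volumes over the free-parameter box (searched on log scale) with an
#' elitist real-coded GA. Deterministic given the seed in the problem's GA
#' settings. With no free parameters the base set and its NRMSE are returned
#' unchanged.
#'
#' @param problem a [tis_fit_problem()].
#' @return An object of class `tis_fit_result`: list with `estimates` (named
#'   vector), `params` (full parameter set with estimates substituted),
#'   `nrmse` (per arm), `total_nrmse`, `trace` (best cost per generation) and
#'   `seed`.
#' @export
fit_parameters <- function(problem) {
  stopifnot(inherits(problem, "tis_fit_problem"))
  free_names <- names(problem$free)

  arm_nrmse <- function(params) {
    vapply(problem$arms, function(arm) {
      obs <- arm$observations
      init <- if (is.null(arm$initial)) tis_initial_state() else arm$initial
      tr <- tis_simulate(initial = init, params = params,
                         schedule = arm$schedule, t_end = max(obs$times),
                         grid_step = 0.25)
      pred <- stats::approx(tr$time, tr$volume_mm3, xout = obs$times)$y
      nrmse(obs, pred)
    }, numeric(1))
  }

  if (!length(free_names)) {
    per_arm <- arm_nrmse(problem$base)
    return(structure(list(estimates = numeric(0), params = problem$base,
                          nrmse = per_arm, total_nrmse = sum(per_arm),
                          trace = sum(per_arm), seed = problem$ga$seed),
                     class = "tis_fit_result"))
  }

  lower <- vapply(problem$free, `[`, numeric(1), 1L)
  upper <- vapply(problem$free, `[`, numeric(1), 2L)
  objective <- function(x) {
    p <- problem$base
    p[free_names] <- as.list(x)
    sum(arm_nrmse(p))
  }

  if (!is.null(problem$ga$seed)) set.seed(problem$ga$seed)
  res <- .ga_real(objective, lower, upper,
                  pop = problem$ga$pop, generations = problem$ga$generations,
                  pcross = problem$ga$pcross, pmut = problem$ga$pmut)
  if (!is.finite(res$value)) {
    stop("no feasible candidate: every simulation in the search failed")
  }
  est <- stats::setNames(res$par, free_names)
  params <- problem$base
  params[free_names] <- as.list(est)
  structure(list(estimates = est, params = params,
                 nrmse = arm_nrmse(params), total_nrmse = res$value,
                 trace = res$trace, seed = problem$ga$seed),
            class = "tis_fit_result")
}

#' @export
print.tis_fit_result <- function(x, ...) {
  cat("<tis_fit_result>\n")
  if (length(x$estimates)) {
    for (nm in names(x$estimates)) {
      cat(sprintf("  %-10s = %.6g\n", nm, x$estimates[[nm]]))
    }
  } else {
    cat("  (no free parameters)\n")
  }
  cat(sprintf("  NRMSE: %s (total %.4g)\n",
              paste(sprintf("%.4g", x$nrmse), collapse = ", "),
              x$total_nrmse))
  invisible(x)
}

#' Default observation days of the calibration experiments
#'
#' Control and 5-FU arms were recorded on days 5, 10, 15, 20, 25 after tumor
#' inoculation; the anti-CD25 arm on days 7, 14, 21, 28, 35.
#'
#' @param arm arm label.
#' @return Numeric vector of recording days.
#' @export
tis_record_days <- function(arm = c("control", "fivefu", "anticd25")) {
  arm <- match.arg(arm)
  if (arm == "anticd25") c(7, 14, 21, 28, 35) else c(5, 10, 15, 20, 25)
}
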