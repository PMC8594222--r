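# Configuration and result serialization: JSON parameter sets and schedules,
# CSV trajectories and observations, and the experiment dispatcher behind the
# command-line interface.

#' Load a parameter set from JSON
#'
#' Reads a JSON document keyed by parameter symbol names; missing keys are
#' filled from the calibrated defaults and the full invariants are validated.
#' A save/load round trip is lossless.
#'
#' @param path JSON file path.
#' @return A [tis_parameters()] object.
#' @export
load_parameters <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path),
                  error = function(e) stop("malformed JSON in '", path, "': ",
                                           conditionMessage(e)))
  if (length(doc) == 0L) return(tis_parameters())
  if (is.null(names(doc))) stop("parameter document must be a JSON object")
  do.call(tis_parameters, as.list(doc))
}

#' Save a parameter set to JSON
#'
#' @param params a [tis_parameters()] object.
#' @param path output file path.
#' @export
save_parameters <- function(params, path) {
  params <- validate_tis_parameters(params)
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load a treatment schedule from JSON
#'
#' The document may contain `fivefu_days`, `anticd25_days` (arrays of days)
#' and the effect-duration and amplitude fields of [tis_schedule()]; missing
#' fields take the defaults.
#'
#' @param path JSON file path.
#' @return A [tis_schedule()] object.
#' @export
load_schedule <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path),
                  error = function(e) stop("malformed JSON in '", path, "': ",
                                           conditionMessage(e)))
  allowed <- c("fivefu_days", "anticd25_days", "fivefu_effect_days",
               "anticd25_effect_days", "fivefu_amplitude",
               "anticd25_amplitude")
  unknown <- setdiff(names(doc), allowed)
  if (length(unknown)) {
    stop("unknown schedule field(s): ", paste(unknown, collapse = ", "))
  }
  do.call(tis_schedule, as.list(doc))
}

#' Save a treatment schedule to JSON
#'
#' @param schedule a [tis_schedule()] object.
#' @param path output file path.
#' @export
save_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "tis_schedule"))
  jsonlite::write_json(unclass(schedule), path, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a trajectory to CSV
#'
#' Columns: `time_day`, the states `C`, `N`, `T`, `M`, `H`, `R`, the
#' cytokines `I`, `F`, `S`, and `volume_mm3`.
#'
#' @param trajectory a [tis_simulate()] result.
#' @param path output CSV path.
#' @export
write_trajectory <- function(trajectory, path) {
  df <- as.data.frame(trajectory)
  out <- df[, c("time", "C", "N", "T", "M", "H", "R", "I", "F", "S",
                "volume_mm3")]
  names(out)[1L] <- "time_day"
  utils::write.csv(format(out, digits = 17, trim = TRUE, scientific = NA),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write observation series to CSV
#'
#' Columns `arm`, `time_day`, `volume_mm3`; several arms may be concatenated.
#'
#' @param observations a [tis_observations()] or list of them.
#' @param path output CSV path.
#' @export
write_observations <- function(observations, path) {
  if (inherits(observations, "tis_observations")) {
    observations <- list(observations)
  }
  df <- do.call(rbind, lapply(observations, function(o) {
    data.frame(arm = o$arm, time_day = o$times, volume_mm3 = o$volumes)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read observation series from CSV
#'
#' @param path CSV with columns `arm`, `time_day`, `volume_mm3`.
#' @return Named list of [tis_observations()], one per arm.
#' @export
read_observations <- function(path) {
  df <- utils::read.csv(path)
  need <- c("arm", "time_day", "volume_mm3")
  if (!all(need %in% names(df))) {
    stop("observation CSV must have columns ", paste(need, collapse = ", "))
  }
  arms <- split(df, df$arm)
  lapply(arms, function(a) {
    a <- a[order(a$time_day), ]
    tis_observations(a$time_day, a$volume_mm3, arm = a$arm[1L])
  })
}

#' Run one of the standard experiments
#'
#' Dispatches a named experiment to the owning module and writes its outputs
#' (CSV/JSON) plus a run manifest (command, seed, configuration echo) into
#' `out_dir`. This is the programmatic surface behind the command-line
#' script in `inst/cli/tisim.R`.
#'
#' @param command one of `"simulate"`, `"synergy"`, `"optimize"`, `"fuzzy"`,
#'   `"gsa"`, `"generate-data"`, `"fit"`.
#' @param config named list of experiment settings; unset fields take the
#'   defaults of the underlying functions. Common fields: `params` (a
#'   `tis_parameters` or JSON path), `schedule` (a `tis_schedule` or JSON
#'   path), `t_end`, `grid_step`, plus per-command fields documented in the
#'   underlying functions.
#' @param out_dir output directory (created if missing).
#' @param seed integer seed applied to every stochastic step.
#' @return Invisibly, a named list of the paths written.
#' @export
run_experiment <- function(command = c("simulate", "synergy", "optimize",
                                       "fuzzy", "gsa", "generate-data",
                                       "fit"),
                           config = list(), out_dir = ".", seed = 1) {
  command <- match.arg(command)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  getp <- function() {
    p <- config$params
    if (is.null(p)) tis_parameters()
    else if (is.character(p)) load_parameters(p)
    else validate_tis_parameters(p)
  }
  gets <- function(field = "schedule", default = tis_schedule()) {
    s <- config[[field]]
    if (is.null(s)) default
    else if (is.character(s)) load_schedule(s)
    else s
  }
  t_end <- if (is.null(config$t_end)) 100 else config$t_end
  grid_step <- if (is.null(config$grid_step)) 0.5 else config$grid_step
  written <- list()

  if (command == "simulate") {
    tr <- tis_simulate(params = getp(), schedule = gets(),
                       t_end = t_end, grid_step = grid_step)
    written$trajectory <- file.path(out_dir, "trajectory.csv")
    write_trajectory(tr, written$trajectory)
  } else if (command == "synergy") {
    syn <- tis_synergy(params = getp(),
                       sched_5fu = gets("sched_5fu",
                                        tis_schedule(fivefu_days = 1:4)),
                       sched_cd25 = gets("sched_cd25",
                                         tis_schedule(anticd25_days = c(3, 6, 10, 13, 17, 20))),
                       t_end = t_end, grid_step = grid_step)
    written$synergy <- file.path(out_dir, "synergy.csv")
    utils::write.csv(as.data.frame(syn), written$synergy, row.names = FALSE,
                     quote = FALSE)
  } else if (command == "optimize") {
    bounds <- if (is.null(config$bounds)) tis_schedule_bounds()
              else do.call(tis_schedule_bounds, config$bounds)
    opt <- optimize_schedules(params = getp(), bounds = bounds,
                              t_end = t_end, seed = seed,
                              ga = config$ga %||% list())
    written$optimum <- file.path(out_dir, "optimum.json")
    jsonlite::write_json(
      list(t_5fu = opt$t_5fu, t_cd25 = opt$t_cd25, cost = opt$cost,
           inhibition_pct = as.list(opt$inhibition_pct), seed = seed),
      written$optimum, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else if (command == "fuzzy") {
    fz <- config$fuzzy
    if (is.character(fz)) {
      doc <- jsonlite::fromJSON(fz)
      base <- getp()
      fz <- lapply(stats::setNames(names(doc), names(doc)), function(nm) {
        tfn_rel(base[[nm]], unlist(doc[[nm]]$rel))
      })
    }
    if (is.null(fz)) fz <- list(a1 = tfn_rel(getp()$a1))
    band <- propagate_fuzzy(fz, params = getp(), schedule = gets(),
                            output = config$output %||% "C",
                            t_end = if (is.null(config$t_end)) 150 else t_end)
    written$band <- file.path(out_dir, "band.csv")
    utils::write.csv(as.data.frame(band), written$band, row.names = FALSE,
                     quote = FALSE)
  } else if (command == "gsa") {
    method <- config$method %||% "prcc"
    if (method == "prcc") {
      res <- tis_gsa_prcc(params = getp(), n = config$n %||% 10000,
                          replications = config$replications %||% 5,
                          days = config$days %||% c(20, 50, 100),
                          seed = seed)
      long <- as.data.frame(as.table(res$mean_masked))
      names(long) <- c("parameter", "outcome", "prcc_mean")
      long$max_p <- as.vector(res$max_p)
      written$prcc <- file.path(out_dir, "prcc.csv")
      utils::write.csv(long, written$prcc, row.names = FALSE, quote = FALSE)
    } else {
      res <- tis_gsa_morris(params = getp(), output = config$output %||% "C",
                            day = config$day %||% 100,
                            r = config$r %||% 1000,
                            levels = config$levels %||% 10, seed = seed)
      written$morris <- file.path(out_dir, "morris.csv")
      utils::write.csv(as.data.frame(res), written$morris,
                       row.names = FALSE, quote = FALSE)
    }
  } else if (command == "generate-data") {
    obs <- generate_synthetic_observations(
      params = getp(), schedule = gets(),
      times = config$times %||% tis_record_days("control"),
      noise_cv = config$noise_cv %||% 0.05, seed = seed,
      arm = config$arm %||% "control")
    written$observations <- file.path(out_dir, "observations.csv")
    write_observations(obs, written$observations)
  } else if (command == "fit") {
    if (is.null(config$problem)) stop("fit requires config$problem")
    problem <- config$problem
    problem$ga$seed <- seed
    fit <- fit_parameters(problem)
    written$fit <- file.path(out_dir, "fit_result.json")
    jsonlite::write_json(
      list(estimates = as.list(fit$estimates), nrmse = fit$nrmse,
           total_nrmse = fit$total_nrmse, seed = seed),
      written$fit, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  manifest <- list(command = command, seed = seed,
                   package_version = as.character(utils::packageVersion("tisim")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   config = .manifest_echo(config),
                   outputs = written)
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  written$manifest <- manifest_path
  invisible(written)
}

.manifest_echo <- function(config) {
  lapply(config, function(v) {
    if (inherits(v, "tis_parameters") || inherits(v, "tis_schedule")) {
      unclass(v)
    } else if (is.function(v)) {
      "<function>"
    } else v
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
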