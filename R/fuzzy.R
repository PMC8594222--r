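# Triangular-fuzzy parameter uncertainty propagated through the model by the
# alpha-cut extension principle.

#' Triangular fuzzy number
#'
#' A fuzzy quantity with triangular membership: support `[lower, upper]`,
#' full membership at `mode`. The alpha-cut at level a is the interval
#' `[lower + a*(mode - lower), upper - a*(upper - mode)]`.
#'
#' @param lower,mode,upper triangle vertices, `lower <= mode <= upper`.
#' @return An object of class `tis_tfn`.
#' @examples
#' tfn(0.9, 1, 1.1) * 4.3992e-2  # fuzzy tumor growth rate
#' @export
tfn <- function(lower, mode, upper) {
  if (!(is.finite(lower) && is.finite(mode) && is.finite(upper))) {
    stop("triangle vertices must be finite")
  }
  if (lower > mode || mode > upper) stop("need lower <= mode <= upper")
  structure(list(lower = lower, mode = mode, upper = upper),
            class = "tis_tfn")
}

#' @export
`*.tis_tfn` <- function(e1, e2) {
  if (inherits(e1, "tis_tfn") && is.numeric(e2)) {
    s <- as.numeric(e2)
    if (s < 0) stop("only non-negative scaling of a fuzzy number is supported")
    tfn(e1$lower * s, e1$mode * s, e1$upper * s)
  } else if (inherits(e2, "tis_tfn") && is.numeric(e1)) {
    e2 * e1
  } else {
    stop("unsupported fuzzy multiplication")
  }
}

#' @export
print.tis_tfn <- function(x, ...) {
  cat(sprintf("<tis_tfn> (%.6g, %.6g, %.6g)\n", x$lower, x$mode, x$upper))
  invisible(x)
}

#' Relative triangular fuzzy number around a nominal value
#'
#' Convenience constructor: `tfn_rel(x, c(0.9, 1, 1.1))` is the fuzzy number
#' with support from 90% to 110% of the nominal `x`.
#'
#' @param nominal crisp nominal value.
#' @param rel length-3 vector of relative vertices.
#' @return A [tfn()].
#' @export
tfn_rel <- function(nominal, rel = c(0.9, 1, 1.1)) {
  tfn(nominal * rel[1L], nominal * rel[2L], nominal * rel[3L])
}

#' Alpha-cut of a triangular fuzzy number
#'
#' @param f a [tfn()].
#' @param alpha membership level in `[0, 1]`.
#' @return Length-2 vector, the closed interval at level `alpha`.
#' @examples
#' a1 <- tfn_rel(4.3992e-2)
#' alpha_cut(a1, 1)  # degenerate at the nominal value
#' alpha_cut(a1, 0)  # the full support
#' @export
alpha_cut <- function(f, alpha) {
  stopifnot(inherits(f, "tis_tfn"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1) {
    stop("alpha must lie in [0, 1]")
  }
  c(f$lower + alpha * (f$mode - f$lower),
    f$upper - alpha * (f$upper - f$mode))
}

# Time-average of one model output over [t0, t_end] (trapezoid rule).
.tis_time_average <- function(params, schedule, output, initial, t0, t_end,
                              grid_step) {
  tr <- tis_simulate(initial = initial, params = params, schedule = schedule,
                     t_end = t_end, grid_step = grid_step)
  sel <- tr$time >= t0
  t <- tr$time[sel]; x <- tr[[output]][sel]
  if (length(t) < 2L) return(x[1L])
  sum(diff(t) * (x[-1L] + x[-length(x)]) / 2) / (t[length(t)] - t[1L])
}

#' Propagate triangular-fuzzy parameters through the model
#'
#' Computes the fuzzy membership function of a time-averaged model output by
#' the alpha-cut extension principle: for each membership level the output
#' interval is the min/max of the crisp output over the Cartesian box of the
#' parameter alpha-cuts, located by full-factorial grid search (`resolution`
#' points per fuzzy dimension) refined by coordinate-wise golden-section
#' search around the incumbent extremes. The levels are processed from
#' alpha = 1 downward and each level inherits the incumbent extremes of the
#' level above (whose boxes it contains), so the returned intervals are
#' nested by construction of the search as well as by theory.
#'
#' The output functional is the trapezoid time-average of one state over
#' `[t0, t_end]` where `t0` defaults to the first injection day (0 for the
#' control arm).
#'
#' @param fuzzy named list mapping parameter names to [tfn()] objects.
#' @param params crisp base [tis_parameters()].
#' @param schedule a [tis_schedule()].
#' @param output one of `"C"`, `"N"`, `"T"`, `"M"`, `"H"`, `"R"`, `"I"`,
#'   `"F"`, `"S"`.
#' @param alphas membership levels; must include 1.
#' @param resolution grid points per fuzzy dimension.
#' @param t_end averaging horizon (day).
#' @param t0 averaging start; `NULL` means the first injection day.
#' @param initial initial state.
#' @param grid_step simulation output step (day).
#' @param refine number of coordinate-refinement sweeps at each extreme.
#' @return An object of class `tis_fuzzy_band`: data frame with columns
#'   `alpha`, `low`, `high`; attributes `output` and `crisp` (the alpha = 1
#'   value).
#' @export
propagate_fuzzy <- function(fuzzy, params = tis_parameters(),
                            schedule = tis_schedule(), output = "C",
                            alphas = seq(0, 1, by = 0.1), resolution = 5,
                            t_end = 150, t0 = NULL,
                            initial = tis_initial_state(), grid_step = 0.5,
                            refine = 2) {
  if (!length(fuzzy)) stop("at least one fuzzy parameter is required")
  if (is.null(names(fuzzy)) || !all(names(fuzzy) %in% .tis_param_names)) {
    stop("fuzzy must be a named list of model parameters")
  }
  if (!any(abs(alphas - 1) < 1e-12)) stop("alpha levels must include 1")
  output <- match.arg(output, c("C", "N", "T", "M", "H", "R", "I", "F", "S"))
  params <- validate_tis_parameters(params)
  if (is.null(t0)) {
    inj <- c(schedule$fivefu_days, schedule$anticd25_days)
    t0 <- if (length(inj)) min(inj) else 0
  }

  nm <- names(fuzzy)
  cache <- new.env(parent = emptyenv())
  evalx <- function(x) {
    key <- paste(sprintf("%.17g", x), collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    p <- params
    p[nm] <- as.list(x)
    v <- .tis_time_average(p, schedule, output, initial, t0, t_end, grid_step)
    cache[[key]] <- v
    v
  }

  refine_extreme <- function(x, lo, hi, maximize) {
    f <- if (maximize) function(z) -evalx(z) else evalx
    for (sweep in seq_len(refine)) {
      for (j in seq_along(x)) {
        if (hi[j] - lo[j] < .Machine$double.eps) next
        g <- function(v) { y <- x; y[j] <- v; f(y) }
        opt <- stats::optimize(g, lower = lo[j], upper = hi[j],
                               tol = (hi[j] - lo[j]) * 1e-3)
        cand <- c(opt$minimum, lo[j], hi[j])
        vals <- vapply(cand, g, numeric(1))
        x[j] <- cand[which.min(vals)]
      }
    }
    x
  }

  ord <- order(alphas, decreasing = TRUE)
  res <- data.frame(alpha = alphas[ord], low = NA_real_, high = NA_real_)
  inc_min <- NULL; inc_max <- NULL
  for (i in seq_len(nrow(res))) {
    a <- res$alpha[i]
    cuts <- lapply(fuzzy, alpha_cut, alpha = a)
    lo <- vapply(cuts, `[`, numeric(1), 1L)
    hi <- vapply(cuts, `[`, numeric(1), 2L)
    grids <- Map(function(l, h) {
      if (h - l < .Machine$double.eps) l else seq(l, h, length.out = resolution)
    }, lo, hi)
    pts <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
    if (!is.null(inc_min)) pts <- rbind(pts, inc_min, inc_max)
    vals <- apply(pts, 1L, evalx)
    x_min <- pts[which.min(vals), ]; x_max <- pts[which.max(vals), ]
    x_min <- refine_extreme(x_min, lo, hi, maximize = FALSE)
    x_max <- refine_extreme(x_max, lo, hi, maximize = TRUE)
    inc_min <- x_min; inc_max <- x_max
    res$low[i] <- evalx(x_min)
    res$high[i] <- evalx(x_max)
    # inherited incumbents keep intervals nested across levels
    if (i > 1L) {
      res$low[i] <- min(res$low[i], res$low[i - 1L])
      res$high[i] <- max(res$high[i], res$high[i - 1L])
    }
  }
  res <- res[order(res$alpha), ]
  rownames(res) <- NULL
  crisp <- res$low[nrow(res)]
  attr(res, "output") <- output
  attr(res, "crisp") <- crisp
  class(res) <- c("tis_fuzzy_band", "data.frame")
  res
}

#' Shift between two fuzzy uncertainty bands
#'
#' Per-level signed displacement of the interval midpoints of a treated band
#' relative to a control band, with an overall direction verdict: `"left"`
#' if every midpoint moves to lower values, `"right"` if every midpoint
#' moves up, `"none"` if the bands coincide, `"mixed"` otherwise.
#'
#' @param band_control,band_treated [propagate_fuzzy()] results for the same
#'   output at the same alpha levels.
#' @return List with `shift` (data frame of alpha and midpoint displacement)
#'   and `direction`.
#' @export
band_shift <- function(band_control, band_treated) {
  stopifnot(inherits(band_control, "tis_fuzzy_band"),
            inherits(band_treated, "tis_fuzzy_band"))
  if (!isTRUE(all.equal(band_control$alpha, band_treated$alpha))) {
    stop("bands must share the same alpha levels")
  }
  if (!identical(attr(band_control, "output"), attr(band_treated, "output"))) {
    stop("bands must describe the same output")
  }
  mid_c <- (band_control$low + band_control$high) / 2
  mid_t <- (band_treated$low + band_treated$high) / 2
  d <- mid_t - mid_c
  direction <- if (all(d == 0)) "none"
    else if (all(d < 0)) "left"
    else if (all(d > 0)) "right"
    else "mixed"
  list(shift = data.frame(alpha = band_control$alpha, shift = d),
       direction = direction)
}
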