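# Global sensitivity analysis: LHS/PRCC with replication and significance
# screening, and Morris elementary-effects screening.

#' Latin hypercube sample of a parameter box
#'
#' Draws a stratified sample: for every parameter, exactly one point falls in
#' each of the n equal-probability bins of its range. Parameters whose range
#' spans two or more decades are stratified on the log scale (rank-based
#' statistics are unaffected; this only improves space filling).
#'
#' @param n sample count (>= 1).
#' @param ranges named list mapping parameter names to `c(lower, upper)`.
#' @param seed integer seed.
#' @return An `n x p` matrix with named columns.
#' @export
lhs_sample <- function(n, ranges, seed = NULL) {
  if (n < 1) stop("n must be at least 1")
  if (!length(ranges) || is.null(names(ranges))) {
    stop("ranges must be a named list of c(lower, upper)")
  }
  for (nm in names(ranges)) {
    b <- ranges[[nm]]
    if (length(b) != 2L || any(!is.finite(b)) || b[1L] >= b[2L]) {
      stop("range for '", nm, "' must be finite with lower < upper")
    }
  }
  if (!is.null(seed)) set.seed(seed)
  u <- lhs::randomLHS(n, length(ranges))
  out <- matrix(NA_real_, n, length(ranges),
                dimnames = list(NULL, names(ranges)))
  for (j in seq_along(ranges)) {
    b <- ranges[[j]]
    log_scale <- b[1L] > 0 && b[2L] / b[1L] >= 100
    out[, j] <- if (log_scale) {
      exp(log(b[1L]) + u[, j] * (log(b[2L]) - log(b[1L])))
    } else {
      b[1L] + u[, j] * (b[2L] - b[1L])
    }
  }
  out
}

#' Default sensitivity ranges: half to twice the calibrated values
#'
#' @param params a [tis_parameters()] object.
#' @param names parameters to include; the default excludes the
#'   treatment-only constants (`d1`, `g1`, `h1`, `k1`, `h6`, `b4_5fu`), which
#'   are inert in the screened no-treatment arm.
#' @return Named list of `c(lower, upper)` ranges.
#' @export
tis_sensitivity_ranges <- function(params = tis_parameters(),
                                   names = NULL) {
  params <- validate_tis_parameters(params)
  if (is.null(names)) {
    names <- setdiff(.tis_param_names,
                     c("d1", "g1", "h1", "k1", "h6", "b4_5fu"))
  }
  stats::setNames(lapply(names, function(nm) {
    c(params[[nm]] / 2, params[[nm]] * 2)
  }), names)
}

#' Partial rank correlation coefficients
#'
#' Rank-transforms all columns and computes, for every parameter/outcome
#' pair, the correlation between the residuals of each after linear
#' regression on the remaining parameters (via the precision matrix of the
#' rank correlations), with a p-value from the t statistic on
#' `n - 2 - (p - 1)` degrees of freedom.
#'
#' @param samples `n x p` parameter matrix.
#' @param outcomes `n x q` outcome matrix (or a vector for q = 1).
#' @return List with `prcc` and `p_value`, both `p x q` matrices.
#' @export
tis_prcc <- function(samples, outcomes) {
  samples <- as.matrix(samples)
  outcomes <- as.matrix(outcomes)
  n <- nrow(samples); p <- ncol(samples); q <- ncol(outcomes)
  if (n <= p + 2) stop("need n > p + 2 samples")
  xr <- apply(samples, 2L, rank)
  yr <- apply(outcomes, 2L, rank)
  prcc <- matrix(NA_real_, p, q,
                 dimnames = list(colnames(samples), colnames(outcomes)))
  pval <- prcc
  df <- n - 2 - (p - 1)
  for (k in seq_len(q)) {
    cm <- stats::cor(cbind(xr, yr[, k]))
    pre <- tryCatch(solve(cm), error = function(e) NULL)
    if (!is.null(pre)) {
      m <- p + 1L
      dg <- pre[cbind(seq_len(p), seq_len(p))]
      r <- -pre[seq_len(p), m] / sqrt(dg * pre[m, m])
    } else {
      # degenerate (e.g. outcome a monotone copy of a parameter): fall back
      # to explicit residualization against the remaining parameters
      r <- vapply(seq_len(p), function(j) {
        X <- cbind(1, xr[, -j, drop = FALSE])
        qrX <- qr(X)
        if (qrX$rank < ncol(X)) {
          stop("rank-deficient design: collinear rank-transformed parameters")
        }
        stats::cor(qr.resid(qrX, xr[, j]), qr.resid(qrX, yr[, k]))
      }, numeric(1))
    }
    r <- pmin(pmax(r, -1), 1)
    tstat <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
    prcc[, k] <- r
    pval[, k] <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  }
  list(prcc = prcc, p_value = pval)
}

#' Replicated LHS/PRCC analysis
#'
#' Re-draws the Latin hypercube `replications` times, evaluates the model on
#' every draw, and aggregates the PRCC estimates: mean and standard
#' deviation over replications, maximum p-value, and a significance mask
#' (`max p < alpha`). Non-significant cells are reported as `NA` in
#' `mean_masked`.
#'
#' @param fn function mapping one named parameter vector to a named vector
#'   of outcomes.
#' @param ranges named list of `c(lower, upper)` ranges.
#' @param n samples per replication.
#' @param replications number of independent LHS draws.
#' @param seed integer seed.
#' @param alpha significance level for the mask (default 0.05).
#' @return List with matrices `mean`, `sd`, `max_p`, `significant`,
#'   `mean_masked` (parameters x outcomes).
#' @export
tis_prcc_replicated <- function(fn, ranges, n = 10000, replications = 5,
                                seed = 1, alpha = 0.05) {
  if (!is.null(seed)) set.seed(seed)
  reps <- vector("list", replications)
  for (r in seq_len(replications)) {
    x <- lhs_sample(n, ranges, seed = NULL)
    proto <- fn(x[1L, ])
    y <- vapply(seq_len(n), function(i) fn(x[i, ]),
                numeric(length(proto)))
    y <- if (is.matrix(y)) t(y) else matrix(y, ncol = 1L)
    colnames(y) <- names(proto)
    reps[[r]] <- tis_prcc(x, y)
  }
  arr_r <- simplify2array(lapply(reps, `[[`, "prcc"))
  arr_p <- simplify2array(lapply(reps, `[[`, "p_value"))
  m <- apply(arr_r, c(1, 2), mean)
  s <- apply(arr_r, c(1, 2), stats::sd)
  mp <- apply(arr_p, c(1, 2), max)
  sig <- mp < alpha
  mm <- m; mm[!sig] <- NA_real_
  list(mean = m, sd = s, max_p = mp, significant = sig, mean_masked = mm)
}

#' Morris elementary-effects screening
#'
#' Trajectory (winding-stairs) Morris design on a hyper-box: each trajectory
#' starts at a random grid point and perturbs one parameter at a time by the
#' standard step `delta = levels / (2 * (levels - 1))` in normalized
#' coordinates, in random order and direction. The elementary effect of a
#' parameter is the output change divided by the signed step; `mu_star` is
#' the mean absolute effect, `sigma` the standard deviation of effects, and
#' the screening reference line is `2 * sigma / sqrt(r)`.
#'
#' @param fn function mapping one named parameter vector to a scalar.
#' @param lower,upper named vectors bounding the box.
#' @param levels number of grid levels (even).
#' @param r number of trajectories (>= 2).
#' @param seed integer seed.
#' @return An object of class `tis_morris`: data frame with columns
#'   `parameter`, `mu_star`, `sigma`, `conf` (`2*sigma/sqrt(r)`), plus
#'   attributes `levels`, `r`.
#' @export
morris_ee <- function(fn, lower, upper, levels = 10, r = 1000, seed = 1) {
  p <- length(lower)
  stopifnot(length(upper) == p, all(upper > lower))
  if (r < 2) stop("need at least 2 trajectories")
  if (levels %% 2 != 0) stop("levels must be even")
  if (!is.null(seed)) set.seed(seed)
  delta <- levels / (2 * (levels - 1))
  base_levels <- (seq_len(levels) - 1) / (levels - 1)
  base_levels <- base_levels[base_levels <= 1 - delta + 1e-12]
  nms <- names(lower)
  denorm <- function(z) lower + z * (upper - lower)

  ee <- matrix(NA_real_, r, p, dimnames = list(NULL, nms))
  dropped <- 0L
  for (tr in seq_len(r)) {
    z <- sample(base_levels, p, replace = TRUE)
    dirs <- sample(c(-1, 1), p, replace = TRUE)
    # make every step feasible from the base point
    dirs[z + dirs * delta > 1 + 1e-12] <- -1
    dirs[z + dirs * delta < -1e-12] <- 1
    ord <- sample.int(p)
    y_prev <- tryCatch(fn(stats::setNames(denorm(z), nms)),
                       error = function(e) NA_real_)
    row <- rep(NA_real_, p)
    ok <- is.finite(y_prev)
    if (ok) {
      for (j in ord) {
        z[j] <- z[j] + dirs[j] * delta
        y_new <- tryCatch(fn(stats::setNames(denorm(z), nms)),
                          error = function(e) NA_real_)
        if (!is.finite(y_new)) { ok <- FALSE; break }
        row[j] <- (y_new - y_prev) / (dirs[j] * delta)
        y_prev <- y_new
      }
    }
    if (ok) ee[tr, ] <- row else dropped <- dropped + 1L
  }
  if (dropped > 0.1 * r) {
    stop("more than 10% of Morris trajectories failed (", dropped, " of ", r, ")")
  }
  keep <- stats::complete.cases(ee)
  ee <- ee[keep, , drop = FALSE]
  res <- data.frame(parameter = nms,
                    mu_star = colMeans(abs(ee)),
                    sigma = apply(ee, 2L, stats::sd))
  res$conf <- 2 * res$sigma / sqrt(nrow(ee))
  attr(res, "levels") <- levels
  attr(res, "r") <- nrow(ee)
  attr(res, "dropped") <- dropped
  class(res) <- c("tis_morris", "data.frame")
  res
}

# Simulate the no-treatment model for one sampled parameter vector and read
# out all nine populations/concentrations at the requested days.
.tis_gsa_outcomes <- function(x, base, days) {
  p <- base
  p[names(x)] <- as.list(unname(x))
  tr <- tis_simulate(params = validate_tis_parameters(p),
                     schedule = tis_schedule(), t_end = max(days),
                     grid_step = max(days) / 200)
  idx <- vapply(days, function(d) which.min(abs(tr$time - d)), integer(1))
  out <- c()
  for (i in seq_along(days)) {
    v <- unlist(tr[idx[i], c("C", "N", "T", "M", "H", "R", "I", "F", "S")])
    names(v) <- paste0(names(v), "_day", days[i])
    out <- c(out, v)
  }
  out
}

#' Replicated PRCC analysis of the tumor-immune model
#'
#' LHS/PRCC of the no-treatment model: parameters sampled on half-to-double
#' ranges, outcomes the nine populations/concentrations at the requested
#' days.
#'
#' @param params base [tis_parameters()].
#' @param n samples per replication.
#' @param replications number of LHS re-draws.
#' @param days read-out days.
#' @param seed integer seed.
#' @param ranges optional range override, as [tis_sensitivity_ranges()].
#' @return As [tis_prcc_replicated()].
#' @export
tis_gsa_prcc <- function(params = tis_parameters(), n = 10000,
                         replications = 5, days = c(20, 50, 100), seed = 1,
                         ranges = tis_sensitivity_ranges(params)) {
  tis_prcc_replicated(function(x) .tis_gsa_outcomes(x, params, days),
                      ranges, n = n, replications = replications,
                      seed = seed)
}

#' Morris screening of the tumor-immune model
#'
#' Elementary-effects screening of the no-treatment model on a +/- 10%
#' hyper-box around the calibrated values, read out as one population or
#' concentration at one day.
#'
#' @param params base [tis_parameters()].
#' @param output state read out (default tumor cells `"C"`).
#' @param day read-out day.
#' @param perturbation half-width of the box as a fraction of nominal.
#' @param levels,r,seed Morris design settings.
#' @param names screened parameters (default: all except treatment-only).
#' @return A [morris_ee()] result.
#' @export
tis_gsa_morris <- function(params = tis_parameters(), output = "C",
                           day = 100, perturbation = 0.10, levels = 10,
                           r = 1000, seed = 1, names = NULL) {
  params <- validate_tis_parameters(params)
  if (is.null(names)) {
    names <- setdiff(.tis_param_names,
                     c("d1", "g1", "h1", "k1", "h6", "b4_5fu"))
  }
  nominal <- unlist(params[names])
  fn <- function(x) {
    p <- params
    p[names] <- as.list(unname(x))
    tr <- tis_simulate(params = validate_tis_parameters(p),
                       schedule = tis_schedule(), t_end = day,
                       grid_step = day / 100)
    tr[[output]][nrow(tr)]
  }
  morris_ee(fn, lower = nominal * (1 - perturbation),
            upper = nominal * (1 + perturbation),
            levels = levels, r = r, seed = seed)
}
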