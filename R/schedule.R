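# Treatment schedules and pulsed drug-forcing signals.

#' Treatment schedule for 5-FU and anti-CD25 therapy
#'
#' A schedule lists the injection days of each drug together with the duration
#' for which each injection keeps its signal active and the signal amplitude
#' per dose. The forcing signals are rectangular pulses; doses whose windows
#' overlap (e.g. two doses on the same day) add their amplitudes.
#'
#' An empty day vector means that drug is never given (control arm for that
#' drug); its signal is identically zero and its on/off indicator is 0.
#'
#' The default anti-CD25 amplitude of `1e9` dose units is the scale at which
#' the calibrated anti-CD25 couplings act on the system: at signal u,
#' Treg depletion proceeds at `h6*u` per day and the Treg block on CTL killing
#' is released when `d1*u^2*R^3` reaches order one; with the calibrated `h6`
#' and `d1` both effects switch on together near u = 1e9. The 5-FU signal is a
#' pure on/off gate, so its amplitude stays 1.
#'
#' @param fivefu_days numeric vector of 5-FU injection days (may be empty).
#' @param anticd25_days numeric vector of anti-CD25 injection days.
#' @param fivefu_effect_days duration (day) each 5-FU dose stays active.
#' @param anticd25_effect_days duration (day) each anti-CD25 dose stays active.
#' @param fivefu_amplitude signal height per 5-FU dose (dimensionless gate).
#' @param anticd25_amplitude signal height per anti-CD25 dose (dose units).
#' @return An object of class `tis_schedule`.
#' @examples
#' # the calibrated experimental arms
#' tis_schedule(fivefu_days = 1:4)
#' tis_schedule(anticd25_days = c(3, 6, 10, 13, 17, 20))
#' @export
tis_schedule <- function(fivefu_days = numeric(0),
                         anticd25_days = numeric(0),
                         fivefu_effect_days = 1,
                         anticd25_effect_days = 1,
                         fivefu_amplitude = 1,
                         anticd25_amplitude = 1e9) {
  chk_days <- function(d, what) {
    d <- as.numeric(d)
    if (length(d) && (any(!is.finite(d)) || any(d < 0))) {
      stop(what, " injection days must be finite and non-negative")
    }
    sort(d)
  }
  fivefu_days <- chk_days(fivefu_days, "5-FU")
  anticd25_days <- chk_days(anticd25_days, "anti-CD25")
  for (v in list(fivefu_effect_days, anticd25_effect_days)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("effect durations must be positive finite scalars")
    }
  }
  for (v in list(fivefu_amplitude, anticd25_amplitude)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop("amplitudes must be non-negative finite scalars")
    }
  }
  structure(
    list(fivefu_days = fivefu_days,
         anticd25_days = anticd25_days,
         fivefu_effect_days = fivefu_effect_days,
         anticd25_effect_days = anticd25_effect_days,
         fivefu_amplitude = fivefu_amplitude,
         anticd25_amplitude = anticd25_amplitude),
    class = "tis_schedule"
  )
}

#' @export
print.tis_schedule <- function(x, ...) {
  fmt <- function(d) if (length(d)) paste(d, collapse = ", ") else "(none)"
  cat("<tis_schedule>\n")
  cat("  5-FU days:      ", fmt(x$fivefu_days),
      sprintf("  [%g day window, amplitude %g]\n",
              x$fivefu_effect_days, x$fivefu_amplitude))
  cat("  anti-CD25 days: ", fmt(x$anticd25_days),
      sprintf("  [%g day window, amplitude %g]\n",
              x$anticd25_effect_days, x$anticd25_amplitude))
  invisible(x)
}

.sched_fields <- function(schedule, drug = c("fivefu", "anticd25")) {
  drug <- match.arg(drug)
  if (drug == "fivefu") {
    list(days = schedule$fivefu_days, dur = schedule$fivefu_effect_days,
         amp = schedule$fivefu_amplitude)
  } else {
    list(days = schedule$anticd25_days, dur = schedule$anticd25_effect_days,
         amp = schedule$anticd25_amplitude)
  }
}

#' Pulsed drug-forcing signal
#'
#' Evaluates the rectangular-pulse forcing signal of one drug at time `t`.
#' Each injection on day d contributes `amplitude` on `[d, d + effect_days)`;
#' overlapping windows add. The attribute `sign` carries the arm-level on/off
#' indicator: 1 if the schedule contains any injection of that drug, else 0.
#'
#' @param schedule a [tis_schedule()].
#' @param drug `"fivefu"` or `"anticd25"`.
#' @param t time (day), finite scalar or vector.
#' @return Numeric vector of signal values with attribute `sign`.
#' @examples
#' s <- tis_schedule(anticd25_days = c(3, 6, 10, 13, 17, 20),
#'                   anticd25_amplitude = 1)
#' drug_signal(s, "anticd25", 3.5)  # inside the day-3 window -> 1
#' drug_signal(s, "anticd25", 5.0)  # outside all windows -> 0
#' @export
drug_signal <- function(schedule, drug = c("fivefu", "anticd25"), t) {
  stopifnot(inherits(schedule, "tis_schedule"))
  f <- .sched_fields(schedule, drug)
  if (any(!is.finite(t))) stop("t must be finite")
  val <- vapply(t, function(tt) {
    if (!length(f$days)) return(0)
    f$amp * sum(tt >= f$days & tt < f$days + f$dur)
  }, numeric(1))
  attr(val, "sign") <- as.numeric(length(f$days) > 0)
  val
}

# Window boundaries of both drugs inside [0, t_end]; segment edges at which
# the integrator is restarted so the discontinuous forcing is resolved.
.schedule_breaks <- function(schedule, t_end) {
  b <- c(0, t_end,
         schedule$fivefu_days, schedule$fivefu_days + schedule$fivefu_effect_days,
         schedule$anticd25_days, schedule$anticd25_days + schedule$anticd25_effect_days)
  sort(unique(b[b >= 0 & b <= t_end]))
}
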