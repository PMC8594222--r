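# Kinetic parameter set of the tumor-immune system model.

# Calibrated defaults. Two values are listed for the MDSC death rate: b4_normal
# applies in untreated conditions, b4_5fu while the 5-FU signal is active.
.tis_default_parameters <- list(
  a1   = 4.3992e-2,  # Panc02 tumor growth rate, 1/day
  Cmax = 1e10,       # maximum sustainable tumor cell population, cell
  b1   = 3.23e-7,    # NK-mediated tumor kill rate, 1/(cell day)
  c1   = 1.1e-7,     # CTL-mediated tumor kill rate, 1/(cell day)
  d1   = 2e-34,      # anti-CD25 weight releasing Treg block on CTL killing, 1/cell^3
  e1   = 0.345,      # Treg suppression of CTL killing, 1/cell
  f1   = 0.286,      # TGF-beta suppression of CTL killing, ml/ng
  g1   = 3.5e-2,     # tumor apoptosis rate under low-dose 5-FU, 1/day
  h1   = 2.5e5,      # anti-CD25 log-kill scale, cell/day
  k1   = 1e-15,      # anti-CD25 cumulative-dose coupling, 1/cell
  l1   = 100,        # depth of immune-cell access to the tumor mass, cell^(1/3)
  a2   = 1.4e4,      # constant NK source, cell/day
  b2   = 4.12e-2,    # NK death rate, 1/day
  c2   = 0.125,      # max IL-2-mediated NK growth, 1/day
  d2   = 0.3,        # IL-2 half-saturation for NK growth, ng/ml
  e2   = 0.125,      # max IFN-gamma-mediated NK growth, 1/day
  f2   = 0.3,        # IFN-gamma half-saturation for NK growth, ng/ml
  g2   = 1e-9,       # NK inactivation by tumor contact, 1/day
  h2   = 1e-10,      # Treg-mediated NK suppression, 1/(cell day)
  a3   = 2e-2,       # CTL death rate, 1/day
  b3   = 8e-2,       # max tumor-mediated CTL recruitment, 1/day
  c3   = 2.02e14,    # recruitment half-saturation, cell^2
  d3   = 1.1e-7,     # CTL stimulation by NK-tumor interaction, 1/(cell day)
  e3   = 1.5e-10,    # CTL inactivation by tumor contact, 1/(cell day)
  f3   = 125e-5,     # max IL-2-mediated CTL growth, 1/day
  g3   = 0.3,        # IL-2 half-saturation for CTL growth, ng/ml
  h3   = 12.5e-2,    # max IFN-gamma-mediated CTL growth, 1/day
  k3   = 0.3,        # IFN-gamma half-saturation for CTL growth, ng/ml
  l3   = 1e-10,      # Treg-mediated CTL suppression, 1/(cell day)
  m3   = 18e-2,      # minimal CTL proliferation factor under MDSC inhibition
  n3   = 6e-3,       # MDSC-inhibition shape parameter, 1/cell^2
  p3   = 2.5e6,      # normal splenic MDSC count, cell
  a4   = 1.25e6,     # normal MDSC production rate, cell/day
  b4_normal = 3.25e-2, # MDSC death rate, untreated, 1/day
  b4_5fu    = 8e-2,    # MDSC death rate during 5-FU treatment, 1/day
  c4   = 0.7e7,      # tumor-induced MDSC expansion coefficient, cell/day
  d4   = 1e10,       # MDSC expansion half-saturation, cell
  a5   = 3.6e5,      # thymic T helper production, cell/day
  b5   = 1.2e-3,     # T helper death rate, 1/day
  c5   = 0.125,      # max IL-2-mediated T helper proliferation, 1/day
  d5   = 0.3,        # IL-2 half-saturation for T helper proliferation, ng/ml
  e5   = 0.125,      # max IFN-gamma-mediated T helper proliferation, 1/day
  f5   = 0.3,        # IFN-gamma half-saturation, ng/ml
  g5   = 1e-10,      # Treg-mediated T helper suppression, 1/(cell day)
  a6   = 5.6e5,      # constant Treg production, cell/day
  b6   = 2.3e-2,     # Treg death rate, 1/day
  c6   = 2e-4,       # Treg origination from CTLs, 1/day
  d6   = 4e-4,       # Treg origination from T helpers, 1/day
  e6   = 0.125,      # max IL-2-mediated Treg growth, 1/day
  f6   = 0.3,        # IL-2 half-saturation for Treg growth, ng/ml
  g6   = 1e-11,      # NK-mediated Treg degradation, 1/(cell day)
  h6   = 1.5e-11,    # anti-CD25-mediated Treg depletion, 1/day per dose unit
  ratio_tau1_alpha1 = 2.2483e11,  # IL-2 decay / secretion ratio, cell ml/ng
  ratio_beta1_tau2  = 4.4691e-13, # IFN-gamma secretion (CTL) / decay, ng/(ml cell)
  ratio_beta2_tau2  = 4.4691e-13, # IFN-gamma secretion (NK) / decay, ng/(ml cell)
  ratio_beta3_tau2  = 4.4691e-13, # IFN-gamma secretion (Th) / decay, ng/(ml cell)
  ratio_lambda1_tau3 = 8.9382e-13 # TGF-beta secretion / decay, ng/(ml cell)
)

# Fixed field order shared with the compiled right-hand side.
.tis_param_names <- names(.tis_default_parameters)

#' Kinetic parameters of the tumor-immune system model
#'
#' Constructs a validated parameter set for the six-equation tumor-immune
#' system (TIS) model. Defaults are the calibrated values for Panc02 tumors in
#' C57BL/6 mice; any subset of fields can be overridden by name.
#'
#' Fields cover the Gompertz tumor growth law (`a1`, `Cmax`), effector-cell
#' kill and suppression rates, Michaelis-Menten cytokine couplings, the
#' treatment-only constants (`g1`, `b4_5fu` for 5-FU; `d1`, `h1`, `k1`, `h6`
#' for anti-CD25), and the quasi-steady-state cytokine ratios
#' (`ratio_tau1_alpha1`, `ratio_beta*_tau2`, `ratio_lambda1_tau3`).
#'
#' @param ... named scalar overrides of default fields, or a single named
#'   list of such overrides.
#' @return An object of class `tis_parameters`: a named list of positive
#'   scalars.
#' @examples
#' p <- tis_parameters()
#' p$a1
#' tis_parameters(a1 = 0.05)$a1
#' @export
tis_parameters <- function(...) {
  over <- list(...)
  if (length(over) == 1L && is.null(names(over)) && is.list(over[[1L]])) {
    over <- over[[1L]]
  }
  p <- .tis_default_parameters
  if (length(over)) {
    if (is.null(names(over)) || any(!nzchar(names(over)))) {
      stop("parameter overrides must be named")
    }
    unknown <- setdiff(names(over), .tis_param_names)
    if (length(unknown)) {
      stop("unknown parameter field(s): ", paste(unknown, collapse = ", "))
    }
    p[names(over)] <- over
  }
  validate_tis_parameters(p)
}

#' Validate a tumor-immune parameter set
#'
#' Checks the structural invariants of a parameter list: every field present,
#' finite, strictly positive; `m3` in (0, 1]; `Cmax` > 1. Returns the object
#' with class `tis_parameters` on success.
#'
#' @param p named list of parameter values.
#' @return The validated `tis_parameters` object.
#' @export
validate_tis_parameters <- function(p) {
  missing <- setdiff(.tis_param_names, names(p))
  if (length(missing)) {
    stop("missing parameter field(s): ", paste(missing, collapse = ", "))
  }
  for (nm in .tis_param_names) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("parameter '", nm, "' must be a finite numeric scalar")
    }
    if (v <= 0) stop("parameter '", nm, "' must be strictly positive")
    p[[nm]] <- as.numeric(v)
  }
  if (p$m3 > 1) stop("parameter 'm3' must lie in (0, 1]")
  if (p$Cmax <= 1) stop("parameter 'Cmax' must exceed 1 cell")
  p <- p[.tis_param_names]
  class(p) <- "tis_parameters"
  p
}

#' @export
print.tis_parameters <- function(x, ...) {
  cat("<tis_parameters> ", length(x), " kinetic constants\n", sep = "")
  cat(sprintf("  a1 = %.4g /day, Cmax = %.3g cells, g1 = %.4g /day (5-FU)\n",
              x$a1, x$Cmax, x$g1))
  invisible(x)
}

# Parameter vector in the fixed order expected by the compiled model.
.tis_param_vector <- function(p) {
  unlist(p[.tis_param_names], use.names = TRUE)
}

#' Absolute cytokine rates consistent with the calibrated ratios
#'
#' The six-equation model only fixes the ratios of cytokine secretion to decay
#' rates. The nine-equation parent model needs absolute rates; this helper
#' builds a consistent set from chosen decay rates (`tau1`, `tau2`, `tau3`),
#' back-computing the secretion rates from the ratios in `params`. Large decay
#' rates recover the quasi-steady-state regime.
#'
#' @param params a `tis_parameters` object.
#' @param tau1,tau2,tau3 decay rates (1/day) of IL-2, IFN-gamma and TGF-beta.
#' @return Named list with `alpha1`, `tau1`, `beta1`, `beta2`, `beta3`,
#'   `tau2`, `lambda1`, `tau3`.
#' @export
tis_absolute_rates <- function(params, tau1 = 50, tau2 = 50, tau3 = 50) {
  params <- validate_tis_parameters(params)
  list(
    alpha1  = tau1 / params$ratio_tau1_alpha1,
    tau1    = tau1,
    beta1   = tau2 * params$ratio_beta1_tau2,
    beta2   = tau2 * params$ratio_beta2_tau2,
    beta3   = tau2 * params$ratio_beta3_tau2,
    tau2    = tau2,
    lambda1 = tau3 * params$ratio_lambda1_tau3,
    tau3    = tau3
  )
}

#' Default initial cell populations
#'
#' The standard initial state: 6e5 tumor cells (the subcutaneous inoculum),
#' 105840 NK cells, 2.1e5 CTLs, 3e3 MDSCs, 564480 T helper cells, 42336 Tregs,
#' and zero cumulative anti-CD25 exposure.
#'
#' @param C,N,T,M,H,R,A optional overrides of individual components.
#' @return Named numeric vector `c(C, N, T, M, H, R, A)`.
#' @export
tis_initial_state <- function(C = 6e5, N = 105840, T = 21e4, M = 3e3,
                              H = 564480, R = 42336, A = 0) {
  y <- c(C = C, N = N, T = T, M = M, H = H, R = R, A = A)
  if (any(!is.finite(y)) || any(y < 0)) {
    stop("initial state components must be finite and non-negative")
  }
  y
}
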