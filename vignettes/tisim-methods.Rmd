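---
title: "Methods: the tumor-immune model and its analysis stack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the tumor-immune model and its analysis stack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tisim)
```

## The model and its assumptions

The core of the package is a six-equation ODE model of the pancreatic
(Panc02, C57BL/6 mouse) tumor microenvironment. The state holds tumor cells
C, NK cells N, cytotoxic T lymphocytes T, MDSCs M, T helper cells H and
regulatory T cells R, plus one auxiliary state A (cumulative anti-CD25
exposure, below). The modelling assumptions are the standard ones of this
family of tumor-immune models:

* Tumor growth is Gompertzian with rate `a1` and carrying capacity `Cmax`;
  immune-mediated killing acts only on the accessible surface layer
  `C/(1 + C^(1/3)/l1)` of the tumor mass.
* NK cells and CTLs kill tumor cells; both are inactivated by tumor contact;
  CTL killing is suppressed by Tregs (factor `1 + e1*R`) and by TGF-β.
* MDSCs blunt the NK-mediated activation of CTLs; Tregs suppress NK, CTL and
  T helper populations; Tregs are fed by CTLs and T helpers.
* The cytokines IL-2, IFN-γ and TGF-β relax much faster than the cell
  populations. They are eliminated by quasi-steady-state (QSS) relations
  (`I = H/(τ1/α1)`, `F = (β1/τ2)T + (β2/τ2)N + (β3/τ2)H`, `S = (λ1/τ3)C`),
  so only the secretion/decay *ratios* appear in the six-equation model. The
  nine-equation parent with explicit cytokine dynamics is implemented as
  well (`tis_simulate_full()`); a test verifies that with fast decay rates
  it agrees with the QSS model to better than 1% over days 5–25, and
  `tis_absolute_rates()` builds absolute rate sets consistent with the
  calibrated ratios.

All kinetic constants live in `tis_parameters()`; the defaults are the
calibrated values for the Panc02 system, and each field is documented with
its unit there. Two read-outs deserve a note: tumor *volume* is tumor cell
count × 1e-6 mm³ (one cell ≈ 1e-6 mm³), and the default initial state
(`tis_initial_state()`) is the standard experimental inoculum of 6e5 tumor
cells with the accompanying immune populations.

## Treatment forcing and the anti-CD25 signal scale

Neither drug is modelled pharmacokinetically. Each injection contributes a
rectangular pulse of fixed duration (default 1 day) to that drug's forcing
signal; pulses that overlap — for example two doses given on the same day —
add. While the 5-FU signal is positive, tumor cells die at extra rate `g1`
and the MDSC death rate switches from `b4_normal` to `b4_5fu`; the 5-FU
signal is therefore a pure on/off gate and its amplitude is 1. The
anti-CD25 signal u enters quantitatively in three places: Treg depletion
`h6·u·R`, release of the Treg block on CTL killing through `1 + d1·u²·R³`,
and the cumulative exposure `A' = u·C` whose logarithm kills tumor cells at
rate `h1·log(1 + k1·A)` in any arm that receives the antibody.

The amplitude of u is a genuine modelling choice: the calibrated constants
only fix the *products* `h6·u` and `d1·u²`. The package default of 1e9 dose
units per injection is the scale singled out by the calibrated constants
themselves: at u = 1e9 the Treg depletion rate `h6·u ≈ 1.5e-2`/day becomes
commensurate with the natural Treg turnover `b6 = 2.3e-2`/day, and
simultaneously `d1·u²·R³` reaches order 1e-2 at typical Treg counts — both
calibrated anti-CD25 couplings switch on together at this scale, and at
substantially smaller amplitudes the therapy is numerically inert while at
amplitudes above ~1e10 it eradicates the tumor within days, contradicting
the growth observed in the antibody-treated calibration experiments. The
amplitude is an explicit schedule field, so any other dose scale can be
explored.

## Numerical integration

`tis_simulate()` integrates the model with `deSolve::lsoda` (adaptive,
stiff-capable), restarting the integrator at every treatment-window
boundary so the discontinuous forcing is resolved exactly; within a segment
the signals are constant and are passed to a compiled right-hand side
(`src/tis_rhs.c`). A plain-R reference implementation of the same
derivatives (`simplified_rhs()`) is exported and the test suite verifies
that both integrate to the same trajectories.

Numerical choices, all visible in the code:

* Tolerances `rtol = 1e-8` and `atol = 1e-6` cells. The exposure state A is
  many orders of magnitude larger than the cell states (it integrates
  signal × cells), so it carries its own absolute tolerance (1e8); in the
  nine-equation model the ng/ml-scale cytokines carry `atol = 1e-12`.
* The Gompertz term evaluates `log(Cmax/max(C, 1))`: one cell is the
  biological atom, and the floor removes the logarithmic singularity at
  C = 0.
* The anti-CD25 log-kill is a *constant* sink (cells/day) once exposure has
  accumulated. It is capacity-limited by the smooth factor `C/(C + 1)` —
  the treatment cannot remove more cells than exist — which is negligible
  above ~100 cells and makes C = 0 a smooth absorbing state (eradication);
  a derivative clamp at C ≤ 0 guards the boundary.
* Non-negativity is enforced on the output grid and at segment joins;
  accuracy is tolerance-controlled, not grid-controlled (halving the output
  step moves the day-100 tumor burden by well under 0.1%).

## Calibration

The goodness-of-fit measure is the NRMSE normalized by the first
observation, `sqrt(Σ(Tᵢ − T̂ᵢ)²/T₁²)`, computed on tumor *volumes* at the
recording days (control and 5-FU arms: days 5, 10, 15, 20, 25; anti-CD25
arm: days 7, 14, 21, 28, 35, with a 2e6-cell inoculum). Estimation follows
the staged protocol of the original experiments: the control arm fixes the
growth rate `a1`; the 5-FU arm then fits (`g1`, `b4_5fu`) with the control
estimates frozen; the anti-CD25 arm fits (`d1`, `h1`, `k1`, `h6`).

The optimizer is a hand-written elitist real-coded GA (tournament
selection, blend crossover p = 0.9, per-gene Gaussian mutation p = 0.1,
elitism 1) searching on log scale inside the user's box bounds — no
evolutionary-optimization package is required. Defaults are population 60
and 120 generations; the test suite uses smaller budgets (population 24–40,
40–60 generations), which noiseless recovery experiments show to be
sufficient for every identifiable parameter.

Because the original in vivo series are not distributed with the package, a
synthetic-observation generator stands in for them:
`generate_synthetic_observations()` perturbs noiseless model volumes with
independent multiplicative log-normal noise (`volume × exp(ε)`,
`ε ~ N(0, cv)`, default cv 0.05, seed-reproducible). It emulates the
magnitude-proportional measurement error of caliper tumor-volume series; it
does *not* emulate inter-animal variability, digitization error, or model
misspecification, so parameter-recovery tests establish the correctness of
the fitting machinery, not fidelity to real data.

Identifiability is a property of the study design, not of the optimizer,
and three of the staged parameters are structurally unidentifiable from
tumor volume alone at the calibrated operating point: the MDSC factor in
the CTL equation equals its floor `m3` except in a vanishingly narrow
window around `M = p3`, so `b4_5fu` barely touches any observable; and the
CTL kill term that `d1` and `h6` modulate is suppressed by `1 + e1·R ≈ 1e4`,
so their influence on C(t) is below measurement resolution. Noiseless
refits recover `a1`, `g1`, `h1` and `k1` tightly while `b4_5fu` and `h6`
drift inside their bounds; the corresponding recovery checks in the test
suite record this honestly rather than asserting a recovery the data cannot
support.

## Synergy analysis

Treatment efficacy at time t is `E = (C_ctrl − C_treated)/C_ctrl`; the
Bliss combination index is `CI = (E_a + E_5 − E_a·E_5)/E_comb`, the
classical Bliss-independence form (synergy iff CI < 1). `tis_synergy()`
simulates the four arms (control, each monotherapy, combination) from a
shared initial state and reports inhibition percentages and CI both from
instantaneous tumor size and from the running time-average (trapezoid rule
from the simulation start), the latter converging to the former as t → 0.
CI is reported as missing (`NA`), never clamped, wherever the combination
has no effect (`E_comb ≤ 0`), including the pre-treatment interval.

## Schedule optimization

`optimize_schedules()` searches jointly over the injection days of both
drugs — by default 4 × 5-FU and 6 × anti-CD25 on integer days 1–20, at most
two doses of one drug per day (the toxicity cap; stacked doses add their
pulse amplitudes). The objective is the three-arm cost
`(1/3N) Σᵢ (C_5F/C_ctrl)² + (C_CD/C_ctrl)² + (C_comb/C_ctrl)²` sampled at
N = 100 evenly spaced times on (0, 100] — dense enough that the cost is
grid-stable well below 1%. The integer GA canonicalizes day multisets
sorted, repairs cap violations by resampling, memoizes candidate costs, and
is seeded with the hand-picked experimental schedule whenever the bounds
admit it, so the returned optimum can never lose to that baseline. The
reported result carries the optimal day vectors, the cost, per-arm final
inhibition percentages and the GA trace.

## Fuzzy uncertainty propagation

Parametric uncertainty is represented by triangular fuzzy numbers
(`tfn()`); `alpha_cut()` returns the interval of membership level α. The
output functional is the trapezoid time-average of one state over
[t0, 150] days, with t0 the first injection day (0 for the control arm).
`propagate_fuzzy()` applies the extension principle α-cut by α-cut: the
output interval at level α is the min/max of the functional over the
Cartesian α-cut box, located by full-factorial grid search (5 points per
fuzzy dimension by default) refined by coordinate-wise golden-section
sweeps at each incumbent extreme. Levels are processed from α = 1 downward
and each level inherits the incumbents of the level above (whose box it
contains), so the returned intervals are nested by construction as well as
by theory. For a monotone response — such as the tumor average under fuzzy
`a1` — the extremes sit at box vertices and the search is exact; this is
asserted in the tests as an internal oracle. `band_shift()` summarizes the
therapy-induced displacement of a band by the per-level midpoint shifts and
a direction verdict (left / right / mixed / none).

## Global sensitivity analysis

Both analyses screen the no-treatment model from the standard initial
state; the treatment-only constants (`d1`, `g1`, `h1`, `k1`, `h6`,
`b4_5fu`) are excluded since they are inert without forcing.

*PRCC.* Latin-hypercube samples (via the `lhs` package) on half-to-double
ranges around the calibrated values; ranges spanning at least two decades
would be stratified on log scale (rank statistics are unaffected — this
only improves space filling). All columns are rank-transformed; the PRCC of
parameter j against an outcome is the correlation of their residuals after
linear regression on the remaining parameters, computed from the precision
matrix of the rank correlations (with an explicit residualization fallback
for degenerate cases). p-values use the t statistic on `n − 2 − (p − 1)`
degrees of freedom, the standard partial-correlation correction. The
analysis is replicated over independent LHS draws; cells whose maximum
p-value reaches 0.05 are masked. Outcomes are all nine
populations/concentrations at the requested days.

*Morris.* Elementary-effects screening on the ±10% hyper-box with the
standard trajectory design: 10 levels, normalized step
`Δ = levels/(2(levels − 1))`, one-at-a-time perturbations in random order
and direction, `EE = Δy/Δ`. Reported are μ* (mean |EE|), σ (sd of EE) and
the screening reference `2σ/√r`. Failed trajectories are dropped; more
than 10% failures abort the analysis.

## Problem sizes in the test suite

The shipped tests favor determinism and short runtimes: GSA checks use
n = 2000 samples × 3 replications (PRCC, day-20 read-out) and r = 50 Morris
trajectories (day-100 read-out), which reproduce the sign and rank
structure of the full-size analysis; recovery experiments use 10 GA seeds
per stage on noiseless synthetic series; fuzzy propagation uses five α
levels. Full-size runs (n = 10000 × 5, r = 1000) are available through the
same functions.

## Known limitations

* No pharmacokinetics: drug exposure is on/off forcing, and the absolute
  anti-CD25 dose scale is conventional (see above), not measured.
* The model is deterministic; stochastic cell-level effects and inter-animal
  variability are outside its scope, and the fuzzy machinery propagates
  *parametric* uncertainty only.
* The cumulative-exposure kill never decays: after the last injection the
  tumor keeps experiencing a constant log-kill, which is what makes early
  dose stacking so effective in the optimizer. This is a faithful property
  of the model structure, not a biological claim.
* Several anti-CD25 constants are unidentifiable from tumor volume alone
  (see Calibration); conclusions that hinge on their individual values
  should not be drawn from volume-only fits.
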