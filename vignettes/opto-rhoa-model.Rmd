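---
title: "A minimal model of optogenetic GEF recruitment and the RhoA/Cdc42 phenotype switch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A minimal model of optogenetic GEF recruitment and the RhoA/Cdc42 phenotype switch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optoRhoA)
```

## The biological problem

Recruiting the catalytic DH–PH module of PDZ-RhoGEF (optoPRG) to the plasma
membrane with a blue-light dimerizer (iLID/SspB) activates RhoA — and yet
the same perturbation makes some cells retract and others protrude. The
phenotype is predicted by the cell's basal optoPRG expression: below a
threshold of roughly 40 a.u. of cytosolic fluorescence nearly all cells
retract, above it most protrude. The mechanistic proposal modeled here is
that the GEF is bifunctional: it activates RhoA (retraction branch) and
Cdc42 (protrusion branch), while its PH domain binds RhoA-GTP into a
signaling-dead complex. At low expression the RhoA branch wins; at high
expression each recruitment pulse instantaneously sequesters free RhoA-GTP,
handing the balance to Cdc42.

`optoRhoA` implements this model end to end: stimulus construction,
forward simulation, per-cell parameter estimation, phenotype scoring and
mapping, a synthetic-data generator standing in for the microscopy, and the
mask-based trace quantifications used on real movies.

## The model

**Stimulus.** Each light pulse increments the normalized membrane GEF level
`g = Gtot/Geq` by a fixed amount $\Delta = \mathrm{fold} - 1$ (measurable
folds span 1.1–3); between pulses `g` relaxes to 1 with the dark-state
dissociation time constant $\tau_\mathrm{off} = 20$ s. Pulses are modeled
as instantaneous because recruitment is fast relative to $\tau_\mathrm{off}$;
a finite-ramp variant (`rise_s`) exists purely to cross-check the jump
handling. There is no saturation: the per-pulse increment is identical for
every pulse, consistent with the fold-change description of the data.

**Free active RhoA.** With $\rho = G_{eq}/K_b$ (basal GEF over the
dissociation constant of the GEF·RhoA-GTP complex), a quasi-steady-state
treatment of the fast binding equilibrium gives

$$\frac{dr}{dt} = \frac{1}{1+\rho g}\left[k_2\,(g - r) - \rho\, r\,\frac{dg}{dt}\right],$$

where `r` is free active RhoA normalized to its dark equilibrium and $k_2$
is the lumped GAP-mediated deactivation rate. Two consequences drive all
the phenomenology: across a pulse the total active pool $r\,(1+\rho g)$ is
conserved, so `r` drops instantaneously by the factor
$(1+\rho g^-)/(1+\rho g^+)$; and relaxation toward the fixed point
$r = g$ is slowed to $k_2/(1+\rho g)$. Sequestration shapes transients
only — held at constant `g`, `r` always converges to `g`.

**Cdc42 and the biosensor.** Cdc42 activation is taken as the same
mass-action law with the shared deactivation rate ($dc/dt = k_2 (g - c)$)
and no sequestration — the minimal symmetric choice, which makes the
$\rho = 0$ limit exactly degenerate with RhoA, as the low-expression
behavior requires. The relocation biosensor is an unsaturated first-order
tracker, $db/dt = k_\mathrm{off}(r - b)$; sensor depletion of RhoA-GTP is
ignored (relocation sensors are used in excess). Point estimates used
throughout: $k_2 = 0.014\ \mathrm{s^{-1}}$,
$k_\mathrm{off} = 0.08\ \mathrm{s^{-1}}$. The printed uncertainty of the
sensor rate exceeds its estimate in the source (plainly a typo); the
package treats 0.08 as a point estimate and does not interpret that error
bar. The absolute catalytic rate of the GEF never appears: it is absorbed
by the normalizations $r = R/R_{eq}$, $g = G_{tot}/G_{eq}$.

**The mass-action oracle.** `simulate_full()` integrates the
un-approximated two-state system (free active RhoA and the complex, with
finite `kon`/`koff` binding and activation by total GEF — PH binding does
not block catalysis). It exists to validate the quasi-steady-state
solution: with binding 100-fold faster than deactivation and
$R_{eq} = 0.01\,K_b$ (the linear-binding regime), the two solutions agree
to $\approx 3\times 10^{-3}$ in sup-norm. One caveat is structural: at the
pulse instants themselves the QSSA jumps discontinuously while the
mass-action system re-equilibrates over $\sim 1/k_\mathrm{off,bind}$, so
`qssa_oracle_distance()` excludes a settling window of
$5/k_\mathrm{off,bind}$ after each pulse — the gap at those instants is
$O(\mathrm{jump})$ for any finite binding rate and says nothing about the
approximation. If binding is so slow that the windows tile the whole
record, the comparison falls back to the full grid and simply reports the
(large) deviation of that regime.

## Numerics

Analytic stimuli (pulse trains, steps) carry their piecewise-exponential
description; the RhoA equation is integrated segment by segment with
`deSolve::lsoda` (rtol $10^{-8}$, atol $10^{-10}$) and the exact jump map
applied at pulse times, so delta-like $dg/dt$ is never discretized. The
Cdc42 and biosensor stages are linear relaxations toward a sampled input
and are solved exactly for piecewise-linear input via an exponential
integrator.

Measured (sampled, noisy) recruitment traces need more care, because the
main equation consumes $dg/dt$:

* Step-like rises are detected (increment above 0.25, or 4 robust scales
  of the typical frame-to-frame increment, whichever is larger), the
  pre- and post-step levels are estimated by least-squares lines through
  up to five neighboring samples, and the analytic jump map is applied at
  the detected steps. Without this, the pulse is smeared across one
  sampling interval; the resulting forward-model error is small in RSS but
  slides the weakly identified rate pair far along its trade-off valley.
* Between steps, `g` is smoothed by a local quadratic (Savitzky–Golay,
  5-point window by default) and $dg/dt$ taken by central differences of
  the smoothed curve; segment edges are pinned to the robust step-level
  estimates so the filter never sees the jumps. Wider windows were
  examined and distort the 20 s dark-state decay; 5 points is the default
  and is configurable.
* Integration between steps uses classical RK4 with steps of at most
  0.25 s — the equation there is a scalar linear ODE with
  data-interpolated coefficients, for which a fine fixed step matches the
  adaptive solver to well below the data noise (clean-trace agreement with
  the analytic path is $\sim 8\times10^{-4}$).

## Fitting

All fits are plain (unweighted) least squares, minimized derivative-free;
an inverse-variance weighting option exists but is off by default.

`fit_rho()` estimates the single per-cell parameter $\rho$ on
$[0, 10]$ by a deterministic scan (including anchors 0.05, 0.5, 2) plus
golden-section/parabolic refinement of the bracketed minimum. Fits are
flagged non-identifiable when the estimate sits at the search bound or when
the observed biosensor trace carries no signal correlated with the best-fit
response (a flat trace cannot constrain $\rho$: against it, least squares
merely selects the flattest model response, which here is an interior
$\rho$, not the bound). Under the default study conditions (20-min traces,
30 s period, fold 1.5, 5% multiplicative noise) the estimator recovers
$\rho = 1$ with a spread of about $\pm 0.07$ (s.d., 12 seeds).

`fit_k2_koff()` pools low-expression cells ($\rho$ fixed to 0, complex
formation negligible) and fits the shared pair $(k_2, k_\mathrm{off})$ by
multi-start Nelder–Mead on log-rates. Two caveats are inherent and
surfaced rather than hidden:

* At $\rho = 0$ the model is two first-order filters in series — exactly
  exchangeable in the two rates. The joint fit determines the pair only up
  to a label swap, so estimates are reported under the `koff > k2`
  convention (the sensor is the faster process, ~6-fold at the point
  estimates) and flagged when the convention had to be applied. This
  mirrors the original analysis, which pinned the sensor kinetics first.
* A lack-of-fit flag fires when the residuals' pooled lag-1
  autocorrelation exceeds 0.05: frame noise is independent, systematic
  model mismatch is smooth, and at these trace lengths the null
  autocorrelation is below 0.015 while forcing $\rho = 0.8$ cells through
  the $\rho = 0$ model yields $\approx 0.13$.

## Phenotype score, calibration, maps

The morphodynamic outcome is summarized over the first $T = 120$ s after
activation ("the first two minutes", configurable) by

$$\gamma = \frac{w\int_0^T (r-1)\,dt - \int_0^T (c-1)\,dt}
{w\int_0^T |r-1|\,dt + \int_0^T |c-1|\,dt},$$

positive for retraction, negative for protrusion, with a gray zone
$|\gamma| \le \epsilon = 0.05$ labeled mixed. The source describes only a
"relative difference" without a formula; this baseline-subtracted,
magnitude-normalized form was chosen because it is dimensionless, bounded
in $[-1, 1]$, exactly zero for a null stimulus, and reproduces every stated
qualitative feature (sign convention, monotone decrease in $\rho$, the
frequency switch). The unnormalized variant is available
(`normalize = FALSE`) for sensitivity analysis. The gray-zone width is a
convention: the source draws one without a number.

The weight `w` (RhoA vs Cdc42 contribution) is not measurable; it is
calibrated so that $\gamma = 0$ at the observed transition
$\rho = 0.5$ under a *sustained step* to $g = 2$ — deliberately not a
pulse train, so the pulsed phenotype map remains a genuine prediction
rather than being true by construction. Calibration is by bracketing and
bisection to $10^{-6}$; with the printed rates it yields $w \approx 3.34$
(RhoA dominates, as the low-expression retraction requires).

`build_phenotype_map()` scores regular trains (default per-pulse fold 1.5,
the source does not print the value; the 1.1–3 sweep covers the
sensitivity) over a $(\rho, \mathrm{period})$ grid. Two structural notes:

* Along the period axis, $\gamma$ has small sawtooth discontinuities
  because the number of pulses inside the fixed scoring window changes
  discretely with the period; labels can therefore dither between a strict
  label and mixed near the boundary. Rows still never place a protrusion
  at a longer period than a retraction.
* At very long periods (one pulse per window) retraction reappears even at
  high $\rho$, so the "switchable band" depends on which periods are
  compared. `switchable_band()` takes an explicit period subset; for the
  15–60 s comparison the band is $\rho \in [0.55, 0.60]$ (center
  $\approx 0.575$) with the default calibration, consistent with the
  reported transition at $\rho \sim 0.5$.

`intensity_sweep()` confirms that scaling only the per-pulse fold never
flips the label at fixed $\rho$ — all terms of the model scale with the
input — and raises a model-behavior flag if it ever does.

## The synthetic-data generator

`gen_cell_traces()`/`gen_cohort()` stand in for the microscopy. They
emulate: pulsed recruitment with the 20 s off-kinetics; biosensor traces
obeying the model at the cell's $\rho$ (including the dip-then-rise shape
at high expression); independent multiplicative Gaussian noise per frame
(default 5%, no temporal autocorrelation — the simplest model sufficient
to exercise the fitters); and a cohort whose expression straddles the
threshold. Expression is log-normal with `meanlog = log(40)` and
`sdlog = 1` — centered on the threshold with the decade-plus spread
typical of transient transfection — and maps linearly to the model by
$\rho = I / (2\,I_\mathrm{thresh})$, anchoring the empirical ~40 a.u.
threshold to the model transition $\rho = 0.5$ (the intensity scale is an
arbitrary-unit convention). The membrane-area response is a deliberate
affine stand-in, not a mechanical model:
$\mathrm{area}(t) = 1 - \beta\,\gamma\,s(t)$ with gain $\beta = 0.6$ and a
smooth ramp $s(t)$ saturating at 150 s, read out at 5 min by the same
gray-zone classifier used for real area traces.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: temporally correlated acquisition noise,
photobleaching and focus drift, cell-to-cell variability in $k_2$ or
$k_\mathrm{off}$, auto-amplification of RhoA activity (the source notes
some observed curve families lie outside the model), and any real membrane
mechanics behind the area readout. Near the threshold the generator
produces genuinely ambiguous cells: with zero noise, cells just below
40 a.u. have $|\beta\gamma|$ inside the classifier dead band and are
labeled mixed, so even the noiseless confusion matrix is not exactly
diagonal at the boundary — matching how mixed phenotypes cluster at
intermediate expression in the data.

## Trace quantification

`normalize_biosensor()` implements the four-step normalization (background
subtraction; mean over cell ∩ activated region; division by the
non-activated cell mean; division by the pre-activation mean), with the
pre-activation baseline taken as the mean over all frames before
activation (the source does not specify a window). Masks are binary grids
with unit-square pixels and areas are pixel counts — no subpixel geometry,
matching thresholded-segmentation practice. `surface_displacement()` is
the normalized cell ∩ region area; `classify_from_area()` applies the
5-min gray-zone rule; `persistence()` is net-over-total displacement.
Background estimation is out of scope: background is a required input.
Optical-flow segmentation and ruffle metrics are likewise out of scope.

## Problem sizes and reproducibility

Simulation grids default to 1 s spacing; synthetic rate-recovery studies
use 20 cells × 20 min; the phenotype map in the shipped analysis is
31 × 23 grid points; recovery studies in the test suite use 12 seeds
(point estimates) and 3 noise levels × 8 seeds (consistency) — sizes at
which the Monte-Carlo conclusions are stable while the whole suite stays
quick to run. Every stochastic routine takes an explicit seed and restores
the caller's RNG state; cohorts are bit-reproducible given their seed.

## Known limitations

* The QSSA is trusted as printed; the underlying derivation appendix was
  not available, so the mass-action oracle (which reproduces it in the
  fast-binding linear regime) is the package's internal evidence.
* $(k_2, k_\mathrm{off})$ are separable only through their magnitudes and
  the label convention; a cell line whose sensor were slower than its GAP
  background would be silently mislabeled by the convention.
* $\gamma$'s exact functional form, the gray-zone width, the per-pulse
  fold of the map, and the area-readout gain are conventions chosen once
  and documented above; conclusions that depend on them should use the
  provided sensitivity hooks (raw-difference $\gamma$, fold sweeps,
  configurable $\epsilon$, $\beta$).
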