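---
title: "Langmuir monolayer isotherm analysis and mixing thermodynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Langmuir monolayer isotherm analysis and mixing thermodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(monofilm)
```

## The measurement and the model

A Langmuir monolayer is a one-molecule-thick film of amphiphiles spread at
the air/water interface. Compressing it with a movable barrier while
recording the surface pressure $\pi$ (mN/m) against the mean molecular area
$A$ (Å²/molecule) yields the $\pi$–$A$ isotherm, the basic observable this
package analyses. Everything downstream rests on four quantities:

* **Lift-off area** — the largest area at which $\pi$ first rises
  measurably above zero.
* **Extrapolated area $A_0$** — the $\pi = 0$ intercept of a line through
  the steep (condensed) branch; a proxy for the in-film molecular cross
  section.
* **Collapse** $(\pi_\mathrm{coll}, A_\mathrm{coll})$ — the point where the
  film fails and ejects material into the third dimension, visible as a
  plateau, kink or pressure drop.
* **Compression modulus** $C_s^{-1} = -A\,(\mathrm{d}\pi/\mathrm{d}A)$ —
  its maximum classifies the film phase by the conventional magnitude
  bands: $<12.5$ gaseous, $12.5$–$50$ liquid-expanded, $50$–$100$ liquid,
  $100$–$250$ liquid-condensed, $>250$ mN/m solid.

For mixed films of composition $X$ the analysis compares the measured mean
area $A_{12}(\pi)$ with the ideal reference
$A_{12}^{id} = \sum_i X_i A_i(\pi)$ built from the pure-component
isotherms at the same pressure. The excess area
$A^{exc} = A_{12} - A_{12}^{id}$ integrates to the excess free enthalpy of
mixing

$$\Delta G^{exc}(\pi) = N_A \int_0^{\pi} A^{exc}\,\mathrm{d}\pi',$$

with the exact unit factor $N_A \times 10^{-23} = 6.02214076$ J·mol⁻¹ per
(Å²·mN/m). Negative values mean the mixture packs more tightly than the
ideal reference — attraction; positive values mean repulsion and a
tendency to demix. Miscibility is cross-checked with the two-dimensional
phase rule: miscible components shift the collapse pressure with
composition, immiscible ones collapse independently at (or pinned to)
their pure-component pressures, sometimes as two collapses in a single
run.

Finally, molecular shape enters through the Israelachvili critical packing
parameter $s = V/(a\,l_c)$, with the chain volume and critical length from
the group-increment formulas $V = 27.4 + 26.9\,n_c$ (Å³) and
$l_c = 1.5 + 1.265\,n_c$ (Å).

## A worked pass through the pipeline

```{r example}
lib <- fixture_library()
iso <- generate_isotherm(lib$erpc_like)
descriptor_set(iso)

ser <- generate_mixture_series(mixture_spec(
  components = list(chol = lib$chol_like, hepc = lib$hepc_like),
  fractions  = lapply(c(0.3, 0.5, 0.7), function(x) c(1 - x, x)),
  beta = 37, pi_ref = 30))
dg_vs_composition(ser, pi = 30)
```

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `smoothing_window` | 11 points | — | width of the local least-squares cubic used for $\mathrm{d}\pi/\mathrm{d}A$; raise to ~21 for noisy data (see below) |
| `lift_off_threshold` | 0.5 | mN/m | detection level above the sensor-noise floor; 3 consecutive points required |
| `a0_fraction` | 0.85 | — | $A_0$ is fitted where $C_s^{-1} \ge 0.85\,C_{s,\max}^{-1}$ (the "steepest linear segment" convention) |
| `slope_fraction` | 0.1 | — | collapse onset: $|\mathrm{d}\pi/\mathrm{d}A|$ falls below this fraction of its running maximum |
| `min_pressure` | 5 | mN/m | collapse search starts above the region where LE–LC transition plateaus live |
| `grid_step` | 0.25 | mN/m | trapezoidal integration grid for $\Delta G^{exc}$; results change $<0.05\%$ on halving |
| miscibility `tolerance` | 1.5 | mN/m | collapse-pressure matching window, set from typical isotherm reproducibility (±2 Å², ±0.1 mN/m) |
| analysis pressures | 5, 10, 20, 30, 35 | mN/m | multi-pressure panels; 30 mN/m is the monolayer–bilayer correspondence pressure used for headline comparisons |

## What the synthetic generator emulates — and what it does not

The generator's pre-collapse branch is the closed form
$A(\pi) = A_\mathrm{coll} + (A_\mathrm{lift} - A_\mathrm{coll})
\left(\frac{\pi_\mathrm{coll} - \pi}{\pi_\mathrm{coll}}\right)^\gamma$,
so $A(0)$ and $A(\pi_\mathrm{coll})$ hit the specified lift-off and
collapse areas exactly and every analysis stage has an analytic oracle
(`isotherm_truth()`, `truth_descriptors()`, `mixture_dg_oracle()`). The
bundled fixtures encode the characteristic parameters of the six film
families the package targets — three single-chain antitumor
alkylphosphocholines (C16, C18, C22:1-like), DPPC, POPC and cholesterol —
with $\gamma$ set from each film's maximum compression modulus via
$C_{s,\max}^{-1} = A_\mathrm{lift}\,\pi_\mathrm{coll}/
(\gamma\,(A_\mathrm{lift}-A_\mathrm{coll}))$, the closed-form modulus at
the lift-off end. Mixed films add a single symmetric interaction term,
$A_{mix} = \sum_i X_i A_i - \beta X_1 X_2 (1 + \pi/\pi_{ref})$: the
simplest family that controls the sign, magnitude and
composition-of-extremum of $A^{exc}$ and integrates in closed form.
Sensor noise is Gaussian on $\pi$ (typically 0.05 mN/m, the accuracy
scale of a Wilhelmy plate); specifying noise without a seed is an error,
so fixtures are reproducible by construction.

Design choices inside the generator worth knowing:

* An LE–LC transition plateau is inserted with a **1.5 mN/m pressure rise**
  across its width. Real transition plateaus are not horizontal, and a
  perfectly flat one would be indistinguishable from a collapse plateau
  under the slope criterion — the rise keeps the two physically distinct
  features distinct in the synthetic data too.
* Within this one-exponent family the modulus maximum sits at the
  lift-off end for $\gamma \lesssim 1.2$ (so $A_0 \approx$ lift-off) and
  diverges toward collapse for larger $\gamma$. Real condensed films stop
  at intermediate $A_0$ values the family cannot represent; descriptor
  recovery is therefore checked against the generator's own closed-form
  truth (same fit-region definition, analytic derivative), not against
  literature $A_0$ values.
* Mixed-film collapse pressures default to the $X$-weighted average of
  the pure values, capped at the lowest collapse among the components
  present; immiscible-style behaviour (pinned collapse, double collapse)
  is opted into per composition.

Passing tests on these fixtures show that the estimators recover known
ground truth through realistic curve shapes, kinks and noise. They do
**not** show robustness to drift, impurity artefacts, film leakage past
the barrier, relaxation during compression, or equation-of-state families
unlike the power form — real-data results should always be inspected
alongside the compression-modulus profile.

## Numerical choices

* **Derivative estimation.** $\mathrm{d}\pi/\mathrm{d}A$ comes from a
  local least-squares cubic on a sliding window (the uneven-spacing
  generalisation of Savitzky–Golay); raw finite differences are unusable
  at ±0.1 mN/m noise. Points whose window straddles the lift-off kink are
  excluded from the modulus maximum, where the polynomial overshoots.
  The 11-point default resolves the noise-free fixtures; the acceptance
  runs use 21 points for 0.05 mN/m noise since the derivative noise
  scales as $w^{-3/2}$.
* **Collapse detection.** An onset is flagged where the smoothed slope
  stays below `slope_fraction` × its running maximum (or the pressure
  drops by more than 0.75 mN/m from its maximum) for 3 consecutive
  points, *and* the median slope over the following 15 points confirms
  it — single-point dips are smoothing ringing at plateau corners, not
  collapses. After an onset, search resumes once the slope re-steepens
  above 3× the plateau slope; a secondary event must lie at least 1 mN/m
  above the primary. Onsets, not plateau midpoints, are reported.
* **Interpolation.** Resampling onto the pressure grid is monotone
  piecewise-linear through the record (running-maximum) points of the
  pressure trace: isotherms have kinks that splines overshoot, and the
  record filter is what makes noisy traces invertible. $A(0)$ is defined
  as the lift-off area so the $\Delta G^{exc}$ integral starts at exactly
  $\pi = 0$; lift-off itself is back-extrapolated to $\pi = 0$ from a
  short window above the detection threshold (short on purpose — branch
  curvature would bias a long fit).
* **Integration.** Trapezoidal on the uniform grid: exact for the
  generator's linear-in-$\pi$ excess term, robust at kinks, and
  convergence is testable by grid refinement.
* **Shape banding.** Cone/truncated-cone boundary at $s = 1/3$ with a
  0.005 tolerance assigning boundary cases to the truncated cone: the
  group-increment inputs carry ~1% uncertainty, so an $s$
  indistinguishable from the cone limit should not flip class on the
  fourth decimal (the C22:1 reference value, $s = 0.3332$, is the case
  in point). Cylinder band $1 \pm 0.05$.
* **Ternary reference.** For pseudo-binary membrane series the default
  ideal area is the three-component weighted sum $\sum_i X_i A_i$ — the
  direct generalisation of the binary formula. Referencing the binary
  host film plus the pure guest instead answers a different question
  ("does the guest stabilise the existing membrane?") and is exposed as
  `reference = "pseudo_binary"`; the two agree at the endpoints but not
  in between, and neither is canonical in the mixed-film literature.
* **Degenerate inputs.** Films that never reach the lift-off threshold,
  grids above the usable pre-collapse range, over-tight $A_0$ fit
  regions, and interaction strengths that drive the mixed area negative
  all fail fast with errors naming the offending quantity.

## Problem sizes

Synthetic isotherms use 400 points (descriptor work) or 300 points
(series work) per compression run, five-point mole-fraction grids, and a
0.25 mN/m integration grid — the scale of one afternoon of trough work,
chosen so the full test suite and the acceptance script run in seconds
while leaving interpolation error an order of magnitude below every
stated tolerance.

## Known limitations

* Compression-only: no hysteresis, relaxation or expansion-cycle
  analysis.
* The miscibility classifier follows the phase rule only; it does not fit
  regular-solution interaction parameters or construct surface phase
  diagrams.
* $A_0$ on strongly condensing films ($\gamma \gg 1$ fixtures) depends on
  the fit-region convention; compare conventions before quoting absolute
  values.
* The packing-parameter formulas cover saturated single chains; rings,
  double bonds and multi-chain lipids require explicit $l_c$/$V$ values,
  as in the bundled reference table.
* Temperature enters as metadata only; no equation-of-state or
  temperature-series modelling.
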