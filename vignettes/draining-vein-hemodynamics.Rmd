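---
title: "Reduced-order hemodynamics of AVM draining veins: model, generator and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reduced-order hemodynamics of AVM draining veins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(veinflow)
```

## The model and its assumptions

`veinflow` treats an AVM draining vein as a single channel: a smooth 3D
centerline with a per-station lumen radius $R(s)$, $s$ the arclength from
the nidus-side inlet. Blood is incompressible and Newtonian with density
$\rho = 1066\ \mathrm{kg\,m^{-3}}$ and dynamic viscosity
$\mu = 0.0035\ \mathrm{Pa\,s}$; the wall is rigid with no slip. The flow is
steady, driven by a prescribed mean velocity $v_{in}$ at the inlet, with
$0\ \mathrm{Pa}$ gauge pressure at the outlet standing in for venous sinus
pressure.

In this regime (velocities of order $0.01$–$0.15\ \mathrm{m\,s^{-1}}$,
radii of a few mm, inlet Reynolds numbers of order $10^1$–$10^2$) the flow
is laminar, and the package closes the axial momentum balance with the
fully developed (Hagen–Poiseuille) profile applied locally:

$$Q = v_{in} A_{in}, \qquad \bar v(s) = Q/A(s), \qquad
\frac{dp}{ds} = -\frac{8 \mu Q}{\pi R(s)^4}, \qquad
\tau_w(s) = \frac{4 \mu Q}{\pi R(s)^3}.$$

The pressure is integrated backward from the outlet by composite
trapezoid on the station grid, so $p(\text{outlet})$ equals the boundary
value exactly and mass conservation $\bar v(s) A(s) = Q$ holds to machine
precision. Surface WSS, when a triangulated surface is present, is the
station value mapped to each face from the nearest centerline station.

This quasi-1D closure is a deliberate trade: every output is analytically
auditable (a uniform tube reproduces the closed-form Hagen–Poiseuille drop
to $10^{-10}$ relative; tapered tubes are checked against brute-force
quadrature at 100$\times$ station density), at the price of discarding 3D
effects. Specifically *not* modelled: secondary (Dean) flows in bends,
entrance and expansion losses, pulsatility, wall compliance, non-Newtonian
rheology. A multiplicative resistance-correction profile $C(s)$ (default
$\equiv 1$) is accepted by `solve_steady_flow()` as a hook for such terms;
it scales the local pressure gradient and nothing else.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| density $\rho$ | 1066 | kg/m³ | standard whole-blood value |
| viscosity $\mu$ | 0.0035 | Pa·s | standard whole-blood value |
| outlet pressure | 0 | Pa | venous sinus reference |
| pressure report offset | 1000 | Pa | reporting reference: published per-segment pressures in this field sit on a ~1000–1075 Pa scale while the boundary condition is 0 Pa at the outlet; the offset is additive, affects no gradient, difference or test statistic, and setting it to 0 recovers the raw field |
| segments $K$ | 15 | — | the spatial resolution at which per-segment pressure/WSS/velocity are reported; groups A = 1–5, B = 6–10, C = 11–15 (posterior/outflow third) |
| high-velocity threshold | 0.113 | m/s | top of the 0–0.15 m/s velocity reporting scale; strict `>` |
| stations | 301 | — | ≥ 20 stations per segment at K = 15 |

## The synthetic generator: what it emulates

No patient geometries ship with the package; the generator replaces them
with parametric tubes whose *morphology distributions* match what is
reported for real draining-vein cohorts:

- **Centerline.** A straight axis plus a helical perturbation (one turn by
  default) under a half-sine envelope, so both endpoints stay on the axis
  and the chord equals the axis length. When a tortuosity-index target is
  given, the helix amplitude is solved by root finding so the realized
  index (actual/absolute length) lands within 1% of the target; stations
  are then resampled at equal arclength. A helix was chosen over planar
  sine modes because its curvature stays bounded as tortuosity grows, so
  indices up to ~3.2 remain buildable without the swept surface locally
  self-intersecting; the generator still warns whenever the curvature
  radius anywhere falls below the tube radius.
- **Radius profile.** Geometric (exponential-in-$s$) interpolation from
  inlet radius to $R_{in}\sqrt{\text{area ratio}}$, so the outlet/inlet
  area ratio is hit exactly; optional Gaussian stenosis (center radius
  $(1-\text{severity})\times$ baseline) and venous-aneurysm bulge
  (center radius $\text{bulge}\times$ baseline).
- **Cohort defaults.** Two groups: *ruptured-like* — strong distal taper
  (area-ratio median 0.29) and higher inlet velocity (median 0.04 m/s) —
  and *unruptured-like* — near-uniform caliber (ratio median 0.74) and
  lower velocity (median 0.02 m/s). Continuous parameters are log-normal
  with medians equal to the reference group medians and `sdlog` fitted to
  the published interquartile ranges (`sdlog = log(Q3/Q1)/(2·0.6745)`;
  where the printed IQR is asymmetric on the log scale this is the
  symmetric least-squares fit). Stenosis/aneurysm prevalences (17%/33%
  ruptured, 20%/40% unruptured) follow the reference cohort. Hard clamps
  (inlet area 3–120 mm², ratio 0.12–2, tortuosity 1.02–3.2, velocity
  0.005–0.15 m/s) keep extreme tail draws physically meshable without
  moving any group median.
- **Determinism.** All randomness descends from one master seed; child
  seeds per subject are derived deterministically, and identical
  parameters give byte-identical STL/CSV artifacts (the pipeline manifest
  checksums verify this end to end).

What the generator does **not** emulate: branching/accessory veins,
nidus-side geometry, caliber irregularity beyond the two focal bumps,
imaging segmentation noise, and any coupling between parameters (draws are
independent per subject). Consequently a green cohort-level test
establishes that the *pipeline* recovers the effects the generator builds
in (taper → distal velocity/WSS amplification → pressure elevation), not
that real ruptured veins behave this way.

## Numerical choices

- Equal-arclength station resampling by linear interpolation on an
  8$\times$-refined parameter grid; refinement changes the actual length
  by well under 0.5%.
- Trapezoid integration of the pressure gradient on the station grid;
  halving the spacing moves the inlet pressure by < 0.1%.
- Segment boundaries are exact multiples of $L/K$; a station exactly on a
  boundary joins the downstream (higher-index) segment — arbitrary but
  fixed and tested. Segment 1 is the inlet (nidus) end, consistent with
  pressure decreasing toward segment 15.
- Segment and patient averages are arclength-weighted station means
  (trapezoid weights); maxima are taken over stations. With the
  reduced-order solver there is no surface/volume-average distinction to
  make.
- Quantiles use the linear-interpolation convention (R type 7).
- Mann–Whitney: exact two-sided p (via the exact U null distribution)
  when both groups have ≤ 10 observations and no ties; otherwise the
  normal approximation with tie-corrected variance and no continuity
  correction. At 20 vs 20 the attained level of that rule is 0.0491,
  verified directly from the null distribution in the test suite.
- Spearman trends use mid-ranks (tie-corrected) then Pearson, with the
  $t$ approximation for p; constant inputs return a flagged degenerate
  result instead of NaN. Both Spearman and Pearson pooled trends are
  reported, since "linear correlation with segmenting" and "Spearman rank
  method" name different estimators; cohort conclusions use direction and
  the $|R| > 0.5$ strength convention.
- The 2×2 high-velocity test is Pearson chi-squared without continuity
  correction (Fisher's exact available); the same comparison is also run
  as a per-patient Mann–Whitney on flag counts, because segment-level and
  patient-level testing answer different questions and published analyses
  have mixed the two.
- No multiple-testing correction is applied across the ~20 comparisons,
  mirroring the analysis convention this package reproduces; treat
  individual p-values accordingly.

## Design decisions that were genuinely open

- **Pooling for trends.** Segment trends pool all subjects' per-segment
  values (e.g. 6 × 15 = 90 points) to yield one correlation per group;
  per-patient trends are also computable from the long segment table.
  Pooled rank correlations are diluted by between-patient level spread —
  see limitations.
- **Tortuosity targeting.** The parameter set carries both a raw helix
  amplitude and an optional tortuosity-index target; the target, when
  present, wins, and the amplitude is solved. In raw-amplitude mode the
  chord is solved so the actual length still matches the target length.
- **Cap areas.** Measured on the planar mesh caps when a surface exists
  (so imported STLs behave identically to generated ones), analytic
  $\pi R^2$ otherwise. A 32-gon cap underestimates the disc area by 0.6%;
  the area *ratio* is unaffected.
- **Velocity-threshold reading.** The high-velocity definition is applied
  to the segment-mean velocity with a strict inequality; a segment sitting
  exactly at 0.113 m/s is not flagged.

## Known limitations

- Within one vessel the closure makes WSS and velocity *deterministic,
  strictly monotone* functions of the radius profile. Real CFD fields
  carry 3D variability that this model cannot produce, so pooled
  segment-trend correlations in near-uniform veins are noisier in reality
  than here: with 5 subjects the pooled unruptured WSS trend ranges widely
  over master seeds (its large-cohort value under the defaults is
  ρ ≈ 0.18), and single-seed cohort results at n = 11 should be read as
  one draw, not an expectation.
- The inlet Reynolds number is recorded per vein (order $10^1$–$10^2$
  under the defaults); the laminar closure is inapplicable to genuinely
  turbulent regimes and the solver makes no attempt to model them.
- Reported pressures are gauge + offset; only differences and gradients
  are physically meaningful.
- The generator draws parameters independently within group; real
  morphology covaries (larger veins carry larger flows), so derived
  quantities (e.g. patient WSS averages) have wider spread here than in
  published cohorts.
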