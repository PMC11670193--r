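# veinflow

Reduced-order hemodynamics of cerebral arteriovenous-malformation (AVM)
draining veins.

## The problem

The vein draining an AVM nidus carries arterialized, high-rate flow
directly into a dural sinus. Elevated intravascular pressure, wall shear
stress (WSS) concentrated in the outflow-proximal ("posterior") portion,
and high-velocity segments along the vein are candidate markers of rupture
risk, but patient CTA/DSA reconstructions are rarely shareable. `veinflow`
is for researchers who want a fully reproducible, analytically auditable
version of that analysis chain: synthetic vein cohorts with controlled
morphology, a steady flow solve with physiological boundary conditions,
equal-arclength spatial summaries, and the nonparametric statistics used to
compare ruptured against unruptured veins.

## The model

A vein is a tube around a 3D centerline with per-station radius `R(s)`.
Blood is incompressible and Newtonian (density `ρ = 1066 kg/m³`, dynamic
viscosity `μ = 0.0035 Pa·s`); walls are rigid with no slip. With a mean
velocity `v_in` prescribed at the inlet and `0 Pa` at the outlet (venous
sinus), the quasi-1D fully developed laminar (Hagen–Poiseuille) closure
gives, per station:

    Q      = v_in · A_in                 (conserved flow rate)
    v(s)   = Q / A(s)
    dp/ds  = −8 μ Q / (π R(s)⁴)          (integrated backward from the outlet)
    τw(s)  = 4 μ Q / (π R(s)³)           (wall shear stress)
    Re     = ρ v_in 2R_in / μ

The centerline is split into `K = 15` equal-arclength segments (1 = inlet,
15 = outlet), grouped A (1–5), B (6–10), C (11–15). A segment is
*high-velocity* when its mean velocity strictly exceeds `0.113 m/s`.
Morphology metrics: tortuosity index = actual length / absolute length;
outlet/inlet cross-sectional area ratio. Cohort comparisons use the
Mann–Whitney U test (exact for ≤ 10 per group without ties), segment trends
use Spearman (and Pearson) correlations pooled across subjects, and
high-velocity proportions use the 2×2 Pearson chi-squared test.

## Worked example

```r
library(veinflow)

# a "ruptured-like" vein: strong distal taper, moderate inlet velocity
g <- generate_vessel(vessel_params(
  inlet_radius = 2.7, outlet_inlet_area_ratio = 0.29,
  target_actual_length = 63, tortuosity_index = 1.5, inlet_velocity = 0.04))
sol  <- solve_steady_flow(g)
segs <- summarize_segments(sol, divide_segments(g, 15))
vein_record("demo", TRUE, g, sol, segs)
```

prints

```
<vein_record> demo (ruptured)
  area ratio 0.290, tortuosity 1.500, actual length 63.0 mm
  pressure avg/max 1029.29 / 1042.58 Pa; WSS avg/max 0.604 / 1.328 Pa
  high-velocity segments: 2 of 15
```

The taper (area ratio 0.29) accelerates the flow from 0.040 to 0.138 m/s,
so WSS rises from 0.21 Pa at the inlet to 1.33 Pa distally and the last two
segments cross the 0.113 m/s threshold. Reported pressures are gauge
pressure plus a 1000 Pa reporting reference (the outlet is 0 Pa gauge), so
the 42.6 Pa inlet–outlet drop reads as 1042.6 → 1000.0 Pa.

The printed 2×2 high-velocity comparison of a reference cohort
(36 flagged of 90 ruptured segments vs 11 of 75 unruptured):

```r
high_velocity_contingency(36, 90, 11, 75)
#> <stat_result> Pearson chi-squared (2x2, no continuity correction)
#>   statistic = 12.89, p = 0.0003307, direction = +1, n = 90 vs 75
#>   estimate  = 25.3          # 40.0% − 14.7%, percentage-point difference
```

A full synthetic cohort (6 ruptured-like vs 5 unruptured-like subjects,
deterministic in the master seed):

```r
stats <- run_pipeline(pipeline_config(cohort = cohort_config(6, 5,
                        master_seed = 1066)), out_dir = "out")
stats$comparisons$pressure_avg   # median [IQR] per group + Mann-Whitney p
stats$trends$ruptured$wss        # pooled WSS-vs-segment correlation
```

`out/` then contains, per subject, `*_centerline.csv`, `*_flow.csv`,
`*_segments.csv`, `*.stl`, `*_wss.vtk`, plus `cohort.csv`, `segments.csv`,
`comparisons.csv`, `trends.csv`, `report.md` and a `manifest.json` whose
MD5 checksums are identical for identical (config, seed).

## Command line

```sh
Rscript inst/cli/veinflow.R run-all --seed 1066 --out results/run1
Rscript inst/cli/veinflow.R solve --centerline vein.csv --inlet-velocity 0.05 --out results/one
```

Subcommands: `generate`, `solve`, `summarize`, `stats`, `run-all`; flags
include `--config` (JSON), `--k-segments`, `--velocity-threshold`,
`--pressure-offset`, `--exact-mw`/`--approx-mw`, `--no-meshes`.

## Scope

No DICOM/CTA segmentation, no 3D Navier–Stokes, no pulsatile flow or
oscillatory shear indices, no branching veins: the object modelled is a
single dominant draining channel in the steady, laminar, rigid-wall
regime. See `vignettes/draining-vein-hemodynamics.Rmd` for the model's
assumptions, the generator's defaults and what a green test does and does
not establish.
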