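Package: veinflow
Title: Reduced-Order Hemodynamics of Cerebral AVM Draining Veins
Version: 0.1.0
Authors@R: person("Vein", "Flow Maintainers", email = "maintainers@veinflow.example", role = c("aut", "cre"))
Description: Synthetic tubular vein geometries, a quasi one-dimensional
    steady incompressible (Hagen-Poiseuille closure) blood flow solver with
    physiological boundary conditions, equal-arclength centerline
    segmentation with per-segment pressure / wall shear stress / velocity
    summaries and high-velocity flagging, and the nonparametric cohort
    statistics (Mann-Whitney U, Spearman rank trends, 2x2 chi-squared)
    used to compare ruptured-like and unruptured-like arteriovenous
    malformation draining veins.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
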