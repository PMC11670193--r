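# Cohort sampling: per-group parameter draws with deterministic child seeds.

#' Generate a synthetic cohort of vessel parameter sets
#'
#' Draws `n_ruptured + n_unruptured` vessel parameter sets from the
#' per-group distributions of a [cohort_config()]. All randomness derives
#' deterministically from `master_seed`: the same configuration always
#' yields the same parameter list, and every vessel carries its own child
#' seed.
#'
#' @param config A [cohort_config()].
#' @return List of entries `list(id, rupture, params)`, ruptured subjects
#'   first, of class `cohort_draw`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n_tot <- config$n_ruptured + config$n_unruptured
  seeds <- derive_seeds(config$master_seed, n_tot + 1L)
  rupture <- rep(c(TRUE, FALSE), c(config$n_ruptured, config$n_unruptured))
  ids <- c(sprintf("R%02d", seq_len(config$n_ruptured)),
           sprintf("U%02d", seq_len(config$n_unruptured)))
  out <- withr::with_seed(seeds[n_tot + 1L], {
    lapply(seq_len(n_tot), function(i) {
      g <- if (rupture[i]) config$ruptured else config$unruptured
      inlet_area <- draw_lognormal(g$inlet_area, 1)
      ratio <- draw_lognormal(g$area_ratio, 1)
      len <- draw_lognormal(g$actual_length, 1)
      tau <- 1 + draw_lognormal(g$tortuosity_minus_1, 1)
      vel <- draw_lognormal(g$velocity, 1)
      sten <- if (stats::runif(1) < g$p_stenosis) {
        list(position = stats::runif(1, g$bump_position[1], g$bump_position[2]),
             severity = stats::runif(1, g$stenosis_severity[1], g$stenosis_severity[2]))
      }
      aneu <- if (stats::runif(1) < g$p_aneurysm) {
        list(position = stats::runif(1, g$bump_position[1], g$bump_position[2]),
             bulge = stats::runif(1, g$aneurysm_bulge[1], g$aneurysm_bulge[2]))
      }
      phase <- stats::runif(1, 0, 2 * pi)
      list(id = ids[i], rupture = rupture[i],
           params = vessel_params(
             inlet_radius = sqrt(inlet_area / pi),
             outlet_inlet_area_ratio = ratio,
             target_actual_length = len,
             tortuosity_index = tau,
             tortuosity_wavelengths = g$wavelengths,
             helix_phase = phase,
             stenosis = sten, aneurysm = aneu,
             inlet_velocity = vel,
             seed = seeds[i]))
    })
  })
  class(out) <- "cohort_draw"
  out
}

#' @export
print.cohort_draw <- function(x, ...) {
  rup <- vapply(x, function(e) e$rupture, logical(1))
  cat(sprintf("<cohort_draw> %d subjects (%d ruptured, %d unruptured)\n",
              length(x), sum(rup), sum(!rup)))
  invisible(x)
}
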