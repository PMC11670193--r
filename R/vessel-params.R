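#' Parameters of a single synthetic draining vein
#'
#' Bundles the generative targets for one vessel: inlet caliber, distal
#' taper (outlet/inlet cross-sectional area ratio), centerline length and
#' tortuosity, optional focal stenosis or venous aneurysm, and the inlet
#' mean blood velocity used as the flow boundary condition.
#'
#' Geometry lengths are millimetres; velocities are m/s. The centerline is a
#' straight axis plus a helical perturbation (sinusoids in the two
#' transverse directions under a half-sine envelope, so both endpoints stay
#' on the axis). When `tortuosity_index` is given, the helix amplitude is
#' solved numerically so the realized tortuosity index (actual length /
#' absolute length) matches the target to better than 1%; otherwise
#' `tortuosity_amplitude` is used as-is and the chord is solved so the
#' realized actual length matches `target_actual_length`.
#'
#' @param inlet_radius Inlet lumen radius, mm (> 0).
#' @param outlet_inlet_area_ratio Outlet/inlet cross-sectional area ratio
#'   (> 0); values < 1 taper distally, 1 is a uniform tube.
#' @param target_actual_length Centerline arclength ("actual length"), mm.
#' @param tortuosity_index Target tortuosity index (actual/absolute length,
#'   >= 1), or `NA` to use `tortuosity_amplitude` directly.
#' @param tortuosity_amplitude Helix amplitude, mm (used when
#'   `tortuosity_index` is `NA`; default 0 gives a straight axis).
#' @param tortuosity_wavelengths Number of helix turns along the vessel.
#' @param helix_phase Phase of the helical perturbation, radians.
#' @param stenosis `NULL` or `list(position =, severity =)`: a Gaussian
#'   radius pinch at normalized arclength `position` in (0,1); at its center
#'   the radius is `(1 - severity)` times the local baseline. `severity`
#'   must be in `[0, 1)` -- no full occlusion.
#' @param aneurysm `NULL` or `list(position =, bulge =)`: a Gaussian radius
#'   bulge; at its center the radius is `bulge` (> 1) times baseline.
#' @param inlet_velocity Inlet mean velocity, m/s (>= 0).
#' @param n_stations Number of centerline stations (default 301, at least
#'   2K+1 for K segments so every segment holds stations).
#' @param seed Integer seed recorded with the vessel (the construction
#'   itself is deterministic given the parameters).
#' @return An object of class `vessel_params`.
#' @seealso [generate_vessel()], [cohort_config()]
#' @export
vessel_params <- function(inlet_radius = 2.7,
                          outlet_inlet_area_ratio = 1,
                          target_actual_length = 60,
                          tortuosity_index = NA_real_,
                          tortuosity_amplitude = 0,
                          tortuosity_wavelengths = 1L,
                          helix_phase = 0,
                          stenosis = NULL,
                          aneurysm = NULL,
                          inlet_velocity = 0.05,
                          n_stations = 301L,
                          seed = 1L) {
  vf_assert(is_scalar_number(inlet_radius) && inlet_radius > 0,
            "inlet_radius must be a positive number (mm)")
  vf_assert(is_scalar_number(outlet_inlet_area_ratio) && outlet_inlet_area_ratio > 0,
            "outlet_inlet_area_ratio must be > 0")
  vf_assert(is_scalar_number(target_actual_length) && target_actual_length > 0,
            "target_actual_length must be > 0 (mm)")
  vf_assert(is_scalar_number(tortuosity_amplitude) && tortuosity_amplitude >= 0,
            "tortuosity_amplitude must be >= 0 (mm)")
  if (!is.na(tortuosity_index)) {
    vf_assert(is_scalar_number(tortuosity_index) && tortuosity_index >= 1,
              "tortuosity_index target must be >= 1")
  }
  vf_assert(is_scalar_number(inlet_velocity) && inlet_velocity >= 0,
            "inlet_velocity must be >= 0 (m/s)")
  n_stations <- as.integer(n_stations)
  vf_assert(n_stations >= 2L, "n_stations must be >= 2")
  stenosis <- check_bump(stenosis, "stenosis")
  if (!is.null(stenosis)) {
    vf_assert(stenosis$severity >= 0 && stenosis$severity < 1,
              "stenosis severity must be in [0, 1): full occlusion is not representable")
  }
  aneurysm <- check_bump(aneurysm, "aneurysm")
  if (!is.null(aneurysm)) {
    vf_assert(aneurysm$bulge > 1, "aneurysm bulge factor must be > 1")
  }
  structure(list(
    inlet_radius = inlet_radius,
    outlet_inlet_area_ratio = outlet_inlet_area_ratio,
    target_actual_length = target_actual_length,
    tortuosity_index = tortuosity_index,
    tortuosity_amplitude = tortuosity_amplitude,
    tortuosity_wavelengths = as.integer(tortuosity_wavelengths),
    helix_phase = helix_phase,
    stenosis = stenosis,
    aneurysm = aneurysm,
    inlet_velocity = inlet_velocity,
    n_stations = n_stations,
    seed = as.integer(seed)
  ), class = "vessel_params")
}

check_bump <- function(b, what) {
  if (is.null(b)) return(NULL)
  vf_assert(is.list(b) && is_scalar_number(b$position),
            sprintf("%s must be NULL or a list with a numeric 'position'", what))
  vf_assert(b$position > 0 && b$position < 1,
            sprintf("%s position must lie strictly inside (0, 1)", what))
  if (what == "stenosis") {
    vf_assert(is_scalar_number(b$severity), "stenosis needs a numeric 'severity'")
    b$width <- b$width %||% 0.05
  } else {
    vf_assert(is_scalar_number(b$bulge), "aneurysm needs a numeric 'bulge'")
    b$width <- b$width %||% 0.08
  }
  vf_assert(is_scalar_number(b$width) && b$width > 0,
            sprintf("%s width must be > 0", what))
  b
}

#' @export
print.vessel_params <- function(x, ...) {
  cat("<vessel_params>\n")
  cat(sprintf("  inlet radius      %.3f mm (area %.2f mm^2)\n",
              x$inlet_radius, pi * x$inlet_radius^2))
  cat(sprintf("  area ratio        %.3f\n", x$outlet_inlet_area_ratio))
  cat(sprintf("  actual length     %.1f mm, tortuosity target %s\n",
              x$target_actual_length,
              if (is.na(x$tortuosity_index)) sprintf("(amplitude %.2f mm)", x$tortuosity_amplitude)
              else sprintf("%.3f", x$tortuosity_index)))
  if (!is.null(x$stenosis))
    cat(sprintf("  stenosis          s=%.2f severity %.2f\n",
                x$stenosis$position, x$stenosis$severity))
  if (!is.null(x$aneurysm))
    cat(sprintf("  aneurysm          s=%.2f bulge %.2f\n",
                x$aneurysm$position, x$aneurysm$bulge))
  cat(sprintf("  inlet velocity    %.3f m/s; %d stations; seed %d\n",
              x$inlet_velocity, x$n_stations, x$seed))
  invisible(x)
}

# One generative distribution: log-normal parameterized by its median and
# the spread of its central 50% (sdlog), with hard physical clamps.
lognormal_spec <- function(median, sdlog, lower = -Inf, upper = Inf) {
  vf_assert(is_scalar_number(median) && median > 0,
            "distribution medians must be positive")
  vf_assert(is_scalar_number(sdlog) && sdlog >= 0, "sdlog must be >= 0")
  list(median = median, sdlog = sdlog, lower = lower, upper = upper)
}

draw_lognormal <- function(spec, n) {
  clamp(stats::rlnorm(n, meanlog = log(spec$median), sdlog = spec$sdlog),
        spec$lower, spec$upper)
}

# sdlog implied by a printed [Q1, Q3] interquartile range of a log-normal
sdlog_from_iqr <- function(q1, q3) log(q3 / q1) / (2 * stats::qnorm(0.75))

#' Cohort generation configuration
#'
#' Describes the two synthetic groups -- "ruptured-like" veins (strong
#' distal taper, higher inlet velocity) and "unruptured-like" veins
#' (near-uniform caliber, lower velocity) -- as per-group sampling
#' distributions for every vessel parameter. Continuous parameters are
#' log-normal, parameterized by their median (the group medians of the
#' reference cohort: e.g. outlet/inlet area ratio 0.29 ruptured vs 0.74
#' unruptured) with spreads set from the printed interquartile ranges;
#' stenosis/aneurysm prevalences and bump positions are Bernoulli/uniform.
#'
#' @param n_ruptured,n_unruptured Group sizes (>= 1).
#' @param ruptured,unruptured Per-group distribution lists; see
#'   [default_group_distributions()]. Any entry supplied here overrides the
#'   default for that group.
#' @param velocity_threshold High-velocity flag threshold, m/s.
#' @param master_seed Integer master seed; child seeds for each vessel are
#'   derived deterministically from it.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_ruptured = 6L, n_unruptured = 5L,
                          ruptured = list(), unruptured = list(),
                          velocity_threshold = 0.113,
                          master_seed = 1066L) {
  vf_assert(n_ruptured >= 1 && n_unruptured >= 1, "group sizes must be >= 1")
  vf_assert(is_scalar_number(velocity_threshold) && velocity_threshold > 0,
            "velocity_threshold must be > 0 (m/s)")
  r <- utils::modifyList(default_group_distributions("ruptured"), ruptured)
  u <- utils::modifyList(default_group_distributions("unruptured"), unruptured)
  for (g in list(r, u)) {
    for (nm in c("inlet_area", "area_ratio", "actual_length", "velocity")) {
      vf_assert(g[[nm]]$median > 0, sprintf("median of '%s' must be positive", nm))
    }
  }
  structure(list(
    n_ruptured = as.integer(n_ruptured),
    n_unruptured = as.integer(n_unruptured),
    ruptured = r, unruptured = u,
    velocity_threshold = velocity_threshold,
    master_seed = as.integer(master_seed)
  ), class = "cohort_config")
}

#' Default per-group sampling distributions
#'
#' Medians are the reference cohort's group medians (inlet area mm^2,
#' outlet/inlet area ratio, actual length mm, tortuosity index, inlet
#' velocity m/s); sdlog values come from the printed interquartile ranges
#' via `sdlog = log(Q3/Q1) / (2 * qnorm(0.75))`. Tortuosity is log-normal
#' on (index - 1). Hard clamps keep extreme tail draws physically meshable:
#' inlet area 3--120 mm^2, area ratio 0.12--2, actual length 20--110 mm,
#' tortuosity 1.02--3.2, inlet velocity 0.005--0.15 m/s (the velocity
#' reporting scale tops out at 0.15 m/s). Stenosis/aneurysm prevalences
#' follow the reference cohort (ruptured 16.7%/33.3%, unruptured
#' 20%/40%).
#'
#' @param group `"ruptured"` or `"unruptured"`.
#' @return Named list of distribution specifications.
#' @export
default_group_distributions <- function(group = c("ruptured", "unruptured")) {
  group <- match.arg(group)
  if (group == "ruptured") {
    list(
      inlet_area    = lognormal_spec(22.87, sdlog_from_iqr(10.93, 68.90), 3, 120),
      area_ratio    = lognormal_spec(0.29, sdlog_from_iqr(0.25, 0.35), 0.12, 2),
      actual_length = lognormal_spec(63.29, sdlog_from_iqr(36.11, 68.58), 20, 110),
      tortuosity_minus_1 = lognormal_spec(0.50, sdlog_from_iqr(0.40, 1.12), 0.02, 2.2),
      velocity      = lognormal_spec(0.04, 0.3, 0.005, 0.15),
      p_stenosis = 1 / 6, p_aneurysm = 2 / 6,
      stenosis_severity = c(0.3, 0.6), aneurysm_bulge = c(1.3, 1.8),
      bump_position = c(0.2, 0.8), wavelengths = 1L
    )
  } else {
    list(
      inlet_area    = lognormal_spec(29.86, sdlog_from_iqr(22.36, 39.17), 3, 120),
      area_ratio    = lognormal_spec(0.74, sdlog_from_iqr(0.63, 1.26), 0.12, 2),
      actual_length = lognormal_spec(71.20, sdlog_from_iqr(42.10, 80.12), 20, 110),
      tortuosity_minus_1 = lognormal_spec(1.06, sdlog_from_iqr(0.15, 2.22), 0.02, 2.2),
      velocity      = lognormal_spec(0.02, 0.3, 0.005, 0.15),
      p_stenosis = 1 / 5, p_aneurysm = 2 / 5,
      stenosis_severity = c(0.3, 0.6), aneurysm_bulge = c(1.3, 1.8),
      bump_position = c(0.2, 0.8), wavelengths = 1L
    )
  }
}
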