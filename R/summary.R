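# Per-segment and per-patient hemodynamic summaries.

#' Summarize a flow solution per segment
#'
#' Arclength-weighted means of reported pressure, wall shear stress and
#' mean velocity over each segment's member stations (trapezoid station
#' weights), the per-segment WSS and pressure maxima, and the
#' high-velocity flag: a segment is flagged when its mean velocity
#' strictly exceeds `threshold` (default 0.113 m/s, the top of the
#' velocity reporting scale).
#'
#' @param solution A [solve_steady_flow()] result.
#' @param scheme A [divide_segments()] scheme for the same geometry.
#' @param threshold High-velocity threshold, m/s (strict `>`).
#' @return Data frame (class `segment_summary`) with one row per segment:
#'   `segment_index`, `group`, `pressure_avg`, `pressure_max`, `wss_avg`,
#'   `wss_max`, `velocity_avg`, `high_velocity`, `arclength_weight_mm`.
#' @export
summarize_segments <- function(solution, scheme, threshold = 0.113) {
  stopifnot(inherits(solution, "flow_solution"),
            inherits(scheme, "segmentation_scheme"))
  st <- solution$stations
  seg <- scheme$segment_of_station
  vf_assert(length(seg) == nrow(st),
            "segmentation scheme and flow solution have different station counts")
  vf_assert(is_scalar_number(threshold) && threshold > 0, "threshold must be > 0")
  w <- trapezoid_weights(st$s_mm)
  K <- scheme$K
  idx <- factor(seg, levels = seq_len(K))
  wsum <- tapply(w, idx, sum)
  if (anyNA(wsum)) vf_stop("empty segment: no stations fall in some segment")
  wmean <- function(x) as.numeric(tapply(x * w, idx, sum) / wsum)
  out <- data.frame(
    segment_index = seq_len(K),
    group = group_of_segment(seq_len(K), scheme$groups),
    pressure_avg = wmean(st$pressure_reported_pa),
    pressure_max = as.numeric(tapply(st$pressure_reported_pa, idx, max)),
    wss_avg = wmean(st$wss_pa),
    wss_max = as.numeric(tapply(st$wss_pa, idx, max)),
    velocity_avg = wmean(st$velocity_mps),
    arclength_weight_mm = as.numeric(wsum)
  )
  out$high_velocity <- out$velocity_avg > threshold
  class(out) <- c("segment_summary", class(out))
  out
}

#' Patient-level summary from segment summaries
#'
#' Averages are arclength-weighted over all segments (hence all stations);
#' maxima are taken over the per-station maxima; `n_high_velocity` counts
#' flagged segments.
#'
#' @param segments A [summarize_segments()] data frame.
#' @return Named list: `pressure_avg`, `pressure_max`, `wss_avg`,
#'   `wss_max`, `velocity_avg`, `n_high_velocity`.
#' @export
summarize_patient <- function(segments) {
  stopifnot(inherits(segments, "segment_summary"))
  w <- segments$arclength_weight_mm
  list(pressure_avg = weighted_mean_(segments$pressure_avg, w),
       pressure_max = max(segments$pressure_max),
       wss_avg = weighted_mean_(segments$wss_avg, w),
       wss_max = max(segments$wss_max),
       velocity_avg = weighted_mean_(segments$velocity_avg, w),
       n_high_velocity = sum(segments$high_velocity))
}

#' Group-level (A/B/C) value of a quantity for each patient
#'
#' Arclength-weighted mean of a per-segment quantity over the segments of
#' one group (A = anterior third, B = middle, C = posterior/outflow
#' third), evaluated per patient. These are the AP/BP/CP, AWSS/BWSS/CWSS
#' and AV/BV/CV quantities of the segment-comparison table.
#'
#' @param records List of [vein_record()] objects.
#' @param group `"A"`, `"B"` or `"C"`.
#' @param quantity `"pressure_avg"`, `"wss_avg"` or `"velocity_avg"`.
#' @return Numeric vector, one value per record (named by subject id).
#' @export
group_segment_table <- function(records, group, quantity = c("pressure_avg", "wss_avg", "velocity_avg")) {
  quantity <- match.arg(quantity)
  vf_assert(is.character(group) && length(group) == 1L && group %in% c("A", "B", "C"),
            "unknown group label (expected \"A\", \"B\" or \"C\")")
  vapply(records, function(rec) {
    seg <- rec$segments[rec$segments$group == group, ]
    weighted_mean_(seg[[quantity]], seg$arclength_weight_mm)
  }, numeric(1), USE.NAMES = TRUE) -> out
  names(out) <- vapply(records, function(r) r$id, character(1))
  out
}

#' Assemble a per-subject vein record
#'
#' Bundles morphology, patient-level hemodynamics and the per-segment
#' summaries for one vein, with its rupture label.
#'
#' @param id Subject identifier.
#' @param rupture Logical rupture label.
#' @param geometry A [vessel_geometry()].
#' @param solution The matching [solve_steady_flow()] result.
#' @param segments The matching [summarize_segments()] data frame.
#' @return An object of class `vein_record`.
#' @export
vein_record <- function(id, rupture, geometry, solution, segments) {
  pat <- summarize_patient(segments)
  structure(list(
    id = id, rupture = isTRUE(rupture),
    morphology = list(
      inlet_area_mm2 = geometry$inlet_area_mm2,
      exit_area_mm2 = geometry$exit_area_mm2,
      area_ratio = area_ratio(geometry$exit_area_mm2, geometry$inlet_area_mm2),
      absolute_length_mm = absolute_length(geometry),
      actual_length_mm = actual_length(geometry),
      tortuosity_index = tortuosity_index(actual_length(geometry),
                                          absolute_length(geometry))),
    patient = pat,
    segments = segments,
    reynolds_number = solution$reynolds_number),
    class = "vein_record")
}

#' @export
print.vein_record <- function(x, ...) {
  cat(sprintf("<vein_record> %s (%s)\n", x$id,
              if (x$rupture) "ruptured" else "unruptured"))
  cat(sprintf("  area ratio %.3f, tortuosity %.3f, actual length %.1f mm\n",
              x$morphology$area_ratio, x$morphology$tortuosity_index,
              x$morphology$actual_length_mm))
  cat(sprintf("  pressure avg/max %.2f / %.2f Pa; WSS avg/max %.3f / %.3f Pa\n",
              x$patient$pressure_avg, x$patient$pressure_max,
              x$patient$wss_avg, x$patient$wss_max))
  cat(sprintf("  high-velocity segments: %d of %d\n",
              x$patient$n_high_velocity, nrow(x$segments)))
  invisible(x)
}

#' Tidy per-patient table of a cohort
#'
#' One row per subject with the morphology and patient-level hemodynamic
#' variables plus the A/B/C group-level pressure, WSS and velocity.
#'
#' @param records List of [vein_record()] objects.
#' @return Data frame, one row per subject.
#' @export
cohort_table <- function(records) {
  base <- do.call(rbind, lapply(records, function(r) {
    data.frame(id = r$id, rupture = r$rupture,
               inlet_area_mm2 = r$morphology$inlet_area_mm2,
               exit_area_mm2 = r$morphology$exit_area_mm2,
               area_ratio = r$morphology$area_ratio,
               absolute_length_mm = r$morphology$absolute_length_mm,
               actual_length_mm = r$morphology$actual_length_mm,
               tortuosity_index = r$morphology$tortuosity_index,
               pressure_avg = r$patient$pressure_avg,
               pressure_max = r$patient$pressure_max,
               wss_avg = r$patient$wss_avg,
               wss_max = r$patient$wss_max,
               velocity_avg = r$patient$velocity_avg,
               n_high_velocity = r$patient$n_high_velocity)
  }))
  for (g in c("A", "B", "C")) {
    base[[paste0(g, "P")]] <- group_segment_table(records, g, "pressure_avg")
    base[[paste0(g, "WSS")]] <- group_segment_table(records, g, "wss_avg")
    base[[paste0(g, "V")]] <- group_segment_table(records, g, "velocity_avg")
  }
  rownames(base) <- NULL
  base
}

#' Long per-segment table of a cohort
#'
#' One row per subject-segment; the pooled input for segment-trend
#' correlations and the per-segment high-velocity contingency table.
#'
#' @param records List of [vein_record()] objects.
#' @return Data frame with `id`, `rupture`, `segment_index`, `group`,
#'   `pressure_avg`, `wss_avg`, `wss_max`, `velocity_avg`,
#'   `high_velocity`.
#' @export
segment_table <- function(records) {
  out <- do.call(rbind, lapply(records, function(r) {
    cbind(data.frame(id = r$id, rupture = r$rupture),
          r$segments[, c("segment_index", "group", "pressure_avg", "wss_avg",
                         "wss_max", "velocity_avg", "high_velocity")])
  }))
  rownames(out) <- NULL
  out
}
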