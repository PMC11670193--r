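# End-to-end pipeline: cohort generation -> geometry -> flow solve ->
# segment summaries -> cohort statistics -> report bundle on disk.

#' Pipeline configuration
#'
#' @param cohort A [cohort_config()] (or list of arguments for one).
#' @param K Number of centerline segments.
#' @param velocity_threshold High-velocity flag threshold, m/s.
#' @param fluid A [fluid_properties()].
#' @param pressure_report_offset Reporting reference added to gauge
#'   pressures, Pa.
#' @param write_meshes Write STL/VTK surfaces per vein (slower; the
#'   centerline and flow CSVs are always written).
#' @param exact_mw Mann-Whitney mode: `"auto"`, `"yes"`, `"no"`.
#' @param quiet Suppress per-stage progress messages.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(), K = 15L,
                            velocity_threshold = 0.113,
                            fluid = fluid_properties(),
                            pressure_report_offset = 1000,
                            write_meshes = TRUE,
                            exact_mw = "auto",
                            quiet = FALSE) {
  if (!inherits(cohort, "cohort_config")) cohort <- do.call(cohort_config, cohort)
  vf_assert(K >= 1, "K must be >= 1")
  vf_assert(velocity_threshold > 0, "velocity_threshold must be > 0")
  vf_assert(pressure_report_offset >= 0, "pressure_report_offset must be >= 0")
  structure(list(cohort = cohort, K = as.integer(K),
                 velocity_threshold = velocity_threshold, fluid = fluid,
                 pressure_report_offset = pressure_report_offset,
                 write_meshes = isTRUE(write_meshes),
                 exact_mw = exact_mw, quiet = isTRUE(quiet)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' Recognized keys (all optional): `n_ruptured`, `n_unruptured`,
#' `master_seed`, `velocity_threshold`, `K`, `pressure_report_offset`,
#' `density`, `dynamic_viscosity`, `write_meshes`, `exact_mw`.
#' Unknown keys fail fast.
#'
#' @param path JSON file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("n_ruptured", "n_unruptured", "master_seed", "velocity_threshold",
             "K", "pressure_report_offset", "density", "dynamic_viscosity",
             "write_meshes", "exact_mw")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) {
    vf_stop("invalid config schema: unknown key(s) ", paste(bad, collapse = ", "))
  }
  co_args <- cfg[intersect(names(cfg), c("n_ruptured", "n_unruptured",
                                         "master_seed", "velocity_threshold"))]
  pipeline_config(
    cohort = do.call(cohort_config, co_args),
    K = cfg$K %||% 15L,
    velocity_threshold = cfg$velocity_threshold %||% 0.113,
    fluid = fluid_properties(density = cfg$density %||% 1066,
                             dynamic_viscosity = cfg$dynamic_viscosity %||% 0.0035),
    pressure_report_offset = cfg$pressure_report_offset %||% 1000,
    write_meshes = cfg$write_meshes %||% TRUE,
    exact_mw = cfg$exact_mw %||% "auto")
}

pipe_log <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf("[veinflow %s] ", format(Sys.time(), "%H:%M:%S")),
                      sprintf(fmt, ...))
}

# geometry -> segments -> flow -> summaries for one subject
analyze_vessel <- function(id, rupture, geometry, config) {
  scheme <- divide_segments(geometry, config$K)
  v_in <- geometry$params$inlet_velocity %||%
    vf_stop("geometry carries no inlet velocity; pass boundary conditions")
  bc <- boundary_conditions(v_in,
                            pressure_report_offset = config$pressure_report_offset)
  sol <- solve_steady_flow(geometry, bc, config$fluid)
  segs <- summarize_segments(sol, scheme, config$velocity_threshold)
  list(record = vein_record(id, rupture, geometry, sol, segs),
       geometry = geometry, scheme = scheme, solution = sol)
}

#' Full cohort statistics report
#'
#' Computes the morphology and patient-level group comparisons, the A/B/C
#' group-level segment comparisons, the pooled high-velocity contingency
#' analysis (per-segment chi-squared and Fisher; per-patient Mann-Whitney
#' on flag counts), and the pooled segment-trend correlations (Spearman and
#' Pearson) of pressure, WSS and velocity against segment index for each
#' group.
#'
#' @param records List of [vein_record()] objects.
#' @param exact_mw Passed to [mann_whitney()].
#' @return List with `cohort` (per-patient table), `segments` (long
#'   table), `comparisons`, `contingency`, `trends`; class
#'   `cohort_statistics`.
#' @export
cohort_statistics <- function(records, exact_mw = "auto") {
  tab <- cohort_table(records)
  seg <- segment_table(records)
  vars <- c("inlet_area_mm2", "exit_area_mm2", "area_ratio",
            "absolute_length_mm", "actual_length_mm", "tortuosity_index",
            "wss_avg", "wss_max", "pressure_avg", "pressure_max",
            "n_high_velocity",
            "AP", "BP", "CP", "AWSS", "BWSS", "CWSS", "AV", "BV", "CV")
  comparisons <- lapply(vars, function(v) compare_groups(tab, v, exact = exact_mw))
  names(comparisons) <- vars

  rup_seg <- seg[seg$rupture, ]
  unr_seg <- seg[!seg$rupture, ]
  contingency <- list(
    chisq = high_velocity_contingency(sum(rup_seg$high_velocity), nrow(rup_seg),
                                      sum(unr_seg$high_velocity), nrow(unr_seg)),
    fisher = high_velocity_contingency(sum(rup_seg$high_velocity), nrow(rup_seg),
                                       sum(unr_seg$high_velocity), nrow(unr_seg),
                                       method = "fisher"),
    per_patient = mann_whitney(tab$n_high_velocity[tab$rupture],
                               tab$n_high_velocity[!tab$rupture],
                               exact = exact_mw))

  trend_set <- function(d) {
    lapply(c(pressure = "pressure_avg", wss = "wss_avg",
             velocity = "velocity_avg"),
           function(q) list(spearman = spearman_trend(d$segment_index, d[[q]]),
                            pearson = pearson_trend(d$segment_index, d[[q]])))
  }
  trends <- list(ruptured = trend_set(rup_seg), unruptured = trend_set(unr_seg))
  structure(list(cohort = tab, segments = seg, comparisons = comparisons,
                 contingency = contingency, trends = trends),
            class = "cohort_statistics")
}

#' @export
print.cohort_statistics <- function(x, ...) {
  cat(sprintf("<cohort_statistics> %d subjects, %d segment rows\n",
              nrow(x$cohort), nrow(x$segments)))
  for (v in c("area_ratio", "pressure_avg", "pressure_max", "wss_avg", "CWSS")) {
    print(x$comparisons[[v]])
  }
  ct <- x$contingency$chisq
  cat(sprintf("high-velocity segments: %.1f%% vs %.1f%%, chi-squared p = %.3g ",
              ct$percent[1], ct$percent[2], ct$p_value))
  cat(sprintf("(per-patient Mann-Whitney p = %.3g)\n",
              x$contingency$per_patient$p_value))
  for (g in names(x$trends)) {
    tr <- x$trends[[g]]
    cat(sprintf("%s trends (Spearman rho): pressure %.3f, WSS %.3f, velocity %.3f\n",
                g, tr$pressure$spearman$estimate, tr$wss$spearman$estimate,
                tr$velocity$spearman$estimate))
  }
  invisible(x)
}

# flat CSV/markdown renderings of the comparisons
comparisons_frame <- function(stats) {
  do.call(rbind, lapply(stats$comparisons, function(cmp) {
    s <- cmp$summary
    data.frame(variable = cmp$variable,
               ruptured_median = s$median[1], ruptured_q1 = s$q1[1],
               ruptured_q3 = s$q3[1],
               unruptured_median = s$median[2], unruptured_q1 = s$q1[2],
               unruptured_q3 = s$q3[2],
               U = cmp$test$statistic, p_value = cmp$test$p_value)
  }))
}

trends_frame <- function(stats) {
  do.call(rbind, lapply(names(stats$trends), function(g) {
    do.call(rbind, lapply(names(stats$trends[[g]]), function(q) {
      tr <- stats$trends[[g]][[q]]
      data.frame(group = g, quantity = q,
                 spearman_rho = tr$spearman$estimate,
                 spearman_p = tr$spearman$p_value,
                 pearson_r = tr$pearson$estimate,
                 pearson_p = tr$pearson$p_value)
    }))
  }))
}

write_markdown_report <- function(stats, path) {
  cf <- comparisons_frame(stats)
  lines <- c("# Cohort report", "",
             "## Group comparisons (median [IQR], Mann-Whitney p)", "",
             "| variable | ruptured | unruptured | p |",
             "|---|---|---|---|",
             sprintf("| %s | %.3f [%.3f, %.3f] | %.3f [%.3f, %.3f] | %.4g |",
                     cf$variable, cf$ruptured_median, cf$ruptured_q1,
                     cf$ruptured_q3, cf$unruptured_median, cf$unruptured_q1,
                     cf$unruptured_q3, cf$p_value),
             "", "## High-velocity segments", "")
  ct <- stats$contingency$chisq
  lines <- c(lines,
             sprintf("- ruptured %d/%d (%.1f%%) vs unruptured %d/%d (%.1f%%)",
                     ct$table[1, 1], sum(ct$table[1, ]), ct$percent[1],
                     ct$table[2, 1], sum(ct$table[2, ]), ct$percent[2]),
             sprintf("- chi-squared = %.3f, p = %.4g; Fisher p = %.4g; per-patient Mann-Whitney p = %.4g",
                     ct$statistic, ct$p_value,
                     stats$contingency$fisher$p_value,
                     stats$contingency$per_patient$p_value),
             "", "## Segment trends (pooled)", "",
             "| group | quantity | Spearman rho | p | Pearson r | p |",
             "|---|---|---|---|---|---|")
  tf <- trends_frame(stats)
  lines <- c(lines,
             sprintf("| %s | %s | %.3f | %.4g | %.3f | %.4g |",
                     tf$group, tf$quantity, tf$spearman_rho, tf$spearman_p,
                     tf$pearson_r, tf$pearson_p))
  writeLines(lines, path)
  invisible(path)
}

#' Run the full pipeline
#'
#' Generates the cohort, builds every vein, solves the flow, summarizes
#' segments, computes the cohort statistics, and writes the report bundle:
#' per-vein geometry/flow/segment files, cohort and segment CSVs,
#' comparison and trend CSVs, a Markdown report, and a JSON manifest with
#' the seeds, package version and MD5 checksum of every artifact.
#' Identical configuration (including `master_seed`) reproduces identical
#' checksums.
#'
#' @param config A [pipeline_config()], or path to a JSON config.
#' @param out_dir Output directory (created; must be writable).
#' @return The `cohort_statistics` object, invisibly, with attributes
#'   `records` and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  vf_assert(!missing(out_dir) && is.character(out_dir),
            "out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir) || file.access(out_dir, 2) != 0) {
    vf_stop("output directory is not writable: ", out_dir)
  }
  t0 <- Sys.time()
  q <- config$quiet
  pipe_log(q, "generating cohort (%d ruptured, %d unruptured, seed %d)",
           config$cohort$n_ruptured, config$cohort$n_unruptured,
           config$cohort$master_seed)
  draws <- generate_cohort(config$cohort)
  records <- vector("list", length(draws))
  files <- character(0)
  for (i in seq_along(draws)) {
    d <- draws[[i]]
    geo <- generate_vessel(d$params, mesh = config$write_meshes)
    res <- analyze_vessel(d$id, d$rupture, geo, config)
    records[[i]] <- res$record
    stem <- file.path(out_dir, d$id)
    write_centerline_csv(geo, paste0(stem, "_centerline.csv"))
    write_flow_csv(res$solution, paste0(stem, "_flow.csv"))
    write_segmentation_csv(res$scheme, paste0(stem, "_segments.csv"))
    files <- c(files, paste0(stem, c("_centerline.csv", "_flow.csv", "_segments.csv")))
    if (config$write_meshes) {
      write_stl(geo, paste0(stem, ".stl"))
      write_vtk_surface(geo, res$solution, paste0(stem, "_wss.vtk"))
      files <- c(files, paste0(stem, c(".stl", "_wss.vtk")))
    }
    pipe_log(q, "subject %s done (%d stations, %d segments)", d$id,
             nrow(geo$centerline), config$K)
  }
  pipe_log(q, "computing cohort statistics")
  stats <- cohort_statistics(records, exact_mw = config$exact_mw)
  utils::write.csv(stats$cohort, file.path(out_dir, "cohort.csv"), row.names = FALSE)
  utils::write.csv(stats$segments, file.path(out_dir, "segments.csv"), row.names = FALSE)
  utils::write.csv(comparisons_frame(stats), file.path(out_dir, "comparisons.csv"),
                   row.names = FALSE)
  utils::write.csv(trends_frame(stats), file.path(out_dir, "trends.csv"),
                   row.names = FALSE)
  write_markdown_report(stats, file.path(out_dir, "report.md"))
  files <- c(files, file.path(out_dir, c("cohort.csv", "segments.csv",
                                         "comparisons.csv", "trends.csv",
                                         "report.md")))
  manifest <- list(
    package = "veinflow",
    version = as.character(utils::packageVersion("veinflow")),
    master_seed = config$cohort$master_seed,
    subject_seeds = vapply(draws, function(d) d$params$seed, integer(1)),
    n_ruptured = config$cohort$n_ruptured,
    n_unruptured = config$cohort$n_unruptured,
    K = config$K,
    velocity_threshold = config$velocity_threshold,
    pressure_report_offset = config$pressure_report_offset,
    checksums = as.list(tools::md5sum(sort(files)))
  )
  names(manifest$checksums) <- basename(names(manifest$checksums))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  pipe_log(q, "pipeline finished in %.1f s",
           as.numeric(difftime(Sys.time(), t0, units = "secs")))
  attr(stats, "records") <- records
  attr(stats, "manifest") <- manifest
  invisible(stats)
}

#' Analyze a cohort in memory
#'
#' [run_pipeline()] without the report bundle: generates the cohort, builds
#' and solves every vein, and returns the records and statistics. Meshes
#' are skipped by default (they do not enter the statistics).
#'
#' @param config A [pipeline_config()].
#' @param mesh Build surface meshes as well.
#' @return A `cohort_statistics` object with a `records` attribute.
#' @export
analyze_cohort <- function(config = pipeline_config(), mesh = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  draws <- generate_cohort(config$cohort)
  records <- lapply(draws, function(d) {
    geo <- generate_vessel(d$params, mesh = mesh)
    analyze_vessel(d$id, d$rupture, geo, config)$record
  })
  stats <- cohort_statistics(records, exact_mw = config$exact_mw)
  attr(stats, "records") <- records
  stats
}

#' Import a reconstructed vein and analyze it
#'
#' Entry point for externally reconstructed geometries: reads an STL
#' surface and the matching centerline CSV, validates them (watertight
#' surface, schema, plausible radii 0.1--20 mm, at least `K` stations),
#' then runs segmentation, the flow solve and the summaries.
#'
#' @param stl_path Path to the STL surface (or `NULL` for centerline-only
#'   analysis).
#' @param centerline_csv Path to the centerline CSV
#'   ([write_centerline_csv()] schema).
#' @param bc A [boundary_conditions()].
#' @param id Subject id for the record.
#' @param rupture Rupture label.
#' @param K Number of segments.
#' @param fluid A [fluid_properties()].
#' @param velocity_threshold High-velocity threshold, m/s.
#' @return A [vein_record()].
#' @export
import_vein <- function(stl_path, centerline_csv, bc, id = "imported",
                        rupture = FALSE, K = 15L,
                        fluid = fluid_properties(),
                        velocity_threshold = 0.113) {
  stopifnot(inherits(bc, "boundary_conditions"))
  cl_df <- read_centerline_csv(centerline_csv)
  n <- nrow(cl_df)
  if (n < K) {
    vf_stop("insufficient stations: centerline has ", n,
            " stations but K = ", K, " segments were requested")
  }
  if (any(cl_df$radius_mm < 0.1 | cl_df$radius_mm > 20)) {
    warning("radii outside 0.1-20 mm: check that the centerline is in millimetres",
            call. = FALSE)
  }
  verts <- NULL; faces <- NULL
  r_end <- cl_df$radius_mm[c(1, n)]
  areas <- list(inlet = pi * r_end[1]^2, exit = pi * r_end[2]^2)
  cl <- as.matrix(cl_df[, c("x_mm", "y_mm", "z_mm")])
  if (!is.null(stl_path)) {
    mesh <- read_stl(stl_path)
    if (!is_watertight(mesh$faces)) {
      vf_stop("imported STL surface is not watertight")
    }
    verts <- mesh$vertices; faces <- mesh$faces
    areas <- mesh_cap_areas(verts, faces, cl)
  }
  geo <- vessel_geometry(verts, faces, cl, cl_df$radius_mm, cl_df$arclength_mm,
                         areas$inlet, areas$exit)
  scheme <- divide_segments(geo, K)
  sol <- solve_steady_flow(geo, bc, fluid)
  segs <- summarize_segments(sol, scheme, velocity_threshold)
  vein_record(id, rupture, geo, sol, segs)
}
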