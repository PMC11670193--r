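test_that("straight uniform parameters give a straight uniform cylinder", {
  g <- generate_vessel(quick_params(inlet_radius = 2.5, target_actual_length = 40),
                       mesh = FALSE)
  expect_equal(tortuosity_index(actual_length(g), absolute_length(g)), 1.0)
  expect_equal(actual_length(g), 40, tolerance = 1e-9)
  expect_true(all(abs(g$radius_mm - 2.5) < 1e-12))
  expect_equal(area_ratio(g$exit_area_mm2, g$inlet_area_mm2), 1.0)
})

test_that("semicircular preset has tortuosity index pi/2", {
  g <- semicircle_geometry(arc_radius_mm = 20, n_stations = 401L)
  expect_equal(tortuosity_index(actual_length(g), absolute_length(g)),
               pi / 2, tolerance = 1e-4)
})

test_that("stenosis and aneurysm bumps hit the analytic radius profile", {
  # severity 0.5 at s = 0.5: radius there is half the local baseline
  p <- quick_params(inlet_radius = 3, outlet_inlet_area_ratio = 0.5,
                    stenosis = list(position = 0.5, severity = 0.5))
  g <- generate_vessel(p, mesh = FALSE)
  i_mid <- (p$n_stations + 1L) %/% 2L  # odd station count: v = 0.5 exactly
  baseline <- 3 * 0.5^(0.5 / 2)
  expect_equal(g$radius_mm[i_mid], 0.5 * baseline, tolerance = 1e-9)
  expect_equal(min(g$radius_mm), g$radius_mm[i_mid], tolerance = 1e-4)

  pa <- quick_params(inlet_radius = 3, aneurysm = list(position = 0.3, bulge = 1.6))
  ga <- generate_vessel(pa, mesh = FALSE)
  v <- ga$arclength_mm / actual_length(ga)
  i30 <- which.min(abs(v - 0.3))
  expect_equal(max(ga$radius_mm), ga$radius_mm[i30], tolerance = 1e-9)
  expect_equal(ga$radius_mm[i30], 3 * 1.6, tolerance = 1e-3)
})

test_that("invalid vessel parameters are rejected", {
  expect_error(vessel_params(stenosis = list(position = 0.5, severity = 1)),
               "severity")
  expect_error(vessel_params(outlet_inlet_area_ratio = 0), "ratio")
  expect_error(vessel_params(inlet_radius = -1), "inlet_radius")
  expect_error(vessel_params(aneurysm = list(position = 0.5, bulge = 0.9)),
               "bulge")
})

test_that("generated meshes are watertight and match the analytic radius", {
  presets <- list(
    quick_params(),
    quick_params(outlet_inlet_area_ratio = 0.29, tortuosity_index = 1.5),
    quick_params(tortuosity_index = 2.2, target_actual_length = 70,
                 stenosis = list(position = 0.4, severity = 0.4)),
    quick_params(aneurysm = list(position = 0.6, bulge = 1.5),
                 outlet_inlet_area_ratio = 0.74)
  )
  for (p in presets) {
    g <- generate_vessel(p, mesh = TRUE)
    expect_true(is_watertight(g$faces))
    for (st in c(31L, 61L, 91L)) {
      expect_equal(mesh_slice_radius(g, st), g$radius_mm[st],
                   tolerance = 0.02)
    }
  }
})

test_that("same parameters give byte-identical STL and centerline CSV", {
  p <- quick_params(tortuosity_index = 1.8, outlet_inlet_area_ratio = 0.4)
  f1 <- withr::local_tempfile(fileext = ".stl")
  f2 <- withr::local_tempfile(fileext = ".stl")
  c1 <- withr::local_tempfile(fileext = ".csv")
  c2 <- withr::local_tempfile(fileext = ".csv")
  write_stl(generate_vessel(p), f1)
  write_stl(generate_vessel(p), f2)
  write_centerline_csv(generate_vessel(p, mesh = FALSE), c1)
  write_centerline_csv(generate_vessel(p, mesh = FALSE), c2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  expect_identical(readLines(c1), readLines(c2))
})

test_that("cohort draws are deterministic and labelled as configured", {
  cfg <- cohort_config(n_ruptured = 6, n_unruptured = 5, master_seed = 7L)
  d1 <- generate_cohort(cfg)
  d2 <- generate_cohort(cfg)
  expect_identical(d1, d2)
  expect_length(d1, 11L)
  expect_equal(sum(vapply(d1, function(e) e$rupture, logical(1))), 6L)
  expect_equal(vapply(d1, function(e) e$id, character(1))[1:2], c("R01", "R02"))
  # different master seed changes the draw
  d3 <- generate_cohort(cohort_config(6, 5, master_seed = 8L))
  expect_false(identical(d1[[1]]$params, d3[[1]]$params))
})

test_that("large-sample group medians reproduce the configured targets", {
  cfg <- cohort_config(n_ruptured = 2000, n_unruptured = 2000, master_seed = 11L)
  d <- generate_cohort(cfg)
  rup <- vapply(d, function(e) e$rupture, logical(1))
  ratio <- vapply(d, function(e) e$params$outlet_inlet_area_ratio, numeric(1))
  vel <- vapply(d, function(e) e$params$inlet_velocity, numeric(1))
  expect_equal(median(ratio[rup]), 0.29, tolerance = 0.10)
  expect_equal(median(ratio[!rup]), 0.74, tolerance = 0.10)
  expect_gt(median(vel[rup]), median(vel[!rup]))
})

test_that("non-positive distribution medians are a config error", {
  expect_no_error(
    cohort_config(ruptured = list(area_ratio = veinflow:::lognormal_spec(1, 0.1))))
  bad <- default_group_distributions("ruptured")
  bad$area_ratio$median <- -1
  expect_error(cohort_config(ruptured = bad), "median")
})
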