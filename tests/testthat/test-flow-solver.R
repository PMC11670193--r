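test_that("transit velocity is ROI distance over time", {
  expect_equal(velocity_from_transit(30, 0.3, "mm"), 0.1)
  expect_equal(velocity_from_transit(0, 1), 0)
  # 56.5 mm in 0.5 s is exactly the high-velocity threshold
  expect_equal(velocity_from_transit(56.5, 0.5, "mm"), 0.113)
  expect_error(velocity_from_transit(10, 0), "roi_time")
  expect_error(velocity_from_transit(10, -1), "roi_time")
})

test_that("Poiseuille wall shear stress closed form and scaling", {
  expect_equal(poiseuille_wss(0, 0.002), 0)
  R <- 0.0025; v <- 0.113; mu <- 0.0035
  Q <- v * pi * R^2
  expect_equal(poiseuille_wss(Q, R, mu), 4 * mu * v / R, tolerance = 1e-12)
  expect_equal(poiseuille_wss(Q, R, mu), 0.6328, tolerance = 1e-9)
  # numerical oracle: wall gradient of the parabolic profile u(r) = 2v(1 - r^2/R^2)
  h <- R * 1e-7
  grad_wall <- (2 * v * (1 - (R - h)^2 / R^2) - 0) / h
  expect_equal(poiseuille_wss(Q, R, mu), mu * grad_wall, tolerance = 1e-6)
  # cubic scaling: doubling R at fixed Q divides wss by 8
  expect_equal(poiseuille_wss(Q, 2 * R, mu), poiseuille_wss(Q, R, mu) / 8)
  expect_error(poiseuille_wss(Q, -1), "radius")
})

test_that("uniform tube solve equals Hagen-Poiseuille exactly", {
  g <- straight_tube_geometry(60, 2.5, n_stations = 301L)
  sol <- solve_steady_flow(g, boundary_conditions(0.113))
  mu <- 0.0035
  dp_expected <- 8 * mu * 0.06 * 0.113 / 0.0025^2
  st <- sol$stations
  expect_equal(st$pressure_pa[1] - st$pressure_pa[301], dp_expected,
               tolerance = 1e-10)
  expect_true(all(abs(st$wss_pa - 4 * mu * 0.113 / 0.0025) < 1e-12))
  # pressure is linear in s on a uniform tube
  fit <- lm(pressure_pa ~ s_mm, data = st)
  expect_lt(max(abs(residuals(fit))), 1e-9)
  expect_equal(sol$reynolds_number, 1066 * 0.113 * 0.005 / mu, tolerance = 1e-12)
})

test_that("zero inflow gives the no-flow state", {
  g <- straight_tube_geometry(60, 2.5)
  sol <- solve_steady_flow(g, boundary_conditions(0, outlet_pressure = 5))
  expect_true(all(sol$stations$pressure_pa == 5))
  expect_true(all(sol$stations$wss_pa == 0))
  expect_true(all(sol$stations$velocity_mps == 0))
})

test_that("tapered-tube pressure matches fine-grid quadrature within 0.1%", {
  p <- vessel_params(inlet_radius = 3, outlet_inlet_area_ratio = 0.29,
                     target_actual_length = 60, inlet_velocity = 0.1,
                     n_stations = 301L)
  bc <- boundary_conditions(0.1)
  fl <- fluid_properties()
  sol <- solve_steady_flow(generate_vessel(p, mesh = FALSE), bc, fl)
  dp_solver <- sol$stations$pressure_pa[1]
  dp_oracle <- oracle_pressure_drop(p, bc, fl, refine = 100L)
  expect_equal(dp_solver, dp_oracle, tolerance = 1e-3)
})

test_that("linearly tapering tube matches the closed-form integral", {
  # R(s) = R0 + a s has int 8 mu Q / (pi R^4) ds = 8 mu Q / (3 pi a) * (R1^-3 - R0^-3)
  n <- 2001L
  R0 <- 0.003; R1 <- 0.0015; L <- 0.06
  cl <- cbind(0, 0, seq(0, L * 1000, length.out = n))
  r_mm <- seq(R0, R1, length.out = n) * 1000
  g <- vessel_geometry(NULL, NULL, cl, r_mm, cl[, 3],
                       pi * (R0 * 1000)^2, pi * (R1 * 1000)^2)
  mu <- 0.0035
  v <- 0.1
  Q <- v * pi * R0^2
  sol <- solve_steady_flow(g, boundary_conditions(v))
  a <- (R1 - R0) / L
  dp_exact <- 8 * mu * Q / (3 * pi * a) * (R0^-3 - R1^-3)
  expect_equal(sol$stations$pressure_pa[1], dp_exact, tolerance = 1e-4)
})

test_that("mass conservation, monotonicity and offset invariants hold", {
  set.seed(4)
  for (i in 1:20) {
    p <- quick_params(inlet_radius = runif(1, 1.5, 4),
                      outlet_inlet_area_ratio = runif(1, 0.25, 1.3),
                      tortuosity_index = runif(1, 1, 2.5),
                      inlet_velocity = runif(1, 0.01, 0.15))
    g <- generate_vessel(p, mesh = FALSE)
    sol <- solve_steady_flow(g)
    st <- sol$stations
    A <- pi * (st$radius_mm / 1000)^2
    expect_lt(max(abs(st$velocity_mps * A - sol$flow_rate_m3s)) /
                sol$flow_rate_m3s, 1e-12)
    expect_true(all(diff(st$pressure_pa) < 0))
    expect_equal(st$pressure_pa[nrow(st)], 0)
    # wss and velocity rise wherever the radius falls (cubic / quadratic laws)
    shrink <- diff(st$radius_mm) < 0
    expect_true(all(diff(st$wss_pa)[shrink] > 0))
    expect_true(all(diff(st$velocity_mps)[shrink] > 0))
    # reported = gauge + offset
    expect_equal(st$pressure_reported_pa, st$pressure_pa + 1000)
  }
})

test_that("station-grid refinement changes inlet pressure by < 0.1%", {
  for (ns in list(c(151L, 301L))) {
    p1 <- vessel_params(outlet_inlet_area_ratio = 0.3, tortuosity_index = 1.8,
                        n_stations = ns[1])
    p2 <- vessel_params(outlet_inlet_area_ratio = 0.3, tortuosity_index = 1.8,
                        n_stations = ns[2])
    d1 <- solve_steady_flow(generate_vessel(p1, mesh = FALSE))$stations$pressure_pa[1]
    d2 <- solve_steady_flow(generate_vessel(p2, mesh = FALSE))$stations$pressure_pa[1]
    expect_lt(abs(d2 - d1) / d1, 1e-3)
  }
})

test_that("resistance-correction hook scales the gradient only", {
  g <- straight_tube_geometry(60, 2.5)
  base <- solve_steady_flow(g, boundary_conditions(0.1))
  doubled <- solve_steady_flow(g, boundary_conditions(0.1),
                               resistance_correction = function(u) rep(2, length(u)))
  expect_equal(doubled$stations$pressure_pa[1], 2 * base$stations$pressure_pa[1],
               tolerance = 1e-12)
  expect_equal(doubled$stations$wss_pa, base$stations$wss_pa)
})

test_that("surface WSS is mapped from the nearest station", {
  g <- straight_tube_geometry(60, 2.5, mesh = TRUE, n_stations = 61L)
  sol <- solve_steady_flow(g, boundary_conditions(0.113))
  expect_length(sol$face_wss_pa, nrow(g$faces))
  expect_true(all(abs(sol$face_wss_pa - 4 * 0.0035 * 0.113 / 0.0025) < 1e-12))
})
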