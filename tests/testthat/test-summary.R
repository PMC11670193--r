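make_case <- function(params, threshold = 0.113, K = 15L) {
  g <- generate_vessel(params, mesh = FALSE)
  sch <- divide_segments(g, K)
  sol <- solve_steady_flow(g)
  list(g = g, sch = sch, sol = sol,
       segs = summarize_segments(sol, sch, threshold))
}

test_that("uniform tube summarizes to uniform segments with no flags", {
  cs <- make_case(vessel_params(inlet_velocity = 0.05))
  expect_equal(nrow(cs$segs), 15L)
  expect_true(all(abs(cs$segs$velocity_avg - 0.05) < 1e-12))
  expect_false(any(cs$segs$high_velocity))
  # exactly at the threshold: strict inequality, still unflagged
  cs2 <- make_case(vessel_params(inlet_velocity = 0.113))
  expect_false(any(cs2$segs$high_velocity))
  # just above: every segment flagged
  cs3 <- make_case(vessel_params(inlet_velocity = 0.113 + 1e-9))
  expect_true(all(cs3$segs$high_velocity))
})

test_that("flags are the terminal run of a tapering ramp, per brute force", {
  # velocity ramps ~0.02 -> 0.15 m/s via the taper
  p <- vessel_params(inlet_velocity = 0.02,
                     outlet_inlet_area_ratio = 0.02 / 0.15)
  cs <- make_case(p)
  st <- cs$sol$stations
  w <- veinflow:::trapezoid_weights(st$s_mm)
  brute <- vapply(1:15, function(k) {
    ix <- cs$sch$segment_of_station == k
    sum(st$velocity_mps[ix] * w[ix]) / sum(w[ix]) > 0.113
  }, logical(1))
  expect_identical(cs$segs$high_velocity, brute)
  flagged <- which(cs$segs$high_velocity)
  expect_true(length(flagged) > 0)
  expect_identical(flagged, seq(min(flagged), 15L))  # consecutive terminal run
  # monotone in threshold
  for (thr in c(0.05, 0.08, 0.113, 0.15)) {
    n_lo <- sum(summarize_segments(cs$sol, cs$sch, thr)$high_velocity)
    n_hi <- sum(summarize_segments(cs$sol, cs$sch, thr + 0.01)$high_velocity)
    expect_gte(n_lo, n_hi)
  }
})

test_that("patient summary aggregates segments correctly", {
  cs <- make_case(vessel_params(inlet_velocity = 0.08))  # uniform
  pat <- summarize_patient(cs$segs)
  expect_equal(pat$pressure_max, max(cs$sol$stations$pressure_reported_pa))
  expect_equal(pat$wss_avg, cs$segs$wss_avg[1], tolerance = 1e-12)
  expect_equal(pat$n_high_velocity, 0L)

  cs2 <- make_case(vessel_params(outlet_inlet_area_ratio = 0.29,
                                 inlet_velocity = 0.05))
  pat2 <- summarize_patient(cs2$segs)
  # monotone decreasing pressure attains its maximum in segment 1
  expect_equal(pat2$pressure_max, cs2$segs$pressure_max[1])
  # patient wss max equals the naive scan over stations
  expect_equal(pat2$wss_max, max(cs2$sol$stations$wss_pa))
  # patient average is the arclength-weighted mean of segment averages
  expect_equal(pat2$pressure_avg,
               sum(cs2$segs$pressure_avg * cs2$segs$arclength_weight_mm) /
                 sum(cs2$segs$arclength_weight_mm))
  expect_true(all(pat2$pressure_max >= cs2$segs$pressure_avg))
  expect_true(all(pat2$wss_max >= cs2$segs$wss_avg))
})

test_that("A/B/C group values follow the taper and use the right segments", {
  cs <- make_case(vessel_params(outlet_inlet_area_ratio = 0.29,
                                inlet_velocity = 0.04))
  rec <- vein_record("S1", TRUE, cs$g, cs$sol, cs$segs)
  cval <- group_segment_table(list(rec), "C", "wss_avg")
  aval <- group_segment_table(list(rec), "A", "wss_avg")
  # cubic WSS-radius law on a distal taper: posterior group far above anterior
  expect_gt(unname(cval), unname(aval))
  seg_c <- cs$segs[cs$segs$segment_index >= 11, ]
  expect_equal(unname(cval),
               sum(seg_c$wss_avg * seg_c$arclength_weight_mm) /
                 sum(seg_c$arclength_weight_mm))
  expect_error(group_segment_table(list(rec), "D", "wss_avg"), "group")

  # uniform field: group value equals the field value in all groups
  csu <- make_case(vessel_params(inlet_velocity = 0.06))
  recu <- vein_record("S2", FALSE, csu$g, csu$sol, csu$segs)
  for (g in c("A", "B", "C")) {
    expect_equal(unname(group_segment_table(list(recu), g, "velocity_avg")),
                 0.06, tolerance = 1e-12)
  }
})

test_that("tapering veins have nondecreasing velocity and wss by segment", {
  set.seed(12)
  for (i in 1:10) {
    p <- quick_params(outlet_inlet_area_ratio = runif(1, 0.2, 0.9),
                      tortuosity_index = runif(1, 1, 2),
                      inlet_velocity = runif(1, 0.02, 0.1))
    cs <- make_case(p)
    expect_true(all(diff(cs$segs$velocity_avg) > -1e-12))
    expect_true(all(diff(cs$segs$wss_avg) > -1e-12))
    expect_true(sum(cs$segs$high_velocity) %in% 0:15)
  }
})
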