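# Shared fixtures: everything is generated in code at test time.

# small, fast vessels for unit tests
quick_params <- function(..., n_stations = 121L) {
  vessel_params(..., n_stations = n_stations)
}

# brute-force fine-grid pressure integration oracle (independent of the
# solver's cumtrapz path): integrates 8 mu Q / (pi R^4) on a refined grid
# by evaluating the analytic radius profile directly
oracle_pressure_drop <- function(params, bc, fluid, refine = 100L) {
  g <- generate_vessel(params, mesh = FALSE)
  L <- actual_length(g) / 1000
  v <- seq(0, 1, length.out = refine * params$n_stations)
  R <- veinflow:::radius_profile(v, params) / 1000
  A_in <- pi * R[1]^2
  Q <- bc$inlet_mean_velocity * A_in
  grad <- 8 * fluid$dynamic_viscosity * Q / (pi * R^4)
  s <- v * L
  # trapezoid on the fine grid, total drop inlet -> outlet
  sum(diff(s) * (grad[-1] + grad[-length(grad)]) / 2)
}

# exhaustive-enumeration Mann-Whitney oracle for tiny samples, no ties:
# two-sided p as the tail probability of U under all C(m+n, m) labelings
oracle_mw_exact_p <- function(a, b) {
  m <- length(a); n <- length(b)
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  rk <- rank(pooled)
  U_obs <- sum(rk[seq_len(m)]) - m * (m + 1) / 2
  combos <- utils::combn(m + n, m)
  U_all <- apply(combos, 2, function(ix) sum(rk[ix]) - m * (m + 1) / 2)
  mu <- m * n / 2
  mean(abs(U_all - mu) >= abs(U_obs - mu))
}
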