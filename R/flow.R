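# Quasi-1D steady incompressible flow with the Hagen-Poiseuille closure.

#' Blood fluid properties
#'
#' Defaults are the standard hemodynamic constants: density 1066 kg/m^3 and
#' dynamic viscosity 0.0035 Pa s (blood as an incompressible Newtonian
#' fluid).
#'
#' @param density Fluid density, kg/m^3.
#' @param dynamic_viscosity Dynamic viscosity, Pa s.
#' @return An object of class `fluid_properties`.
#' @export
fluid_properties <- function(density = 1066, dynamic_viscosity = 0.0035) {
  vf_assert(is_scalar_number(density) && density > 0, "density must be > 0")
  vf_assert(is_scalar_number(dynamic_viscosity) && dynamic_viscosity > 0,
            "dynamic_viscosity must be > 0")
  structure(list(density = density, dynamic_viscosity = dynamic_viscosity),
            class = "fluid_properties")
}

#' Flow boundary conditions
#'
#' A prescribed mean velocity at the vein inlet and a reference pressure
#' (default 0 Pa, mimicking venous sinus pressure) at the outlet. Reported
#' pressures add `pressure_report_offset` (default 1000 Pa) so tables read
#' on the conventional ~1000-1020 Pa scale; the offset never affects
#' gradients or group differences.
#'
#' @param inlet_mean_velocity Inlet mean velocity, m/s (>= 0).
#' @param outlet_pressure Outlet gauge pressure, Pa.
#' @param pressure_report_offset Additive reporting reference, Pa (>= 0).
#' @return An object of class `boundary_conditions`.
#' @export
boundary_conditions <- function(inlet_mean_velocity,
                                outlet_pressure = 0,
                                pressure_report_offset = 1000) {
  vf_assert(is_scalar_number(inlet_mean_velocity) && inlet_mean_velocity >= 0,
            "inlet_mean_velocity must be >= 0")
  vf_assert(is_scalar_number(outlet_pressure), "outlet_pressure must be numeric")
  vf_assert(is_scalar_number(pressure_report_offset) && pressure_report_offset >= 0,
            "pressure_report_offset must be >= 0")
  structure(list(inlet_mean_velocity = inlet_mean_velocity,
                 outlet_pressure = outlet_pressure,
                 pressure_report_offset = pressure_report_offset),
            class = "boundary_conditions")
}

#' Transit velocity from an angiographic ROI
#'
#' Mean velocity estimated as the distance travelled through a region of
#' interest divided by the transit time (the quantitative-angiography
#' boundary-condition measurement).
#'
#' @param roi_distance Distance through the ROI, metres (mm inputs should
#'   be divided by 1000 by the caller; see `distance_unit`).
#' @param roi_time Transit time, seconds (> 0).
#' @param distance_unit `"m"` (default) or `"mm"`.
#' @return Speed in m/s.
#' @export
velocity_from_transit <- function(roi_distance, roi_time, distance_unit = c("m", "mm")) {
  distance_unit <- match.arg(distance_unit)
  vf_assert(is_scalar_number(roi_distance) && roi_distance >= 0,
            "roi_distance must be >= 0")
  if (!is_scalar_number(roi_time) || roi_time <= 0) {
    vf_stop("roi_time must be > 0")
  }
  d <- if (distance_unit == "mm") roi_distance / 1000 else roi_distance
  d / roi_time
}

#' Poiseuille wall shear stress
#'
#' Fully developed laminar tube flow: `tau_w = 4 mu Q / (pi R^3)`,
#' equivalently `4 mu v_bar / R`.
#'
#' @param Q Volumetric flow rate, m^3/s (>= 0).
#' @param R Lumen radius, m (> 0).
#' @param mu Dynamic viscosity, Pa s (> 0).
#' @return Wall shear stress, Pa.
#' @export
poiseuille_wss <- function(Q, R, mu = 0.0035) {
  vf_assert(all(R > 0), "radius must be > 0")
  vf_assert(all(Q >= 0), "flow rate must be >= 0")
  vf_assert(is_scalar_number(mu) && mu > 0, "viscosity must be > 0")
  4 * mu * Q / (pi * R^3)
}

#' Poiseuille pressure gradient magnitude
#'
#' `|dp/ds| = 8 mu Q / (pi R^4)` for fully developed laminar tube flow.
#'
#' @inheritParams poiseuille_wss
#' @return Pressure gradient magnitude, Pa/m.
#' @export
poiseuille_pressure_gradient <- function(Q, R, mu = 0.0035) {
  vf_assert(all(R > 0), "radius must be > 0")
  vf_assert(is_scalar_number(mu) && mu > 0, "viscosity must be > 0")
  8 * mu * Q / (pi * R^4)
}

#' Solve steady flow along a vessel
#'
#' Reduced-order (quasi-1D) steady incompressible solution with the
#' Hagen-Poiseuille closure on the station grid: the conserved flow rate is
#' `Q = v_inlet * A_inlet`; mean velocity `v(s) = Q / A(s)`; the gauge
#' pressure integrates `dp/ds = -8 mu Q / (pi R(s)^4)` backward from the
#' outlet condition by composite trapezoid; wall shear stress is
#' `4 mu Q / (pi R(s)^3)`. When the geometry carries a surface mesh, WSS is
#' mapped to each face from the nearest centerline station (orthogonal
#' projection).
#'
#' @param geometry A [vessel_geometry()].
#' @param bc [boundary_conditions()]; defaults to the geometry's stored
#'   inlet velocity with a 0 Pa outlet.
#' @param fluid [fluid_properties()].
#' @param resistance_correction Optional per-station multiplicative factor
#'   on the local pressure gradient (length-n vector or function of
#'   normalized arclength; default 1, i.e. plain Poiseuille).
#' @return An object of class `flow_solution`: `stations` data frame
#'   (`s_mm`, `radius_mm`, `velocity_mps`, `pressure_pa` gauge,
#'   `pressure_reported_pa`, `wss_pa`), conserved `flow_rate_m3s`,
#'   `reynolds_number` (rho v_in 2R_in / mu), `face_wss_pa` (or `NULL`),
#'   and the inputs.
#' @examples
#' g <- straight_tube_geometry(60, 2.5)
#' sol <- solve_steady_flow(g, boundary_conditions(0.113))
#' max(sol$stations$pressure_pa) # 8 mu L v / R^2 = 30.37 Pa
#' @export
solve_steady_flow <- function(geometry, bc = NULL,
                              fluid = fluid_properties(),
                              resistance_correction = NULL) {
  stopifnot(inherits(geometry, "vessel_geometry"))
  if (is.null(bc)) {
    v_in <- geometry$params$inlet_velocity %||%
      vf_stop("no boundary conditions given and the geometry carries no inlet velocity")
    bc <- boundary_conditions(v_in)
  }
  stopifnot(inherits(bc, "boundary_conditions"), inherits(fluid, "fluid_properties"))
  n <- length(geometry$radius_mm)
  vf_assert(n >= 2, "geometry must have at least two stations")
  vf_assert(all(geometry$radius_mm > 0), "negative or zero radius station")

  mu <- fluid$dynamic_viscosity
  R <- geometry$radius_mm / 1000          # m
  s <- geometry$arclength_mm / 1000       # m
  A <- pi * R^2
  Q <- bc$inlet_mean_velocity * A[1]
  v <- Q / A
  tau <- poiseuille_wss(Q, R, mu)
  grad <- poiseuille_pressure_gradient(Q, R, mu)
  if (!is.null(resistance_correction)) {
    corr <- if (is.function(resistance_correction)) {
      resistance_correction(s / s[n])
    } else {
      resistance_correction
    }
    vf_assert(length(corr) %in% c(1L, n) && all(corr > 0),
              "resistance_correction must be positive, length 1 or n")
    grad <- grad * corr
  }
  # integrate the drop from the outlet backward: p(s) = p_out + int_s^L grad
  drop_from_inlet <- cumtrapz(s, grad)
  p <- bc$outlet_pressure + (drop_from_inlet[n] - drop_from_inlet)

  face_wss <- NULL
  if (!is.null(geometry$vertices)) {
    centroids <- (geometry$vertices[geometry$faces[, 1], , drop = FALSE] +
                  geometry$vertices[geometry$faces[, 2], , drop = FALSE] +
                  geometry$vertices[geometry$faces[, 3], , drop = FALSE]) / 3
    nearest <- nearest_station(centroids, geometry$centerline)
    face_wss <- tau[nearest]
  }

  structure(list(
    stations = data.frame(
      s_mm = geometry$arclength_mm,
      radius_mm = geometry$radius_mm,
      velocity_mps = v,
      pressure_pa = p,
      pressure_reported_pa = p + bc$pressure_report_offset,
      wss_pa = tau),
    flow_rate_m3s = Q,
    reynolds_number = fluid$density * bc$inlet_mean_velocity * 2 * R[1] / mu,
    face_wss_pa = face_wss,
    bc = bc, fluid = fluid),
    class = "flow_solution")
}

# index of the nearest centerline station for each query point (rows)
nearest_station <- function(points, centerline) {
  n <- nrow(centerline)
  d2 <- matrix(0, nrow(points), n)
  for (j in 1:3) {
    d2 <- d2 + outer(points[, j], centerline[, j], "-")^2
  }
  max.col(-d2, ties.method = "first")
}

#' @export
print.flow_solution <- function(x, ...) {
  st <- x$stations
  cat("<flow_solution>\n")
  cat(sprintf("  flow rate         %.3e m^3/s (Re = %.1f)\n",
              x$flow_rate_m3s, x$reynolds_number))
  cat(sprintf("  velocity          %.4f -> %.4f m/s\n",
              st$velocity_mps[1], st$velocity_mps[nrow(st)]))
  cat(sprintf("  gauge pressure    %.3f -> %.3f Pa (drop %.3f)\n",
              st$pressure_pa[1], st$pressure_pa[nrow(st)],
              st$pressure_pa[1] - st$pressure_pa[nrow(st)]))
  cat(sprintf("  WSS               %.4f -> %.4f Pa\n",
              st$wss_pa[1], st$wss_pa[nrow(st)]))
  invisible(x)
}
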