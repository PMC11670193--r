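# Synthetic vessel construction: helical centerline, analytic radius
# profile, parallel-transport tube mesh.

# Helical centerline sampled at parameter u in [0,1]:
#   z = chord * u
#   x = A sin(pi u) cos(2 pi k u + phase)
#   y = A sin(pi u) sin(2 pi k u + phase)
# The half-sine envelope pins both endpoints to the axis, so the chord
# (absolute length) equals the axis length exactly.
helix_points <- function(u, chord, amplitude, k, phase) {
  env <- sin(pi * u)
  ang <- 2 * pi * k * u + phase
  cbind(x = amplitude * env * cos(ang),
        y = amplitude * env * sin(ang),
        z = chord * u)
}

polyline_length <- function(p) sum(sqrt(rowSums(diff(p)^2)))

# arclength of the helix on a fine parameter grid
helix_arclength <- function(chord, amplitude, k, phase, m = 4001L) {
  polyline_length(helix_points(seq(0, 1, length.out = m), chord, amplitude, k, phase))
}

# Solve the free shape parameter so the realized actual length equals the
# target. Returns list(chord, amplitude).
solve_centerline_shape <- function(params) {
  L <- params$target_actual_length
  k <- params$tortuosity_wavelengths
  ph <- params$helix_phase
  tau <- params$tortuosity_index
  if (!is.na(tau) && tau > 1 + 1e-9) {
    chord <- L / tau
    f <- function(a) helix_arclength(chord, a, k, ph) - L
    hi <- L / 2
    while (f(hi) < 0) hi <- hi * 2
    a <- stats::uniroot(f, c(0, hi), tol = L * 1e-7)$root
    list(chord = chord, amplitude = a)
  } else if (!is.na(tau) || params$tortuosity_amplitude == 0) {
    list(chord = L, amplitude = 0)
  } else {
    a <- params$tortuosity_amplitude
    f <- function(ch) helix_arclength(ch, a, k, ph) - L
    lo <- L * 1e-4
    if (f(lo) > 0) {
      vf_stop("tortuosity_amplitude too large for target_actual_length: ",
              "the transverse wiggle alone exceeds the requested arclength")
    }
    ch <- stats::uniroot(f, c(lo, L), tol = L * 1e-7)$root
    list(chord = ch, amplitude = a)
  }
}

# Analytic radius profile at normalized arclength v in [0,1]:
# geometric interpolation inlet -> outlet (hits the area ratio exactly)
# times Gaussian stenosis / aneurysm bumps.
radius_profile <- function(v, params) {
  r <- params$inlet_radius * params$outlet_inlet_area_ratio^(v / 2)
  st <- params$stenosis
  if (!is.null(st)) {
    r <- r * (1 - st$severity * exp(-(v - st$position)^2 / (2 * st$width^2)))
  }
  an <- params$aneurysm
  if (!is.null(an)) {
    r <- r * (1 + (an$bulge - 1) * exp(-(v - an$position)^2 / (2 * an$width^2)))
  }
  r
}

# Resample a fine polyline at equal-arclength stations (linear interpolation).
resample_equal_arclength <- function(p_fine, n_stations) {
  s_fine <- c(0, cumsum(sqrt(rowSums(diff(p_fine)^2))))
  s_target <- seq(0, s_fine[length(s_fine)], length.out = n_stations)
  apply(p_fine, 2, function(col) stats::approx(s_fine, col, xout = s_target)$y)
}

#' Generate a synthetic draining-vein geometry
#'
#' Builds the centerline (straight axis plus enveloped helix, resampled at
#' equal-arclength stations), evaluates the analytic radius/area profile at
#' every station, and (optionally) triangulates a watertight surface mesh
#' around it by parallel transport of a cross-sectional frame.
#'
#' The construction is fully deterministic: identical parameters give
#' bit-identical centerlines and meshes.
#'
#' @param params A [vessel_params()] object.
#' @param mesh Build the triangulated surface (default `TRUE`). Centerline
#'   and radius profile -- all the flow solver needs -- are always built.
#' @param n_theta Circumferential resolution of the tube mesh.
#' @return A [vessel_geometry()] object.
#' @examples
#' g <- generate_vessel(vessel_params(tortuosity_index = 1.5), mesh = FALSE)
#' tortuosity_index(actual_length(g), absolute_length(g))
#' @export
generate_vessel <- function(params, mesh = TRUE, n_theta = 32L) {
  stopifnot(inherits(params, "vessel_params"))
  shape <- solve_centerline_shape(params)
  m <- max(4001L, 8L * params$n_stations)
  p_fine <- helix_points(seq(0, 1, length.out = m), shape$chord,
                         shape$amplitude, params$tortuosity_wavelengths,
                         params$helix_phase)
  cl <- resample_equal_arclength(p_fine, params$n_stations)
  s <- c(0, cumsum(sqrt(rowSums(diff(cl)^2))))
  v <- s / s[length(s)]
  r <- radius_profile(v, params)

  check_local_clearance(cl, r)

  verts <- NULL; faces <- NULL
  inlet_area <- pi * r[1]^2
  exit_area <- pi * r[length(r)]^2
  if (mesh) {
    tube <- tube_mesh(cl, r, n_theta)
    verts <- tube$vertices; faces <- tube$faces
    if (!is_watertight(faces)) {
      vf_stop("internal error: generated tube mesh is not watertight")
    }
    caps <- mesh_cap_areas(tube$vertices, tube$faces, cl)
    inlet_area <- caps$inlet; exit_area <- caps$exit
  }
  vessel_geometry(vertices = verts, faces = faces, centerline = cl,
                  radius_mm = r, arclength_mm = s,
                  inlet_area_mm2 = inlet_area, exit_area_mm2 = exit_area,
                  params = params)
}

# Warn when the centerline bends tighter than the tube is wide -- the swept
# surface would locally self-intersect.
check_local_clearance <- function(cl, r) {
  n <- nrow(cl)
  if (n < 3) return(invisible())
  d1 <- (cl[3:n, , drop = FALSE] - cl[1:(n - 2), , drop = FALSE]) / 2
  d2 <- cl[3:n, , drop = FALSE] - 2 * cl[2:(n - 1), , drop = FALSE] +
    cl[1:(n - 2), , drop = FALSE]
  cross <- cbind(d1[, 2] * d2[, 3] - d1[, 3] * d2[, 2],
                 d1[, 3] * d2[, 1] - d1[, 1] * d2[, 3],
                 d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1])
  kappa <- sqrt(rowSums(cross^2)) / (sqrt(rowSums(d1^2))^3 + 1e-300)
  clearance <- kappa * r[2:(n - 1)]
  if (any(clearance > 1)) {
    warning("centerline curvature radius is smaller than the tube radius at ",
            sum(clearance > 1), " station(s); the surface may self-intersect",
            call. = FALSE)
  }
  invisible()
}

# Parallel-transport frames along the centerline (rotation-minimizing
# normals), then rings of n_theta vertices plus two cap apices.
tube_mesh <- function(cl, r, n_theta = 32L) {
  n <- nrow(cl)
  tang <- rbind(cl[2, ] - cl[1, ],
                cl[3:n, , drop = FALSE] - cl[1:(n - 2), , drop = FALSE],
                cl[n, ] - cl[n - 1, ])
  tang <- normalize_rows(tang)
  normal <- matrix(0, n, 3)
  ref <- if (abs(tang[1, 3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  n0 <- ref - sum(ref * tang[1, ]) * tang[1, ]
  normal[1, ] <- n0 / sqrt(sum(n0^2))
  for (i in 2:n) {
    ni <- normal[i - 1, ] - sum(normal[i - 1, ] * tang[i, ]) * tang[i, ]
    nn <- sqrt(sum(ni^2))
    if (nn < 1e-12) { # tangent flipped ~180 degrees; fall back to any normal
      ni <- ref - sum(ref * tang[i, ]) * tang[i, ]
      nn <- sqrt(sum(ni^2))
    }
    normal[i, ] <- ni / nn
  }
  binorm <- cbind(tang[, 2] * normal[, 3] - tang[, 3] * normal[, 2],
                  tang[, 3] * normal[, 1] - tang[, 1] * normal[, 3],
                  tang[, 1] * normal[, 2] - tang[, 2] * normal[, 1])
  theta <- 2 * pi * (seq_len(n_theta) - 1) / n_theta
  verts <- matrix(0, n * n_theta + 2L, 3)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * n_theta + seq_len(n_theta)
    verts[rows, ] <- matrix(cl[i, ], n_theta, 3, byrow = TRUE) +
      r[i] * (cos(theta) %o% normal[i, ] + sin(theta) %o% binorm[i, ])
  }
  apex_in <- n * n_theta + 1L
  apex_out <- n * n_theta + 2L
  verts[apex_in, ] <- cl[1, ]
  verts[apex_out, ] <- cl[n, ]

  quads <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    a <- (i - 1L) * n_theta + seq_len(n_theta)          # ring i
    b <- i * n_theta + seq_len(n_theta)                 # ring i+1
    a2 <- a[c(2:n_theta, 1L)]
    b2 <- b[c(2:n_theta, 1L)]
    # outward-consistent winding: (a, a2, b2) and (a, b2, b)
    quads[[i]] <- rbind(cbind(a, a2, b2), cbind(a, b2, b))
  }
  side <- do.call(rbind, quads)
  ring1 <- seq_len(n_theta)
  ringN <- (n - 1L) * n_theta + seq_len(n_theta)
  cap_in <- cbind(apex_in, ring1[c(2:n_theta, 1L)], ring1)
  cap_out <- cbind(apex_out, ringN, ringN[c(2:n_theta, 1L)])
  faces <- rbind(side, cap_in, cap_out)
  dimnames(faces) <- NULL
  list(vertices = verts, faces = faces)
}

#' Check that a triangle mesh is watertight
#'
#' A closed orientable 2-manifold: every undirected edge is shared by
#' exactly two triangles, traversed once in each direction.
#'
#' @param faces Integer matrix of vertex index triples (one row per
#'   triangle).
#' @return `TRUE` or `FALSE`.
#' @export
is_watertight <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  key_dir <- paste(e[, 1], e[, 2])
  key_undir <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key_undir) == 2L) && !anyDuplicated(key_dir)
}

#' Straight uniform tube preset
#'
#' @param length_mm,radius_mm Tube length and radius, mm.
#' @param n_stations Centerline stations.
#' @param mesh Build the surface mesh.
#' @param inlet_velocity Inlet mean velocity carried in the parameters, m/s.
#' @return A [vessel_geometry()].
#' @export
straight_tube_geometry <- function(length_mm = 60, radius_mm = 2.5,
                                   n_stations = 301L, mesh = FALSE,
                                   inlet_velocity = 0.113) {
  generate_vessel(vessel_params(inlet_radius = radius_mm,
                                outlet_inlet_area_ratio = 1,
                                target_actual_length = length_mm,
                                inlet_velocity = inlet_velocity,
                                n_stations = n_stations),
                  mesh = mesh)
}

#' Planar semicircular centerline preset
#'
#' A uniform tube bent into a half-circle of radius `arc_radius_mm`: actual
#' length pi*R, absolute length 2R, tortuosity index pi/2.
#'
#' @param arc_radius_mm Radius of the semicircular centerline, mm.
#' @param tube_radius_mm Lumen radius, mm.
#' @param n_stations Centerline stations.
#' @param mesh Build the surface mesh.
#' @return A [vessel_geometry()].
#' @export
semicircle_geometry <- function(arc_radius_mm = 20, tube_radius_mm = 2,
                                n_stations = 301L, mesh = FALSE) {
  th <- seq(0, pi, length.out = n_stations)
  cl <- cbind(x = arc_radius_mm * sin(th),
              y = rep(0, n_stations),
              z = arc_radius_mm * (1 - cos(th)))
  s <- c(0, cumsum(sqrt(rowSums(diff(cl)^2))))
  r <- rep(tube_radius_mm, n_stations)
  verts <- NULL; faces <- NULL
  inlet_area <- pi * tube_radius_mm^2
  exit_area <- inlet_area
  if (mesh) {
    tm <- tube_mesh(cl, r)
    verts <- tm$vertices; faces <- tm$faces
    caps <- mesh_cap_areas(verts, faces, cl)
    inlet_area <- caps$inlet; exit_area <- caps$exit
  }
  vessel_geometry(verts, faces, cl, r, s, inlet_area, exit_area)
}
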