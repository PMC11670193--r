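# VesselGeometry container and centerline morphology metrics.

#' Vessel geometry container
#'
#' One draining vein: an optional triangulated surface plus an ordered
#' centerline with per-station radius and cumulative arclength. Geometry is
#' stored in millimetres; the flow solver converts to SI internally.
#'
#' @param vertices Numeric n x 3 matrix of surface vertices (mm), or `NULL`.
#' @param faces Integer m x 3 matrix of triangles, or `NULL`.
#' @param centerline Numeric k x 3 matrix of ordered centerline points (mm),
#'   inlet first.
#' @param radius_mm Per-station lumen radius (mm, > 0).
#' @param arclength_mm Per-station cumulative arclength (mm, strictly
#'   increasing from 0).
#' @param inlet_area_mm2,exit_area_mm2 Cross-sectional areas of the inlet
#'   and outlet caps (mm^2). Measured on the planar mesh caps when a mesh
#'   is present, analytic `pi r^2` otherwise.
#' @param params The generating [vessel_params()], if any.
#' @return An object of class `vessel_geometry`.
#' @export
vessel_geometry <- function(vertices, faces, centerline, radius_mm,
                            arclength_mm, inlet_area_mm2, exit_area_mm2,
                            params = NULL) {
  centerline <- as.matrix(centerline)
  vf_assert(ncol(centerline) == 3 && nrow(centerline) >= 2,
            "centerline must be an n x 3 matrix with n >= 2")
  n <- nrow(centerline)
  vf_assert(length(radius_mm) == n && all(radius_mm > 0),
            "radius_mm must be positive at every station")
  vf_assert(length(arclength_mm) == n && all(diff(arclength_mm) > 0),
            "arclength_mm must be strictly increasing")
  vf_assert(inlet_area_mm2 > 0 && exit_area_mm2 > 0, "cap areas must be > 0")
  if (!is.null(vertices)) {
    vertices <- as.matrix(vertices)
    faces <- as.matrix(faces)
    vf_assert(ncol(vertices) == 3 && ncol(faces) == 3, "mesh must be triangles in 3D")
    # endpoints must sit on the cap centroids (within one typical edge length)
    edge <- stats::median(sqrt(rowSums(
      (vertices[faces[, 1], , drop = FALSE] - vertices[faces[, 2], , drop = FALSE])^2)))
    caps <- cap_vertex_sets(vertices, centerline)
    d_in <- sqrt(sum((colMeans(vertices[caps$inlet, , drop = FALSE]) - centerline[1, ])^2))
    d_out <- sqrt(sum((colMeans(vertices[caps$exit, , drop = FALSE]) - centerline[n, ])^2))
    vf_assert(d_in <= edge && d_out <= edge,
              "centerline endpoints do not coincide with the mesh cap centroids")
  }
  structure(list(vertices = vertices, faces = faces, centerline = centerline,
                 radius_mm = as.numeric(radius_mm),
                 arclength_mm = as.numeric(arclength_mm),
                 inlet_area_mm2 = inlet_area_mm2, exit_area_mm2 = exit_area_mm2,
                 params = params),
            class = "vessel_geometry")
}

#' @export
print.vessel_geometry <- function(x, ...) {
  n <- nrow(x$centerline)
  cat("<vessel_geometry>\n")
  cat(sprintf("  stations          %d, actual length %.2f mm, absolute %.2f mm\n",
              n, actual_length(x), absolute_length(x)))
  cat(sprintf("  tortuosity index  %.3f\n",
              tortuosity_index(actual_length(x), absolute_length(x))))
  cat(sprintf("  inlet area        %.2f mm^2, exit area %.2f mm^2 (ratio %.3f)\n",
              x$inlet_area_mm2, x$exit_area_mm2,
              area_ratio(x$exit_area_mm2, x$inlet_area_mm2)))
  cat(sprintf("  surface           %s\n",
              if (is.null(x$vertices)) "none (centerline only)"
              else sprintf("%d vertices, %d triangles", nrow(x$vertices), nrow(x$faces))))
  invisible(x)
}

# vertices lying on the inlet/outlet cap planes (within tol of the plane
# through the respective centerline endpoint, perpendicular to the end
# tangent)
cap_vertex_sets <- function(vertices, centerline, tol = 1e-6) {
  n <- nrow(centerline)
  t_in <- centerline[2, ] - centerline[1, ]
  t_in <- t_in / sqrt(sum(t_in^2))
  t_out <- centerline[n, ] - centerline[n - 1, ]
  t_out <- t_out / sqrt(sum(t_out^2))
  d_in <- abs((vertices - matrix(centerline[1, ], nrow(vertices), 3, byrow = TRUE)) %*% t_in)
  d_out <- abs((vertices - matrix(centerline[n, ], nrow(vertices), 3, byrow = TRUE)) %*% t_out)
  scale <- max(abs(vertices)) * 1e-6 + tol
  list(inlet = which(d_in < scale), exit = which(d_out < scale))
}

# Planar cap areas: sum of triangle areas over faces whose three vertices
# all lie on the inlet (resp. outlet) cap plane.
mesh_cap_areas <- function(vertices, faces, centerline) {
  caps <- cap_vertex_sets(vertices, centerline)
  tri_area <- function(f) {
    a <- vertices[f[, 1], , drop = FALSE]
    b <- vertices[f[, 2], , drop = FALSE]
    c_ <- vertices[f[, 3], , drop = FALSE]
    u <- b - a; v <- c_ - a
    cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                u[, 3] * v[, 1] - u[, 1] * v[, 3],
                u[, 1] * v[, 2] - u[, 2] * v[, 1])
    sum(sqrt(rowSums(cr^2))) / 2
  }
  on_in <- matrix(faces %in% caps$inlet, ncol = 3)
  on_out <- matrix(faces %in% caps$exit, ncol = 3)
  list(inlet = tri_area(faces[rowSums(on_in) == 3L, , drop = FALSE]),
       exit = tri_area(faces[rowSums(on_out) == 3L, , drop = FALSE]))
}

#' Cross-section radius recovered by slicing the surface mesh
#'
#' Intersects the mesh with the plane through the station perpendicular to
#' the local centerline tangent and returns the effective radius
#' `perimeter / (2 pi)` of the intersection curve restricted to the
#' station's neighborhood. Used as an independent check that the analytic
#' radius profile and the triangulated surface agree.
#'
#' @param geometry A [vessel_geometry()] with a surface mesh.
#' @param station Station index.
#' @return Effective radius in mm.
#' @export
mesh_slice_radius <- function(geometry, station) {
  vf_assert(!is.null(geometry$vertices), "geometry has no surface mesh")
  cl <- geometry$centerline
  n <- nrow(cl)
  vf_assert(station >= 1 && station <= n, "station out of range")
  i0 <- max(1L, station - 1L); i1 <- min(n, station + 1L)
  tang <- cl[i1, ] - cl[i0, ]
  tang <- tang / sqrt(sum(tang^2))
  p0 <- cl[station, ]
  v <- geometry$vertices
  f <- geometry$faces
  h <- as.numeric((v - matrix(p0, nrow(v), 3, byrow = TRUE)) %*% tang)
  # nudge the plane off any vertex lying exactly on it (station rings do),
  # so every local triangle registers as crossing
  h <- h + 1e-5 * geometry$radius_mm[station]
  # keep only intersection segments near the station (exclude other coils)
  keep_dist <- 4 * geometry$radius_mm[station]
  hs <- cbind(h[f[, 1]], h[f[, 2]], h[f[, 3]])
  crossing <- which(apply(hs, 1, min) < 0 & apply(hs, 1, max) > 0)
  per <- 0
  for (fi in crossing) {
    idx <- f[fi, ]
    pts <- matrix(NA_real_, 0, 3)
    for (pair in list(c(1, 2), c(2, 3), c(3, 1))) {
      ha <- h[idx[pair[1]]]; hb <- h[idx[pair[2]]]
      if ((ha < 0) != (hb < 0)) {
        t <- ha / (ha - hb)
        pts <- rbind(pts, v[idx[pair[1]], ] + t * (v[idx[pair[2]], ] - v[idx[pair[1]], ]))
      }
    }
    if (nrow(pts) == 2 &&
        sqrt(sum((colMeans(pts) - p0)^2)) < keep_dist) {
      per <- per + sqrt(sum((pts[2, ] - pts[1, ])^2))
    }
  }
  per / (2 * pi)
}

#' Tortuosity index
#'
#' Ratio of the centerline arclength ("actual length") to the straight
#' inlet-outlet distance ("absolute length"); 1 for a straight vessel,
#' larger for tortuous ones.
#'
#' @param actual_length Centerline arclength (any length unit).
#' @param absolute_length Straight-line inlet-outlet distance (same unit).
#' @param tol Relative slack allowed for `actual_length` to fall below
#'   `absolute_length` before it is treated as a geometry error.
#' @return Dimensionless index >= 1.
#' @export
tortuosity_index <- function(actual_length, absolute_length, tol = 1e-9) {
  vf_assert(is_scalar_number(absolute_length) && absolute_length > 0,
            "absolute_length must be > 0")
  vf_assert(is_scalar_number(actual_length) && actual_length > 0,
            "actual_length must be > 0")
  if (actual_length < absolute_length * (1 - tol)) {
    vf_stop("geometry error: actual length (", actual_length,
            ") is shorter than absolute length (", absolute_length, ")")
  }
  max(actual_length / absolute_length, 1)
}

#' Outlet/inlet cross-sectional area ratio
#'
#' @param exit_area,inlet_area Cap areas (> 0, same unit).
#' @return `exit_area / inlet_area`.
#' @export
area_ratio <- function(exit_area, inlet_area) {
  vf_assert(is_scalar_number(exit_area) && exit_area > 0, "exit_area must be > 0")
  vf_assert(is_scalar_number(inlet_area) && inlet_area > 0, "inlet_area must be > 0")
  exit_area / inlet_area
}

#' Straight-line inlet-outlet distance ("absolute length")
#'
#' @param geometry A [vessel_geometry()].
#' @return Length in mm.
#' @export
absolute_length <- function(geometry) {
  cl <- geometry$centerline
  d <- sqrt(sum((cl[nrow(cl), ] - cl[1, ])^2))
  if (d <= 0) vf_stop("degenerate centerline: coincident endpoints")
  d
}

#' Centerline arclength ("actual length")
#'
#' @param geometry A [vessel_geometry()].
#' @return Length in mm.
#' @export
actual_length <- function(geometry) {
  geometry$arclength_mm[length(geometry$arclength_mm)]
}
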