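# File-format plumbing: STL, centerline/flow/segmentation CSV, legacy VTK,
# JSON configuration.

#' Write a surface mesh as STL
#'
#' @param geometry A [vessel_geometry()] with a mesh.
#' @param path Output path.
#' @param binary Binary STL (default) or ASCII.
#' @return `path`, invisibly.
#' @export
write_stl <- function(geometry, path, binary = TRUE) {
  vf_assert(!is.null(geometry$vertices), "geometry has no surface mesh to write")
  v <- geometry$vertices; f <- geometry$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  u <- b - a; w <- c_ - a
  nrm <- normalize_rows(cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
                              u[, 3] * w[, 1] - u[, 1] * w[, 3],
                              u[, 1] * w[, 2] - u[, 2] * w[, 1]))
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80), con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    # 12 floats + attribute short per triangle
    dat <- t(cbind(nrm, a, b, c_))
    for (i in seq_len(nrow(f))) {
      writeBin(as.numeric(dat[, i]), con, size = 4, endian = "little")
      writeBin(as.integer(0), con, size = 2, endian = "little")
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid vessel", con)
    for (i in seq_len(nrow(f))) {
      writeLines(c(
        sprintf("  facet normal %.9e %.9e %.9e", nrm[i, 1], nrm[i, 2], nrm[i, 3]),
        "    outer loop",
        sprintf("      vertex %.9e %.9e %.9e", a[i, 1], a[i, 2], a[i, 3]),
        sprintf("      vertex %.9e %.9e %.9e", b[i, 1], b[i, 2], b[i, 3]),
        sprintf("      vertex %.9e %.9e %.9e", c_[i, 1], c_[i, 2], c_[i, 3]),
        "    endloop",
        "  endfacet"), con)
    }
    writeLines("endsolid vessel", con)
  }
  invisible(path)
}

#' Read an STL surface mesh
#'
#' Autodetects binary vs ASCII. Duplicate vertices are merged so the
#' returned triangulation can be checked for watertightness.
#'
#' @param path STL file path.
#' @return List with `vertices` (n x 3) and `faces` (m x 3).
#' @export
read_stl <- function(path) {
  head <- readBin(path, "raw", n = 5)
  is_ascii <- identical(rawToChar(head), "solid") && {
    # binary STLs may also start with "solid": check the triangle count
    sz <- file.size(path)
    con <- file(path, "rb"); on.exit(close(con))
    seek(con, 80); nt <- readBin(con, "integer", size = 4, endian = "little")
    sz != 84 + 50 * nt
  }
  if (is_ascii) {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex", lines, value = TRUE)
    xyz <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p) {
      as.numeric(p[2:4])
    }))
  } else {
    con <- file(path, "rb")
    on.exit(close(con), add = TRUE)
    seek(con, 80)
    nt <- readBin(con, "integer", size = 4, endian = "little")
    xyz <- matrix(NA_real_, 3L * nt, 3)
    for (i in seq_len(nt)) {
      vals <- readBin(con, "numeric", n = 12, size = 4, endian = "little")
      readBin(con, "integer", n = 1, size = 2, endian = "little")
      xyz[3L * (i - 1L) + 1:3, ] <- matrix(vals[4:12], 3, 3, byrow = TRUE)
    }
  }
  key <- apply(xyz, 1, function(p) paste(signif(p, 12), collapse = ","))
  uid <- match(key, unique(key))
  verts <- xyz[!duplicated(key), , drop = FALSE]
  faces <- matrix(uid, ncol = 3, byrow = TRUE)
  list(vertices = verts, faces = faces)
}

centerline_columns <- c("station_index", "x_mm", "y_mm", "z_mm",
                        "arclength_mm", "radius_mm")

#' Write a centerline table as CSV
#'
#' Columns: `station_index, x_mm, y_mm, z_mm, arclength_mm, radius_mm`.
#'
#' @param geometry A [vessel_geometry()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_centerline_csv <- function(geometry, path) {
  cl <- geometry$centerline
  df <- data.frame(station_index = seq_len(nrow(cl)) - 1L,
                   x_mm = cl[, 1], y_mm = cl[, 2], z_mm = cl[, 3],
                   arclength_mm = geometry$arclength_mm,
                   radius_mm = geometry$radius_mm)
  utils::write.csv(format(df, digits = 15, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a centerline CSV
#'
#' @param path CSV with the [write_centerline_csv()] schema.
#' @return Data frame with the validated columns.
#' @export
read_centerline_csv <- function(path) {
  df <- utils::read.csv(path)
  missing <- setdiff(centerline_columns, names(df))
  if (length(missing)) {
    vf_stop("centerline CSV schema error: missing column(s) ",
            paste(missing, collapse = ", "))
  }
  df
}

#' Write a flow solution as per-station CSV
#'
#' Columns: `s_mm, radius_mm, velocity_mps, pressure_pa` (reported scale)
#' and `pressure_gauge_pa, wss_pa`.
#'
#' @param solution A [solve_steady_flow()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_flow_csv <- function(solution, path) {
  st <- solution$stations
  df <- data.frame(s_mm = st$s_mm, radius_mm = st$radius_mm,
                   velocity_mps = st$velocity_mps,
                   pressure_pa = st$pressure_reported_pa,
                   pressure_gauge_pa = st$pressure_pa,
                   wss_pa = st$wss_pa)
  utils::write.csv(format(df, digits = 15, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a segmentation scheme as CSV
#'
#' @param scheme A [divide_segments()] scheme.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segmentation_csv <- function(scheme, path) {
  utils::write.csv(segmentation_table(scheme), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Export the surface with per-face WSS as legacy VTK
#'
#' ASCII legacy `.vtk` PolyData with a `wss_pa` scalar per triangle, for
#' ParaView-style visualization.
#'
#' @param geometry A [vessel_geometry()] with a mesh.
#' @param solution The matching [solve_steady_flow()] result (with
#'   `face_wss_pa`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vtk_surface <- function(geometry, solution, path) {
  vf_assert(!is.null(geometry$vertices), "geometry has no surface mesh")
  vf_assert(!is.null(solution$face_wss_pa), "solution has no per-face WSS")
  v <- geometry$vertices; f <- geometry$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "vessel surface with wall shear stress",
               "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d float", nrow(v))), con)
  writeLines(sprintf("%.9e %.9e %.9e", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("POLYGONS %d %d", nrow(f), 4L * nrow(f)), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  writeLines(c(sprintf("CELL_DATA %d", nrow(f)),
               "SCALARS wss_pa float 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%.9e", solution$face_wss_pa), con)
  invisible(path)
}
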