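# Equal-arclength segmentation of the centerline and the A/B/C grouping.

#' Divide a vessel into K equal-arclength segments
#'
#' Splits the centerline into `K` consecutive segments of identical
#' arclength, numbered 1 at the inlet (nidus-proximal) end to `K` at the
#' outlet (sinus) end, and assigns every station to a segment. A station
#' falling exactly on an interior boundary belongs to the downstream
#' (higher-index) segment. With the default `K = 15`, segments are grouped
#' as A = 1-5 (anterior), B = 6-10 (middle), C = 11-15 (posterior/outflow).
#'
#' @param geometry A [vessel_geometry()].
#' @param K Number of segments (default 15).
#' @return An object of class `segmentation_scheme`: list with `K`,
#'   `boundaries` (K+1 arclengths, mm), `segment_of_station`, `groups`.
#' @export
divide_segments <- function(geometry, K = 15L) {
  K <- as.integer(K)
  vf_assert(K >= 1L, "K must be >= 1")
  s <- geometry$arclength_mm
  n <- length(s)
  if (n < K) {
    vf_stop("insufficient stations: ", n, " stations cannot fill ", K,
            " segments (at least one segment would be empty)")
  }
  total <- s[n]
  boundaries <- seq(0, total, length.out = K + 1L)
  seg <- findInterval(s, boundaries, rightmost.closed = TRUE)
  # equal-arclength stations guarantee non-empty segments for n >= K;
  # guard anyway for imported centerlines with irregular spacing
  if (length(unique(seg)) < K) {
    vf_stop("insufficient stations: some of the ", K,
            " segments contain no centerline station")
  }
  groups <- segment_groups(K)
  structure(list(K = K, boundaries = boundaries,
                 segment_of_station = seg, groups = groups,
                 total_length_mm = total),
            class = "segmentation_scheme")
}

# A/B/C thirds of the K segments (exact thirds for K divisible by 3;
# K = 15 gives the canonical 1-5 / 6-10 / 11-15)
segment_groups <- function(K) {
  cuts <- round(K * c(1, 2) / 3)
  list(A = seq_len(cuts[1]),
       B = seq(cuts[1] + 1L, cuts[2]),
       C = seq(cuts[2] + 1L, K))
}

# group label per segment index
group_of_segment <- function(seg, groups) {
  lab <- character(length(seg))
  for (g in names(groups)) lab[seg %in% groups[[g]]] <- g
  lab
}

#' @export
print.segmentation_scheme <- function(x, ...) {
  cat("<segmentation_scheme>\n")
  cat(sprintf("  K = %d equal segments of %.3f mm (total %.2f mm)\n",
              x$K, diff(x$boundaries[1:2]), x$total_length_mm))
  cat(sprintf("  groups: A = %s, B = %s, C = %s\n",
              paste(range(x$groups$A), collapse = "-"),
              paste(range(x$groups$B), collapse = "-"),
              paste(range(x$groups$C), collapse = "-")))
  invisible(x)
}

#' Segmentation as a data frame
#'
#' @param scheme A `segmentation_scheme`.
#' @return Data frame with `segment_index`, `s_start_mm`, `s_end_mm`,
#'   `group`.
#' @export
segmentation_table <- function(scheme) {
  data.frame(segment_index = seq_len(scheme$K),
             s_start_mm = scheme$boundaries[-(scheme$K + 1L)],
             s_end_mm = scheme$boundaries[-1L],
             group = group_of_segment(seq_len(scheme$K), scheme$groups))
}
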