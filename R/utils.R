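# Internal helpers shared across modules.

# clamp a numeric vector into [lo, hi]
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# stop() with a consistent prefix and no call noise
vf_stop <- function(...) stop(..., call. = FALSE)

vf_assert <- function(cond, ...) {
  if (!isTRUE(cond)) vf_stop(...)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# trapezoid weights for stations at arclengths s (strictly increasing):
# w_i integrates a piecewise-linear field, w_1 and w_n take half end intervals
trapezoid_weights <- function(s) {
  n <- length(s)
  if (n == 1L) return(1)
  d <- diff(s)
  c(d[1] / 2, (d[-1] + d[-(n - 1)]) / 2, d[n - 1] / 2)
}

weighted_mean_ <- function(x, w) sum(x * w) / sum(w)

# cumulative trapezoid integral of y over x, anchored at 0 at x[1]
cumtrapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum(diff(x) * (y[-1] + y[-n]) / 2))
}

# unit rows of an n x 3 matrix
normalize_rows <- function(m) {
  nr <- sqrt(rowSums(m^2))
  nr[nr == 0] <- 1
  m / nr
}

# deterministic child seeds below 2^31, derived from a master seed
derive_seeds <- function(master_seed, n) {
  withr::with_seed(as.integer(master_seed), sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
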