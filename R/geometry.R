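# Small 3D vector and polyline helpers shared across modules.
# Points are rows of n x 3 numeric matrices, coordinates in millimetres.

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(a) sqrt(sum(a * a))

vunit <- function(a) {
  n <- vnorm(a)
  if (n == 0) ssm_stop("degenerate_vector", "cannot normalize a zero vector")
  a / n
}

#' @keywords internal
as_point_matrix <- function(x, what = "points") {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  dimnames(x) <- NULL
  if (ncol(x) != 3L)
    ssm_stop("bad_dimensions", "%s must have 3 columns (x, y, z)", what)
  x
}

# Cumulative chordal arc length of a polyline (first entry 0).
polyline_arc <- function(pts) {
  if (nrow(pts) < 2L) return(0)
  seg <- sqrt(rowSums((pts[-1L, , drop = FALSE] -
                       pts[-nrow(pts), , drop = FALSE])^2))
  c(0, cumsum(seg))
}

# Linear interpolation of a polyline at arc positions `s` (clamped to range).
# Handles zero-length segments by skipping them.
interp_polyline <- function(pts, arc, s) {
  s <- pmin(pmax(s, arc[1L]), arc[length(arc)])
  keep <- c(TRUE, diff(arc) > 0)
  pts <- pts[keep, , drop = FALSE]
  arc <- arc[keep]
  out <- matrix(NA_real_, length(s), 3L)
  for (k in 1:3)
    out[, k] <- stats::approx(arc, pts[, k], xout = s, rule = 2)$y
  out
}

# Resample a polyline at (approximately) uniform arc spacing, keeping both
# endpoints. Returns list(points, arc).
resample_polyline <- function(pts, spacing) {
  arc <- polyline_arc(pts)
  total <- arc[length(arc)]
  n <- max(2L, ceiling(total / spacing) + 1L)
  s <- seq(0, total, length.out = n)
  list(points = interp_polyline(pts, arc, s), arc = s)
}

# Tangent by central differences on an arc-length resampled polyline,
# one-sided at the ends. Returns unit vectors, one per input arc position.
polyline_tangent <- function(pts, arc, s) {
  h <- if (length(arc) > 1L) (arc[length(arc)] - arc[1L]) / (length(arc) - 1L) else 1
  t(vapply(s, function(si) {
    lo <- max(si - h, arc[1L])
    hi <- min(si + h, arc[length(arc)])
    p <- interp_polyline(pts, arc, c(lo, hi))
    vunit(p[2L, ] - p[1L, ])
  }, numeric(3)))
}
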