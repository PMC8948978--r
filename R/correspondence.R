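#' Longitudinally rearrange a contour grid
#'
#' For each angular column of the grid independently, treats its points
#' (proximal to distal) as a 3D polyline and re-places them at equal
#' arc-length spacing by linear interpolation along that polyline. The
#' first and last ring points are unchanged. This prevents the crossing of
#' adjacent contour rings along any column and establishes even
#' longitudinal point correspondence.
#'
#' @param grid a [contour_grid()].
#' @return A rearranged [contour_grid()].
#' @export
rearrange_longitudinal <- function(grid) {
  stopifnot(inherits(grid, "contour_grid"))
  pts <- grid$points
  d <- dim(pts)
  for (j in seq_len(d[2L])) {
    col <- pts[, j, ]
    if (max(polyline_arc(col)) <= 0)
      ssm_stop("degenerate_column",
               "angular column %d has zero length (all points coincident)", j)
    # iterate equal-arc interpolation to its fixed point: the re-placed
    # points then sit at equal spacing along their own chordal polyline,
    # i.e. consecutive inter-point distances are equal, which prevents
    # crossing of adjacent rings; convergence is fast for the mildly
    # curved columns of a vessel
    for (it in seq_len(200L)) {
      arc <- polyline_arc(col)
      s <- seq(0, arc[length(arc)], length.out = d[1L])
      new <- interp_polyline(col, arc, s)
      delta <- max(abs(new - col))
      col <- new
      if (delta < 1e-12) break
    }
    pts[, j, ] <- col
  }
  contour_grid(pts, arc = grid$arc, baseline_point = grid$baseline_point)
}

#' Translate a grid to the LRA baseline
#'
#' Pure translation (no rotation or scaling) of every contour point by
#' `-baseline_point`, so that the centerline point at the LRA baseline
#' moves to the origin and all necks share one anchor.
#'
#' @param grid a [contour_grid()].
#' @param baseline_point 3D point; defaults to the grid's recorded baseline.
#' @return The aligned [contour_grid()] (baseline at the origin).
#' @export
align_to_baseline <- function(grid, baseline_point = grid$baseline_point) {
  stopifnot(inherits(grid, "contour_grid"))
  if (is.null(baseline_point))
    ssm_stop("missing_baseline", "grid carries no baseline point and none was given")
  pts <- grid$points
  for (k in 1:3) pts[, , k] <- pts[, , k] - baseline_point[k]
  contour_grid(pts, arc = grid$arc, baseline_point = c(0, 0, 0))
}

#' Flatten a contour grid to a shape vector
#'
#' Flattening order is ring-major, then ray, then coordinate: grid point
#' (ring 1, ray 1) occupies vector positions 1-3 (x, y, z). With the
#' default 10 x 36 grid the shape vector has 1080 entries.
#'
#' @param grid a [contour_grid()].
#' @return Numeric vector of length `rings * rays * 3`, with attribute
#'   `"grid_dim"` recording `c(rings, rays)`.
#' @export
flatten_grid <- function(grid) {
  stopifnot(inherits(grid, "contour_grid"))
  d <- dim(grid$points)
  v <- as.vector(aperm(grid$points, c(3L, 2L, 1L)))
  attr(v, "grid_dim") <- d[1:2]
  v
}

#' @rdname flatten_grid
#' @param v a shape vector of length `rings * rays * 3`.
#' @param rings,rays grid dimensions (defaults 10 and 36).
#' @export
unflatten_grid <- function(v, rings = 10L, rays = 36L) {
  gd <- attr(v, "grid_dim")
  if (!is.null(gd)) { rings <- gd[1L]; rays <- gd[2L] }
  if (length(v) != rings * rays * 3L)
    ssm_stop("bad_dimensions",
             "shape vector has length %d, expected %d (%d rings x %d rays x 3)",
             length(v), rings * rays * 3L, rings, rays)
  contour_grid(aperm(array(as.numeric(v), c(3L, rays, rings)), c(3L, 2L, 1L)))
}

#' Assemble a shape cohort
#'
#' Stacks aligned shape vectors into the `n x p` matrix consumed by
#' [fit_ssm()].
#'
#' @param vectors list of shape vectors (equal lengths), or a numeric
#'   matrix with one shape per row.
#' @param ids patient identifiers (unique); defaults to `s1, s2, ...`.
#' @param rings,rays grid dimensions recorded with the cohort.
#' @return Object of class `shape_cohort` with `ids` and `matrix`.
#' @export
shape_cohort <- function(vectors, ids = NULL, rings = 10L, rays = 36L) {
  X <- if (is.matrix(vectors)) vectors else do.call(rbind, vectors)
  if (nrow(X) < 3L) ssm_stop("bad_cohort", "a cohort needs at least 3 shapes")
  stopifnot_finite(X, "cohort matrix")
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(X)))
  if (anyDuplicated(ids)) ssm_stop("bad_cohort", "duplicated patient ids")
  if (ncol(X) != rings * rays * 3L)
    ssm_stop("bad_dimensions", "cohort columns (%d) do not match %d x %d grid",
             ncol(X), rings, rays)
  structure(list(ids = as.character(ids), matrix = unname(X),
                 rings = as.integer(rings), rays = as.integer(rays)),
            class = "shape_cohort")
}

#' @export
print.shape_cohort <- function(x, ...) {
  cat(sprintf("shape_cohort: %d shapes x %d coordinates (%d x %d grid)\n",
              nrow(x$matrix), ncol(x$matrix), x$rings, x$rays))
  invisible(x)
}

#' Process one neck into an aligned shape vector
#'
#' Convenience composition of the per-patient pipeline:
#' [parametrize_neck()], [rearrange_longitudinal()], [align_to_baseline()],
#' [flatten_grid()].
#'
#' @inheritParams parametrize_neck
#' @return An aligned shape vector.
#' @export
process_neck <- function(mesh, cll, landmarks, config = param_config(),
                         id = NULL) {
  grid <- parametrize_neck(mesh, cll, landmarks, config, id = id)
  flatten_grid(align_to_baseline(rearrange_longitudinal(grid)))
}

#' Write / read a cohort matrix as CSV
#'
#' One row per shape, `rings * rays * 3` columns labelled
#' `r<ring>_a<angle>_<x|y|z>`, with patient ids in the first column.
#'
#' @param cohort a [shape_cohort()].
#' @param path output `.csv` path.
#' @export
write_cohort_csv <- function(cohort, path) {
  ang <- round((seq_len(cohort$rays) - 1L) * 360 / cohort$rays)
  labels <- as.vector(vapply(seq_len(cohort$rings), function(r)
    as.vector(vapply(ang, function(a)
      sprintf("r%d_a%d_%s", r, a, c("x", "y", "z")), character(3L))),
    character(3L * cohort$rays)))
  df <- data.frame(id = cohort$ids, cohort$matrix, check.names = FALSE)
  names(df) <- c("id", labels)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) ssm_stop("missing_file", "cohort file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE, comment.char = "#")
  last <- names(df)[ncol(df)]
  m <- regmatches(last, regexec("^r([0-9]+)_a[0-9]+_z$", last))[[1L]]
  rings <- if (length(m)) as.integer(m[2L]) else 10L
  rays <- (ncol(df) - 1L) / rings / 3L
  shape_cohort(as.matrix(df[, -1L]), ids = df[[1L]], rings = rings,
               rays = as.integer(rays))
}
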