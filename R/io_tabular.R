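#' Center lumen line
#'
#' An ordered polyline along the vessel lumen centerline, millimetres.
#' Cumulative chordal arc length is derived on construction.
#'
#' @param points numeric n x 3 matrix of ordered 3D points (mm).
#' @return Object of class `centerline` with `points` and `arc` (mm).
#' @export
centerline <- function(points) {
  points <- as_point_matrix(points, "centerline points")
  if (anyNA(points) || !all(is.finite(points)))
    ssm_stop("nonfinite_input", "centerline contains NaN/Inf coordinates")
  dup <- c(FALSE, rowSums((points[-1L, , drop = FALSE] -
                           points[-nrow(points), , drop = FALSE])^2) == 0)
  if (any(dup)) {
    ssm_warn("duplicate_points", "collapsed %d duplicate consecutive point(s)",
             sum(dup))
    points <- points[!dup, , drop = FALSE]
  }
  if (nrow(points) < 2L)
    ssm_stop("too_few_points", "a centerline needs at least 2 distinct points")
  structure(list(points = points, arc = polyline_arc(points)),
            class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("centerline: %d points, length %.2f mm\n",
              nrow(x$points), max(x$arc)))
  invisible(x)
}

#' Read a center lumen line from CSV or JSON
#'
#' CSV files have columns x, y, z (header optional); JSON files contain an
#' array of `[x, y, z]` triples. Point order is preserved.
#'
#' @param path path to a `.csv` or `.json` file.
#' @return A [centerline()].
#' @export
read_centerline <- function(path) {
  if (!file.exists(path))
    ssm_stop("missing_file", "centerline file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  pts <- if (ext == "json") {
    as.matrix(jsonlite::fromJSON(path))
  } else {
    first <- readLines(path, n = 1L)
    has_header <- any(is.na(suppressWarnings(
      as.numeric(strsplit(gsub("#.*$", "", first), ",")[[1L]]))))
    as.matrix(utils::read.csv(path, header = has_header, comment.char = "#"))
  }
  centerline(pts)
}

#' Write a center lumen line as CSV
#' @param cll a [centerline()].
#' @param path output `.csv` path.
#' @export
write_centerline <- function(cll, path) {
  utils::write.csv(data.frame(x = cll$points[, 1], y = cll$points[, 2],
                              z = cll$points[, 3]),
                   path, row.names = FALSE)
  invisible(path)
}

#' Neck landmarks
#'
#' The lowest renal artery (LRA) orifice coordinate, and optionally the
#' manually placed distal neck-end coordinate.
#'
#' @param lra 3D point (mm).
#' @param distal_end 3D point (mm) or `NULL` when the neck end is to be
#'   detected automatically from the diameter criterion.
#' @return Object of class `neck_landmarks`.
#' @export
neck_landmarks <- function(lra, distal_end = NULL) {
  lra <- as.numeric(lra)
  if (length(lra) != 3L || !all(is.finite(lra)))
    ssm_stop("bad_landmark", "lra must be a finite 3D point")
  if (!is.null(distal_end)) {
    distal_end <- as.numeric(distal_end)
    if (length(distal_end) != 3L || !all(is.finite(distal_end)))
      ssm_stop("bad_landmark", "distal_end must be a finite 3D point")
    if (all(distal_end == lra))
      ssm_stop("bad_landmark", "distal_end coincides with lra")
  }
  structure(list(lra = lra, distal_end = distal_end), class = "neck_landmarks")
}

#' Read neck landmarks from JSON or CSV
#'
#' JSON: object with key `lra` (and optionally `distal_end`), each `[x,y,z]`.
#' CSV: columns name,x,y,z with rows named `lra` / `distal_end`.
#'
#' @param path input file path.
#' @return A [neck_landmarks()].
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path))
    ssm_stop("missing_file", "landmark file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    obj <- jsonlite::fromJSON(path)
    if (is.null(obj$lra)) ssm_stop("bad_landmark", "no 'lra' entry in %s", path)
    neck_landmarks(obj$lra, obj$distal_end)
  } else {
    df <- utils::read.csv(path, comment.char = "#")
    row <- function(nm) {
      i <- match(nm, df[[1L]])
      if (is.na(i)) NULL else as.numeric(df[i, 2:4])
    }
    if (is.null(row("lra"))) ssm_stop("bad_landmark", "no 'lra' row in %s", path)
    neck_landmarks(row("lra"), row("distal_end"))
  }
}

#' Write neck landmarks as JSON
#' @param landmarks a [neck_landmarks()].
#' @param path output `.json` path.
#' @export
write_landmarks <- function(landmarks, path) {
  obj <- list(lra = landmarks$lra)
  if (!is.null(landmarks$distal_end)) obj$distal_end <- landmarks$distal_end
  jsonlite::write_json(obj, path, digits = NA)
  invisible(path)
}
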