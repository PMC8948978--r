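#' Parametrization configuration
#'
#' Settings for the tubular neck parametrization. Defaults follow the
#' standard protocol: ten cross-sectional stations along the neck centerline
#' and 36 rays per station at 10 degree intervals.
#'
#' The coordinate frame is assumed LPS-like by default: x = patient-left,
#' y = patient-posterior, z = cranial. The `anterior` axis only defines the
#' 0 degree ray direction (projected into each station's normal plane) and
#' the left/right labels, which makes ray indices anatomically comparable
#' across patients.
#'
#' @param n_stations number of cross-sectional stations (default 10).
#' @param n_rays number of rays per station (default 36).
#' @param anterior global anterior axis (default `c(0, -1, 0)`).
#' @param left global patient-left axis (default `c(1, 0, 0)`), used as
#'   fallback 0-degree reference when the tangent is within 5 degrees of
#'   the anterior axis.
#' @param lra_max_dist maximum accepted distance (mm) between the LRA
#'   landmark and the centerline; larger values suggest a unit or frame
#'   mismatch and raise an error. Default 30.
#' @param neck_end `"landmark"` uses the distal-end landmark when present,
#'   falling back to the diameter rule; `"diameter"` always uses the
#'   10 percent diameter-increase rule.
#' @param diameter_step walking step (mm) for neck-end detection. Default 1.
#' @param diameter_ratio diameter-increase threshold relative to the LRA
#'   baseline diameter. Default 1.10.
#' @param min_length minimum accepted neck length (mm). Default 5.
#' @param max_radius maximum accepted ray-intersection distance (mm);
#'   beyond this a mesh hole is suspected. Default 60.
#' @param resample_spacing arc-length resampling step (mm) of the centerline
#'   used for tangent estimation. Default 0.5.
#' @return A list of class `param_config`.
#' @export
param_config <- function(n_stations = 10L, n_rays = 36L,
                         anterior = c(0, -1, 0), left = c(1, 0, 0),
                         lra_max_dist = 30, neck_end = c("landmark", "diameter"),
                         diameter_step = 1, diameter_ratio = 1.10,
                         min_length = 5, max_radius = 60,
                         resample_spacing = 0.5) {
  neck_end <- match.arg(neck_end)
  if (n_stations < 3L) ssm_stop("bad_config", "need at least 3 stations")
  if (n_rays < 8L) ssm_stop("bad_config", "need at least 8 rays")
  structure(list(n_stations = as.integer(n_stations),
                 n_rays = as.integer(n_rays),
                 anterior = vunit(anterior), left = vunit(left),
                 lra_max_dist = lra_max_dist, neck_end = neck_end,
                 diameter_step = diameter_step, diameter_ratio = diameter_ratio,
                 min_length = min_length, max_radius = max_radius,
                 resample_spacing = resample_spacing),
            class = "param_config")
}

#' Contour grid
#'
#' The point-correspondence structure of one parametrized neck: `rings`
#' stations (proximal to distal) times `rays` circumferential contour points
#' (0 to 350 degrees), each a 3D point in mm. With the default configuration
#' this is the 10 x 36 grid of 360 contour points.
#'
#' @param points numeric array `rings x rays x 3`.
#' @param arc station arc positions (mm from the LRA baseline).
#' @param baseline_point 3D centerline point at the LRA baseline (the
#'   alignment anchor).
#' @return Object of class `contour_grid`.
#' @export
contour_grid <- function(points, arc = NULL, baseline_point = NULL) {
  if (!is.array(points) || length(dim(points)) != 3L || dim(points)[3L] != 3L)
    ssm_stop("bad_dimensions", "contour grid must be a rings x rays x 3 array")
  stopifnot_finite(points, "contour grid")
  structure(list(points = points, arc = arc, baseline_point = baseline_point),
            class = "contour_grid")
}

#' @export
print.contour_grid <- function(x, ...) {
  d <- dim(x$points)
  cat(sprintf("contour_grid: %d rings x %d rays (%d contour points)\n",
              d[1L], d[2L], d[1L] * d[2L]))
  invisible(x)
}

#' Project the LRA landmark onto the centerline
#'
#' Finds the arc-length position of the point on the centerline polyline
#' (projection onto segments, not just vertices) closest to a landmark.
#' Ties are broken toward the more proximal (smaller-arc) foot.
#'
#' @param cll a [centerline()].
#' @param point 3D landmark coordinate (mm).
#' @param max_dist maximum accepted landmark-to-centerline distance (mm).
#' @return Arc-length position in mm.
#' @export
project_to_cll <- function(cll, point, max_dist = 30) {
  P <- cll$points; arc <- cll$arc
  best_d2 <- Inf; best_arc <- NA_real_
  for (i in seq_len(nrow(P) - 1L)) {
    p0 <- P[i, ]; d <- P[i + 1L, ] - p0
    len2 <- sum(d * d)
    tt <- if (len2 == 0) 0 else min(max(sum((point - p0) * d) / len2, 0), 1)
    foot <- p0 + tt * d
    d2 <- sum((point - foot)^2)
    if (d2 < best_d2 - 1e-12) {  # strict improvement keeps the proximal foot on ties
      best_d2 <- d2
      best_arc <- arc[i] + tt * sqrt(len2)
    }
  }
  if (sqrt(best_d2) > max_dist)
    ssm_stop("landmark_off_centerline",
             "landmark is %.1f mm from the centerline (max %.1f mm); check units/frame",
             sqrt(best_d2), max_dist)
  best_arc
}

#' @rdname project_to_cll
#' @param landmarks a [neck_landmarks()]; its `lra` point is projected.
#' @export
project_lra <- function(cll, landmarks, max_dist = 30) {
  project_to_cll(cll, landmarks$lra, max_dist)
}

# Build the station frame (origin, tangent, ray0) at one arc position.
# `rs` is the 0.5 mm resampled centerline from resample_polyline().
station_frame <- function(rs, arc_pos, config) {
  origin <- drop(interp_polyline(rs$points, rs$arc, arc_pos))
  tangent <- drop(polyline_tangent(rs$points, rs$arc, arc_pos))
  ref <- config$anterior
  # fall back to the left axis when anterior is within 5 degrees of the tangent
  if (abs(sum(ref * tangent)) > cos(5 * pi / 180)) ref <- config$left
  ray0 <- vunit(ref - sum(ref * tangent) * tangent)
  list(origin = origin, tangent = tangent, ray0 = ray0)
}

#' Cast a ring of rays at one station
#'
#' Casts `n_rays` rays from the station origin in its normal plane at equal
#' angular intervals (right-handed rotation of `ray0` about the tangent) and
#' intersects each with the mesh (Moller-Trumbore ray-triangle intersection
#' over all triangles). The nearest strictly positive hit is returned per ray.
#'
#' @param mesh a [lumen_mesh()].
#' @param frame a station frame: list with `origin`, `tangent`, `ray0`.
#' @param n_rays number of rays (default 36).
#' @param max_radius maximum accepted hit distance (mm).
#' @param pre optional precomputed triangle arrays (internal reuse).
#' @return `n_rays x 3` matrix of contour points, with the ray distances in
#'   attribute `"distances"` and hit triangle indices in `"triangles"`.
#' @export
cast_ring <- function(mesh, frame, n_rays = 36L, max_radius = 60, pre = NULL) {
  if (is.null(pre)) pre <- ray_precompute(mesh)
  pre <- ray_plane_subset(pre, frame$origin, frame$tangent)
  e2 <- vcross(frame$tangent, frame$ray0)
  ang <- (seq_len(n_rays) - 1L) * 2 * pi / n_rays
  pts <- matrix(NA_real_, n_rays, 3L)
  dist <- numeric(n_rays)
  tri <- integer(n_rays)
  for (j in seq_len(n_rays)) {
    dir <- cos(ang[j]) * frame$ray0 + sin(ang[j]) * e2
    hit <- ray_hit(frame$origin, dir, pre)
    if (!is.finite(hit$t) || hit$t > max_radius)
      ssm_stop("ray_miss",
               "ray at angle %.0f deg %s (station origin %.1f, %.1f, %.1f); suspected mesh hole",
               ang[j] * 180 / pi,
               if (is.finite(hit$t)) sprintf("hit at %.1f mm > max radius %.1f mm",
                                             hit$t, max_radius)
               else "has no mesh intersection",
               frame$origin[1L], frame$origin[2L], frame$origin[3L])
    pts[j, ] <- frame$origin + hit$t * dir
    dist[j] <- hit$t
    tri[j] <- hit$triangle
  }
  attr(pts, "distances") <- dist
  attr(pts, "triangles") <- tri
  pts
}

#' Measure the lumen diameter at a station
#'
#' Operationalizes "diameter" as twice the mean of the 36 ray-intersection
#' distances, which is rotation-stable and reuses the ray machinery.
#'
#' @inheritParams cast_ring
#' @return Diameter in mm.
#' @export
measure_diameter <- function(mesh, frame, n_rays = 36L, max_radius = 60,
                             pre = NULL) {
  pts <- cast_ring(mesh, frame, n_rays = n_rays, max_radius = max_radius,
                   pre = pre)
  2 * mean(attr(pts, "distances"))
}

#' Detect the distal neck end by the diameter rule
#'
#' Walks distally along the centerline from the LRA baseline in steps and
#' returns the first arc position where the lumen diameter reaches
#' `ratio` (default 1.10, i.e. a 10 percent increase) times the baseline
#' diameter, refined by bisection to 0.1 mm.
#'
#' @param mesh a [lumen_mesh()].
#' @param cll a [centerline()].
#' @param baseline_arc arc position (mm) of the LRA baseline.
#' @param step walking step in mm (default 1).
#' @param ratio diameter threshold relative to baseline (default 1.10).
#' @param config a [param_config()].
#' @return Arc-length position (mm) of the detected neck end.
#' @export
detect_neck_end <- function(mesh, cll, baseline_arc, step = 1, ratio = 1.10,
                            config = param_config()) {
  rs <- resample_polyline(cll$points, config$resample_spacing)
  pre <- ray_precompute(mesh)
  dia <- function(s) measure_diameter(mesh, station_frame(rs, s, config),
                                      n_rays = config$n_rays,
                                      max_radius = config$max_radius, pre = pre)
  d0 <- dia(baseline_arc)
  target <- ratio * d0 * (1 - 1e-9)  # tolerate roundoff when the threshold
                                     # is reached exactly at the last station
  total <- max(cll$arc)
  arcs <- unique(c(seq(baseline_arc + step, total, by = step), total))
  prev <- baseline_arc
  max_ratio <- 1
  for (s in arcs) {
    d <- dia(s)
    max_ratio <- max(max_ratio, d / d0)
    if (d >= target) {
      lo <- prev; hi <- s
      while (hi - lo > 0.1) {
        mid <- (lo + hi) / 2
        if (dia(mid) >= target) hi <- mid else lo <- mid
      }
      return(hi)
    }
    prev <- s
  }
  ssm_stop("neck_end_not_found",
           "diameter never reached %.0f%% of baseline before the centerline end (max ratio %.3f)",
           100 * ratio, max_ratio)
}

#' Place equidistant stations along the neck
#'
#' Divides the truncated centerline between the LRA baseline and the neck
#' end into equidistant stations including both endpoints: arc positions
#' `baseline + k * (end - baseline) / (n - 1)`, `k = 0 .. n-1`. Tangents are
#' estimated by central differences on the 0.5 mm arc-length resampled
#' polyline (one-sided at the ends).
#'
#' @inheritParams detect_neck_end
#' @param end_arc arc position (mm) of the distal neck end.
#' @return List of station frames with attribute `"arc"` (arc positions, mm).
#' @export
place_stations <- function(cll, baseline_arc, end_arc, config = param_config()) {
  if (end_arc <= baseline_arc)
    ssm_stop("bad_neck_bounds", "neck end (%.1f mm) not distal to baseline (%.1f mm)",
             end_arc, baseline_arc)
  if (end_arc - baseline_arc < config$min_length)
    ssm_stop("neck_too_short", "neck length %.1f mm is below the minimum %.1f mm",
             end_arc - baseline_arc, config$min_length)
  rs <- resample_polyline(cll$points, config$resample_spacing)
  arcs <- baseline_arc + (seq_len(config$n_stations) - 1L) *
    (end_arc - baseline_arc) / (config$n_stations - 1L)
  frames <- lapply(arcs, function(s) station_frame(rs, s, config))
  attr(frames, "arc") <- arcs
  frames
}

#' Parametrize an aortic neck as a contour grid
#'
#' Full tubular parametrization of one patient: project the LRA landmark
#' onto the centerline, locate the distal neck end (the distal landmark if
#' supplied, otherwise the 10 percent diameter rule), place equidistant
#' stations, and cast a ring of rays at each. With the default
#' configuration the result is the 10 x 36 grid of 360 contour points.
#'
#' @param mesh a [lumen_mesh()].
#' @param cll a [centerline()].
#' @param landmarks a [neck_landmarks()].
#' @param config a [param_config()].
#' @param id optional patient identifier used in error messages.
#' @return A [contour_grid()] with station arc positions (relative to the
#'   LRA baseline) and the baseline centerline point recorded for alignment.
#' @export
parametrize_neck <- function(mesh, cll, landmarks, config = param_config(),
                             id = NULL) {
  ctx <- if (is.null(id)) "" else sprintf(" [patient %s]", id)
  res <- tryCatch(
    {
      baseline_arc <- project_lra(cll, landmarks, config$lra_max_dist)
      end_arc <- if (config$neck_end == "landmark" &&
                     !is.null(landmarks$distal_end)) {
        project_to_cll(cll, landmarks$distal_end, max_dist = config$lra_max_dist)
      } else {
        detect_neck_end(mesh, cll, baseline_arc, step = config$diameter_step,
                        ratio = config$diameter_ratio, config = config)
      }
      frames <- place_stations(cll, baseline_arc, end_arc, config)
      pre <- ray_precompute(mesh)
      pts <- array(NA_real_, c(config$n_stations, config$n_rays, 3L))
      for (i in seq_along(frames)) {
        pts[i, , ] <- cast_ring(mesh, frames[[i]], n_rays = config$n_rays,
                                max_radius = config$max_radius, pre = pre)
      }
      rs <- resample_polyline(cll$points, config$resample_spacing)
      contour_grid(pts, arc = attr(frames, "arc") - baseline_arc,
                   baseline_point = drop(interp_polyline(rs$points, rs$arc,
                                                         baseline_arc)))
    },
    neckssm_error = function(e) {
      if (nzchar(ctx)) e$message <- paste0(e$message, ctx)
      stop(e)
    }
  )
  res
}
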