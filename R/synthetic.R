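#' Synthetic neck generator parameters
#'
#' Parameters of the parametric tube model used to emulate an infrarenal
#' aortic neck (lumen mesh, center lumen line, and landmarks). The five
#' deformation dials deliberately mirror the principal shape features seen
#' in aneurysm-neck populations: length, left/right deflection, anterior
#' deflection, diameter, and deflection of the distal neck end.
#'
#' The centerline runs from the LRA baseline at the origin to the distal
#' neck end; `length` is its proximal-to-distal axial (cranio-caudal)
#' extent in mm. Deflections displace the centerline laterally: the bows
#' with a smooth half-sine profile (apex mid-neck, zero at both ends), the
#' distal tilt with a smooth quadratic ramp over the distal third whose end
#' slope equals the tilt angle. Cross-sections are circles of local
#' diameter `baseline_diameter * (1 + taper * t)` (t = normalized axial
#' position) perpendicular to the local tangent. The mesh extends slightly
#' beyond both landmarks, as a real lumen segmentation does, so the end
#' stations are interior to the mesh.
#'
#' @param baseline_diameter lumen diameter at the LRA baseline, mm.
#' @param length axial extent of the neck, mm.
#' @param bow_lr apex lateral offset, mm (positive = patient-left).
#' @param bow_ant apex anterior offset, mm.
#' @param taper fractional diameter change per unit normalized length
#'   (positive = conical widening).
#' @param distal_tilt deflection angle of the distal segment, degrees
#'   (positive = patient-left).
#' @param noise_sd per-vertex radial Gaussian noise SD, mm.
#' @param axial_samples number of mesh cross-section rows (>= 11).
#' @param circumferential_samples vertices per cross-section row (>= 36).
#' @return A list of class `neck_params`.
#' @export
neck_params <- function(baseline_diameter = 24, length = 25, bow_lr = 0,
                        bow_ant = 0, taper = 0, distal_tilt = 0,
                        noise_sd = 0, axial_samples = 40L,
                        circumferential_samples = 36L) {
  p <- list(baseline_diameter = baseline_diameter, length = length,
            bow_lr = bow_lr, bow_ant = bow_ant, taper = taper,
            distal_tilt = distal_tilt, noise_sd = noise_sd,
            axial_samples = as.integer(axial_samples),
            circumferential_samples = as.integer(circumferential_samples))
  if (p$baseline_diameter <= 0) ssm_stop("bad_params", "baseline_diameter must be > 0")
  if (p$length <= 0) ssm_stop("bad_params", "length must be > 0")
  if (p$noise_sd < 0) ssm_stop("bad_params", "noise_sd must be >= 0")
  if (p$axial_samples < 11L) ssm_stop("bad_params", "axial_samples must be >= 11")
  if (p$circumferential_samples < 36L)
    ssm_stop("bad_params", "circumferential_samples must be >= 36")
  structure(p, class = "neck_params")
}

# Axis conventions shared with param_config(): x = left, y = posterior,
# z = cranial; anterior = (0, -1, 0). The neck runs caudally from the LRA
# baseline at z = 0 toward negative... by convention here the distal end is
# at z = +length so that "proximal ring 1, distal ring 10" reads upward in
# t; only relative geometry matters for the model.
.gen_anterior <- c(0, -1, 0)

# Centerline of the analytic tube at normalized axial positions t (vector).
# Returns n x 3 matrix. Linear in every deformation parameter.
neck_centerline_points <- function(params, t) {
  L <- params$length
  tilt <- params$distal_tilt * pi / 180
  t0 <- 0.5
  ramp <- ifelse(t > t0, (t - t0)^2 / (2 * (1 - t0)), 0)  # slope = tilt at t = 1
  x <- params$bow_lr * sin(pi * t) + tilt * L * ramp
  y <- -params$bow_ant * sin(pi * t)
  cbind(x, y, L * t)
}

# Local radius at normalized axial position t.
neck_radius <- function(params, t) {
  params$baseline_diameter / 2 * (1 + params$taper * t)
}

# Unit tangent of the analytic centerline at t (central difference on the
# smooth formula; h small enough to be exact to ~1e-8 for these curves).
neck_tangent <- function(params, t) {
  h <- 1e-4
  p <- neck_centerline_points(params, c(t - h, t + h))
  vunit(p[2L, ] - p[1L, ])
}

#' Closed-form surface point of a noise-free synthetic neck
#'
#' Ground-truth oracle for the ray-cast parametrization: the exact smooth
#' surface point at normalized axial position `t` and circumferential angle
#' `angle` (degrees, measured right-handedly about the local tangent from
#' the projected anterior direction, matching [cast_ring()]).
#'
#' @param params a [neck_params()] with `noise_sd = 0`.
#' @param t normalized axial station in `[0, 1]`.
#' @param angle circumferential angle in degrees.
#' @return A 3D point (mm).
#' @export
analytic_ring <- function(params, t, angle) {
  if (params$noise_sd > 0)
    ssm_stop("bad_params", "analytic_ring is only defined for noise_sd = 0")
  centre <- drop(neck_centerline_points(params, t))
  tangent <- neck_tangent(params, t)
  ref <- .gen_anterior
  if (abs(sum(ref * tangent)) > cos(5 * pi / 180)) ref <- c(1, 0, 0)
  e1 <- vunit(ref - sum(ref * tangent) * tangent)
  e2 <- vcross(tangent, e1)
  th <- angle * pi / 180
  unname(centre + neck_radius(params, t) * (cos(th) * e1 + sin(th) * e2))
}

# Self-intersection heuristic: adjacent cross-section planes must not cross
# within the tube radius, i.e. local curvature * radius < 1 along the tube.
check_tube_feasible <- function(params, t_range) {
  t <- seq(t_range[1L], t_range[2L], length.out = 200L)
  p <- neck_centerline_points(params, t)
  h <- t[2L] - t[1L]
  d1 <- (p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE]) / h
  d2 <- (d1[-1L, , drop = FALSE] - d1[-nrow(d1), , drop = FALSE]) / h
  speed <- sqrt(rowSums(d1^2))
  sp <- (speed[-1L] + speed[-length(speed)]) / 2
  kappa <- sqrt(rowSums(cross_rows(d1[-1L, , drop = FALSE], d2)^2)) / sp^3
  r <- neck_radius(params, t[c(-1L, -length(t))])
  if (max(kappa * r) >= 0.95)
    ssm_stop("self_intersecting_tube",
             "tube self-intersects: curvature x radius reaches %.2f (limit 0.95)",
             max(kappa * r))
  invisible(TRUE)
}

#' Generate one synthetic aortic neck
#'
#' Builds the (mesh, centerline, landmarks) triple for one synthetic
#' patient. The mesh is a closed-tube triangulation of circular
#' cross-sections perpendicular to the centerline tangent, with optional
#' per-vertex radial Gaussian noise; it extends 8 percent beyond both
#' landmarks axially. Circumferential vertices are offset by half an
#' angular step relative to the parametrization's ray angles so ray hits
#' fall mid-edge rather than on vertices. Deterministic given `seed`.
#'
#' @param params a [neck_params()].
#' @param seed integer seed for the vertex noise.
#' @return List with elements `mesh` ([lumen_mesh()]), `cll`
#'   ([centerline()]), `landmarks` ([neck_landmarks()]), and `params`.
#' @export
generate_neck <- function(params, seed = 1L) {
  stopifnot(inherits(params, "neck_params"))
  ext <- 0.08
  check_tube_feasible(params, c(-ext, 1 + ext))
  A <- params$axial_samples
  C <- params$circumferential_samples
  tt <- seq(-ext, 1 + ext, length.out = A)
  ang <- (seq_len(C) - 0.5) * 2 * pi / C  # half-step offset from ray angles
  centres <- neck_centerline_points(params, tt)
  radii <- neck_radius(params, tt)
  verts <- matrix(NA_real_, A * C, 3L)
  for (i in seq_len(A)) {
    tangent <- neck_tangent(params, tt[i])
    ref <- .gen_anterior
    if (abs(sum(ref * tangent)) > cos(5 * pi / 180)) ref <- c(1, 0, 0)
    e1 <- vunit(ref - sum(ref * tangent) * tangent)
    e2 <- vcross(tangent, e1)
    ring <- radii[i] * (outer(cos(ang), e1) + outer(sin(ang), e2))
    verts[(i - 1L) * C + seq_len(C), ] <- sweep(ring, 2L, centres[i, ], `+`)
  }
  if (params$noise_sd > 0) {
    noise <- withr::with_seed(as.integer(seed),
                              stats::rnorm(A * C, sd = params$noise_sd))
    centre_rows <- centres[rep(seq_len(A), each = C), , drop = FALSE]
    radial <- verts - centre_rows
    radial <- radial / sqrt(rowSums(radial^2))
    verts <- verts + noise * radial
  }
  faces <- tube_faces(A, C)
  # centerline and landmarks span exactly the neck, t in [0, 1]
  t_cll <- seq(0, 1, length.out = 101L)
  cll_pts <- neck_centerline_points(params, t_cll)
  list(mesh = lumen_mesh(verts, faces),
       cll = centerline(cll_pts),
       landmarks = neck_landmarks(cll_pts[1L, ], cll_pts[nrow(cll_pts), ]),
       params = params)
}

# Open-ended tube triangulation of an A x C vertex grid (row-major,
# ring index fastest within a row). Each quad is split along its first
# diagonal: (a, b, c) and (a, c, d).
tube_faces <- function(A, C) {
  faces <- matrix(0L, 2L * (A - 1L) * C, 3L)
  k <- 0L
  for (i in seq_len(A - 1L)) {
    for (j in seq_len(C)) {
      jn <- if (j == C) 1L else j + 1L
      a <- (i - 1L) * C + j
      b <- i * C + j
      cc <- i * C + jn
      d <- (i - 1L) * C + jn
      faces[k + 1L, ] <- c(a, b, cc)
      faces[k + 2L, ] <- c(a, cc, d)
      k <- k + 2L
    }
  }
  faces
}

#' Cohort specification
#'
#' Describes a synthetic study population: per-shape offsets for the five
#' deformation modes are drawn independently from
#' `Normal(0, mode_variances)` and added to `mean_params`; vertex noise is
#' scaled so that its share of the total shape-space variance equals
#' `noise_variance_fraction` (calibrated empirically inside
#' [generate_cohort()]).
#'
#' @param n number of synthetic patients (>= 3).
#' @param mode_variances named numeric vector of parameter-space variances
#'   for `length` (mm^2), `bow_lr` (mm^2), `bow_ant` (mm^2), `diameter`
#'   (mm^2), `distal_tilt` (deg^2). Non-negative.
#' @param mean_params a [neck_params()] giving the population mean anatomy.
#' @param noise_variance_fraction fraction of total shape variance carried
#'   by vertex noise, in `[0, 1)`.
#' @param seed integer seed; the whole cohort is deterministic given it.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n, mode_variances = c(length = 0, bow_lr = 0,
                                              bow_ant = 0, diameter = 0,
                                              distal_tilt = 0),
                        mean_params = neck_params(),
                        noise_variance_fraction = 0, seed = 1L) {
  nm <- c("length", "bow_lr", "bow_ant", "diameter", "distal_tilt")
  mv <- mode_variances[nm]
  if (anyNA(mv)) ssm_stop("bad_spec", "mode_variances must be named: %s",
                          paste(nm, collapse = ", "))
  if (any(mv < 0)) ssm_stop("bad_spec", "mode variances must be non-negative")
  if (n < 3L) ssm_stop("bad_spec", "a cohort needs n >= 3")
  if (noise_variance_fraction < 0 || noise_variance_fraction >= 1)
    ssm_stop("bad_spec", "noise_variance_fraction must be in [0, 1)")
  if (all(mv == 0) && noise_variance_fraction > 0)
    ssm_stop("bad_spec",
             "noise_variance_fraction > 0 requires at least one mode variance > 0")
  structure(list(n = as.integer(n), mode_variances = mv,
                 mean_params = mean_params,
                 noise_variance_fraction = noise_variance_fraction,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Apply additive mode offsets (named length, bow_lr, bow_ant, diameter,
# distal_tilt) to a neck_params object.
apply_mode_offsets <- function(params, offsets) {
  p <- unclass(params)
  p$length <- p$length + offsets[["length"]]
  p$bow_lr <- p$bow_lr + offsets[["bow_lr"]]
  p$bow_ant <- p$bow_ant + offsets[["bow_ant"]]
  p$baseline_diameter <- p$baseline_diameter + offsets[["diameter"]]
  p$distal_tilt <- p$distal_tilt + offsets[["distal_tilt"]]
  do.call(neck_params, p)
}

# Aligned shape vector of a noise-free parameter set, measured through the
# actual pipeline (parametrize -> rearrange -> align). Used for mode
# sensitivity calibration.
measured_shape_vector <- function(params, config) {
  g <- generate_neck(params, seed = 1L)
  grid <- parametrize_neck(g$mesh, g$cll, g$landmarks, config)
  flatten_grid(align_to_baseline(rearrange_longitudinal(grid)))
}

# Per-mode shape-space sensitivity directions by secant differences of the
# measured pipeline at mean_params +/- h per mode. Returns a 5-column
# matrix (one unit-parameter direction per mode).
mode_sensitivities <- function(mean_params, config, h = rep(1, 5L)) {
  nm <- c("length", "bow_lr", "bow_ant", "diameter", "distal_tilt")
  h <- rep_len(h, 5L)
  vapply(seq_along(nm), function(m) {
    off <- stats::setNames(numeric(5L), nm)
    off[m] <- h[m]
    gp <- measured_shape_vector(apply_mode_offsets(mean_params, off), config)
    gm <- measured_shape_vector(apply_mode_offsets(mean_params, -off), config)
    (gp - gm) / (2 * h[m])
  }, numeric(3L * config$n_stations * config$n_rays))
}

#' Calibrate a cohort spec to a target shape-variance spectrum
#'
#' Converts target proportions of shape-space variance for the five
#' deformation modes into parameter-space variances, using secant
#' sensitivities of the measured parametrization pipeline at the mean
#' anatomy. The absolute scale is anchored by `length_sd`, the population
#' SD of neck length in mm.
#'
#' @param n cohort size.
#' @param proportions five non-negative numbers, the target shape-variance
#'   shares of (length, bow_lr, bow_ant, diameter, distal_tilt); only their
#'   ratios matter.
#' @param noise_variance_fraction residual-noise share of total shape
#'   variance, in `[0, 1)`.
#' @param mean_params mean anatomy, a [neck_params()].
#' @param length_sd population SD of neck length (mm) anchoring the
#'   absolute variance scale. Default 4.
#' @param seed cohort seed.
#' @param config parametrization settings used for calibration.
#' @return A [cohort_spec()].
#' @export
spectrum_cohort_spec <- function(n, proportions = c(51, 30, 12, 2, 2),
                                 noise_variance_fraction = 0.05,
                                 mean_params = neck_params(),
                                 length_sd = 4, seed = 1L,
                                 config = param_config()) {
  if (length(proportions) != 5L || any(proportions < 0) || proportions[1L] <= 0)
    ssm_stop("bad_spec", "proportions must be 5 non-negative values with proportions[1] > 0")
  nm <- c("length", "bow_lr", "bow_ant", "diameter", "distal_tilt")
  # first pass: unit-step secants; second pass: secants at +/- 1 sd
  V <- mode_sensitivities(mean_params, config, h = 1)
  g2 <- colSums(V^2)  # shape variance per unit parameter variance
  scale_c <- length_sd^2 * g2[1L] / proportions[1L]
  sd0 <- sqrt(ifelse(proportions > 0, scale_c * proportions / g2, 0))
  for (m in seq_along(nm)[sd0 > 0]) {
    off <- stats::setNames(numeric(5L), nm); off[nm[m]] <- sd0[m]
    gp <- measured_shape_vector(apply_mode_offsets(mean_params, off), config)
    gm <- measured_shape_vector(apply_mode_offsets(mean_params, -off), config)
    g2[m] <- sum(((gp - gm) / (2 * sd0[m]))^2)
  }
  scale_c <- length_sd^2 * g2[1L] / proportions[1L]
  variances <- ifelse(proportions > 0, scale_c * proportions / g2, 0)
  cohort_spec(n, mode_variances = stats::setNames(variances, nm),
              mean_params = mean_params,
              noise_variance_fraction = noise_variance_fraction, seed = seed)
}

#' Generate a synthetic cohort
#'
#' Draws per-shape mode offsets from the spec, calibrates the vertex-noise
#' SD so that noise carries the requested fraction of total shape-space
#' variance, and generates one (mesh, centerline, landmarks) triple per
#' synthetic patient. Shapes whose parameters are geometrically infeasible
#' (self-intersecting tube, non-positive length/diameter) are redrawn; if
#' more than half of all draws are rejected the spec is declared infeasible.
#' Deterministic given `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @param config a [param_config()], used only for the internal noise
#'   calibration probes.
#' @return List with `shapes` (list of [generate_neck()] triples), `truth`
#'   (data frame of the per-shape mode draws), and `noise_sd` (calibrated
#'   vertex noise SD, mm).
#' @export
generate_cohort <- function(spec, config = param_config()) {
  stopifnot(inherits(spec, "cohort_spec"))
  nm <- names(spec$mode_variances)
  sds <- sqrt(spec$mode_variances)

  noise_sd <- 0
  if (spec$noise_variance_fraction > 0) {
    V <- mode_sensitivities(spec$mean_params, config,
                            h = pmax(sds, 1e-3))
    v_modes <- sum(colSums(V^2) * spec$mode_variances)
    v_noise <- v_modes * spec$noise_variance_fraction /
      (1 - spec$noise_variance_fraction)
    # probe: unit-SD vertex noise through the measured pipeline
    unit <- mean(vapply(1:2, function(k) {
      p1 <- apply_mode_offsets(spec$mean_params,
                               stats::setNames(numeric(5L), nm))
      clean <- generate_neck(p1, seed = 1000L + k)
      noisy_params <- do.call(neck_params,
                              utils::modifyList(unclass(p1), list(noise_sd = 1)))
      noisy <- generate_neck(noisy_params, seed = 1000L + k)
      gc_ <- parametrize_neck(clean$mesh, clean$cll, clean$landmarks, config)
      gn_ <- parametrize_neck(noisy$mesh, noisy$cll, noisy$landmarks, config)
      vc <- flatten_grid(align_to_baseline(rearrange_longitudinal(gc_)))
      vn <- flatten_grid(align_to_baseline(rearrange_longitudinal(gn_)))
      sum((vn - vc)^2)
    }, numeric(1L)))
    noise_sd <- sqrt(v_noise / unit)
  }

  draws <- withr::with_seed(spec$seed, {
    shapes <- vector("list", spec$n)
    truth <- matrix(NA_real_, spec$n, 5L, dimnames = list(NULL, nm))
    attempts <- 0L
    for (i in seq_len(spec$n)) {
      repeat {
        attempts <- attempts + 1L
        if (attempts > 2L * spec$n)
          ssm_stop("infeasible_spec",
                   "more than half of all cohort draws were rejected as infeasible")
        off <- stats::setNames(stats::rnorm(5L, sd = sds), nm)
        sub_seed <- sample.int(.Machine$integer.max, 1L)
        p <- tryCatch(apply_mode_offsets(spec$mean_params, off),
                      neckssm_error = function(e) NULL)
        if (is.null(p)) next
        p <- do.call(neck_params,
                     utils::modifyList(unclass(p), list(noise_sd = noise_sd)))
        shape <- tryCatch(generate_neck(p, seed = sub_seed),
                          neckssm_error_self_intersecting_tube = function(e) NULL)
        if (!is.null(shape)) {
          shapes[[i]] <- shape
          truth[i, ] <- off
          break
        }
      }
    }
    list(shapes = shapes, truth = truth)
  })
  list(shapes = draws$shapes,
       truth = as.data.frame(draws$truth),
       noise_sd = noise_sd)
}
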