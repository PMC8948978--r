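test_that("landmark projection returns the perpendicular foot arc position", {
  cll <- centerline(cbind(0, 0, seq(0, 30, by = 5)))
  expect_equal(project_to_cll(cll, c(5, 0, 10)), 10)
  # a landmark exactly on a vertex projects to that vertex's arc position
  expect_equal(project_to_cll(cll, c(0, 0, 15)), 15)
  # far landmarks are rejected (suspected unit/frame mismatch)
  expect_error(project_to_cll(cll, c(100, 0, 10)),
               class = "neckssm_error_landmark_off_centerline")
})

test_that("equidistant projections break ties toward the proximal foot", {
  # V-shaped polyline; a point above the apex is equidistant from both legs
  cll <- suppressWarnings(centerline(rbind(c(-10, 0, 10), c(0, 0, 0),
                                           c(10, 0, 10))))
  q <- c(0, 0, 5)
  # brute force: feet on the two segments are (-2.5,0,2.5) and (2.5,0,2.5),
  # both at distance sqrt(12.5); the proximal (first-segment) foot wins
  a <- project_to_cll(cll, q)
  d_feet <- sqrt(sum((q - c(-2.5, 0, 2.5))^2))
  expect_equal(d_feet, sqrt(12.5))
  expect_equal(a, sqrt(200) - sqrt(12.5), tolerance = 1e-9)
  expect_lt(a, max(cll$arc) / 2)
})

test_that("ray-probe diameter recovers cylinder, cone, and ellipse sections", {
  g <- cylinder_neck()
  rs <- neckssm:::resample_polyline(g$cll$points, 0.5)
  cfg <- param_config()
  fr <- neckssm:::station_frame(rs, 15, cfg)
  expect_equal(measure_diameter(g$mesh, fr), 24,
               tolerance = 2 * faceting_tol(12, 36))

  pc <- neck_params(baseline_diameter = 24, length = 30, taper = 0.10)
  gc_ <- generate_neck(pc, seed = 1)
  rsc <- neckssm:::resample_polyline(gc_$cll$points, 0.5)
  frc <- neckssm:::station_frame(rsc, 30, cfg)
  expect_equal(measure_diameter(gc_$mesh, frc), 26.4,
               tolerance = 2 * faceting_tol(13.2, 36))

  # elliptical section, semi-axes 10 and 14: compare the 36-ray mean
  # against the closed-form polar radius averaged at the same angles
  aa <- 14; bb <- 10
  th <- (seq_len(720) - 0.5) * 2 * pi / 720
  ring_r <- aa * bb / sqrt((bb * cos(th))^2 + (aa * sin(th))^2)
  rows <- lapply(c(-5, 0, 5), function(z)
    cbind(-ring_r * sin(th), -ring_r * cos(th), z))
  mesh <- lumen_mesh(do.call(rbind, rows), neckssm:::tube_faces(3L, 720L))
  fr_e <- list(origin = c(0, 0, 0), tangent = c(0, 0, 1), ray0 = c(0, -1, 0))
  ray_ang <- (0:35) * 10 * pi / 180
  oracle <- 2 * mean(aa * bb / sqrt((bb * cos(ray_ang))^2 +
                                    (aa * sin(ray_ang))^2))
  expect_equal(measure_diameter(mesh, fr_e), oracle, tolerance = 0.01)
})

test_that("neck-end detection stops at the 10 percent diameter increase", {
  # taper 0.10 over the neck: threshold reached exactly at the distal end
  p1 <- neck_params(baseline_diameter = 24, length = 30, taper = 0.10)
  g1 <- generate_neck(p1, seed = 1)
  end1 <- detect_neck_end(g1$mesh, g1$cll, 0)
  expect_equal(end1, 30, tolerance = 0.2)

  # taper 0.20: 1 + 0.20 t = 1.10 at t = 0.5
  p2 <- neck_params(baseline_diameter = 24, length = 40, taper = 0.20)
  g2 <- generate_neck(p2, seed = 1)
  end2 <- detect_neck_end(g2$mesh, g2$cll, 0)
  expect_equal(end2, 20, tolerance = 0.2)

  # constant diameter: threshold never reached
  g3 <- cylinder_neck()
  expect_error(detect_neck_end(g3$mesh, g3$cll, 0),
               class = "neckssm_error_neck_end_not_found")
})

test_that("stations divide the truncated centerline equidistantly", {
  cll <- centerline(cbind(0, 0, seq(0, 40, by = 0.5)))
  frames <- place_stations(cll, 0, 27)
  expect_equal(attr(frames, "arc"), seq(0, 27, by = 3))
  for (fr in frames) {
    expect_equal(fr$tangent, c(0, 0, 1), tolerance = 1e-9)
    expect_equal(fr$ray0, c(0, -1, 0), tolerance = 1e-9)
    expect_equal(sum(fr$tangent * fr$ray0), 0, tolerance = 1e-9)
  }
  expect_error(place_stations(cll, 0, 3),
               class = "neckssm_error_neck_too_short")
  expect_error(place_stations(cll, 10, 5),
               class = "neckssm_error_bad_neck_bounds")
})

test_that("station tangents track a quarter-circle centerline to under 1 degree", {
  th <- seq(0, pi / 2, length.out = 100)
  R <- 50
  cll <- centerline(cbind(R * sin(th), 0, R * (1 - cos(th))))
  frames <- place_stations(cll, 5, max(cll$arc) - 5)
  arcs <- attr(frames, "arc")
  for (i in seq_along(frames)) {
    phi <- arcs[i] / R  # analytic tangent of the circle at arc position
    truth <- c(cos(phi), 0, sin(phi))
    ang <- acos(min(1, sum(frames[[i]]$tangent * truth))) * 180 / pi
    expect_lt(ang, 1)
  }
})

test_that("ray casting equals the brute-force all-triangle intersector", {
  p <- neck_params(baseline_diameter = 24, length = 30, bow_lr = 4,
                   bow_ant = 3, taper = 0.05, noise_sd = 0.4)
  g <- generate_neck(p, seed = 13)
  rs <- neckssm:::resample_polyline(g$cll$points, 0.5)
  cfg <- param_config()
  for (arc in c(4, 15, 26)) {
    fr <- neckssm:::station_frame(rs, arc, cfg)
    ring <- cast_ring(g$mesh, fr)
    e2 <- neckssm:::vcross(fr$tangent, fr$ray0)
    for (j in c(1L, 8L, 17L, 30L)) {
      ang <- (j - 1) * 10 * pi / 180
      dir <- cos(ang) * fr$ray0 + sin(ang) * e2
      bf <- brute_force_hit(g$mesh, fr$origin, dir)
      expect_identical(attr(ring, "triangles")[j], bf$triangle)
      expect_equal(attr(ring, "distances")[j], bf$t, tolerance = 1e-12)
      expect_equal(ring[j, ], fr$origin + bf$t * dir, tolerance = 1e-12)
    }
  }
})

test_that("cast rings on a cylinder sit at the commanded angles and radius", {
  g <- cylinder_neck()
  rs <- neckssm:::resample_polyline(g$cll$points, 0.5)
  fr <- neckssm:::station_frame(rs, 15, param_config())
  ring <- cast_ring(g$mesh, fr)
  r <- sqrt(ring[, 1]^2 + ring[, 2]^2)
  expect_equal(r, rep(12, 36), tolerance = faceting_tol(12, 36))
  # commanded angle: atan2 in the (ray0, tangent x ray0) frame
  e2 <- neckssm:::vcross(fr$tangent, fr$ray0)
  ang <- atan2(ring %*% e2, ring %*% fr$ray0) * 180 / pi
  expect_equal((ang[, 1] + 360) %% 360, (0:35) * 10, tolerance = 1e-6)
})

test_that("contour rings on a bowed tube match the analytic surface", {
  p <- neck_params(baseline_diameter = 24, length = 30, bow_lr = 5)
  g <- generate_neck(p, seed = 1)
  grid <- parametrize_neck(g$mesh, g$cll, g$landmarks)
  for (ri in c(2, 5, 8)) {
    # map the station's arc position to the generator's axial parameter
    tfun <- function(t) {
      tt <- seq(0, t, length.out = 400)
      sum(sqrt(rowSums(diff(neckssm:::neck_centerline_points(p, tt))^2)))
    }
    tt <- stats::uniroot(function(t) tfun(t) - grid$arc[ri], c(0, 1))$root
    for (ai in c(1, 13, 25)) {
      truth <- analytic_ring(p, tt, (ai - 1) * 10)
      expect_lt(sqrt(sum((grid$points[ri, ai, ] - truth)^2)), 0.2)
    }
  }
})

test_that("a mesh hole is reported as a ray miss naming the station", {
  g <- cylinder_neck()
  # remove the triangles nearest anterior at mid-height
  keep <- rep(TRUE, nrow(g$mesh$faces))
  ctr <- (g$mesh$vertices[g$mesh$faces[, 1], ] +
          g$mesh$vertices[g$mesh$faces[, 2], ] +
          g$mesh$vertices[g$mesh$faces[, 3], ]) / 3
  keep[ctr[, 2] < -11 & abs(ctr[, 3] - 15) < 2] <- FALSE
  holed <- lumen_mesh(g$mesh$vertices, g$mesh$faces[keep, ])
  rs <- neckssm:::resample_polyline(g$cll$points, 0.5)
  fr <- neckssm:::station_frame(rs, 15, param_config())
  expect_error(cast_ring(holed, fr), class = "neckssm_error_ray_miss")
})

test_that("parametrization returns a full finite grid of 360 contour points", {
  g <- cylinder_neck()
  grid <- parametrize_neck(g$mesh, g$cll, g$landmarks)
  expect_identical(dim(grid$points), c(10L, 36L, 3L))
  expect_true(all(is.finite(grid$points)))
  r <- sqrt(grid$points[, , 1]^2 + grid$points[, , 2]^2)
  expect_equal(as.vector(r), rep(12, 360), tolerance = faceting_tol(12, 36))
})

test_that("the grid is invariant under mesh vertex permutation", {
  g <- cylinder_neck()
  grid1 <- parametrize_neck(g$mesh, g$cll, g$landmarks)
  perm <- withr::with_seed(4, sample.int(nrow(g$mesh$vertices)))
  inv <- order(perm)
  shuffled <- lumen_mesh(g$mesh$vertices[perm, , drop = FALSE],
                         matrix(inv[g$mesh$faces], ncol = 3L))
  grid2 <- parametrize_neck(shuffled, g$cll, g$landmarks)
  expect_equal(grid2$points, grid1$points, tolerance = 1e-9)
})

test_that("parametrization errors carry the patient id", {
  g <- cylinder_neck()
  err <- tryCatch(parametrize_neck(g$mesh, g$cll,
                                   neck_landmarks(c(0, 0, 0)),
                                   param_config(neck_end = "diameter"),
                                   id = "pt42"),
                  neckssm_error = function(e) e)
  expect_match(conditionMessage(err), "pt42")
})
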