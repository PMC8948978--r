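test_that("a degenerate parameter set yields a straight circular cylinder", {
  g <- cylinder_neck()
  r <- sqrt(g$mesh$vertices[, 1]^2 + g$mesh$vertices[, 2]^2)
  expect_equal(r, rep(12, length(r)), tolerance = 1e-9)
  expect_equal(g$landmarks$lra, c(0, 0, 0))
  expect_equal(g$landmarks$distal_end, c(0, 0, 30))
  expect_equal(max(g$cll$arc), 30)
})

test_that("linear taper scales the distal cross-section diameter in closed form", {
  p <- neck_params(baseline_diameter = 24, length = 30, taper = 0.10)
  # analytic surface: radius 12 * (1 + 0.10 * t), so 13.2 mm distally
  d_end <- sqrt(sum((analytic_ring(p, 1, 90) - c(0, 0, 30))^2))
  expect_equal(d_end, 13.2, tolerance = 1e-9)
  g <- generate_neck(p, seed = 1)
  # every mesh vertex sits exactly on the linear cone surface
  z <- g$mesh$vertices[, 3]
  rr <- sqrt(rowSums(g$mesh$vertices[, 1:2]^2))
  expect_equal(rr, 12 * (1 + 0.10 * z / 30), tolerance = 1e-9)
})

test_that("generation is deterministic in the seed and varies across seeds", {
  p <- neck_params(noise_sd = 0.5)
  a <- generate_neck(p, seed = 7)
  b <- generate_neck(p, seed = 7)
  c_ <- generate_neck(p, seed = 8)
  expect_identical(a$mesh$vertices, b$mesh$vertices)
  expect_false(isTRUE(all.equal(a$mesh$vertices, c_$mesh$vertices)))
})

test_that("analytic_ring matches cylinder and cone closed forms", {
  p <- neck_params(baseline_diameter = 24, length = 30)
  # anterior (0 deg) at mid-height: anterior axis is -y
  expect_equal(analytic_ring(p, 0.5, 0), c(0, -12, 15), tolerance = 1e-9)
  pc <- neck_params(baseline_diameter = 24, length = 30, taper = 0.10)
  for (a in c(0, 45, 210)) {
    pt <- analytic_ring(pc, 1, a)
    expect_equal(sqrt(sum((pt - c(0, 0, 30))^2)), 13.2, tolerance = 1e-9)
  }
  # bow vanishes at t = 0: the proximal ring stays centred on the origin
  # at the baseline radius regardless of bow amplitude
  pb <- neck_params(baseline_diameter = 24, length = 30, bow_lr = 5)
  for (a in c(0, 120, 250))
    expect_equal(sqrt(sum(analytic_ring(pb, 0, a)^2)), 12, tolerance = 1e-7)
  expect_error(analytic_ring(neck_params(noise_sd = 1), 0.5, 0),
               class = "neckssm_error_bad_params")
})

test_that("contour points converge to the analytic surface as faceting refines", {
  errs <- vapply(c(36L, 72L, 144L), function(C) {
    p <- neck_params(baseline_diameter = 24, length = 30, bow_lr = 4,
                     circumferential_samples = C)
    g <- generate_neck(p, seed = 1)
    grid <- parametrize_neck(g$mesh, g$cll, g$landmarks)
    # compare mid rings against analytic_ring at the matching axial position
    err <- 0
    for (ri in c(3, 6, 9)) {
      tt <- grid$arc[ri] / max(g$cll$arc)
      for (ai in c(1, 10, 19, 28)) {
        truth <- analytic_ring(p, tt, (ai - 1) * 10)
        err <- max(err, sqrt(sum((grid$points[ri, ai, ] - truth)^2)))
      }
    }
    err
  }, numeric(1))
  expect_true(all(diff(errs) < 0))      # strictly decreasing
  expect_lt(errs[1], 0.5)               # within coarse faceting + arc mapping
})

test_that("an over-bowed tube is rejected as self-intersecting", {
  expect_error(generate_neck(neck_params(baseline_diameter = 40, length = 20,
                                         bow_lr = 30), seed = 1),
               class = "neckssm_error_self_intersecting_tube")
})

test_that("a zero-variance noise-free cohort repeats one anatomy", {
  spec <- cohort_spec(4, c(length = 0, bow_lr = 0, bow_ant = 0,
                           diameter = 0, distal_tilt = 0), seed = 5)
  co <- generate_cohort(spec)
  expect_length(co$shapes, 4L)
  expect_equal(co$noise_sd, 0)
  for (i in 2:4)
    expect_identical(co$shapes[[i]]$mesh$vertices,
                     co$shapes[[1]]$mesh$vertices)
})

test_that("cohort generation is deterministic and returns the true draws", {
  spec <- cohort_spec(4, c(length = 4, bow_lr = 1, bow_ant = 1,
                           diameter = 1, distal_tilt = 4), seed = 9)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$truth, b$truth)
  expect_identical(a$shapes[[3]]$mesh$vertices, b$shapes[[3]]$mesh$vertices)
  expect_named(a$truth, c("length", "bow_lr", "bow_ant", "diameter",
                          "distal_tilt"))
  expect_equal(nrow(a$truth), 4L)
})

test_that("cohort spec validation rejects malformed inputs", {
  expect_error(cohort_spec(2, c(length = 1, bow_lr = 0, bow_ant = 0,
                                diameter = 0, distal_tilt = 0)),
               class = "neckssm_error_bad_spec")
  expect_error(cohort_spec(5, c(length = -1, bow_lr = 0, bow_ant = 0,
                                diameter = 0, distal_tilt = 0)),
               class = "neckssm_error_bad_spec")
  expect_error(cohort_spec(5, c(length = 0, bow_lr = 0, bow_ant = 0,
                                diameter = 0, distal_tilt = 0),
                           noise_variance_fraction = 0.1),
               class = "neckssm_error_bad_spec")
})

test_that("single-mode cohorts put the generative draw in the first component", {
  spec <- cohort_spec(30, c(length = 16, bow_lr = 0, bow_ant = 0,
                            diameter = 0, distal_tilt = 0), seed = 21)
  co <- generate_cohort(spec)
  vectors <- lapply(co$shapes, function(s)
    process_neck(s$mesh, s$cll, s$landmarks))
  model <- fit_ssm(shape_cohort(vectors))
  expect_gt(abs(stats::cor(model$scores[, 1], co$truth$length)), 0.99)
})
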