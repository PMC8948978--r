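test_that("an identical-shape cohort has zero components and mean = the shape", {
  v <- as.numeric(flatten_grid(unflatten_grid(stats::rnorm(1080))))
  X <- rbind(v, v, v, v)
  model <- fit_ssm(shape_cohort(X))
  expect_length(model$eigenvalues, 0L)
  expect_equal(model$mean, v)
})

test_that("SVD eigenvalues match the explicit covariance eigendecomposition", {
  X <- small_cohort()$cohort$matrix
  model <- fit_ssm(shape_cohort(X))
  oracle <- covariance_pca(X)
  m <- length(model$eigenvalues)
  expect_equal(model$eigenvalues, oracle$values[seq_len(m)],
               tolerance = 1e-8)
  # eigenvectors agree up to sign; the sign convention fixes them
  for (j in seq_len(m)) {
    dot <- abs(sum(model$eigenvectors[, j] * oracle$vectors[, j]))
    expect_equal(dot, 1, tolerance = 1e-6)
    i <- which.max(abs(model$eigenvectors[, j]))
    expect_gt(model$eigenvectors[i, j], 0)
  }
})

test_that("total variance is conserved by the decomposition", {
  X <- small_cohort()$cohort$matrix
  model <- fit_ssm(shape_cohort(X))
  expect_equal(sum(model$eigenvalues), sum(apply(X, 2, stats::var)),
               tolerance = 1e-8)
})

test_that("the model is invariant to the ordering of training shapes", {
  X <- small_cohort()$cohort$matrix
  m1 <- fit_ssm(shape_cohort(X))
  perm <- withr::with_seed(2, sample.int(nrow(X)))
  m2 <- fit_ssm(shape_cohort(X[perm, ]))
  expect_equal(m2$mean, m1$mean, tolerance = 1e-10)
  expect_equal(m2$eigenvalues, m1$eigenvalues, tolerance = 1e-8)
  expect_equal(m2$eigenvectors[, 1:5], m1$eigenvectors[, 1:5],
               tolerance = 1e-6)
})

test_that("explained variance fractions normalize and accumulate to one", {
  model <- structure(list(eigenvalues = c(3, 1)), class = "neck_ssm")
  ev <- explained_variance(model)
  expect_equal(ev$fraction, c(0.75, 0.25))
  full <- fit_ssm(small_cohort()$cohort)
  ev2 <- explained_variance(full)
  expect_true(all(diff(ev2$cumulative) >= -1e-12))
  expect_equal(ev2$cumulative[length(ev2$cumulative)], 1)
})

test_that("projection and reconstruction satisfy the PCA identities", {
  X <- small_cohort()$cohort$matrix
  model <- fit_ssm(shape_cohort(X))
  m <- length(model$eigenvalues)
  # mean projects to zero
  expect_equal(project_shape(model, model$mean), rep(0, m), tolerance = 1e-9)
  # an eigen-direction shape projects onto its own axis
  s1 <- model$mean + 2 * sqrt(model$eigenvalues[1]) * model$eigenvectors[, 1]
  sc <- project_shape(model, s1)
  expect_equal(sc[1], 2 * sqrt(model$eigenvalues[1]), tolerance = 1e-9)
  expect_equal(sc[-1], rep(0, m - 1), tolerance = 1e-9)
  # full-rank reconstruction of training shapes is exact
  for (i in c(1, 5, 10)) {
    rec <- reconstruct_shape(model, project_shape(model, X[i, ]))
    expect_lt(shape_rmse(X[i, ], rec), 1e-6)
  }
  # reconstruction is affine in the scores
  a <- stats::rnorm(m); b <- stats::rnorm(m)
  expect_equal(reconstruct_shape(model, (a + b) / 2),
               (reconstruct_shape(model, a) + reconstruct_shape(model, b)) / 2,
               tolerance = 1e-10)
  expect_equal(reconstruct_shape(model, numeric(0)), model$mean)
  expect_error(project_shape(model, X[1, ], k = m + 1),
               class = "neckssm_error_bad_k")
})

test_that("training scores reproduce the centered data", {
  X <- small_cohort()$cohort$matrix
  model <- fit_ssm(shape_cohort(X))
  recon <- model$scores %*% t(model$eigenvectors) +
    matrix(model$mean, nrow(X), ncol(X), byrow = TRUE)
  expect_equal(recon, unname(X), tolerance = 1e-6)
})

test_that("mode meshes are open tubes anchored at the mean shape", {
  model <- fit_ssm(small_cohort()$cohort)
  m0 <- mode_mesh(model, 1, 0)
  expect_equal(nrow(m0$faces), 2L * 9L * 36L)  # open-ended tube
  expect_equal(flatten_grid(attr(m0, "grid")), model$mean,
               ignore_attr = TRUE)
  mp <- mode_mesh(model, 1, 3)
  mm <- mode_mesh(model, 1, -3)
  expect_equal(flatten_grid(attr(mp, "grid")) - flatten_grid(attr(mm, "grid")),
               6 * sqrt(model$eigenvalues[1]) * model$eigenvectors[, 1],
               ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("single-mode cohorts vary only along their one real component", {
  spec <- cohort_spec(20, c(length = 16, bow_lr = 0, bow_ant = 0,
                            diameter = 0, distal_tilt = 0), seed = 77)
  co <- generate_cohort(spec)
  vectors <- lapply(co$shapes, function(s)
    process_neck(s$mesh, s$cll, s$landmarks))
  model <- fit_ssm(shape_cohort(vectors))
  ev <- explained_variance(model)
  expect_gt(ev$fraction[1], 0.99)
  gp <- flatten_grid(attr(mode_mesh(model, 1, 3), "grid"))
  gm <- flatten_grid(attr(mode_mesh(model, 1, -3), "grid"))
  # the +/-3 SD meshes differ along the length mode: predominantly z
  d <- matrix(gp - gm, ncol = 3, byrow = TRUE)
  expect_gt(sum(d[, 3]^2) / sum(d^2), 0.95)
})

test_that("score range check flags bounds from the empirical distribution", {
  model <- fit_ssm(small_cohort()$cohort)
  sr <- score_range(model)
  expect_equal(nrow(sr), length(model$eigenvalues))
  expect_equal(sr$s_min, apply(model$scores, 2, min) / sqrt(model$eigenvalues),
               tolerance = 1e-12)
  expect_true(all(sr$s_min <= 0 & sr$s_max >= 0))
})
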