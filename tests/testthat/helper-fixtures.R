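# Shared fixtures, built in code at test time.

# ASCII STL of the unit cube (12 triangles, 8 distinct vertices).
write_unit_cube_stl <- function(path) {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  quads <- list(c(1, 2, 4, 3), c(5, 7, 8, 6), c(1, 5, 6, 2),
                c(3, 4, 8, 7), c(1, 3, 7, 5), c(2, 6, 8, 4))
  tris <- do.call(rbind, lapply(quads, function(q)
    rbind(q[c(1, 2, 3)], q[c(1, 3, 4)])))
  con <- file(path, "w"); on.exit(close(con))
  writeLines("solid cube", con)
  for (i in seq_len(nrow(tris))) {
    writeLines("  facet normal 0 0 0", con)
    writeLines("    outer loop", con)
    for (j in 1:3)
      writeLines(sprintf("      vertex %g %g %g",
                         v[tris[i, j], 1], v[tris[i, j], 2], v[tris[i, j], 3]), con)
    writeLines(c("    endloop", "  endfacet"), con)
  }
  writeLines("endsolid cube", con)
  path
}

# Independent brute-force ray-triangle intersector: scalar Moller-Trumbore
# over every triangle, no plane prefilter, no vectorization.
brute_force_hit <- function(mesh, origin, dir) {
  v <- mesh$vertices; f <- mesh$faces
  best_t <- Inf; best_tri <- NA_integer_
  for (i in seq_len(nrow(f))) {
    v0 <- v[f[i, 1], ]; e1 <- v[f[i, 2], ] - v0; e2 <- v[f[i, 3], ] - v0
    h <- c(dir[2] * e2[3] - dir[3] * e2[2],
           dir[3] * e2[1] - dir[1] * e2[3],
           dir[1] * e2[2] - dir[2] * e2[1])
    a <- sum(e1 * h)
    if (abs(a) < 1e-12) next
    inv <- 1 / a
    s <- origin - v0
    u <- inv * sum(s * h)
    q <- c(s[2] * e1[3] - s[3] * e1[2],
           s[3] * e1[1] - s[1] * e1[3],
           s[1] * e1[2] - s[2] * e1[1])
    vv <- inv * sum(dir * q)
    tt <- inv * sum(e2 * q)
    if (u >= -1e-12 && vv >= -1e-12 && u + vv <= 1 + 1e-12 && tt > 1e-9 &&
        tt < best_t) {
      best_t <- tt; best_tri <- i
    }
  }
  list(t = best_t, triangle = best_tri)
}

# Independent PCA oracle: eigendecomposition of the explicit sample
# covariance matrix.
covariance_pca <- function(X) {
  n <- nrow(X)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  C <- crossprod(Xc) / (n - 1)
  e <- eigen(C, symmetric = TRUE)
  list(mean = mu, values = pmax(e$values, 0), vectors = e$vectors)
}

# Memoized expensive fixtures shared across test files.
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env))
    assign(name, force(expr), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# A modest multi-mode synthetic cohort with noise, plus its aligned vectors.
small_cohort <- function() {
  fixture("small_cohort", {
    spec <- cohort_spec(10, c(length = 9, bow_lr = 4, bow_ant = 1,
                              diameter = 1, distal_tilt = 9),
                        noise_variance_fraction = 0.05, seed = 31L)
    co <- generate_cohort(spec)
    vectors <- lapply(co$shapes, function(s)
      process_neck(s$mesh, s$cll, s$landmarks))
    list(raw = co, cohort = shape_cohort(vectors))
  })
}

# A straight cylinder neck (no modes, no noise).
cylinder_neck <- function() {
  fixture("cylinder_neck",
          generate_neck(neck_params(baseline_diameter = 24, length = 30),
                        seed = 1L))
}

# Faceting tolerance of a ray-cast contour on a C-gon cross-section whose
# vertices are offset half a step from the ray angles.
faceting_tol <- function(radius, C) radius * (1 - cos(pi / C))
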