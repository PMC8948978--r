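#' Fit a statistical shape model
#'
#' Point-distribution model by PCA: the mean shape is the arithmetic mean
#' of the corresponded contour points over patients; the centered shape
#' matrix is decomposed by singular value decomposition. Component
#' variances (eigenvalues) are the squared singular values divided by
#' `n - 1`; components with variance below `1e-10` times the largest are
#' discarded, so a general-position cohort of n shapes yields exactly
#' `n - 1` components. Eigenvector signs are fixed so the largest-magnitude
#' entry of each column is positive, which makes the decomposition
#' reproducible across linear-algebra backends.
#'
#' @param cohort a [shape_cohort()] (or an `n x p` matrix).
#' @return Object of class `neck_ssm` with elements `mean` (length p),
#'   `eigenvectors` (p x m, orthonormal columns), `eigenvalues`
#'   (m variances, mm^2, descending), `scores` (n x m), `n_train`,
#'   `rings`, `rays`, `ids`.
#' @export
fit_ssm <- function(cohort) {
  if (is.matrix(cohort)) cohort <- shape_cohort(cohort,
                                                rings = 1L,
                                                rays = ncol(cohort) / 3L)
  X <- cohort$matrix
  n <- nrow(X)
  if (n < 3L) ssm_stop("bad_cohort", "need at least 3 shapes to fit an SSM")
  stopifnot_finite(X, "cohort matrix")
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  sv <- svd(Xc)
  ev <- sv$d^2 / (n - 1)
  keep <- if (ev[1L] > 0) which(ev > 1e-10 * ev[1L]) else integer(0)
  keep <- keep[keep <= n - 1L]
  V <- sv$v[, keep, drop = FALSE]
  U <- sv$u[, keep, drop = FALSE]
  # sign convention: largest-magnitude entry of each eigenvector positive
  if (length(keep)) {
    flip <- vapply(seq_len(ncol(V)), function(j) {
      i <- which.max(abs(V[, j]))
      sign(V[i, j])
    }, numeric(1L))
    V <- sweep(V, 2L, flip, `*`)
    U <- sweep(U, 2L, flip, `*`)
  }
  scores <- U %*% diag(sv$d[keep], nrow = length(keep))
  structure(list(mean = mu, eigenvectors = V, eigenvalues = ev[keep],
                 scores = scores, n_train = n,
                 rings = cohort$rings, rays = cohort$rays, ids = cohort$ids),
            class = "neck_ssm")
}

#' @export
print.neck_ssm <- function(x, ...) {
  cat(sprintf("neck_ssm: %d components from %d training shapes (%d x %d grid)\n",
              length(x$eigenvalues), x$n_train, x$rings, x$rays))
  if (length(x$eigenvalues)) {
    fr <- x$eigenvalues / sum(x$eigenvalues)
    k <- min(5L, length(fr))
    cat(sprintf("  first %d variance fractions: %s\n", k,
                paste(sprintf("%.1f%%", 100 * fr[1:k]), collapse = ", ")))
  }
  invisible(x)
}

#' Explained variance of an SSM
#'
#' @param model a [fit_ssm()] model.
#' @return List with `fraction` (per-component share of total variance) and
#'   `cumulative` (non-decreasing, ending at 1).
#' @export
explained_variance <- function(model) {
  stopifnot(inherits(model, "neck_ssm"))
  tot <- sum(model$eigenvalues)
  if (tot <= 0) ssm_stop("zero_variance", "model has zero total variance")
  fr <- model$eigenvalues / tot
  list(fraction = fr, cumulative = cumsum(fr))
}

#' Project a shape onto the model's principal components
#'
#' @param model a `neck_ssm`.
#' @param shape a shape vector of the model's dimension.
#' @param k number of leading components (default: all).
#' @return Numeric vector of `k` scores.
#' @export
project_shape <- function(model, shape, k = length(model$eigenvalues)) {
  stopifnot(inherits(model, "neck_ssm"))
  if (k < 0L || k > length(model$eigenvalues))
    ssm_stop("bad_k", "k = %d out of range [0, %d]", k, length(model$eigenvalues))
  shape <- as.numeric(shape)
  if (length(shape) != length(model$mean))
    ssm_stop("bad_dimensions", "shape has length %d, model expects %d",
             length(shape), length(model$mean))
  drop(crossprod(model$eigenvectors[, seq_len(k), drop = FALSE],
                 shape - model$mean))
}

#' Reconstruct a shape from component scores
#'
#' @param model a `neck_ssm`.
#' @param scores numeric vector of leading-component scores (length <= m).
#' @return A shape vector: `mean + sum(score_i * eigenvector_i)`.
#' @export
reconstruct_shape <- function(model, scores) {
  stopifnot(inherits(model, "neck_ssm"))
  k <- length(scores)
  if (k > length(model$eigenvalues))
    ssm_stop("bad_k", "%d scores given but model has %d components",
             k, length(model$eigenvalues))
  if (k == 0L) return(model$mean)
  model$mean + drop(model$eigenvectors[, seq_len(k), drop = FALSE] %*% scores)
}

#' Mode-shape mesh at a given SD multiplier
#'
#' Unflattens `mean + s * sqrt(eigenvalue) * eigenvector` into a contour
#' grid and triangulates it as an open-ended tube (with the default grid,
#' 9 x 36 quads = 648 triangles). `s = +/-3` spans 99.7 percent of a
#' normally distributed component; use [score_range()] to identify
#' components whose empirical score distribution is not normal and whose
#' visualization bound should follow the observed score range instead.
#'
#' @param model a `neck_ssm`.
#' @param pc_index component index (1-based).
#' @param s SD multiplier.
#' @return A [lumen_mesh()] with attributes `pc`, `s`, and `grid`.
#' @export
mode_mesh <- function(model, pc_index, s) {
  stopifnot(inherits(model, "neck_ssm"))
  if (pc_index < 1L || pc_index > length(model$eigenvalues))
    ssm_stop("bad_k", "pc_index %d out of range", pc_index)
  v <- model$mean + s * sqrt(model$eigenvalues[pc_index]) *
    model$eigenvectors[, pc_index]
  grid <- unflatten_grid(v, rings = model$rings, rays = model$rays)
  mesh <- tryCatch(
    lumen_mesh(matrix(aperm(grid$points, c(2L, 1L, 3L)),
                      model$rings * model$rays, 3L),
               tube_faces(model$rings, model$rays)),
    neckssm_error_degenerate_triangle = function(e) {
      ssm_warn("self_intersecting_mode",
               "mode mesh at s = %.1f contains degenerate geometry", s)
      structure(list(vertices = matrix(aperm(grid$points, c(2L, 1L, 3L)),
                                       model$rings * model$rays, 3L),
                     faces = tube_faces(model$rings, model$rays)),
                class = "lumen_mesh")
    })
  attr(mesh, "pc") <- pc_index
  attr(mesh, "s") <- s
  attr(mesh, "grid") <- grid
  mesh
}

#' Per-component score normality and visualization bounds
#'
#' Tests each component's training-score distribution for normality
#' (Shapiro-Wilk, alpha = 0.05) and reports the empirical score range in SD
#' units. For non-normal components the mode visualization should be
#' bounded by the observed range rather than +/-3 SD (e.g. a shortest-neck
#' bound of -1 SD when lengths are right-skewed).
#'
#' @param model a `neck_ssm`.
#' @param alpha significance level for the Shapiro-Wilk test.
#' @return Data frame with `pc`, `shapiro_p`, `normal`, `s_min`, `s_max`.
#' @export
score_range <- function(model, alpha = 0.05) {
  stopifnot(inherits(model, "neck_ssm"))
  m <- length(model$eigenvalues)
  out <- data.frame(pc = seq_len(m), shapiro_p = NA_real_, normal = NA,
                    s_min = NA_real_, s_max = NA_real_)
  for (j in seq_len(m)) {
    sdj <- sqrt(model$eigenvalues[j])
    sc <- model$scores[, j]
    out$shapiro_p[j] <- if (stats::sd(sc) > 0)
      stats::shapiro.test(sc)$p.value else NA_real_
    out$s_min[j] <- min(sc) / sdj
    out$s_max[j] <- max(sc) / sdj
  }
  out$normal <- !is.na(out$shapiro_p) & out$shapiro_p >= alpha
  out
}

# --- model serialization ----------------------------------------------

#' Write / read a fitted SSM
#'
#' Serializes a model to a single self-describing JSON container with an
#' explicit schema version and the grid dimensions; the round trip is
#' lossless to full double precision.
#'
#' @param model a `neck_ssm`.
#' @param path output `.json` path.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "neck_ssm"))
  p <- length(model$mean); m <- length(model$eigenvalues)
  if (!identical(dim(model$eigenvectors), c(p, m)) ||
      !identical(nrow(model$scores), model$n_train))
    ssm_stop("bad_dimensions", "model fields have inconsistent dimensions")
  obj <- list(schema = "neckssm-model", schema_version = 1L,
              rings = model$rings, rays = model$rays,
              n_train = model$n_train, ids = model$ids,
              mean = model$mean, eigenvalues = model$eigenvalues,
              eigenvectors = model$eigenvectors, scores = model$scores)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (!file.exists(path)) ssm_stop("missing_file", "model file not found: %s", path)
  obj <- jsonlite::fromJSON(path)
  if (is.null(obj$schema) || obj$schema != "neckssm-model")
    ssm_stop("unknown_schema", "not a neckssm model file: %s", path)
  if (obj$schema_version != 1L)
    ssm_stop("unknown_schema", "unsupported model schema version %s",
             obj$schema_version)
  p <- length(obj$mean); m <- length(obj$eigenvalues)
  V <- matrix(obj$eigenvectors, ncol = max(m, 1L))
  S <- matrix(obj$scores, ncol = max(m, 1L))
  if (m == 0L) { V <- matrix(0, p, 0L); S <- matrix(0, obj$n_train, 0L) }
  if (nrow(V) != p || ncol(V) != m || nrow(S) != obj$n_train ||
      p != obj$rings * obj$rays * 3L)
    ssm_stop("dimension_mismatch",
             "model file dimensions are inconsistent: %s", path)
  structure(list(mean = as.numeric(obj$mean), eigenvectors = V,
                 eigenvalues = as.numeric(obj$eigenvalues), scores = S,
                 n_train = as.integer(obj$n_train),
                 rings = as.integer(obj$rings), rays = as.integer(obj$rays),
                 ids = as.character(obj$ids)),
            class = "neck_ssm")
}
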