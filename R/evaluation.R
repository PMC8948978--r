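#' Root-mean-square point-to-point error between two shapes
#'
#' RMSE over the corresponded 3D contour points: the square root of the
#' mean (over points) of squared Euclidean point-to-point distance, in mm.
#'
#' @param a,b shape vectors of equal length (coordinates interleaved
#'   x, y, z per point as produced by [flatten_grid()]).
#' @return RMSE in mm (zero iff the shapes are identical).
#' @export
shape_rmse <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b))
    ssm_stop("bad_dimensions", "shape vectors differ in length (%d vs %d)",
             length(a), length(b))
  D <- matrix(a - b, ncol = 3L, byrow = TRUE)
  sqrt(mean(rowSums(D^2)))
}

#' Compactness curve
#'
#' Cumulative explained-variance fraction at each component count 1..m:
#' how many components are needed to describe a given share of the total
#' shape variation.
#'
#' @param model a [fit_ssm()] model.
#' @return Numeric vector, monotone non-decreasing, ending at 1.
#' @export
compactness <- function(model) {
  explained_variance(model)$cumulative
}

# normal-approximation 95% CI on a mean
mean_ci <- function(x) {
  m <- mean(x)
  se <- stats::sd(x) / sqrt(length(x))
  c(mean = m, lower = m - 1.96 * se, upper = m + 1.96 * se)
}

#' Leave-one-out generalization
#'
#' For each shape in turn, fits an SSM on the remaining `n - 1` shapes,
#' projects the left-out shape onto the first `k` components, reconstructs
#' it, and records the RMSE. Reports the per-`k` mean with a 95 percent
#' confidence interval (normal approximation on the mean). Deterministic.
#'
#' @param cohort a [shape_cohort()].
#' @param k_values component counts to evaluate.
#' @return List with `per_shape` (n x length(k) RMSE matrix, mm) and
#'   `summary` (data frame: k, mean, lower, upper).
#' @export
generalization_loo <- function(cohort, k_values = c(5L, 9L)) {
  stopifnot(inherits(cohort, "shape_cohort"))
  X <- cohort$matrix
  n <- nrow(X)
  if (n < 4L) ssm_stop("bad_cohort", "leave-one-out needs n >= 4")
  if (max(k_values) > n - 2L)
    ssm_stop("bad_k", "k = %d exceeds the n - 2 = %d components available per fold",
             max(k_values), n - 2L)
  rmse <- matrix(NA_real_, n, length(k_values),
                 dimnames = list(cohort$ids, paste0("k", k_values)))
  for (i in seq_len(n)) {
    fold <- fit_ssm(shape_cohort(X[-i, , drop = FALSE],
                                 ids = cohort$ids[-i],
                                 rings = cohort$rings, rays = cohort$rays))
    for (jk in seq_along(k_values)) {
      k <- min(k_values[jk], length(fold$eigenvalues))
      rec <- reconstruct_shape(fold, project_shape(fold, X[i, ], k))
      rmse[i, jk] <- shape_rmse(X[i, ], rec)
    }
  }
  summary <- do.call(rbind, lapply(seq_along(k_values), function(jk) {
    ci <- mean_ci(rmse[, jk])
    data.frame(k = k_values[jk], mean = ci[["mean"]],
               lower = ci[["lower"]], upper = ci[["upper"]])
  }))
  list(per_shape = rmse, summary = summary)
}

#' Specificity
#'
#' Draws random score vectors (component i ~ Normal(0, eigenvalue_i),
#' i <= k), reconstructs each as a shape, and measures the RMSE to its
#' most similar training shape. Low values mean the model only generates
#' shapes resembling real anatomy. Deterministic given `seed`.
#'
#' @param model a `neck_ssm` fitted on `cohort`.
#' @param cohort the training [shape_cohort()].
#' @param k number of components to sample.
#' @param n_samples number of random shapes (default 1000).
#' @param seed integer seed (required, recorded in the report).
#' @return List with `per_sample` (RMSE per random shape, mm) and
#'   `summary` (data frame: k, mean, lower, upper, n_samples, seed).
#' @export
specificity <- function(model, cohort, k, n_samples = 1000L, seed) {
  stopifnot(inherits(model, "neck_ssm"), inherits(cohort, "shape_cohort"))
  m <- length(model$eigenvalues)
  if (k > m) ssm_stop("bad_k", "k = %d exceeds the %d model components", k, m)
  if (n_samples < 1L) ssm_stop("bad_spec", "n_samples must be >= 1")
  scores <- withr::with_seed(as.integer(seed),
    matrix(stats::rnorm(n_samples * k), nrow = n_samples))
  if (k > 0L)
    scores <- sweep(scores, 2L, sqrt(model$eigenvalues[seq_len(k)]), `*`)
  # reconstructions: mean + scores %*% t(V_k)
  R <- matrix(model$mean, n_samples, length(model$mean), byrow = TRUE)
  if (k > 0L)
    R <- R + scores %*% t(model$eigenvectors[, seq_len(k), drop = FALSE])
  X <- cohort$matrix
  npts <- ncol(X) / 3L
  # squared distances via ||r||^2 + ||x||^2 - 2 r.x
  d2 <- outer(rowSums(R^2), rep(1, nrow(X))) +
    outer(rep(1, n_samples), rowSums(X^2)) - 2 * tcrossprod(R, X)
  per_sample <- sqrt(pmax(apply(d2, 1L, min), 0) / npts)
  ci <- mean_ci(per_sample)
  list(per_sample = per_sample,
       summary = data.frame(k = k, mean = ci[["mean"]], lower = ci[["lower"]],
                            upper = ci[["upper"]], n_samples = n_samples,
                            seed = as.integer(seed)))
}

#' Full SSM quality report
#'
#' Composes the three standard shape-model quality metrics on one cohort:
#' compactness, leave-one-out generalization, and specificity, each
#' summarized with 95 percent confidence intervals.
#'
#' @param cohort a [shape_cohort()].
#' @param k_values component counts for generalization and specificity.
#' @param n_samples random shapes per specificity evaluation.
#' @param seed integer seed for the specificity sampling.
#' @return Object of class `eval_report` with `compactness`,
#'   `generalization`, `specificity`, `k_values`, `n_samples`, `seed`.
#' @export
evaluate_all <- function(cohort, k_values = c(5L, 9L), n_samples = 1000L,
                         seed = 1L) {
  model <- fit_ssm(cohort)
  gen <- generalization_loo(cohort, k_values)
  spec <- lapply(seq_along(k_values), function(jk)
    specificity(model, cohort, k_values[jk], n_samples,
                seed = as.integer(seed) + jk - 1L))
  spec_summary <- do.call(rbind, lapply(spec, `[[`, "summary"))
  structure(list(compactness = compactness(model),
                 generalization = gen$summary,
                 generalization_per_shape = gen$per_shape,
                 specificity = spec_summary,
                 k_values = k_values, n_samples = n_samples,
                 seed = as.integer(seed)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("SSM quality report\n")
  k5 <- min(5L, length(x$compactness))
  cat(sprintf("  compactness at %d PCs: %.1f%%\n", k5,
              100 * x$compactness[k5]))
  for (i in seq_len(nrow(x$generalization)))
    cat(sprintf("  generalization, %d PCs: %.2f mm (95%% CI %.2f-%.2f)\n",
                x$generalization$k[i], x$generalization$mean[i],
                x$generalization$lower[i], x$generalization$upper[i]))
  for (i in seq_len(nrow(x$specificity)))
    cat(sprintf("  specificity,    %d PCs: %.2f mm (95%% CI %.2f-%.2f)\n",
                x$specificity$k[i], x$specificity$mean[i],
                x$specificity$lower[i], x$specificity$upper[i]))
  invisible(x)
}

#' Write an evaluation report
#'
#' @param report an [evaluate_all()] report.
#' @param path output path; `.json` writes the full report, `.csv` writes
#'   the generalization/specificity summary table.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(unclass(report)[c("compactness", "generalization",
                                           "specificity", "k_values",
                                           "n_samples", "seed")],
                         path, digits = NA, auto_unbox = TRUE,
                         dataframe = "columns")
  } else if (ext == "csv") {
    gen <- report$generalization; gen$metric <- "generalization"
    sp <- report$specificity[, c("k", "mean", "lower", "upper")]
    sp$metric <- "specificity"
    utils::write.csv(rbind(gen, sp), path, row.names = FALSE)
  } else ssm_stop("unknown_format", "unsupported report extension '.%s'", ext)
  invisible(path)
}
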