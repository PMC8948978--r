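# Ray-triangle intersection (Moller-Trumbore), vectorized over all triangles
# of a mesh. Rays originate on the centerline, so the nearest strictly
# positive hit is the local lumen wall.

# Precompute per-triangle arrays once per mesh.
ray_precompute <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  v0 <- v[f[, 1L], , drop = FALSE]
  list(v0 = v0,
       e1 = v[f[, 2L], , drop = FALSE] - v0,
       e2 = v[f[, 3L], , drop = FALSE] - v0)
}

# Returns list(t, triangle) for the smallest strictly positive ray parameter,
# or t = Inf when nothing is hit. `origin`, `dir` are length-3; `pre` comes
# from ray_precompute().
ray_hit <- function(origin, dir, pre, eps = 1e-12, tmin = 1e-9) {
  e1 <- pre$e1; e2 <- pre$e2
  # h = dir x e2 (row-wise, dir constant)
  h1 <- dir[2L] * e2[, 3L] - dir[3L] * e2[, 2L]
  h2 <- dir[3L] * e2[, 1L] - dir[1L] * e2[, 3L]
  h3 <- dir[1L] * e2[, 2L] - dir[2L] * e2[, 1L]
  a <- e1[, 1L] * h1 + e1[, 2L] * h2 + e1[, 3L] * h3
  s1 <- origin[1L] - pre$v0[, 1L]
  s2 <- origin[2L] - pre$v0[, 2L]
  s3 <- origin[3L] - pre$v0[, 3L]
  # q = s x e1
  q1 <- s2 * e1[, 3L] - s3 * e1[, 2L]
  q2 <- s3 * e1[, 1L] - s1 * e1[, 3L]
  q3 <- s1 * e1[, 2L] - s2 * e1[, 1L]
  inv <- 1 / a
  u <- inv * (s1 * h1 + s2 * h2 + s3 * h3)
  v <- inv * (dir[1L] * q1 + dir[2L] * q2 + dir[3L] * q3)
  tt <- inv * (e2[, 1L] * q1 + e2[, 2L] * q2 + e2[, 3L] * q3)
  ok <- abs(a) >= eps & u >= -eps & v >= -eps & (u + v) <= 1 + eps & tt > tmin
  if (!any(ok)) return(list(t = Inf, triangle = NA_integer_))
  idx <- which(ok)
  best <- idx[which.min(tt[idx])]
  list(t = tt[best], triangle = if (is.null(pre$index)) best else pre$index[best])
}

# Restrict a precomputed triangle set to those straddling the plane through
# `origin` with normal `normal` (rays cast in that plane can only hit these).
# Keeps the original triangle indices in `index`.
ray_plane_subset <- function(pre, origin, normal, tol = 1e-7) {
  d0 <- (pre$v0[, 1L] - origin[1L]) * normal[1L] +
        (pre$v0[, 2L] - origin[2L]) * normal[2L] +
        (pre$v0[, 3L] - origin[3L]) * normal[3L]
  d1 <- d0 + pre$e1[, 1L] * normal[1L] + pre$e1[, 2L] * normal[2L] +
        pre$e1[, 3L] * normal[3L]
  d2 <- d0 + pre$e2[, 1L] * normal[1L] + pre$e2[, 2L] * normal[2L] +
        pre$e2[, 3L] * normal[3L]
  keep <- which(pmin(d0, d1, d2) <= tol & pmax(d0, d1, d2) >= -tol)
  idx <- if (is.null(pre$index)) keep else pre$index[keep]
  list(v0 = pre$v0[keep, , drop = FALSE], e1 = pre$e1[keep, , drop = FALSE],
       e2 = pre$e2[keep, , drop = FALSE], index = idx)
}
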