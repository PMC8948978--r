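#' Lumen surface mesh
#'
#' Constructs a triangular surface mesh of the aortic lumen. Vertices are in
#' millimetres; faces are 1-based vertex-index triples.
#'
#' @param vertices numeric n x 3 matrix of vertex coordinates (mm).
#' @param faces integer m x 3 matrix of vertex indices (1-based).
#' @return An object of class `lumen_mesh` with elements `vertices`, `faces`.
#' @export
lumen_mesh <- function(vertices, faces) {
  vertices <- as_point_matrix(vertices, "vertices")
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(faces) != 3L)
    ssm_stop("bad_dimensions", "faces must have 3 columns")
  if (nrow(vertices) < 4L)
    ssm_stop("empty_mesh", "a surface mesh needs at least 4 vertices")
  if (nrow(faces) < 1L)
    ssm_stop("empty_mesh", "mesh has no faces")
  stopifnot_finite(vertices, "mesh vertices")
  if (any(faces < 1L) || any(faces > nrow(vertices)))
    ssm_stop("bad_face_index", "face indices out of range [1, %d]", nrow(vertices))
  a <- vertices[faces[, 1L], , drop = FALSE]
  area2 <- sqrt(rowSums(cross_rows(vertices[faces[, 2L], , drop = FALSE] - a,
                                   vertices[faces[, 3L], , drop = FALSE] - a)^2))
  if (any(area2 <= 1e-12))
    ssm_stop("degenerate_triangle", "%d degenerate (zero-area) triangle(s)",
             sum(area2 <= 1e-12))
  structure(list(vertices = vertices, faces = faces), class = "lumen_mesh")
}

# Row-wise cross product of two n x 3 matrices.
cross_rows <- function(a, b) {
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
}

#' @export
print.lumen_mesh <- function(x, ...) {
  cat(sprintf("lumen_mesh: %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Read a triangular surface mesh
#'
#' Reads STL (ASCII or binary), PLY (ASCII), or OBJ meshes; the format is
#' detected from the file extension. Quad faces (PLY/OBJ) are triangulated
#' deterministically by splitting along the quad's first diagonal
#' (v1-v3): triangles (v1, v2, v3) and (v1, v3, v4). Coordinates are taken
#' as millimetres and never rescaled.
#'
#' @param path path to a `.stl`, `.ply`, or `.obj` file.
#' @return A [lumen_mesh()].
#' @export
read_mesh <- function(path) {
  if (!file.exists(path))
    ssm_stop("missing_file", "mesh file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  m <- switch(ext,
    stl = read_stl(path),
    ply = read_ply(path),
    obj = read_obj(path),
    ssm_stop("unknown_format", "unsupported mesh extension '.%s' (%s)", ext, path)
  )
  lumen_mesh(m$vertices, m$faces)
}

# --- STL ---------------------------------------------------------------

is_binary_stl <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  head <- readBin(con, "raw", 80L)
  if (length(head) < 80L) return(FALSE)
  ntri <- readBin(con, "integer", 1L, size = 4L)
  if (length(ntri) != 1L) return(FALSE)
  file.size(path) == 84 + 50 * ntri
}

read_stl <- function(path) {
  tri <- if (is_binary_stl(path)) read_stl_binary(path) else read_stl_ascii(path)
  if (nrow(tri) == 0L) ssm_stop("empty_mesh", "STL file has no facets: %s", path)
  # STL stores soup triangles; merge exactly coincident vertices.
  key <- paste(tri[, 1L], tri[, 2L], tri[, 3L], sep = "/")
  idx <- match(key, unique(key))
  verts <- tri[!duplicated(key), , drop = FALSE]
  faces <- matrix(idx, ncol = 3L, byrow = TRUE)
  list(vertices = verts, faces = faces)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) %% 3L != 0L)
    ssm_stop("parse_failure", "ASCII STL vertex count not a multiple of 3: %s", path)
  nums <- lapply(strsplit(trimws(vl), "\\s+"), function(f) as.numeric(f[2:4]))
  tri <- do.call(rbind, nums)
  if (anyNA(tri)) ssm_stop("parse_failure", "unparseable ASCII STL: %s", path)
  tri
}

read_stl_binary <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  readBin(con, "raw", 80L)
  ntri <- readBin(con, "integer", 1L, size = 4L)
  tri <- matrix(NA_real_, 3L * ntri, 3L)
  for (i in seq_len(ntri)) {
    vals <- readBin(con, "numeric", 12L, size = 4L)
    readBin(con, "raw", 2L)
    tri[(3L * i - 2L):(3L * i), ] <- matrix(vals[4:12], 3L, 3L, byrow = TRUE)
  }
  tri
}

#' Write a mesh to STL or PLY
#'
#' @param mesh a [lumen_mesh()].
#' @param path output path ending in `.stl` (ASCII) or `.ply` (ASCII).
#' @param comment optional comment line embedded in the file header.
#' @export
write_mesh <- function(mesh, path, comment = NULL) {
  stopifnot(inherits(mesh, "lumen_mesh"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    stl = write_stl_ascii(mesh, path),
    ply = write_ply(mesh, path, comment),
    ssm_stop("unknown_format", "unsupported mesh extension '.%s'", ext)
  )
  invisible(path)
}

write_stl_ascii <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  n <- cross_rows(v[f[, 2L], , drop = FALSE] - a, v[f[, 3L], , drop = FALSE] - a)
  n <- n / sqrt(rowSums(n^2))
  con <- file(path, "w"); on.exit(close(con))
  writeLines("solid neckssm", con)
  for (i in seq_len(nrow(f))) {
    writeLines(sprintf("  facet normal %.9g %.9g %.9g", n[i, 1], n[i, 2], n[i, 3]), con)
    writeLines("    outer loop", con)
    for (j in 1:3) {
      p <- v[f[i, j], ]
      writeLines(sprintf("      vertex %.9g %.9g %.9g", p[1], p[2], p[3]), con)
    }
    writeLines(c("    endloop", "  endfacet"), con)
  }
  writeLines("endsolid neckssm", con)
}

# --- PLY (ASCII) -------------------------------------------------------

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L || trimws(lines[1L]) != "ply")
    ssm_stop("parse_failure", "not a PLY file: %s", path)
  endh <- match("end_header", trimws(lines))
  if (is.na(endh)) ssm_stop("parse_failure", "PLY header not terminated: %s", path)
  header <- trimws(lines[seq_len(endh)])
  if (!any(grepl("^format\\s+ascii", header)))
    ssm_stop("parse_failure", "only ASCII PLY is supported: %s", path)
  nv <- as.integer(sub("^element\\s+vertex\\s+", "",
                       grep("^element\\s+vertex\\s+", header, value = TRUE)[1L]))
  nf <- as.integer(sub("^element\\s+face\\s+", "",
                       grep("^element\\s+face\\s+", header, value = TRUE)[1L]))
  if (is.na(nv) || is.na(nf))
    ssm_stop("parse_failure", "PLY missing vertex/face elements: %s", path)
  body <- lines[(endh + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  vparts <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  verts <- do.call(rbind, lapply(vparts, function(f) as.numeric(f[1:3])))
  fparts <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  faces <- triangulate_face_lists(lapply(fparts, function(f) {
    cnt <- as.integer(f[1L])
    as.integer(f[1L + seq_len(cnt)]) + 1L  # PLY is 0-based
  }))
  if (anyNA(verts)) ssm_stop("parse_failure", "unparseable PLY vertices: %s", path)
  list(vertices = verts, faces = faces)
}

write_ply <- function(mesh, path, comment = NULL) {
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0"), con)
  if (!is.null(comment)) writeLines(paste("comment", comment), con)
  writeLines(c(sprintf("element vertex %d", nrow(v)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
}

# --- OBJ ---------------------------------------------------------------

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  if (length(vl) == 0L || length(fl) == 0L)
    ssm_stop("empty_mesh", "OBJ file has no vertices or faces: %s", path)
  verts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                                 function(f) as.numeric(f[2:4])))
  face_lists <- lapply(strsplit(trimws(fl), "\\s+"), function(f) {
    as.integer(vapply(strsplit(f[-1L], "/"), `[[`, "", 1L))
  })
  faces <- triangulate_face_lists(face_lists)
  if (anyNA(verts) || anyNA(faces))
    ssm_stop("parse_failure", "unparseable OBJ: %s", path)
  list(vertices = verts, faces = faces)
}

# Triangles pass through; quads split along the first diagonal (v1-v3);
# larger polygons are rejected.
triangulate_face_lists <- function(face_lists) {
  out <- lapply(face_lists, function(idx) {
    if (length(idx) == 3L) matrix(idx, 1L, 3L)
    else if (length(idx) == 4L)
      rbind(idx[c(1L, 2L, 3L)], idx[c(1L, 3L, 4L)])
    else ssm_stop("non_triangulatable_face",
                  "face with %d vertices cannot be triangulated", length(idx))
  })
  do.call(rbind, out)
}
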