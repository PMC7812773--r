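#' Triangular surface mesh
#'
#' Lightweight container for a per-hemisphere cortical sheet: vertex
#' coordinates in mm, triangular faces (1-based index triples), a hemisphere
#' label and optional per-vertex region labels. Geodesic distances and
#' connective-field profiles are defined on this object.
#'
#' @param vertices numeric matrix, n x 3, vertex coordinates in mm.
#' @param faces integer matrix, m x 3, 1-based vertex indices per triangle.
#' @param hemisphere `"L"` or `"R"`.
#' @param region optional character/integer vector of per-vertex region labels.
#' @return An object of class `cf_mesh`.
#' @export
cf_mesh <- function(vertices, faces, hemisphere = c("L", "R"), region = NULL) {
  hemisphere <- match.arg(hemisphere)
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  if (nrow(faces) > 0L &&
      (min(faces) < 1L || max(faces) > nrow(vertices))) {
    stop("face indices out of range [1, ", nrow(vertices), "]")
  }
  if (!is.null(region) && length(region) != nrow(vertices)) {
    stop("region labels must have one entry per vertex")
  }
  structure(
    list(vertices = vertices, faces = faces, hemisphere = hemisphere,
         region = region),
    class = "cf_mesh"
  )
}

#' @exportS3Method base::print
print.cf_mesh <- function(x, ...) {
  cat(sprintf("<cf_mesh> %d vertices, %d faces, hemisphere %s\n",
              nrow(x$vertices), nrow(x$faces), x$hemisphere))
  invisible(x)
}

#' Build a planar regular triangulated grid mesh
#'
#' Constructs a flat `rows` x `cols` sheet of vertices spaced `spacing` mm
#' apart, triangulated with one diagonal per grid cell. On a planar sheet the
#' geodesic distance equals the Euclidean straight-line distance, which makes
#' the grid an exact oracle for the geodesic solver. Used by the synthetic
#' generator as a stand-in for a fiducial (midgray) cortical surface.
#'
#' @param rows,cols grid dimensions, both >= 2.
#' @param spacing vertex spacing in mm (> 0).
#' @param hemisphere `"L"` or `"R"`.
#' @return A [cf_mesh()] with `rows * cols` vertices in the z = 0 plane;
#'   vertex order is row-major (column index varies fastest).
#' @examples
#' m <- make_mesh(4, 5, spacing = 2)
#' nrow(m$vertices)  # 20
#' @export
make_mesh <- function(rows, cols, spacing = 1, hemisphere = c("L", "R")) {
  hemisphere <- match.arg(hemisphere)
  if (rows < 2 || cols < 2) {
    stop("invalid geometry: rows and cols must both be >= 2")
  }
  if (spacing <= 0) stop("invalid geometry: spacing must be > 0")
  rows <- as.integer(rows); cols <- as.integer(cols)
  ij <- expand.grid(col = seq_len(cols), row = seq_len(rows))
  vertices <- cbind(
    x = (ij$col - 1) * spacing,
    y = (ij$row - 1) * spacing,
    z = 0
  )
  idx <- function(r, c) (r - 1L) * cols + c
  faces <- matrix(0L, nrow = 2L * (rows - 1L) * (cols - 1L), ncol = 3L)
  k <- 0L
  for (r in seq_len(rows - 1L)) {
    c <- seq_len(cols - 1L)
    a <- idx(r, c); b <- idx(r, c + 1L)
    d <- idx(r + 1L, c); e <- idx(r + 1L, c + 1L)
    faces[k + seq_along(c), ] <- cbind(a, b, e)
    faces[k + length(c) + seq_along(c), ] <- cbind(a, e, d)
    k <- k + 2L * length(c)
  }
  m <- cf_mesh(vertices, faces, hemisphere,
               region = rep("V1", rows * cols))
  m$grid <- list(rows = rows, cols = cols, spacing = spacing)
  m
}

# undirected edge list (two columns, i < j), one row per unique mesh edge
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

mesh_edge_lengths <- function(mesh, edges = mesh_edges(mesh)) {
  d <- mesh$vertices[edges[, 1], , drop = FALSE] -
    mesh$vertices[edges[, 2], , drop = FALSE]
  sqrt(rowSums(d^2))
}

mesh_face_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- cbind(
    e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
    e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
    e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  )
  0.5 * sqrt(rowSums(cx^2))
}

# connected components over mesh edges; returns integer component id per vertex
mesh_components <- function(mesh) {
  n <- nrow(mesh$vertices)
  edges <- mesh_edges(mesh)
  # union-find
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(nrow(edges))) {
    a <- find(edges[k, 1]); b <- find(edges[k, 2])
    if (a != b) parent[a] <- b
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Validate a surface mesh
#'
#' Report-only diagnostic: checks connectivity, degenerate (zero-area or
#' repeated-vertex) faces, out-of-range face indices and non-finite
#' coordinates. Never throws; downstream functions decide what is fatal.
#'
#' @param mesh a [cf_mesh()].
#' @return A list with fields `n_vertices`, `n_faces`, `n_components`,
#'   `degenerate_faces` (indices), `nonfinite_vertices` (indices) and a
#'   logical `ok` that is `TRUE` when no problem was found.
#' @export
validate_mesh <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  nonfinite <- which(!apply(is.finite(v), 1, all))
  repeated <- which(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3])
  areas <- mesh_face_areas(mesh)
  zero_area <- which(areas <= .Machine$double.eps * 100)
  degenerate <- sort(union(repeated, zero_area))
  comp <- mesh_components(mesh)
  report <- list(
    n_vertices = nrow(v),
    n_faces = nrow(f),
    n_components = max(comp),
    component_id = comp,
    degenerate_faces = degenerate,
    nonfinite_vertices = nonfinite
  )
  report$ok <- report$n_components == 1L &&
    length(degenerate) == 0L && length(nonfinite) == 0L
  report
}
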