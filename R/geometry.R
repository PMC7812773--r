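#' Geodesic distances on a surface mesh by the heat method
#'
#' Pairwise geodesic distances among a set of source-region vertices, computed
#' per hemisphere on the triangular mesh. Distances come from simulated heat
#' diffusion along the surface: a unit of heat is placed at each source
#' vertex, diffused for a short time `t`, and the normalized temperature
#' gradient is integrated back into a distance function (the heat method).
#' The diffusion time is `t_factor` times the squared mean edge length, the
#' standard choice. The returned matrix is symmetrized by averaging the
#' from/to estimates.
#'
#' Because the heat method is approximate, small violations of the triangle
#' inequality (a few percent) can occur; the fitting stages only ever use the
#' distances inside `exp(-d^2 / 2 sigma^2)` kernels, where this is immaterial.
#'
#' @param mesh a [cf_mesh()]; all vertices must belong to one hemisphere.
#' @param source_vertices integer indices of the source-region vertices
#'   (default: all mesh vertices).
#' @param t_factor multiplier on the squared mean edge length used as the
#'   heat-diffusion time (default 1).
#' @param clamp_to_edge_paths if `TRUE` (default), heat estimates are capped
#'   at the shortest path length through the mesh edge graph. The edge-graph
#'   path is a true upper bound on the polyhedral geodesic, so the cap can
#'   only reduce error; it removes the occasional boundary-driven
#'   overestimates of the diffusion solve.
#' @return An object of class `cf_distmat`: a list with `d` (square symmetric
#'   matrix, mm, zero diagonal), `vertices` (the source vertex indices) and
#'   `hemisphere`.
#' @references Crane, Weischedel & Wardetzky (2013), "Geodesics in heat".
#' @export
geodesic_distances <- function(mesh, source_vertices = NULL, t_factor = 1,
                               clamp_to_edge_paths = TRUE) {
  n <- nrow(mesh$vertices)
  if (is.null(source_vertices)) source_vertices <- seq_len(n)
  source_vertices <- as.integer(source_vertices)
  if (length(source_vertices) == 0L) stop("source_vertices must be nonempty")
  if (min(source_vertices) < 1L || max(source_vertices) > n) {
    stop("source vertex index out of range")
  }
  if (!is.null(mesh$vertex_hemisphere)) {
    h <- unique(mesh$vertex_hemisphere[source_vertices])
    if (length(h) > 1L) {
      stop("source vertices span both hemispheres; ",
           "compute one distance matrix per hemisphere")
    }
  }
  comp <- mesh_components(mesh)
  main <- comp[source_vertices[1]]
  off <- source_vertices[comp[source_vertices] != main]
  if (length(off) > 0L) {
    stop("source vertex ", off[1],
         " is disconnected from the rest of the source region")
  }
  # restrict all operators to the component carrying the sources, so a stray
  # disconnected patch elsewhere in the mesh cannot make the solve singular
  keep <- which(comp == main)
  sub <- if (length(keep) < n) submesh(mesh, keep) else mesh
  src_local <- match(source_vertices, keep)
  if (length(keep) == n) src_local <- source_vertices

  ops <- heat_operators(sub, t_factor = t_factor)
  ns <- length(source_vertices)
  d <- matrix(0, ns, ns)
  for (k in seq_len(ns)) {
    dk <- heat_distance_from(ops, src_local[k])
    d[k, ] <- dk[src_local]
  }
  d <- (d + t(d)) / 2
  if (clamp_to_edge_paths) {
    # true bracketing of the polyhedral geodesic: the straight-line chord is
    # a lower bound, the shortest edge-graph path an upper bound
    chord <- as.matrix(stats::dist(sub$vertices[src_local, , drop = FALSE]))
    d <- pmax(pmin(d, edge_path_distances(sub, src_local)), chord)
  }
  diag(d) <- 0
  d[d < 0] <- 0
  structure(
    list(d = d, vertices = source_vertices, hemisphere = mesh$hemisphere),
    class = "cf_distmat"
  )
}

#' @exportS3Method base::print
print.cf_distmat <- function(x, ...) {
  cat(sprintf("<cf_distmat> %d source vertices, hemisphere %s, max %.2f mm\n",
              length(x$vertices), x$hemisphere, max(x$d)))
  invisible(x)
}

# all-pairs shortest path lengths through the mesh edge graph, restricted to
# the given vertices (an upper bound on the polyhedral geodesic distance)
edge_path_distances <- function(mesh, vertices) {
  e <- mesh_edges(mesh)
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  ng <- igraph::gorder(g)
  if (ng < nrow(mesh$vertices)) {
    g <- igraph::add_vertices(g, nrow(mesh$vertices) - ng)
  }
  igraph::distances(g, v = vertices, to = vertices,
                    weights = mesh_edge_lengths(mesh, e))
}

submesh <- function(mesh, keep) {
  map <- integer(nrow(mesh$vertices))
  map[keep] <- seq_along(keep)
  f <- mesh$faces
  fk <- f[rowSums(matrix(f %in% keep, nrow(f), 3)) == 3L, , drop = FALSE]
  fk[] <- map[fk]
  cf_mesh(mesh$vertices[keep, , drop = FALSE], fk, mesh$hemisphere,
          region = mesh$region[keep])
}

# Precompute the sparse operators of the heat method:
#   A = M + t L   (heat step),  L = cotan Laplacian (PSD convention),
#   G  : 3F x n gradient operator (per-face, un-normalized),
#   Dv : n x 3F divergence operator.
heat_operators <- function(mesh, t_factor = 1) {
  v <- mesh$vertices
  f <- mesh$faces
  n <- nrow(v)
  nf <- nrow(f)
  i1 <- f[, 1]; i2 <- f[, 2]; i3 <- f[, 3]
  p1 <- v[i1, , drop = FALSE]
  p2 <- v[i2, , drop = FALSE]
  p3 <- v[i3, , drop = FALSE]
  e12 <- p2 - p1; e23 <- p3 - p2; e31 <- p1 - p3
  cross3 <- function(a, b) {
    cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
          a[, 3] * b[, 1] - a[, 1] * b[, 3],
          a[, 1] * b[, 2] - a[, 2] * b[, 1])
  }
  nrm <- cross3(e12, -e31)
  dblA <- sqrt(rowSums(nrm^2))
  if (any(dblA <= 0)) stop("mesh has zero-area faces")
  unit_n <- nrm / dblA
  # cotangent of the angle at each corner
  cot_at <- function(a, b) rowSums(a * b) / sqrt(rowSums(cross3(a, b)^2))
  c1 <- cot_at(e12, -e31)   # angle at vertex 1 (between e12 and e13)
  c2 <- cot_at(-e12, e23)   # at vertex 2
  c3 <- cot_at(-e23, e31)   # at vertex 3
  # cotan Laplacian, PSD convention: L_ii = sum w_ij, L_ij = -w_ij
  wi <- c(i1, i2, i3, i2, i3, i1)
  wj <- c(i2, i3, i1, i1, i2, i3)
  wx <- 0.5 * c(c3, c1, c2, c3, c1, c2)
  W <- Matrix::sparseMatrix(i = wi, j = wj, x = wx, dims = c(n, n))
  L <- Matrix::Diagonal(n, Matrix::rowSums(W)) - W
  # lumped mass matrix: one third of incident face areas
  area3 <- dblA / 6  # (dblA/2) / 3
  mass <- as.vector(Matrix::sparseMatrix(
    i = c(i1, i2, i3), j = rep(1L, 3L * nf), x = rep(area3, 3),
    dims = c(n, 1)))
  t_step <- t_factor * mean(mesh_edge_lengths(mesh))^2
  A <- Matrix::Diagonal(n, mass) + t_step * L
  # gradient operator: X_f = (1/2A_f) sum_corner u_corner (N x e_opposite)
  rot <- rbind(cross3(unit_n, e23), cross3(unit_n, e31), cross3(unit_n, e12)) /
    dblA
  # triplets: rows are 3F entries ordered in coordinate blocks (f varies fastest)
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  corner_idx <- list(i1, i2, i3)
  for (c_i in 1:3) {
    ropp <- rot[((c_i - 1) * nf + 1):(c_i * nf), , drop = FALSE]
    for (coord in 1:3) {
      rows <- c(rows, (coord - 1L) * nf + seq_len(nf))
      cols <- c(cols, corner_idx[[c_i]])
      vals <- c(vals, ropp[, coord])
    }
  }
  G <- Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(3L * nf, n))
  # divergence operator: div_i = 0.5 sum_{f contains i} cot(opp1) e1.X + cot(opp2) e2.X
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  add_div <- function(vidx, ea, cota, eb, cotb) {
    for (coord in 1:3) {
      rows <<- c(rows, vidx, vidx)
      cols <<- c(cols, (coord - 1L) * nf + seq_len(nf),
                 (coord - 1L) * nf + seq_len(nf))
      vals <<- c(vals, 0.5 * cota * ea[, coord], 0.5 * cotb * eb[, coord])
    }
  }
  add_div(i1, e12, c3, -e31, c2)   # edges from v1: 1->2 (opp angle v3), 1->3 (opp v2)
  add_div(i2, e23, c1, -e12, c3)
  add_div(i3, e31, c2, -e23, c1)
  Dv <- Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(n, 3L * nf))
  eps <- 1e-8 * mean(Matrix::diag(L))
  # boundary vertices: endpoints of edges incident to exactly one face.
  # On meshes with boundary the heat solution is averaged over Neumann and
  # Dirichlet conditions (Crane et al. 2013), which cancels the reflection /
  # absorption biases near the rim.
  ue <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  ue <- cbind(pmin(ue[, 1], ue[, 2]), pmax(ue[, 1], ue[, 2]))
  key <- paste(ue[, 1], ue[, 2])
  boundary <- sort(unique(as.vector(ue[key %in% names(which(table(key) == 1L)), ])))
  interior <- setdiff(seq_len(n), boundary)
  chA_int <- if (length(boundary) > 0L && length(interior) > 0L) {
    Matrix::Cholesky(Matrix::forceSymmetric(
      A[interior, interior, drop = FALSE]))
  } else NULL
  list(
    n = n, nf = nf,
    chA = Matrix::Cholesky(Matrix::forceSymmetric(A)),
    chA_int = chA_int, interior = interior, boundary = boundary,
    chL = Matrix::Cholesky(Matrix::forceSymmetric(L + eps * Matrix::Diagonal(n))),
    G = G, Dv = Dv, t_step = t_step
  )
}

heat_distance_from <- function(ops, s) {
  delta <- numeric(ops$n)
  delta[s] <- 1
  u <- as.vector(Matrix::solve(ops$chA, delta, system = "A"))
  if (!is.null(ops$chA_int)) {
    ud <- numeric(ops$n)
    ud[ops$interior] <- as.vector(
      Matrix::solve(ops$chA_int, delta[ops$interior], system = "A"))
    u <- (u + ud) / 2
  }
  g <- matrix(as.vector(ops$G %*% u), nrow = ops$nf)
  gn <- sqrt(rowSums(g^2))
  gn[gn == 0] <- 1
  x <- -g / gn
  div <- as.vector(ops$Dv %*% as.vector(x))
  phi <- as.vector(Matrix::solve(ops$chL, div, system = "A"))
  d <- phi - phi[s]
  if (sum(d) < 0) d <- -d
  d[d < 0] <- 0
  d
}
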