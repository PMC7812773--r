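# Shared fixtures, built once per test run and cached. All synthetic data is
# generated in code under fixed seeds; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# preprocess every run of every condition identically
preprocess_study <- function(d, fs = 1) {
  pp <- function(x) preprocess_run(x, fs)
  for (cond in names(d$source)) {
    for (h in c("L", "R")) {
      d$source[[cond]][[h]] <- lapply(d$source[[cond]][[h]], pp)
    }
    d$targets[[cond]] <- lapply(d$targets[[cond]], pp)
  }
  d
}

# full study: simulate, preprocess, geometry, pRF eligibility, candidates
build_study <- function(cfg, conditions = c("retinotopy", "rest")) {
  d <- preprocess_study(simulate_dataset(cfg, conditions = conditions),
                        cfg$sampling_rate)
  dists <- lapply(d$meshes, geodesic_distances)
  prf <- lapply(stats::setNames(nm = c("L", "R")), function(h) {
    prf_grid_fit(average_runs(d$source$retinotopy[[h]]), d$aperture)
  })
  centers <- lapply(stats::setNames(nm = c("L", "R")), function(h) {
    select_cf_centers(prf[[h]], d$aperture)
  })
  list(data = d, dists = dists, prf = prf, centers = centers,
       candidates = cf_candidates(centers), config = cfg)
}

# the default study conditions, with CF fits for both cognitive states
default_study <- function() fixture("default_study", function() {
  st <- build_study(synthetic_config())
  st$fit_rest <- cf_crossvalidate(st$data$targets$rest, st$data$source$rest,
                                  st$candidates, st$dists)
  st$fit_stim <- cf_crossvalidate(st$data$targets$retinotopy,
                                  st$data$source$retinotopy,
                                  st$candidates, st$dists)
  st
})

# 100 pure-null targets (mean-signal-driven only), resting state
null_study <- function() fixture("null_study", function() {
  st <- build_study(synthetic_config(n_targets = 100L,
                                     n_null_targets = 100L))
  st$fit_rest <- cf_crossvalidate(st$data$targets$rest, st$data$source$rest,
                                  st$candidates, st$dists)
  st
})

# focal-CF targets without mean-signal coupling, resting state
focal_study <- function() fixture("focal_study", function() {
  st <- build_study(synthetic_config(global_coupling = 0))
  st$fit_rest <- cf_crossvalidate(st$data$targets$rest, st$data$source$rest,
                                  st$candidates, st$dists)
  st
})

# Euclidean distance on the source sheet between two vertex selections; Inf
# when the hemispheres disagree or either selection is missing
v0_distance <- function(meshes, v0_a, hemi_a, v0_b, hemi_b) {
  vapply(seq_along(v0_a), function(i) {
    if (is.na(hemi_a[i]) || is.na(hemi_b[i]) || hemi_a[i] != hemi_b[i]) {
      return(Inf)
    }
    m <- meshes[[hemi_a[i]]]
    sqrt(sum((m$vertices[v0_a[i], ] - m$vertices[v0_b[i], ])^2))
  }, numeric(1))
}

# independent edge-graph shortest-path oracle (igraph Dijkstra)
dijkstra_oracle <- function(mesh) {
  e <- confield:::mesh_edges(mesh)
  w <- confield:::mesh_edge_lengths(mesh, e)
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  igraph::distances(g, weights = w)
}

# exact planar distance matrix (on flat sheets the geodesic IS the straight
# line); lets CF-engine tests run independently of the heat-method solver
planar_distmat <- function(mesh) {
  structure(list(d = as.matrix(stats::dist(mesh$vertices)),
                 vertices = seq_len(nrow(mesh$vertices)),
                 hemisphere = mesh$hemisphere),
            class = "cf_distmat")
}

# hand-built distance matrix over a 1D chain of vertices, spacing `s` mm
chain_distmat <- function(n, s = 1, hemisphere = "L") {
  x <- (seq_len(n) - 1) * s
  structure(list(d = abs(outer(x, x, "-")), vertices = seq_len(n),
                 hemisphere = hemisphere),
            class = "cf_distmat")
}
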