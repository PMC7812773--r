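#!/usr/bin/env Rscript
# Stage 2 — geodesic distances on the source sheets.
#
# Heat-method geodesics among all source vertices, one matrix per
# hemisphere (the two sheets are separate meshes, so distances never cross
# the midline). Computed once and cached; the CF stage only ever reads
# these matrices.

suppressPackageStartupMessages(library(confield))

dir.create("results/geometry", recursive = TRUE, showWarnings = FALSE)

for (h in c("L", "R")) {
  mesh <- read_surface(sprintf("results/data/mesh_%s.surf.gii", h))
  rep <- validate_mesh(mesh)
  stopifnot(rep$ok)
  D <- geodesic_distances(mesh)
  write_distances(D, sprintf("results/geometry/dists_%s.tsv", h))
  eu <- as.matrix(dist(mesh$vertices))
  rel <- abs(D$d - eu)[eu > 0] / eu[eu > 0]
  cat(sprintf(
    "%s: %d x %d distances, max %.1f mm; planar check: median |rel. error| vs straight line %.2g\n",
    h, nrow(D$d), ncol(D$d), max(D$d), median(rel)))
}
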