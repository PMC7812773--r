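#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic study.
#
# Two planar hemisphere sheets stand in for left and right V1, each vertex
# carrying a planted pRF; targets throughout the "brain" couple to the
# sheets through planted Gaussian connective fields plus a global
# mean-signal nuisance. Three conditions are acquired: a bar-sweep
# retinotopy session (stimulated sources) and rest / movie sessions
# (resting-mode sources, independent noise). Everything downstream is
# recoverable from the ground truth written here.

suppressPackageStartupMessages(library(confield))

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- synthetic_config()
data <- simulate_dataset(cfg)

for (h in c("L", "R")) {
  write_surface(data$meshes[[h]], file.path(out, sprintf("mesh_%s.surf.gii", h)))
  write.table(data$prf_gt[[h]], file.path(out, sprintf("prf_truth_%s.tsv", h)),
              sep = "\t", row.names = FALSE, quote = FALSE)
}
write.table(data$cf_gt, file.path(out, "cf_truth.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)

for (cond in names(data$source)) {
  for (h in c("L", "R")) {
    for (run in seq_along(data$source[[cond]][[h]])) {
      write_timecourses(data$source[[cond]][[h]][[run]],
                        file.path(out, sprintf("src_%s_%s_run%d.tsv", cond, h, run)),
                        sampling_rate = cfg$sampling_rate, run = run,
                        condition = cond)
    }
  }
  for (run in seq_along(data$targets[[cond]])) {
    write_timecourses(data$targets[[cond]][[run]],
                      file.path(out, sprintf("tgt_%s_run%d.tsv", cond, run)),
                      sampling_rate = cfg$sampling_rate, run = run,
                      condition = cond)
  }
}
jsonlite::write_json(unclass(cfg), file.path(out, "config.json"),
                     auto_unbox = TRUE, digits = NA)

cat(sprintf(
  "Simulated %d source vertices per hemisphere, %d targets (%d null),\n%d conditions x %d runs x %d timepoints at %g Hz (seed %d).\n",
  nrow(data$meshes$L$vertices), cfg$n_targets, cfg$n_null_targets,
  length(data$source), cfg$n_runs, cfg$n_timepoints_per_run,
  cfg$sampling_rate, cfg$seed))
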