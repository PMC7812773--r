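#' Default end-to-end pipeline configuration
#'
#' Resolves every stage's tunables into one schema-versioned document:
#' synthetic-study parameters, preprocessing (210-s third-order
#' Savitzky-Golay window), pRF stage (grids declared at run time, HRF off
#' for synthetic data, eligibility R^2 threshold 0.2), CF stage (the 13-value
#' sigma grid, one fold per run) and contrast stage (ratio floor 0.01).
#' Unknown keys are rejected, and every pipeline run writes its fully
#' resolved configuration next to its outputs.
#'
#' @param ... named overrides; nested lists are merged key-wise and unknown
#'   keys raise an error.
#' @return Nested list of class `cf_config`.
#' @export
cf_default_config <- function(...) {
  cfg <- list(
    schema_version = "1",
    seed = 1L,
    synthetic = unclass(synthetic_config()),
    preprocess = list(window_period_s = 210, polyorder = 3),
    prf = list(r2_threshold = 0.2, hrf = FALSE, grids = NULL),
    cf = list(sigma_grid = cf_sigma_grid()),
    contrast = list(ratio_floor = 0.01)
  )
  over <- list(...)
  merge_strict <- function(base, over, path = "") {
    bad <- setdiff(names(over), names(base))
    if (length(bad)) {
      stop("unknown config key", if (length(bad) > 1) "s", ": ",
           paste0(path, bad, collapse = ", "))
    }
    for (k in names(over)) {
      if (is.list(base[[k]]) && is.list(over[[k]]) && !is.null(names(base[[k]]))) {
        base[[k]] <- merge_strict(base[[k]], over[[k]], paste0(path, k, "."))
      } else {
        base[[k]] <- over[[k]]
      }
    }
    base
  }
  if (length(over)) cfg <- merge_strict(cfg, over)
  cfg$synthetic$seed <- cfg$seed
  class(cfg) <- "cf_config"
  cfg
}

#' Average time courses across runs (or participants)
#'
#' Element-wise mean of equally shaped matrices. Used to build the
#' retinotopy template time courses the pRF stage is fitted on.
#'
#' @param runs list of matrices with identical dimensions.
#' @return One matrix.
#' @export
average_runs <- function(runs) {
  stopifnot(length(runs) >= 1)
  Reduce(`+`, runs) / length(runs)
}

config_fingerprint <- function(config) {
  js <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  sprintf("%08x", stream_seed(1L, as.character(js)))
}

#' Run the full synthetic-study pipeline
#'
#' Executes every stage in order on generated data: simulate both
#' hemispheres and all conditions; preprocess every run of every condition
#' identically (high-pass + z-score); compute per-hemisphere geodesic
#' distance matrices once (fitting never recomputes geometry); fit pRFs on
#' the run-averaged retinotopy source data; select eligible CF centers;
#' cross-validate CF fits per condition with null-model correction; and
#' contrast resting-state against movie-watching connectivity (preference
#' ratio, weighted parameter correlation, laterality). All outputs are
#' written as TSV/JSON under `out_dir`, together with the resolved
#' configuration, its fingerprint, the package version and a stage log.
#'
#' @param config a [cf_default_config()].
#' @param out_dir output directory (created if missing).
#' @return Invisibly, a list with the in-memory results (`data`, `dists`,
#'   `prf`, `centers`, `cf` per condition, `contrast`, `paths`).
#' @export
run_pipeline <- function(config = cf_default_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "log.txt")
  logf <- function(...) {
    cat(sprintf(...), "\n", sep = "", file = log_path, append = TRUE)
  }
  cat("", file = log_path)
  version <- as.character(utils::packageVersion("confield"))
  fingerprint <- config_fingerprint(config)
  logf("confield %s | config %s", version, fingerprint)

  stage <- "simulate"
  res <- tryCatch({
    syn_cfg <- do.call(synthetic_config, config$synthetic)
    data <- simulate_dataset(syn_cfg)
    logf("simulate: %d source vertices/hemisphere, %d targets, %d runs x %d tp",
         nrow(data$meshes$L$vertices), nrow(data$cf_gt), syn_cfg$n_runs,
         syn_cfg$n_timepoints_per_run)

    stage <- "preprocess"
    fs <- syn_cfg$sampling_rate
    pp <- function(x) preprocess_run(x, fs, config$preprocess$window_period_s,
                                     config$preprocess$polyorder)
    # identical preprocessing for every condition label, asserted by loop
    for (cond in names(data$source)) {
      for (h in c("L", "R")) {
        data$source[[cond]][[h]] <- lapply(data$source[[cond]][[h]], pp)
      }
      data$targets[[cond]] <- lapply(data$targets[[cond]], pp)
    }
    logf("preprocess: Savitzky-Golay order %d, %g-s window, z-scored, %d conditions",
         config$preprocess$polyorder, config$preprocess$window_period_s,
         length(data$source))

    stage <- "geometry"
    dists <- lapply(data$meshes, geodesic_distances)
    logf("geometry: per-hemisphere geodesic matrices (%d x %d), cached",
         nrow(dists$L$d), ncol(dists$L$d))

    stage <- "fit-prf"
    grids <- config$prf$grids
    if (is.null(grids)) grids <- prf_default_grids(data$aperture$radius)
    hrf <- if (isTRUE(config$prf$hrf)) hrf_double_gamma(fs) else NULL
    prf <- list()
    centers <- list()
    for (h in c("L", "R")) {
      template <- average_runs(data$source$retinotopy[[h]])
      g <- prf_grid_fit(template, data$aperture, grids, hrf = hrf)
      prf[[h]] <- prf_iterative_fit(template, data$aperture, g, hrf = hrf)
      centers[[h]] <- select_cf_centers(prf[[h]], data$aperture,
                                        config$prf$r2_threshold)
      logf("fit-prf %s: median r2 %.3f, %d/%d eligible centers", h,
           stats::median(prf[[h]]$r2), length(centers[[h]]), nrow(prf[[h]]))
    }

    stage <- "fit-cf"
    candidates <- cf_candidates(centers, config$cf$sigma_grid)
    logf("fit-cf: %d candidates (%d + %d centers x %d sigmas)",
         nrow(candidates), length(centers$L), length(centers$R),
         length(config$cf$sigma_grid))
    cf <- list()
    for (cond in setdiff(names(data$targets), "retinotopy")) {
      cf[[cond]] <- cf_crossvalidate(data$targets[[cond]],
                                     data$source[[cond]], candidates, dists)
      s <- cf[[cond]]$summary
      logf("fit-cf %s: mean cv_r %.3f, mean null_r %.3f, mean corrected %.3f",
           cond, mean(s$cv_r, na.rm = TRUE), mean(s$null_r, na.rm = TRUE),
           mean(s$corrected, na.rm = TRUE))
      for (k in sort(unique(cf[[cond]]$folds$fold))) {
        fk <- cf[[cond]]$folds[cf[[cond]]$folds$fold == k, ]
        logf("  fold %d: mean test_r %.3f, mean null_r %.3f", k,
             mean(fk$test_r, na.rm = TRUE), mean(fk$null_r, na.rm = TRUE))
      }
    }

    stage <- "contrast"
    contrast <- NULL
    if (all(c("rest", "movie") %in% names(cf))) {
      rest <- cf$rest$summary
      movie <- cf$movie$summary
      ratio <- rc_preference_ratio(rest$corrected, movie$corrected,
                                   config$contrast$ratio_floor)
      vf_rest <- cf_to_visual_field(rest, data$prf_gt)
      vf_movie <- cf_to_visual_field(movie, data$prf_gt)
      w <- pmax((rest$corrected + movie$corrected) / 2, 0)
      w[is.na(w)] <- 0
      sig_cor <- weighted_correlation(rest$sigma_cf, movie$sigma_cf, w)
      ecc_cor <- weighted_correlation(vf_rest$ecc, vf_movie$ecc, w)
      lat <- list(
        rest = laterality_index(data$cf_gt$hemisphere, vf_rest$hemifield),
        movie = laterality_index(data$cf_gt$hemisphere, vf_movie$hemifield)
      )
      contrast <- list(
        table = data.frame(
          target = rest$target, ratio = ratio,
          rho_rs = rest$corrected, rho_mw = movie$corrected,
          masked = is.na(ratio)
        ),
        sigma_correlation = sig_cor,
        ecc_correlation = ecc_cor,
        laterality = lat
      )
      logf("contrast: mean ratio %.3f (%d masked), sigma rho %.3f, ecc rho %.3f",
           mean(ratio, na.rm = TRUE), sum(is.na(ratio)), sig_cor$rho,
           ecc_cor$rho)
    }
    list(data = data, dists = dists, prf = prf, centers = centers,
         candidates = candidates, cf = cf, contrast = contrast)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })

  stage <- "write"
  stamp <- list(package_version = version, config_fingerprint = fingerprint)
  write_tsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  for (h in c("L", "R")) {
    write_surface(res$data$meshes[[h]],
                  file.path(out_dir, paste0("mesh_", h, ".surf.gii")))
    write_distances(res$dists[[h]],
                    file.path(out_dir, paste0("dists_", h, ".tsv")))
    write_tsv(res$prf[[h]], paste0("prf_", h, ".tsv"))
  }
  write_tsv(res$data$cf_gt, "ground_truth_cf.tsv")
  for (cond in names(res$cf)) {
    write_tsv(res$cf[[cond]]$summary, paste0("cf_", cond, ".tsv"))
    write_tsv(res$cf[[cond]]$folds, paste0("cf_", cond, "_folds.tsv"))
  }
  if (!is.null(res$contrast)) {
    write_tsv(res$contrast$table, "contrast.tsv")
    jsonlite::write_json(
      c(stamp, list(
        sigma_correlation = res$contrast$sigma_correlation,
        ecc_correlation = res$contrast$ecc_correlation,
        laterality = res$contrast$laterality
      )),
      file.path(out_dir, "stats.json"), auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(c(stamp, list(config = unclass(config))),
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  res$paths <- list(out_dir = out_dir, log = log_path)
  invisible(res)
}
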