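#' Default synthetic-study configuration
#'
#' Parameters of the in-silico study the generator emulates: two hemispheres
#' of a retinotopically organized source sheet (planar stand-ins for V1),
#' stimulus-driven or resting-state source dynamics, and target vertices
#' coupled to the sheet through Gaussian connective fields plus a global
#' (mean-signal) nuisance component, acquired over several runs.
#'
#' Defaults: ~500 source vertices per hemisphere (22 x 23 grid, 2-mm
#' spacing), 200 targets, 4 runs of 300 timepoints at 1 Hz, noise SD 1.5
#' z-units (which puts target within-set r^2 near 0.3), planted CF size 5 mm,
#' resting-state spatial correlation length 4 mm.
#'
#' @param ... named overrides of any default field; unknown names error.
#' @return A list of class `cf_synth_config`.
#' @export
synthetic_config <- function(...) {
  cfg <- list(
    mesh_rows = 22L,
    mesh_cols = 23L,
    vertex_spacing = 2,          # mm
    n_runs = 4L,
    n_timepoints_per_run = 300L,
    sampling_rate = 1,           # Hz
    noise_sd = 1.5,              # z units
    global_coupling = 0.3,       # weight of mean-source nuisance in targets
    source_global = 0.5,         # z-units: brain-wide signal shared by all
                                 # source vertices of both hemispheres (the
                                 # arousal-like component the null model is
                                 # built to absorb)
    spatial_corr_length = 4,     # mm, resting-state latent field
    n_targets = 200L,
    n_null_targets = 0L,
    target_sigma_cf = 5,         # mm, planted CF size (member of the σ grid)
    signal_amplitude = 1,        # gain of the CF-driven target component
    ecc_range = c(0.5, 8),       # deg, planted eccentricity span
    angle_range = c(-80, 80),    # deg, planted polar-angle span (hemifield)
    prf_sigma_intercept = 0.2,   # deg, planted pRF size at fixation
    prf_sigma_slope = 0.2,       # pRF size growth per deg eccentricity
    field_radius = 8,            # deg, stimulus aperture radius
    aperture_grid_res = 101L,
    seed = 1L
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
    cfg[names(over)] <- over
  }
  stopifnot(
    cfg$mesh_rows >= 2, cfg$mesh_cols >= 2, cfg$vertex_spacing > 0,
    cfg$n_runs >= 1, cfg$n_timepoints_per_run >= 1, cfg$sampling_rate > 0,
    cfg$noise_sd >= 0, cfg$n_targets >= 1, cfg$n_null_targets >= 0
  )
  class(cfg) <- "cf_synth_config"
  cfg
}

#' Derive a reproducible sub-seed for a named random stream
#'
#' All randomness in the generator and pipeline flows from one root seed,
#' expanded into independent named streams so that stages can be re-run in
#' isolation without perturbing each other.
#'
#' @param root integer root seed.
#' @param name character stream name.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
stream_seed <- function(root, name) {
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% 2147483647
  as.integer((as.numeric(root) * 2654435761 + h) %% 2147483647)
}

#' Plant a retinotopic map on a grid mesh
#'
#' Assigns each source vertex a population receptive field: eccentricity
#' varies linearly along the grid columns, polar angle along the rows, and
#' pRF size grows linearly with eccentricity, as in early visual cortex.
#' Left-hemisphere maps cover the right visual hemifield (x0 >= 0) and vice
#' versa, mirroring cortical contralaterality.
#'
#' @param mesh a grid mesh from [make_mesh()].
#' @param ecc_range length-2 numeric, degrees, eccentricity at the first and
#'   last grid column.
#' @param angle_range length-2 numeric, degrees, polar angle (relative to the
#'   horizontal meridian of the contralateral hemifield) at the first and
#'   last grid row; must stay within (-90, 90) so the map remains
#'   contralateral.
#' @param sigma_intercept,sigma_slope linear pRF-size model
#'   `sigma = sigma_intercept + sigma_slope * eccentricity` (deg).
#' @return data.frame with one row per vertex: `vertex`, `x0`, `y0`, `sigma`
#'   (deg), `ecc`, `angle` (deg, atan2 convention) and `hemisphere`.
#' @export
make_retinotopic_map <- function(mesh, ecc_range = c(0.5, 8),
                                 angle_range = c(-80, 80),
                                 sigma_intercept = 0.2, sigma_slope = 0.2) {
  if (is.null(mesh$grid)) stop("make_retinotopic_map needs a grid mesh")
  if (nrow(mesh$vertices) == 0L) stop("empty mesh")
  rows <- mesh$grid$rows; cols <- mesh$grid$cols
  col_i <- rep(seq_len(cols), times = rows)
  row_i <- rep(seq_len(rows), each = cols)
  ecc <- ecc_range[1] + (col_i - 1) * diff(ecc_range) / (cols - 1)
  th <- angle_range[1] + (row_i - 1) * diff(angle_range) / (rows - 1)
  if (any(abs(th) >= 90)) stop("angle_range must lie within (-90, 90)")
  # th is measured from the horizontal meridian of the contralateral hemifield
  ang <- if (mesh$hemisphere == "L") th else 180 - th
  x0 <- ecc * cospi(ang / 180)
  y0 <- ecc * sinpi(ang / 180)
  data.frame(
    vertex = seq_len(rows * cols),
    x0 = x0, y0 = y0,
    sigma = sigma_intercept + sigma_slope * ecc,
    ecc = ecc, angle = atan2(y0, x0) * 180 / pi,
    hemisphere = mesh$hemisphere
  )
}

#' Build a retinotopic stimulus aperture movie
#'
#' Binary frames on a square visual-field grid: either a bar that sweeps the
#' field in four directions (right, up, left, down) or a wedge that rotates
#' through a full cycle. Optional blank padding frames at the start and end.
#'
#' @param kind `"bar"` or `"wedge"`.
#' @param field_radius aperture radius in degrees.
#' @param n_frames total number of frames (including padding).
#' @param grid_res pixels per side of the square grid (default 101).
#' @param pad_frames blank frames prepended and appended (default 0).
#' @param bar_width bar width in degrees (default `field_radius / 4`).
#' @param wedge_width wedge angular width in degrees (default 45).
#' @return An object of class `cf_aperture`: list with `frames` (array
#'   `grid_res x grid_res x n_frames`, 0/1), `x`, `y` (pixel-center
#'   coordinates in degrees, x right-positive, y up-positive, origin at
#'   fixation), `radius`, `kind`.
#' @export
make_aperture <- function(kind = c("bar", "wedge"), field_radius = 8,
                          n_frames = 300, grid_res = 101, pad_frames = 0,
                          bar_width = field_radius / 4, wedge_width = 45) {
  kind <- match.arg(kind)
  if (n_frames < 1) stop("n_frames must be >= 1")
  active <- n_frames - 2L * pad_frames
  if (active < 1) stop("padding leaves no active frames")
  gx <- seq(-field_radius, field_radius, length.out = grid_res)
  px <- matrix(gx, grid_res, grid_res, byrow = TRUE)       # x per pixel
  py <- matrix(rev(gx), grid_res, grid_res, byrow = FALSE) # y up-positive
  in_disk <- (px^2 + py^2) <= field_radius^2
  frames <- array(0, dim = c(grid_res, grid_res, n_frames))
  if (kind == "bar") {
    dirs <- rbind(c(1, 0), c(0, 1), c(-1, 0), c(0, -1))
    per <- diff(round(seq(0, active, length.out = 5L)))
    fr <- pad_frames
    for (s in 1:4) {
      nf <- per[s]
      proj <- dirs[s, 1] * px + dirs[s, 2] * py
      pos <- seq(-field_radius, field_radius, length.out = nf)
      for (k in seq_len(nf)) {
        frames[, , fr + k] <- in_disk & (abs(proj - pos[k]) <= bar_width / 2)
      }
      fr <- fr + nf
    }
  } else {
    pa <- atan2(py, px) * 180 / pi
    centers <- seq(0, 360, length.out = active + 1L)[seq_len(active)]
    for (k in seq_len(active)) {
      dang <- (pa - centers[k] + 180) %% 360 - 180
      frames[, , pad_frames + k] <- in_disk & (abs(dang) <= wedge_width / 2)
    }
  }
  structure(
    list(frames = frames, x = gx, y = rev(gx), radius = field_radius,
         kind = kind),
    class = "cf_aperture"
  )
}

# frames flattened to pixels x time (sparse: apertures are mostly blank),
# plus matching pixel coordinate vectors
aperture_flat <- function(aperture) {
  d <- dim(aperture$frames)
  px <- rep(aperture$x, each = d[1])
  py <- rep(aperture$y, times = d[2])
  fl <- Matrix::Matrix(matrix(aperture$frames, d[1] * d[2], d[3]),
                       sparse = TRUE)
  list(frames = fl, px = px, py = py)
}

#' Simulate source-sheet BOLD time courses
#'
#' Stimulated mode: each vertex responds with the overlap of its planted
#' Gaussian pRF and the aperture frame (the linear pRF model), z-scored, plus
#' white noise. Resting mode: a latent spatiotemporal field made by smoothing
#' white noise across the sheet with a Gaussian kernel of length scale
#' `spatial_corr_length`, z-scored, plus white noise — topographic structure
#' arising from the sheet's internal organization rather than a stimulus.
#'
#' @param mesh source mesh (one hemisphere).
#' @param ground_truth pRF table from [make_retinotopic_map()] for this mesh.
#' @param config a [synthetic_config()].
#' @param aperture a [make_aperture()] movie; required in stimulated mode.
#' @param resting logical; `TRUE` selects resting mode.
#' @param stream name prefix for the random streams (default derived from
#'   hemisphere and mode) so that different conditions get independent noise.
#' @param global_stream name of the random stream for the shared brain-wide
#'   component (weight `config$source_global`); both hemispheres of one
#'   condition must be simulated with the same `global_stream` so they share
#'   it. `NULL` (default) disables the shared component.
#' @return List of `config$n_runs` matrices, vertices x timepoints.
#' @export
simulate_source <- function(mesh, ground_truth, config, aperture = NULL,
                            resting = FALSE, stream = NULL,
                            global_stream = NULL) {
  if (nrow(ground_truth) != nrow(mesh$vertices)) {
    stop("ground truth must cover all mesh vertices")
  }
  if (!resting && is.null(aperture)) {
    stop("stimulated mode requires an aperture")
  }
  n_t <- config$n_timepoints_per_run
  nv <- nrow(mesh$vertices)
  if (is.null(stream)) {
    stream <- paste0("source-", mesh$hemisphere, if (resting) "-rest" else "-stim")
  }
  if (!resting) {
    ap <- aperture_flat(aperture)
    if (ncol(ap$frames) != n_t) {
      stop("aperture has ", ncol(ap$frames), " frames but runs have ", n_t,
           " timepoints")
    }
    g <- prf_gaussians(ground_truth$x0, ground_truth$y0, ground_truth$sigma,
                       ap$px, ap$py)
    clean <- zscore(t(as.matrix(Matrix::crossprod(ap$frames, g))))  # vertices x time
  } else {
    eu <- as.matrix(stats::dist(mesh$vertices))
    K <- exp(-eu^2 / (2 * config$spatial_corr_length^2))
  }
  lapply(seq_len(config$n_runs), function(run) {
    g <- 0
    if (!is.null(global_stream) && config$source_global > 0) {
      set.seed(stream_seed(config$seed, paste0(global_stream, "-run", run)))
      g <- config$source_global * stats::rnorm(n_t)
    }
    set.seed(stream_seed(config$seed, paste0(stream, "-run", run)))
    if (resting) {
      # local field: smoothed white noise with its per-timepoint spatial mean
      # removed, so the sheet-wide common signal lives entirely in the shared
      # global component and the field carries only spatial structure
      lat <- K %*% matrix(stats::rnorm(nv * n_t), nv, n_t)
      lat <- sweep(lat, 2, colMeans(lat))
      clean <- zscore(lat)
    }
    sweep(clean + config$noise_sd * matrix(stats::rnorm(nv * n_t), nv, n_t),
          2, g, "+")
  })
}

#' Plant connective-field ground truth for target vertices
#'
#' Assigns each target a hemisphere, a CF center vertex `v0` on that
#' hemisphere's source sheet, a CF size, and flags a designated subset as
#' "null targets" that will be driven only by the mean source signal (the
#' nontopographic nuisance the null model is built to absorb). Targets are
#' coupled to their own hemisphere's sheet, so their visual-field
#' representation is contralateral by construction.
#'
#' @param meshes named list with elements `L` and `R` (source meshes).
#' @param config a [synthetic_config()].
#' @return data.frame: `target`, `hemisphere`, `v0` (index into that
#'   hemisphere's source vertices), `sigma_cf` (mm), `amplitude`, `is_null`.
#' @export
make_cf_ground_truth <- function(meshes, config) {
  n <- config$n_targets
  set.seed(stream_seed(config$seed, "cf-ground-truth"))
  hemi <- sample(c("L", "R"), n, replace = TRUE)
  v0 <- vapply(hemi, function(h) {
    sample.int(nrow(meshes[[h]]$vertices), 1L)
  }, integer(1))
  is_null <- rep(FALSE, n)
  if (config$n_null_targets > 0) {
    is_null[sample.int(n, min(config$n_null_targets, n))] <- TRUE
  }
  data.frame(
    target = seq_len(n),
    hemisphere = hemi,
    v0 = unname(v0),
    sigma_cf = config$target_sigma_cf,
    amplitude = config$signal_amplitude,
    is_null = is_null
  )
}

#' Simulate target time courses coupled to the source sheet
#'
#' Each target's signal is the z-scored Gaussian-CF-weighted sum of its
#' hemisphere's source time courses (weights
#' `exp(-d^2 / (2 sigma_cf^2))` over geodesic distance from `v0`), scaled by
#' its amplitude, plus `global_coupling` times the z-scored mean source
#' signal of both hemispheres, plus white noise. Null targets receive only
#' the mean-signal component plus noise.
#'
#' @param source_tcs named list (`L`, `R`) of per-run source matrices, as
#'   returned by [simulate_source()] for each hemisphere.
#' @param ground_truth table from [make_cf_ground_truth()].
#' @param meshes named list (`L`, `R`) of source meshes (used for the planar
#'   source-sheet distances defining the planted kernels).
#' @param config a [synthetic_config()].
#' @param stream random-stream name prefix (default `"targets"`).
#' @return List of per-run matrices, targets x timepoints.
#' @export
simulate_targets <- function(source_tcs, ground_truth, meshes, config,
                             stream = "targets") {
  n_runs <- length(source_tcs$L)
  if (n_runs < 1 || length(source_tcs$R) != n_runs) {
    stop("source time courses must exist for every run in both hemispheres")
  }
  w_by_target <- lapply(seq_len(nrow(ground_truth)), function(i) {
    h <- ground_truth$hemisphere[i]
    nv <- nrow(meshes[[h]]$vertices)
    if (ground_truth$v0[i] < 1 || ground_truth$v0[i] > nv) {
      stop("ground-truth v0 out of range for target ", i)
    }
    d <- sqrt(colSums((t(meshes[[h]]$vertices) -
                         meshes[[h]]$vertices[ground_truth$v0[i], ])^2))
    exp(-d^2 / (2 * ground_truth$sigma_cf[i]^2))
  })
  lapply(seq_len(n_runs), function(run) {
    s_l <- source_tcs$L[[run]]
    s_r <- source_tcs$R[[run]]
    mean_src <- zscore(colMeans(rbind(s_l, s_r)))
    set.seed(stream_seed(config$seed, paste0(stream, "-run", run)))
    out <- matrix(0, nrow(ground_truth), ncol(s_l))
    for (i in seq_len(nrow(ground_truth))) {
      if (ground_truth$is_null[i]) {
        sig <- mean_src
      } else {
        s <- if (ground_truth$hemisphere[i] == "L") s_l else s_r
        sig <- ground_truth$amplitude[i] *
          zscore(as.vector(w_by_target[[i]] %*% s)) +
          config$global_coupling * mean_src
      }
      out[i, ] <- sig + config$noise_sd * stats::rnorm(ncol(s_l))
    }
    out
  })
}

#' Generate a complete synthetic study
#'
#' Builds both hemisphere meshes, planted retinotopic maps, the stimulus
#' aperture, source time courses per condition, and CF-coupled targets. The
#' `retinotopy` condition uses stimulated-mode sources; `rest` and `movie`
#' use resting-mode sources with independent random streams (the generator
#' has no naturalistic-movie model; what matters downstream is that the two
#' states share the planted coupling but none of the noise). All conditions
#' share one CF ground truth, so cross-state stability of fitted parameters
#' can be measured against a common reference.
#'
#' @param config a [synthetic_config()].
#' @param conditions subset of `c("retinotopy", "rest", "movie")`.
#' @return List of class `cf_synth_data` with `meshes`, `prf_gt`
#'   (per-hemisphere pRF tables), `aperture`, `cf_gt`, `source`
#'   (condition -> hemisphere -> run matrices) and `targets`
#'   (condition -> run matrices).
#' @export
simulate_dataset <- function(config = synthetic_config(),
                             conditions = c("retinotopy", "rest", "movie")) {
  conditions <- match.arg(conditions, several.ok = TRUE)
  meshes <- list(
    L = make_mesh(config$mesh_rows, config$mesh_cols, config$vertex_spacing, "L"),
    R = make_mesh(config$mesh_rows, config$mesh_cols, config$vertex_spacing, "R")
  )
  prf_gt <- lapply(meshes, make_retinotopic_map,
                   ecc_range = config$ecc_range,
                   angle_range = config$angle_range,
                   sigma_intercept = config$prf_sigma_intercept,
                   sigma_slope = config$prf_sigma_slope)
  aperture <- make_aperture("bar", field_radius = config$field_radius,
                            n_frames = config$n_timepoints_per_run,
                            grid_res = config$aperture_grid_res)
  cf_gt <- make_cf_ground_truth(meshes, config)
  source <- list(); targets <- list()
  for (cond in conditions) {
    resting <- cond != "retinotopy"
    src <- list(
      L = simulate_source(meshes$L, prf_gt$L, config,
                          aperture = aperture, resting = resting,
                          stream = paste0("source-L-", cond),
                          global_stream = paste0("global-", cond)),
      R = simulate_source(meshes$R, prf_gt$R, config,
                          aperture = aperture, resting = resting,
                          stream = paste0("source-R-", cond),
                          global_stream = paste0("global-", cond))
    )
    source[[cond]] <- src
    targets[[cond]] <- simulate_targets(src, cf_gt, meshes, config,
                                        stream = paste0("targets-", cond))
  }
  structure(
    list(config = config, meshes = meshes, prf_gt = prf_gt,
         aperture = aperture, cf_gt = cf_gt, source = source,
         targets = targets),
    class = "cf_synth_data"
  )
}
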