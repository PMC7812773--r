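#' Canonical double-gamma hemodynamic response function
#'
#' SPM-style difference of two gamma densities (peak ~5 s, undershoot ~15 s),
#' sampled at `sampling_rate` over `duration` seconds and scaled to unit
#' peak. Used (optionally) to convolve pRF predictions; the connective-field
#' stage never convolves.
#'
#' @param sampling_rate Hz.
#' @param duration length of the kernel in seconds (default 32).
#' @return Numeric vector of kernel samples.
#' @export
hrf_double_gamma <- function(sampling_rate = 1, duration = 32) {
  t <- seq(0, duration, by = 1 / sampling_rate)
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / max(h)
}

# causal convolution, truncated to input length
conv_causal <- function(x, kernel) {
  n <- length(x)
  out <- stats::convolve(x, rev(kernel), type = "open")[seq_len(n)]
  out
}

# pixels x vertices matrix of Gaussian receptive fields (linear pRF model)
prf_gaussians <- function(x0, y0, sigma, px, py) {
  if (any(sigma <= 0)) stop("sigma must be > 0")
  d2 <- outer(px^2 + py^2, x0^2 + y0^2, "+") -
    2 * (outer(px, x0) + outer(py, y0))
  exp(sweep(d2, 2, -2 * sigma^2, "/"))
}

#' Predict a time course from pRF parameters
#'
#' The linear Gaussian pRF model: per frame, the sum over aperture pixels of
#' the stimulus mask times a 2D Gaussian at (`x0`, `y0`) with spread `sigma`,
#' scaled by `amplitude` and offset by `baseline`. Optionally convolved with
#' a canonical hemodynamic response.
#'
#' @param params list or one-row data.frame with `x0`, `y0`, `sigma` (deg)
#'   and optionally `amplitude` (default 1) and `baseline` (default 0).
#' @param aperture a [make_aperture()] object.
#' @param hrf `NULL` for no convolution (default), or a kernel vector such as
#'   [hrf_double_gamma()].
#' @return Numeric vector, one value per aperture frame.
#' @export
prf_predict <- function(params, aperture, hrf = NULL) {
  if (params$sigma <= 0) stop("sigma must be > 0")
  amplitude <- if (is.null(params$amplitude)) 1 else params$amplitude
  baseline <- if (is.null(params$baseline)) 0 else params$baseline
  ap <- aperture_flat(aperture)
  g <- prf_gaussians(params$x0, params$y0, params$sigma, ap$px, ap$py)
  pred <- as.vector(Matrix::crossprod(ap$frames, g))
  if (!is.null(hrf)) pred <- conv_causal(pred, hrf)
  amplitude * pred + baseline
}

#' Default pRF search grids
#'
#' Coarse grids spanning the stimulus aperture: 11 x 11 positions over
#' `[-radius, radius]` and six log-spaced sizes from 0.25 deg to half the
#' aperture radius. Declared here (not in the method's source) so runs can
#' log the exact grids they used.
#'
#' @param field_radius aperture radius in degrees.
#' @return List with `x0`, `y0`, `sigma` grid vectors.
#' @export
prf_default_grids <- function(field_radius) {
  list(
    x0 = seq(-field_radius, field_radius, length.out = 11),
    y0 = seq(-field_radius, field_radius, length.out = 11),
    sigma = exp(seq(log(0.25), log(field_radius / 2), length.out = 6))
  )
}

#' Grid-stage pRF fit
#'
#' For every vertex, evaluates all combinations of the `x0`/`y0`/`sigma`
#' grids and keeps the one maximizing within-set variance explained (squared
#' correlation between data and prediction), with amplitude and baseline
#' fitted by least squares given the prediction. Ties are broken by the first
#' grid combination in `expand.grid(x0, y0, sigma)` order (x0 varying
#' fastest). Vertices for which every grid prediction is constant are flagged
#' with `r2 = 0`.
#'
#' @param tc matrix, vertices x timepoints (same sampling as the aperture
#'   frames).
#' @param aperture a [make_aperture()] object.
#' @param grids list with `x0`, `y0`, `sigma` vectors (default
#'   [prf_default_grids()] at the aperture radius).
#' @param hrf optional hemodynamic kernel applied to predictions.
#' @return data.frame: `vertex`, `x0`, `y0`, `sigma`, `amplitude`,
#'   `baseline`, `r2`, `flagged`.
#' @export
prf_grid_fit <- function(tc, aperture, grids = NULL, hrf = NULL) {
  tc <- as_tc_matrix(tc)
  if (is.null(grids)) grids <- prf_default_grids(aperture$radius)
  stopifnot(length(grids$x0) > 0, length(grids$y0) > 0, length(grids$sigma) > 0)
  combos <- expand.grid(x0 = grids$x0, y0 = grids$y0, sigma = grids$sigma,
                        KEEP.OUT.ATTRS = FALSE)
  ap <- aperture_flat(aperture)
  if (ncol(ap$frames) != ncol(tc)) {
    stop("aperture frame count (", ncol(ap$frames),
         ") does not match timepoints (", ncol(tc), ")")
  }
  g <- prf_gaussians(combos$x0, combos$y0, combos$sigma, ap$px, ap$py)
  pred <- as.matrix(Matrix::crossprod(ap$frames, g))  # time x combos
  if (!is.null(hrf)) pred <- apply(pred, 2, conv_causal, kernel = hrf)
  pm <- colMeans(pred)
  pc <- sweep(pred, 2, pm)
  pnorm2 <- colSums(pc^2)
  usable <- pnorm2 > .Machine$double.eps * nrow(pred)
  dm <- rowMeans(tc)
  dc <- tc - dm
  dnorm2 <- rowSums(dc^2)
  # squared correlations, vertices x combos
  num <- dc %*% pc
  r2 <- num^2 / outer(dnorm2, pnorm2)
  r2[, !usable] <- -Inf
  r2[dnorm2 == 0, ] <- -Inf
  best <- max.col(r2, ties.method = "first")
  ib <- cbind(seq_len(nrow(tc)), best)
  beta <- num[ib] / pnorm2[best]
  out <- data.frame(
    vertex = seq_len(nrow(tc)),
    x0 = combos$x0[best], y0 = combos$y0[best], sigma = combos$sigma[best],
    amplitude = beta,
    baseline = dm - beta * pm[best],
    r2 = r2[ib],
    flagged = FALSE
  )
  bad <- !is.finite(out$r2)
  if (any(bad)) {
    out$r2[bad] <- 0
    out$amplitude[bad] <- 0
    out$baseline[bad] <- dm[bad]
    out$flagged[bad] <- TRUE
  }
  out
}

#' Iterative pRF refinement (bounded quasi-Newton)
#'
#' Refines the grid-stage (`x0`, `y0`, `sigma`) per vertex with L-BFGS-B,
#' profiling amplitude and baseline out by least squares at every objective
#' evaluation. If the optimizer fails or ends below the grid-stage fit, the
#' grid parameters are returned and the vertex is flagged.
#'
#' @param tc matrix, vertices x timepoints.
#' @param aperture a [make_aperture()] object.
#' @param init data.frame from [prf_grid_fit()] (one row per vertex of `tc`).
#' @param bounds list with `x0`, `y0`, `sigma` length-2 ranges; default
#'   positions within 1.5x the aperture radius and sigma in
#'   `[0.05, 2 * radius]`.
#' @param hrf optional hemodynamic kernel.
#' @return data.frame like [prf_grid_fit()]'s, with refined parameters.
#' @export
prf_iterative_fit <- function(tc, aperture, init, bounds = NULL, hrf = NULL) {
  tc <- as_tc_matrix(tc)
  stopifnot(nrow(init) == nrow(tc))
  if (is.null(bounds)) {
    r <- aperture$radius
    bounds <- list(x0 = c(-1.5 * r, 1.5 * r), y0 = c(-1.5 * r, 1.5 * r),
                   sigma = c(0.05, 2 * r))
  }
  ap <- aperture_flat(aperture)
  lower <- c(bounds$x0[1], bounds$y0[1], bounds$sigma[1])
  upper <- c(bounds$x0[2], bounds$y0[2], bounds$sigma[2])
  out <- init
  for (i in seq_len(nrow(tc))) {
    d <- tc[i, ]
    dc <- d - mean(d)
    dn2 <- sum(dc^2)
    if (dn2 == 0 || init$flagged[i]) next
    obj <- function(par) {
      gp <- exp(-((ap$px - par[1])^2 + (ap$py - par[2])^2) / (2 * par[3]^2))
      p <- as.vector(Matrix::crossprod(ap$frames, gp))
      if (!is.null(hrf)) p <- conv_causal(p, hrf)
      pc <- p - mean(p)
      pn2 <- sum(pc^2)
      if (pn2 < .Machine$double.eps) return(1)
      1 - sum(dc * pc)^2 / (dn2 * pn2)  # 1 - r^2
    }
    start <- pmin(pmax(c(init$x0[i], init$y0[i], init$sigma[i]), lower), upper)
    fit <- tryCatch(
      stats::optim(start, obj, method = "L-BFGS-B", lower = lower,
                   upper = upper),
      error = function(e) NULL
    )
    if (is.null(fit) || (1 - fit$value) < init$r2[i] - 1e-9) {
      out$flagged[i] <- TRUE
      next
    }
    par <- fit$par
    gp <- exp(-((ap$px - par[1])^2 + (ap$py - par[2])^2) / (2 * par[3]^2))
    p <- as.vector(Matrix::crossprod(ap$frames, gp))
    if (!is.null(hrf)) p <- conv_causal(p, hrf)
    pc <- p - mean(p)
    beta <- sum(dc * pc) / sum(pc^2)
    out$x0[i] <- par[1]; out$y0[i] <- par[2]; out$sigma[i] <- par[3]
    out$amplitude[i] <- beta
    out$baseline[i] <- mean(d) - beta * mean(p)
    out$r2[i] <- 1 - fit$value
  }
  out
}

#' Select eligible connective-field center vertices
#'
#' A source vertex may serve as a CF center only if its pRF fit is credible:
#' within-set R^2 above threshold, peak position inside the stimulus aperture
#' (eccentricity of (`x0`, `y0`) at most the aperture radius), and positive
#' amplitude. Order of the surviving vertices is preserved.
#'
#' @param prfs data.frame from the pRF fit (per source vertex).
#' @param aperture a [make_aperture()] object (supplies the radius).
#' @param r2_threshold eligibility threshold on within-set R^2 (default 0.2,
#'   exclusive: a vertex must exceed it).
#' @return Integer vector of eligible vertex indices.
#' @export
select_cf_centers <- function(prfs, aperture, r2_threshold = 0.2) {
  keep <- prfs$r2 > r2_threshold &
    sqrt(prfs$x0^2 + prfs$y0^2) <= aperture$radius &
    prfs$amplitude > 0
  idx <- prfs$vertex[keep]
  if (length(idx) == 0L) {
    stop("no eligible CF centers; review the R^2 threshold (",
         r2_threshold, ") and the pRF fits")
  }
  idx
}
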