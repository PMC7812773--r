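#' Savitzky-Golay high-pass filter
#'
#' Removes slow drifts from per-vertex BOLD time courses by subtracting a
#' Savitzky-Golay smoothed trend (third-order polynomial over a 210-s window
#' by default). Subtracting the smooth is the standard detrending use of the
#' filter: the residual keeps fluctuations faster than the window period and
#' suppresses slower ones. Filtering is applied per run; never concatenate
#' runs before calling this.
#'
#' @param x numeric matrix, vertices x timepoints, one run.
#' @param sampling_rate sampling rate in Hz.
#' @param window_period trend window length in seconds (default 210). The
#'   window is converted to an odd number of samples at `sampling_rate`.
#' @param polyorder polynomial order of the fit (default 3).
#' @return Matrix of the same shape: `x` minus its smoothed trend.
#' @export
highpass_savgol <- function(x, sampling_rate, window_period = 210,
                            polyorder = 3) {
  x <- as_tc_matrix(x)
  n <- ncol(x)
  win <- round(window_period * sampling_rate)
  if (win %% 2 == 0) win <- win + 1L
  if (win <= polyorder) {
    stop("filter window (", win, " samples) must exceed polyorder ",
         polyorder)
  }
  if (win > n) {
    stop("run (", n, " samples) is shorter than the ", window_period,
         "-s filter window (", win, " samples); pass a shorter ",
         "window_period explicitly if this is intended")
  }
  x - savgol_trend(x, polyorder, win)
}

# Savitzky-Golay smoothing of every row of a matrix. Equivalent to running
# signal::sgolayfilt row by row, but the projection matrix is built once:
# interior samples are a symmetric FIR convolution with the central
# projection row, the first and last half-windows use the off-center rows.
savgol_trend <- function(x, p, n) {
  fm <- signal::sgolay(p = p, n = n)
  fm <- matrix(as.numeric(fm), n, n)
  m <- (n + 1L) / 2L
  n_t <- ncol(x)
  y <- t(stats::filter(t(x), fm[m, ], method = "convolution", sides = 2))
  y <- matrix(as.numeric(y), nrow(x), n_t)
  head_rows <- fm[seq_len(m - 1L), , drop = FALSE]
  tail_rows <- fm[seq(m + 1L, n), , drop = FALSE]
  y[, seq_len(m - 1L)] <- x[, seq_len(n), drop = FALSE] %*% t(head_rows)
  y[, seq(n_t - m + 2L, n_t)] <-
    x[, seq(n_t - n + 1L, n_t), drop = FALSE] %*% t(tail_rows)
  y
}

#' z-score time courses over time
#'
#' Per vertex: subtract the temporal mean and divide by the population
#' (divide-by-N) standard deviation. Constant vertices map to all zeros
#' instead of dividing by zero.
#'
#' @param x numeric matrix, vertices x timepoints (a plain vector is treated
#'   as a single vertex).
#' @return Matrix of the same shape with per-vertex mean 0 and SD 1 (or all
#'   zeros for constant rows).
#' @export
zscore <- function(x) {
  vec <- is.null(dim(x))
  x <- as_tc_matrix(x)
  m <- rowMeans(x)
  xc <- x - m
  s <- sqrt(rowMeans(xc^2))
  s[s == 0] <- Inf  # constant rows -> zeros
  out <- xc / s
  if (vec) as.vector(out) else out
}

#' Preprocess one run
#'
#' The preprocessing applied identically to every experiment type:
#' Savitzky-Golay high-pass filtering followed by z-scoring over time.
#'
#' @inheritParams highpass_savgol
#' @return Preprocessed matrix, vertices x timepoints, in z units.
#' @export
preprocess_run <- function(x, sampling_rate, window_period = 210,
                           polyorder = 3) {
  zscore(highpass_savgol(x, sampling_rate, window_period, polyorder))
}

as_tc_matrix <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  x
}
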