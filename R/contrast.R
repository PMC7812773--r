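#' Translate CF fits into visual-field coordinates
#'
#' The source sheet's retinotopic map anchors every CF center to a position
#' in visual space: a target's represented location is the pRF position of
#' its best-fitting CF center vertex, and its hemifield is the contralateral
#' hemifield of the CF's hemisphere (left-hemisphere V1 represents the right
#' visual field and vice versa).
#'
#' @param cf data.frame of CF fits (columns `v0`, `hemisphere`; e.g. the
#'   `summary` of [cf_crossvalidate()]).
#' @param prfs named list (`L`, `R`) of per-source-vertex pRF tables with
#'   columns `vertex`, `x0`, `y0`.
#' @return data.frame: `target`, `x0`, `y0`, `ecc` (deg), `angle` (deg),
#'   `hemifield` (`"L"`/`"R"`), `hemisphere` (of the CF).
#' @export
cf_to_visual_field <- function(cf, prfs) {
  n <- nrow(cf)
  x0 <- y0 <- rep(NA_real_, n)
  for (h in c("L", "R")) {
    rows <- which(cf$hemisphere == h)
    if (length(rows) == 0) next
    j <- match(cf$v0[rows], prfs[[h]]$vertex)
    if (anyNA(j)) {
      stop("no pRF for CF center vertex ",
           cf$v0[rows][which(is.na(j))[1]], " (hemisphere ", h, ")")
    }
    x0[rows] <- prfs[[h]]$x0[j]
    y0[rows] <- prfs[[h]]$y0[j]
  }
  data.frame(
    target = if (!is.null(cf$target)) cf$target else seq_len(n),
    x0 = x0, y0 = y0,
    ecc = sqrt(x0^2 + y0^2),
    angle = atan2(y0, x0) * 180 / pi,
    hemifield = ifelse(is.na(cf$hemisphere), NA_character_,
                       ifelse(cf$hemisphere == "L", "R", "L")),
    hemisphere = cf$hemisphere
  )
}

#' Normalized resting-state vs. movie-watching preference ratio
#'
#' `rho_rs / (rho_rs + rho_mw)` over null-model-corrected cross-validated
#' correlations: 0.5 means equal retinotopic connectivity in both
#' conditions, values above 0.5 a resting-state preference. Because the
#' constituents are null-corrected, nontopographic condition differences
#' (e.g. arousal) do not move the ratio. Negative corrected values are
#' clamped to zero first — the ratio is only meaningful over nonnegative
#' constituents — and entries whose clamped denominator falls below `floor`
#' are returned as `NA` (masked) rather than divided out.
#'
#' @param rho_rs,rho_mw corrected correlations for the resting-state and
#'   movie-watching conditions (vectorized).
#' @param floor minimal clamped denominator for a defined ratio
#'   (default 0.01).
#' @return Numeric vector in `[0, 1]`, `NA` where masked.
#' @export
rc_preference_ratio <- function(rho_rs, rho_mw, floor = 0.01) {
  rs <- pmax(rho_rs, 0)
  mw <- pmax(rho_mw, 0)
  den <- rs + mw
  out <- ifelse(den < floor, NA_real_, rs / den)
  out[is.na(rho_rs) | is.na(rho_mw)] <- NA_real_
  out
}

# Kish effective sample size of a weight vector
effective_n <- function(w) sum(w)^2 / sum(w^2)

#' Weighted Pearson correlation with weighting-adjusted degrees of freedom
#'
#' Correlation between `x` and `y` under observation weights `w` (here
#' typically null-model-corrected correlation values, so that poorly
#' explained vertices contribute little). The t-test uses the Kish effective
#' sample size `(sum w)^2 / sum(w^2)` in place of n, shrinking the degrees
#' of freedom when weights are uneven; with uniform weights the statistic
#' reduces exactly to the classical Pearson test.
#'
#' @param x,y numeric vectors, equal length.
#' @param w nonnegative weights, not all zero.
#' @return List with `rho`, `t`, `df`, `p`, `n_eff`.
#' @export
weighted_correlation <- function(x, y, w) {
  stopifnot(length(x) == length(y), length(x) == length(w))
  keep <- !(is.na(x) | is.na(y) | is.na(w))
  x <- x[keep]; y <- y[keep]; w <- w[keep]
  if (any(w < 0)) stop("weights must be nonnegative")
  if (sum(w) <= 0) stop("weights must not all be zero")
  mx <- sum(w * x) / sum(w)
  my <- sum(w * y) / sum(w)
  cov <- sum(w * (x - mx) * (y - my))
  vx <- sum(w * (x - mx)^2)
  vy <- sum(w * (y - my)^2)
  rho <- cov / sqrt(vx * vy)
  n_eff <- effective_n(w)
  df <- n_eff - 2
  if (df <= 0) stop("effective sample size too small for a test")
  t <- rho * sqrt(df / max(1 - rho^2, .Machine$double.eps))
  list(rho = rho, t = t, df = df,
       p = 2 * stats::pt(-abs(t), df), n_eff = n_eff)
}

#' Weighted paired t-test with weighting-adjusted degrees of freedom
#'
#' Tests whether the paired differences `a - b` have zero mean under
#' observation weights `w`. The weighted variance uses the reliability-
#' weights correction `sum(w) - sum(w^2)/sum(w)` in the denominator and the
#' standard error uses the Kish effective sample size, so uniform weights
#' reproduce the classical paired t-test exactly.
#'
#' @param a,b paired numeric vectors.
#' @param w nonnegative weights, not all zero.
#' @return List with `t`, `df`, `p`, `mean_diff`, `n_eff`.
#' @export
weighted_ttest_diff <- function(a, b, w) {
  stopifnot(length(a) == length(b), length(a) == length(w))
  keep <- !(is.na(a) | is.na(b) | is.na(w))
  a <- a[keep]; b <- b[keep]; w <- w[keep]
  if (any(w < 0)) stop("weights must be nonnegative")
  if (sum(w > 0) < 2) stop("need >= 2 effectively weighted pairs")
  d <- a - b
  sw <- sum(w)
  md <- sum(w * d) / sw
  v <- sum(w * (d - md)^2) / (sw - sum(w^2) / sw)
  n_eff <- effective_n(w)
  df <- n_eff - 1
  se <- sqrt(v / n_eff)
  t <- if (se == 0) {
    if (md == 0) 0 else sign(md) * Inf
  } else md / se
  p <- if (is.infinite(t)) 0 else 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p, mean_diff = md, n_eff = n_eff)
}

#' Per-unit contralaterality index
#'
#' `(n_contra - n_ipsi) / (n_contra + n_ipsi)` over a unit's targets, where
#' a target counts as contralateral when its represented hemifield is
#' opposite its own anatomical hemisphere: +1 means all representations
#' contralateral, -1 all ipsilateral, 0 balanced.
#'
#' @param target_hemisphere `"L"`/`"R"` per target (anatomical side of the
#'   target).
#' @param hemifield `"L"`/`"R"` per target (represented visual hemifield,
#'   e.g. from [cf_to_visual_field()]); NA pairs are dropped.
#' @return A single signed index in `[-1, 1]`.
#' @export
laterality_index <- function(target_hemisphere, hemifield) {
  stopifnot(length(target_hemisphere) == length(hemifield))
  keep <- !(is.na(target_hemisphere) | is.na(hemifield))
  th <- target_hemisphere[keep]; hf <- hemifield[keep]
  if (length(th) == 0) return(NA_real_)
  contra <- sum(th != hf)
  ipsi <- sum(th == hf)
  (contra - ipsi) / (contra + ipsi)
}

#' Test for contralateral bias of visual-field representations
#'
#' Two-sided one-sample t-test of per-unit signed contralaterality indices
#' (from [laterality_index()], or any signed laterality values) against
#' zero.
#'
#' @param values numeric vector, one signed index per unit (NA dropped).
#' @return List with `t`, `df`, `p`, `mean`, `n` (see [cf_significance()]).
#' @export
laterality_test <- function(values) {
  cf_significance(values)
}
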