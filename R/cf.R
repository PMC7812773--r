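#' The candidate CF size grid (mm)
#'
#' Sizes range from very small (in effect the center vertex alone) to kernels
#' spanning almost the entire source sheet.
#'
#' @return Numeric vector of 13 sigma values in mm.
#' @export
cf_sigma_grid <- function() {
  c(0.5, 1, 2, 3, 4, 5, 7, 10, 15, 20, 30, 40, 80)
}

#' Build the candidate connective-field set
#'
#' One candidate per (eligible center vertex, sigma) pair, over both
#' hemispheres. Candidates are ordered by sigma ascending, then hemisphere
#' (L before R), then center index; the grid-fit tie-break (smallest sigma,
#' then lowest center) is "first candidate in this order".
#'
#' @param centers named list (`L`, `R`) of eligible center vertex indices
#'   (as produced by [select_cf_centers()] per hemisphere; either element
#'   may be missing or empty).
#' @param sigma_grid candidate sigmas in mm, strictly positive and sorted
#'   (default [cf_sigma_grid()]).
#' @return data.frame of class `cf_candidates`: `hemisphere`, `v0`, `sigma`.
#' @export
cf_candidates <- function(centers, sigma_grid = cf_sigma_grid()) {
  if (any(sigma_grid <= 0) || is.unsorted(sigma_grid, strictly = TRUE)) {
    stop("sigma_grid must be strictly positive and strictly increasing")
  }
  hemis <- intersect(c("L", "R"), names(centers))
  rows <- list()
  for (s in sigma_grid) {
    for (h in hemis) {
      v <- centers[[h]]
      if (length(v) == 0) next
      rows[[length(rows) + 1L]] <-
        data.frame(hemisphere = h, v0 = as.integer(v), sigma = s)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cf_candidates", "data.frame")
  out
}

#' Gaussian connective-field profile on the source surface
#'
#' Weight `exp(-d^2 / (2 sigma^2))` for every source vertex, with `d` the
#' geodesic distance from the center vertex `v0`. Weights live on one
#' hemisphere only (the hemisphere of the distance matrix); the profile is 1
#' at the center.
#'
#' @param v0 center vertex id (must be in `dists$vertices`).
#' @param sigma spread in mm on the cortical surface.
#' @param dists a [geodesic_distances()] result for the source region.
#' @return Numeric weight vector over `dists$vertices`.
#' @export
cf_profile <- function(v0, sigma, dists) {
  j <- match(v0, dists$vertices)
  if (is.na(j)) stop("v0 (", v0, ") is not in the source vertex set")
  exp(-dists$d[, j]^2 / (2 * sigma^2))
}

#' Predict a target time course from a CF profile
#'
#' The dot product between the CF's vertex profile and the source-region
#' vertex-by-time matrix, z-scored. All source-region vertices enter the
#' prediction (eligibility criteria apply to CF centers only), and nothing
#' outside the source region ever does.
#'
#' @param profile weight vector over source vertices.
#' @param source_tc matrix, source vertices x timepoints.
#' @return z-scored numeric vector, one value per timepoint.
#' @export
cf_predict <- function(profile, source_tc) {
  source_tc <- as_tc_matrix(source_tc)
  if (length(profile) != nrow(source_tc)) {
    stop("profile length (", length(profile),
         ") does not match source vertex count (", nrow(source_tc), ")")
  }
  zscore(as.vector(profile %*% source_tc))
}

# Precompute the source-vertex weight matrix for every candidate, per
# hemisphere: columns follow cf_candidates order restricted to that
# hemisphere. Weights depend only on geometry, never on data or folds.
candidate_weights <- function(candidates, dists) {
  out <- list()
  for (h in intersect(c("L", "R"), unique(candidates$hemisphere))) {
    ch <- candidates[candidates$hemisphere == h, ]
    D2 <- dists[[h]]$d^2
    cols <- match(ch$v0, dists[[h]]$vertices)
    if (anyNA(cols)) stop("candidate center missing from ", h, " distance matrix")
    W <- exp(sweep(D2[, cols, drop = FALSE], 2, -2 * ch$sigma^2, "/"))
    out[[h]] <- W
  }
  out
}

# T x n_candidates matrix of z-scored candidate predictions, in candidate order
candidate_predictions <- function(candidates, source_tc, weights) {
  preds <- matrix(0, ncol(source_tc[[1]]), nrow(candidates))
  for (h in names(weights)) {
    idx <- which(candidates$hemisphere == h)
    preds[, idx] <- crossprod(source_tc[[h]], weights[[h]])
  }
  zscore_cols(preds)
}

zscore_cols <- function(m) {
  mm <- colMeans(m)
  mc <- sweep(m, 2, mm)
  s <- sqrt(colMeans(mc^2))
  s[s == 0] <- Inf
  sweep(mc, 2, s, "/")
}

#' Within-set grid fit of connective fields
#'
#' For every target time course, evaluates every candidate (both
#' hemispheres) and selects the one with the highest squared Pearson
#' correlation between the z-scored candidate prediction and the target —
#' the hemisphere of the winner doubles as a laterality proxy. Correlation
#' is computed directly on the time courses, without hemodynamic
#' convolution. Exact ties go to the earliest candidate (smallest sigma,
#' then L before R, then lowest center index). Zero-variance targets are
#' flagged and excluded from downstream statistics.
#'
#' @param target_tc matrix, targets x timepoints.
#' @param candidates a [cf_candidates()] table.
#' @param source_tc named list (`L`, `R`) of source matrices (vertices x
#'   timepoints) for the same timepoints as `target_tc`.
#' @param dists named list (`L`, `R`) of [geodesic_distances()] results.
#' @return data.frame: `target`, `v0`, `hemisphere`, `sigma_cf`, `r`
#'   (signed within-set correlation of the winner), `r2`, `flagged`.
#' @export
cf_grid_fit <- function(target_tc, candidates, source_tc, dists) {
  target_tc <- as_tc_matrix(target_tc)
  weights <- candidate_weights(candidates, dists)
  zp <- candidate_predictions(candidates, source_tc, weights)
  fit_given_predictions(target_tc, candidates, zp)
}

fit_given_predictions <- function(target_tc, candidates, zp) {
  n_t <- ncol(target_tc)
  zt <- zscore(target_tc)
  flagged <- rowSums(zt != 0) == 0
  r <- crossprod(zp, t(zt)) / n_t         # candidates x targets
  best <- apply(r^2, 2, which.max)
  out <- data.frame(
    target = seq_len(nrow(target_tc)),
    v0 = candidates$v0[best],
    hemisphere = candidates$hemisphere[best],
    sigma_cf = candidates$sigma[best],
    r = r[cbind(best, seq_len(nrow(target_tc)))],
    flagged = flagged
  )
  out$r2 <- out$r^2
  out$v0[flagged] <- NA_integer_
  out$hemisphere[flagged] <- NA_character_
  out$sigma_cf[flagged] <- NA_real_
  out$r[flagged] <- NA_real_
  out$r2[flagged] <- NA_real_
  out
}

#' Leave-one-run-out cross-validation of connective fields
#'
#' A k-fold scheme with one fold per run: for each fold the candidate grid
#' fit runs on the remaining runs concatenated (each run preprocessed on its
#' own beforehand), and the selected (v0, sigma) generates an out-of-set
#' prediction of the held-out run, scored by Pearson correlation. The same
#' folds score the nontopographic null model — the z-scored average time
#' course of all source vertices of both hemispheres — and the corrected
#' value is the CF's out-of-set correlation minus the null model's
#' ([null_model_correction()]). Parameters and correlations are averaged
#' across folds; sigma is averaged numerically while the reported `v0` (and
#' its hemisphere) is the modal selection, since vertex ids cannot be
#' averaged.
#'
#' @param target_runs list of per-run target matrices (targets x timepoints).
#' @param source_runs named list (`L`, `R`), each a list of per-run source
#'   matrices.
#' @param candidates a [cf_candidates()] table.
#' @param dists named list (`L`, `R`) of [geodesic_distances()] results.
#' @return List of class `cf_fit`: `summary` (one row per target: `target`,
#'   `v0`, `hemisphere`, `sigma_cf`, `cv_r`, `null_r`, `corrected`,
#'   `flagged`) and `folds` (per fold x target: fold, training selection and
#'   out-of-set correlations).
#' @export
cf_crossvalidate <- function(target_runs, source_runs, candidates, dists) {
  n_runs <- length(target_runs)
  if (n_runs < 2) {
    stop("cross-validation needs >= 2 runs; use cf_grid_fit() explicitly ",
         "for a within-set fit")
  }
  stopifnot(length(source_runs$L) == n_runs, length(source_runs$R) == n_runs)
  weights <- candidate_weights(candidates, dists)
  folds <- list()
  for (k in seq_len(n_runs)) {
    train <- setdiff(seq_len(n_runs), k)
    src_train <- list(
      L = do.call(cbind, source_runs$L[train]),
      R = do.call(cbind, source_runs$R[train])
    )
    tgt_train <- do.call(cbind, target_runs[train])
    zp <- candidate_predictions(candidates, src_train, weights)
    fit <- fit_given_predictions(tgt_train, candidates, zp)
    # out-of-set: predict the held-out run with the training-selected CF
    src_test <- list(L = source_runs$L[[k]], R = source_runs$R[[k]])
    tgt_test <- target_runs[[k]]
    sel <- paste(fit$hemisphere, fit$v0, fit$sigma_cf)
    uniq <- which(!duplicated(sel) & !fit$flagged)
    pred_cols <- match(sel, sel[uniq])
    zp_test <- matrix(NA_real_, ncol(tgt_test), length(uniq))
    for (h in c("L", "R")) {
      hsel <- which(fit$hemisphere[uniq] == h)
      if (length(hsel) == 0) next
      cand_idx <- vapply(uniq[hsel], function(i) {
        which(candidates$hemisphere == h &
                candidates$v0 == fit$v0[i] &
                candidates$sigma == fit$sigma_cf[i])[1]
      }, integer(1))
      within_h <- match(cand_idx, which(candidates$hemisphere == h))
      zp_test[, hsel] <- crossprod(src_test[[h]],
                                   weights[[h]][, within_h, drop = FALSE])
    }
    zp_test <- zscore_cols(zp_test)
    zt_test <- zscore(tgt_test)
    test_r <- colSums(t(zt_test) * zp_test[, pred_cols, drop = FALSE]) /
      ncol(tgt_test)
    test_r[fit$flagged] <- NA_real_
    null_pred <- zscore(colMeans(rbind(src_test$L, src_test$R)))
    null_r <- as.vector(zt_test %*% null_pred) / ncol(tgt_test)
    null_r[fit$flagged] <- NA_real_
    folds[[k]] <- data.frame(
      fold = k, target = fit$target, v0 = fit$v0,
      hemisphere = fit$hemisphere, sigma_cf = fit$sigma_cf,
      train_r = fit$r, test_r = test_r, null_r = null_r,
      flagged = fit$flagged
    )
  }
  fold_df <- do.call(rbind, folds)
  n_tgt <- nrow(target_runs[[1]])
  summary <- do.call(rbind, lapply(seq_len(n_tgt), function(i) {
    fi <- fold_df[fold_df$target == i, ]
    if (all(fi$flagged)) {
      return(data.frame(target = i, v0 = NA_integer_,
                        hemisphere = NA_character_, sigma_cf = NA_real_,
                        cv_r = NA_real_, null_r = NA_real_,
                        corrected = NA_real_, flagged = TRUE))
    }
    fi <- fi[!fi$flagged, ]
    key <- paste(fi$hemisphere, fi$v0)
    mode_key <- names(sort(table(key), decreasing = TRUE))[1]
    mk <- fi[match(mode_key, key), ]
    cv_r <- mean(fi$test_r)
    null_r <- mean(fi$null_r)
    data.frame(
      target = i, v0 = mk$v0, hemisphere = mk$hemisphere,
      sigma_cf = mean(fi$sigma_cf), cv_r = cv_r, null_r = null_r,
      corrected = null_model_correction(cv_r, null_r), flagged = FALSE
    )
  }))
  structure(list(summary = summary, folds = fold_df, n_runs = n_runs),
            class = "cf_fit")
}

#' @exportS3Method base::print
print.cf_fit <- function(x, ...) {
  ok <- !x$summary$flagged
  cat(sprintf(
    "<cf_fit> %d targets, %d folds; mean cv_r %.3f, mean corrected %.3f\n",
    nrow(x$summary), x$n_runs, mean(x$summary$cv_r[ok]),
    mean(x$summary$corrected[ok])))
  invisible(x)
}

#' Null-model correction of cross-validated correlations
#'
#' References the CF model's out-of-set correlation against the
#' nontopographic null model (prediction by the average source time course)
#' by subtraction. The corrected value is no longer interpretable as a
#' correlation, but conservatively indexes topographically specific
#' connectivity: common drivers such as arousal or overall stimulus energy
#' raise both terms and cancel. The operator is isolated here so a ratio or
#' partialling variant could be swapped in.
#'
#' @param cv_r out-of-set CF correlation (vectorized).
#' @param null_r out-of-set null-model correlation, same folds.
#' @return `cv_r - null_r`.
#' @export
null_model_correction <- function(cv_r, null_r) {
  cv_r - null_r
}

#' One-sample t-test of corrected values against zero
#'
#' Two-sided one-sample t-test across units (subjects or simulated
#' replicates) of null-model-corrected prediction performance.
#'
#' @param values numeric vector, one corrected value per unit (NA dropped).
#' @return List with `t`, `df`, `p`, `mean`, `n`.
#' @export
cf_significance <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) stop("need at least 2 units for a t-test")
  if (stats::sd(values) == 0) {
    m <- mean(values)
    t <- if (m == 0) 0 else sign(m) * Inf
    return(list(t = t, df = n - 1, p = if (m == 0) 1 else 0, mean = m, n = n))
  }
  ht <- stats::t.test(values, mu = 0, alternative = "two.sided")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean = mean(values), n = n)
}
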