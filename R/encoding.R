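#' Fit the kinematic encoding model at one occlusion level
#'
#' The encoding model predicts the probability that the small object is
#' reached in the first interval from the single-trial kinematic difference
#' `dK` (first minus second interval, visible epochs only):
#' `P(small first) = sigma(dK . beta_enc + b_enc)`, with classification by
#' the Heaviside rule `H(sigma(.) - 0.5)` (the exact 0.5 tie predicts
#' large-first). It is an ideal-observer bound: the label is the true
#' configuration, not anybody's response. Coefficients are L2-regularized
#' with the penalty chosen by inner cross-validation; reported accuracy comes
#' from an outer stratified k-fold with folds grouped by stimulus pair, so
#' uncertainty is across stimuli rather than trials.
#'
#' @param design trial stubs or completed sessions (only trials at
#'   `occlusion` are used; duplicated trials across observers are reduced to
#'   the unique design trials).
#' @param stimuli the `kc_stimuli` set.
#' @param occlusion occlusion level in percent.
#' @param k outer CV folds (default 10).
#' @param seed fold seed.
#' @param lambdas penalty grid for the inner selection.
#' @return object of class `kc_encoding_fit`.
#' @export
fit_encoding <- function(design, stimuli, occlusion, k = 10L, seed = 1L,
                         lambdas = kc_lambda_grid()) {
  tr <- design[design$occlusion_level == occlusion, , drop = FALSE]
  key <- paste(tr$first_stimulus_id, tr$second_stimulus_id, tr$configuration)
  tr <- tr[!duplicated(paste(tr$trial_id, key)), , drop = FALSE]
  if (nrow(tr) < 20L) stop("need at least 20 trials at this occlusion level")
  y <- tr$configuration == "small_first"
  if (length(unique(y)) < 2L) stop("both configurations must be present")
  X <- session_delta_matrix(tr, stimuli)
  e_vis <- seq_len(occlusion / 10)
  keep <- grepl(paste0("_e(", paste(e_vis, collapse = "|"), ")$"), colnames(X))
  X <- X[, keep, drop = FALSE]
  if (all(X == 0)) stop("degenerate all-zero kinematic difference matrix")
  pair <- paste(pmin(tr$first_stimulus_id, tr$second_stimulus_id),
                pmax(tr$first_stimulus_id, tr$second_stimulus_id))
  fit <- cv_ridge_fit(X, y, k = k, seed = seed, lambdas = lambdas,
                      groups = pair)
  structure(list(occlusion_level = occlusion, beta_enc = fit$beta,
                 b_enc = fit$intercept, penalty = fit$lambda,
                 cv_accuracy = fit$cv_accuracy, cv_sem = fit$cv_sem,
                 fold_assignments = fit$fold_assignments,
                 cv_prob = fit$cv_prob, n_trials = nrow(tr),
                 features = dimnames(stimuli$features)[[2]]),
            class = "kc_encoding_fit")
}

#' @export
print.kc_encoding_fit <- function(x, ...) {
  cat(sprintf("<kc_encoding_fit> occlusion %d%%: CV accuracy %.3f (SEM %.3f), lambda %.3g, %d trials\n",
              x$occlusion_level, x$cv_accuracy, x$cv_sem, x$penalty, x$n_trials))
  invisible(x)
}

#' Feature contributions and cross-occlusion stability of encoding weights
#'
#' Contribution of feature `f` at a level is the summed absolute encoding
#' coefficient over that level's visible epochs, normalized to sum to 1 over
#' features; the per-epoch breakdown is retained for stacked displays.
#' Stability between two levels is the Pearson correlation of the coefficient
#' vectors on their shared feature-by-epoch support. Features are ordered by
#' their contribution at the highest fitted level, descending.
#'
#' @param fits list of `kc_encoding_fit` objects at two or more levels.
#' @return list of class `kc_encoding_profile`: `contribution` (feature x
#'   level matrix), `by_epoch` (named list of feature x epoch matrices of
#'   normalized |coefficients|), `stability` (level x level correlation
#'   matrix), `feature_order`.
#' @export
encoding_profile <- function(fits) {
  if (length(fits) < 2L) stop("need encoding fits at two or more levels")
  levels <- vapply(fits, function(f) f$occlusion_level, numeric(1))
  ord <- order(levels)
  fits <- fits[ord]; levels <- levels[ord]
  features <- fits[[1]]$features
  by_epoch <- list()
  contrib <- matrix(0, nrow = length(features), ncol = length(levels),
                    dimnames = list(features, paste0(levels, "%")))
  for (i in seq_along(fits)) {
    b <- fits[[i]]$beta_enc
    tot <- sum(abs(b))
    m <- matrix(abs(b) / max(tot, 1e-300), nrow = length(features),
                byrow = TRUE, dimnames = list(features, NULL))
    by_epoch[[paste0(levels[i], "%")]] <- m
    contrib[, i] <- rowSums(m)
  }
  stab <- matrix(NA_real_, length(levels), length(levels),
                 dimnames = list(paste0(levels, "%"), paste0(levels, "%")))
  for (i in seq_along(fits)) for (j in seq_along(fits)) {
    ni <- length(fits[[i]]$beta_enc); nj <- length(fits[[j]]$beta_enc)
    shared <- intersect(names(fits[[i]]$beta_enc), names(fits[[j]]$beta_enc))
    if (length(shared) < 2L) next
    stab[i, j] <- stats::cor(fits[[i]]$beta_enc[shared],
                             fits[[j]]$beta_enc[shared])
  }
  feature_order <- features[order(contrib[, ncol(contrib)], decreasing = TRUE)]
  structure(list(contribution = contrib, by_epoch = by_epoch,
                 stability = stab, feature_order = feature_order,
                 levels = levels),
            class = "kc_encoding_profile")
}
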