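#' Fit a per-observer kinematic readout model at one occlusion level
#'
#' The readout model mirrors the encoding model but predicts the observer's
#' own response: `P(report small first) = sigma(dK . beta_read + b_read)`.
#' `dK . beta_read` captures how the observer integrates kinematic evidence;
#' the intercept `b_read` is the evidence-independent bias toward one
#' response. Same estimator and CV protocol as [fit_encoding()] (L2 penalty
#' by inner CV, outer stratified k-fold), but folds are plain
#' label-stratified: readout uncertainty is summarized across participants,
#' not stimuli.
#'
#' An observer who answered identically on every trial yields a degenerate
#' fit: zero coefficients, cv_accuracy equal to the base rate, flagged.
#'
#' @param session a `kc_session` for one observer (or a subset of one).
#' @param stimuli the `kc_stimuli` set.
#' @param occlusion occlusion level in percent.
#' @param k outer CV folds.
#' @param seed fold seed.
#' @param lambdas penalty grid.
#' @return object of class `kc_readout_fit`, including per-trial held-out
#'   probabilities `cv_prob`, `predicted_accuracy` (held-out fraction of
#'   trials where the model's predicted choice matches the true
#'   configuration) and per-trial `predicted_confidence` = |P - 0.5|.
#' @export
fit_readout <- function(session, stimuli, occlusion, k = 10L, seed = 1L,
                        lambdas = kc_lambda_grid()) {
  obs <- unique(session$observer_id)
  if (length(obs) != 1L) stop("fit_readout expects a single observer's session")
  tr <- session[session$occlusion_level == occlusion, , drop = FALSE]
  if (nrow(tr) < 15L) stop("need at least 15 trials at this occlusion level")
  y <- tr$chose_small_first
  X <- session_delta_matrix(tr, stimuli)
  e_vis <- seq_len(occlusion / 10)
  keep <- grepl(paste0("_e(", paste(e_vis, collapse = "|"), ")$"), colnames(X))
  X <- X[, keep, drop = FALSE]
  truth <- tr$configuration == "small_first"

  if (length(unique(y)) < 2L) {
    base <- mean(y == y[1])  # = 1; accuracy of always predicting the answer
    fit <- list(beta = stats::setNames(rep(0, ncol(X)), colnames(X)),
                intercept = 0, lambda = NA_real_,
                cv_accuracy = max(mean(y), 1 - mean(y)),
                fold_accuracy = NA_real_, cv_sem = NA_real_,
                fold_assignments = rep(NA_integer_, nrow(tr)),
                cv_prob = rep(mean(y), nrow(tr)))
    degenerate <- TRUE
  } else {
    fit <- cv_ridge_fit(X, y, k = k, seed = seed, lambdas = lambdas)
    degenerate <- FALSE
  }
  pred_choice <- fit$cv_prob > 0.5
  structure(list(observer_id = obs, group = unique(session$group),
                 occlusion_level = occlusion,
                 beta_read = fit$beta, b_read = fit$intercept,
                 penalty = fit$lambda, cv_accuracy = fit$cv_accuracy,
                 cv_sem = fit$cv_sem, fold_assignments = fit$fold_assignments,
                 cv_prob = fit$cv_prob,
                 predicted_accuracy = mean(pred_choice == truth),
                 predicted_confidence = abs(fit$cv_prob - 0.5),
                 observed_accuracy = mean(tr$correct),
                 confidence = tr$confidence,
                 trial_id = tr$trial_id,
                 X = X, labels = y,
                 degenerate = degenerate,
                 chance_level = NA_real_, null_quantiles = NULL),
            class = "kc_readout_fit")
}

#' @export
print.kc_readout_fit <- function(x, ...) {
  cat(sprintf("<kc_readout_fit> %s (%s) occlusion %d%%: CV accuracy %.3f%s%s\n",
              x$observer_id, x$group, x$occlusion_level, x$cv_accuracy,
              if (is.finite(x$chance_level))
                sprintf(", chance %.3f", x$chance_level) else "",
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Permutation null distribution of cross-validated readout accuracy
#'
#' Response labels are permuted within the occlusion level and the full
#' nested-CV pipeline is re-run per permutation. The chance level is the
#' mean of the resulting null distribution of CV accuracies.
#'
#' @param fit a `kc_readout_fit` (its stored design matrix and labels are
#'   re-used).
#' @param n_perm number of permutations, at least 100 (the mean is unstable
#'   below that).
#' @param seed permutation seed.
#' @param k outer CV folds for the permuted fits.
#' @return the fit with `chance_level`, `null_quantiles` (2.5/5/95/97.5\%)
#'   and the full `null_distribution` filled in.
#' @export
readout_chance_null <- function(fit, n_perm = 500L, seed = 1L, k = 10L) {
  stopifnot(inherits(fit, "kc_readout_fit"))
  if (n_perm < 100L) stop("n_perm must be at least 100")
  set.seed(seed)
  perms <- replicate(n_perm, sample(fit$labels), simplify = FALSE)
  null <- vapply(seq_len(n_perm), function(i) {
    yp <- perms[[i]]
    if (length(unique(yp)) < 2L) return(max(mean(yp), 1 - mean(yp)))
    cv_ridge_fit(fit$X, yp, k = k, seed = seed + i)$cv_accuracy
  }, numeric(1))
  fit$null_distribution <- null
  fit$chance_level <- mean(null)
  fit$null_quantiles <- stats::quantile(null, c(0.025, 0.05, 0.95, 0.975))
  fit
}

#' Fractional contribution of evidence-independent bias to readout
#'
#' `|b_read| / (|b_read| + mean over trials of |dK . beta_read|)`: 0 when the
#' intercept is zero, 1 when the readout carries an intercept but no
#' kinematic term. Undefined (NA) for degenerate fits with zero denominator.
#'
#' @param fit a `kc_readout_fit`.
#' @return a single number in [0, 1], or NA for a degenerate fit.
#' @export
bias_fraction <- function(fit) {
  stopifnot(inherits(fit, "kc_readout_fit"))
  ev <- mean(abs(as.vector(fit$X %*% fit$beta_read)))
  den <- abs(fit$b_read) + ev
  if (!is.finite(den) || den < 1e-12) return(NA_real_)
  abs(fit$b_read) / den
}

#' Sign-flip test of the readout intercept across observers
#'
#' Tests whether `b_read` differs from zero at the group level by randomly
#' flipping each observer's intercept sign and comparing the observed mean
#' against the flip distribution (two-sided).
#'
#' @param fits list of `kc_readout_fit` objects (one group, one level or
#'   pooled).
#' @param n_flip number of sign-flip draws.
#' @param seed RNG seed.
#' @return list with `mean_b`, `p_value`, `n`.
#' @export
bias_sign_test <- function(fits, n_flip = 2000L, seed = 1L) {
  b <- vapply(fits, function(f) f$b_read, numeric(1))
  b <- b[is.finite(b)]
  if (length(b) < 2L) stop("need at least two observers")
  set.seed(seed)
  obs <- mean(b)
  flips <- replicate(n_flip, mean(b * sample(c(-1, 1), length(b), TRUE)))
  p <- (1 + sum(abs(flips) >= abs(obs))) / (n_flip + 1)
  list(mean_b = obs, p_value = p, n = length(b))
}

#' Predicted versus observed performance and confidence agreement
#'
#' Collects, per observer and occlusion level, the readout model's held-out
#' predicted accuracy against the observer's observed accuracy, and pools
#' per-trial model prediction confidence (|P - 0.5|) against the reported
#' confidence rating. Confidence is never used in fitting. Pearson r and
#' two-sided p are computed per group.
#'
#' @param fits list of `kc_readout_fit` objects (any mix of observers,
#'   groups and levels).
#' @return list of class `kc_readout_predictions`: `accuracy_pairs`
#'   (data.frame observer_id, group, occlusion_level, predicted, observed),
#'   `accuracy_cor` (per-group r, p, n), `confidence_pairs`,
#'   `confidence_cor`.
#' @export
readout_predictions <- function(fits) {
  acc <- do.call(rbind, lapply(fits, function(f) data.frame(
    observer_id = f$observer_id, group = f$group,
    occlusion_level = f$occlusion_level,
    predicted = f$predicted_accuracy, observed = f$observed_accuracy,
    stringsAsFactors = FALSE)))
  conf <- do.call(rbind, lapply(fits, function(f) data.frame(
    observer_id = f$observer_id, group = f$group,
    occlusion_level = rep(f$occlusion_level, length(f$cv_prob)),
    predicted_confidence = f$predicted_confidence,
    reported_confidence = f$confidence, stringsAsFactors = FALSE)))
  cor_by_group <- function(df, xv, yv) {
    do.call(rbind, lapply(split(df, df$group), function(d) {
      if (nrow(d) < 3L || stats::sd(d[[xv]]) == 0 || stats::sd(d[[yv]]) == 0)
        return(data.frame(group = d$group[1], r = NA_real_, p = NA_real_,
                          n = nrow(d)))
      ct <- stats::cor.test(d[[xv]], d[[yv]])
      data.frame(group = d$group[1], r = unname(ct$estimate),
                 p = ct$p.value, n = nrow(d))
    }))
  }
  structure(list(
    accuracy_pairs = acc,
    accuracy_cor = cor_by_group(acc, "predicted", "observed"),
    confidence_pairs = conf,
    confidence_cor = cor_by_group(conf, "predicted_confidence",
                                  "reported_confidence")),
    class = "kc_readout_predictions")
}

#' Fraction of encoded information read by an observer
#'
#' Proxy for single-trial extracted information: the observer's above-chance
#' accuracy as a fraction of the encoding model's above-chance accuracy at
#' the same occlusion level, clipped below at 0. Undefined when the encoding
#' model itself is at or below chance.
#'
#' Passing a list of encoding fits and a list of readout fits pools an
#' integration period: observed and encoding accuracies are averaged over
#' the matched occlusion levels before the ratio is formed, which stabilizes
#' the denominator where single-level encoding accuracy sits just above
#' chance.
#'
#' @param enc a `kc_encoding_fit`, or a list of them (one per level).
#' @param read a `kc_readout_fit` at the same occlusion level, or a list
#'   matching `enc` level for level.
#' @return a number, 0 or larger (clipped below at 0; values above 1 mean
#'   the observer beat the encoding bound), or NA when undefined.
#' @export
information_read <- function(enc, read) {
  if (inherits(enc, "kc_encoding_fit")) enc <- list(enc)
  if (inherits(read, "kc_readout_fit")) read <- list(read)
  stopifnot(all(vapply(enc, inherits, logical(1), "kc_encoding_fit")),
            all(vapply(read, inherits, logical(1), "kc_readout_fit")),
            length(enc) == length(read))
  le <- vapply(enc, function(f) f$occlusion_level, numeric(1))
  lr <- vapply(read, function(f) f$occlusion_level, numeric(1))
  if (!identical(sort(le), sort(lr)))
    stop("encoding and readout fits must share the occlusion levels")
  acc_enc <- mean(vapply(enc, function(f) f$cv_accuracy, numeric(1)))
  acc_obs <- mean(vapply(read, function(f) f$observed_accuracy, numeric(1)))
  if (acc_enc <= 0.5) return(NA_real_)
  max(0, (acc_obs - 0.5) / (acc_enc - 0.5))
}
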