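#' Kinematic difference vector for one trial
#'
#' The single-trial evidence consumed by encoding and readout models:
#' first-interval minus second-interval stimulus features, restricted to the
#' epochs visible at the given occlusion level, flattened feature-major
#' (all epochs of feature 1, then all epochs of feature 2, ...). Names are
#' `<feature>_e<epoch>`.
#'
#' @param trial one row of a design or session data.frame.
#' @param stimuli a `kc_stimuli` set.
#' @param occlusion occlusion level in percent, on the 10..(10*E) grid;
#'   defaults to the trial's own level.
#' @return named numeric vector of length `F * occlusion/10`.
#' @export
trial_delta_features <- function(trial, stimuli, occlusion = trial$occlusion_level) {
  stopifnot(inherits(stimuli, "kc_stimuli"))
  E <- dim(stimuli$features)[3]
  if (length(occlusion) != 1L || !occlusion %in% (10L * seq_len(E)))
    stop("occlusion must be one of ", paste(10L * seq_len(E), collapse = ", "))
  i1 <- match(trial$first_stimulus_id, stimuli$meta$stimulus_id)
  i2 <- match(trial$second_stimulus_id, stimuli$meta$stimulus_id)
  if (is.na(i1) || is.na(i2)) stop("trial references a missing stimulus")
  e_vis <- seq_len(occlusion / 10)
  m <- stimuli$features[i1, , e_vis, drop = FALSE] -
       stimuli$features[i2, , e_vis, drop = FALSE]
  m <- array(m, dim = dim(m)[2:3])
  v <- as.vector(t(m))  # feature-major
  names(v) <- feature_epoch_names(dimnames(stimuli$features)[[2]],
                                  length(e_vis))
  v
}

# n_trials x (F*E) matrix of full-grid delta features with epochs beyond each
# trial's occlusion level zeroed (masking is equivalent to restriction for
# any weight vector). Column order is feature-major, matching
# trial_delta_features().
session_delta_matrix <- function(design, stimuli) {
  feats <- stimuli$features
  F <- dim(feats)[2]; E <- dim(feats)[3]
  i1 <- match(design$first_stimulus_id, stimuli$meta$stimulus_id)
  i2 <- match(design$second_stimulus_id, stimuli$meta$stimulus_id)
  if (anyNA(i1) || anyNA(i2)) stop("design references a missing stimulus")
  fm <- matrix(NA_real_, nrow = dim(feats)[1], ncol = F * E)
  for (f in seq_len(F))
    fm[, (f - 1L) * E + seq_len(E)] <- feats[, f, ]
  dk <- fm[i1, , drop = FALSE] - fm[i2, , drop = FALSE]
  colnames(dk) <- feature_epoch_names(dimnames(feats)[[2]], E)
  epoch_of <- rep(seq_len(E), times = F)
  vis <- outer(design$occlusion_level / 10, epoch_of, `>=`)
  dk * vis
}
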