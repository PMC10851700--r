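#' Construct a synthetic observer profile
#'
#' An observer is a noisy linear reader of the kinematic difference between
#' the two movements of a trial: the decision variable is
#' `d = dK . w / c + bias + noise`, where `c` is a per-occlusion-level
#' divisive normalization constant (the norm of the true size-effect
#' direction restricted to the visible epochs), and the response is
#' `small first` when `d > 0`. The normalization models an observer who
#' scales the pooled evidence by how much of the movement is visible, and
#' puts the decision variable on a common scale across occlusion levels.
#' The control preset reads the generator's true size-effect direction over
#' all time epochs; the patient preset reads the identical direction but
#' with zero weight on epochs at or below its null-integration window
#' (default 20\% of movement duration) and attenuated evidence (default
#' gain 0.7) thereafter, and its confidence is decoupled from the evidence
#' inside the same early window.
#'
#' @param group `"control"` or `"patient"`.
#' @param params the `kc_params` the stimuli were generated with; the
#'   observer's weights are proportional to its size-effect direction.
#' @param noise_sd decision noise SD (default 1.5).
#' @param lapse probability of a stimulus-independent random flip of the
#'   choice (default 0.02, must be in [0, 0.5)).
#' @param bias evidence-independent offset on the decision variable
#'   (default 0).
#' @param readout_gain attenuation applied to patient weights outside the
#'   null window (default 0.7).
#' @param confidence_gain multiplier on |d| before confidence binning.
#' @return a list of class `kc_observer`.
#' @export
observer_preset <- function(group = c("control", "patient"),
                            params = default_gen_params(),
                            noise_sd = 1.5, lapse = 0.02, bias = 0,
                            readout_gain = 0.7, confidence_gain = 1) {
  group <- match.arg(group)
  stopifnot(inherits(params, "kc_params"))
  if (lapse < 0 || lapse >= 0.5) stop("lapse must lie in [0, 0.5)")
  w <- as.vector(t(params$delta))  # feature-major: f1e1..f1eE, f2e1, ...
  names(w) <- feature_epoch_names(params$features, params$n_epochs)
  nrm <- sqrt(sum(w^2))
  if (nrm > 0) w <- w / nrm
  reference <- w  # true size-effect direction, sets the per-level norms
  null_window <- 0
  miscal_window <- 0
  if (group == "patient") {
    null_window <- 20
    miscal_window <- 20
    epoch_of <- rep(seq_len(params$n_epochs), times = length(params$features))
    w[epoch_of <= null_window / 10] <- 0
    w[epoch_of > null_window / 10] <- readout_gain * w[epoch_of > null_window / 10]
  }
  structure(list(group = group, weights = w, reference = reference,
                 bias = bias, noise_sd = noise_sd,
                 lapse = lapse, null_window_pct = null_window,
                 confidence_gain = confidence_gain,
                 confidence_miscalibrated_window_pct = miscal_window,
                 n_epochs = params$n_epochs, features = params$features),
            class = "kc_observer")
}

#' @export
print.kc_observer <- function(x, ...) {
  cat(sprintf("<kc_observer> group=%s null_window=%d%% noise_sd=%.2f lapse=%.3f bias=%.2f\n",
              x$group, x$null_window_pct, x$noise_sd, x$lapse, x$bias))
  invisible(x)
}

feature_epoch_names <- function(features, n_epochs) {
  as.vector(t(outer(features, seq_len(n_epochs), function(f, e)
    sprintf("%s_e%d", f, e))))
}

# Quantile boundaries of the |d| distribution of the control preset over the
# trials of a design: P(|d| <= q) is a mixture of folded normals, solved for
# the quartiles by root finding. Deterministic given stimuli + design.
confidence_bins <- function(design, stimuli, params = stimuli$params) {
  ctrl <- observer_preset("control", params)
  mu <- abs(trial_decision_means(ctrl, design, stimuli))
  s <- max(ctrl$noise_sd, 1e-9)
  cdf <- function(q) mean(stats::pnorm((q - mu) / s) - stats::pnorm((-q - mu) / s))
  hi <- max(mu) + 10 * s
  ctrl$confidence_gain * vapply(c(0.25, 0.5, 0.75), function(p) {
    stats::uniroot(function(q) cdf(q) - p, c(0, hi), tol = 1e-9)$root
  }, numeric(1))
}

# mean decision variable (dK . w / c_level + bias) per trial, visible epochs
# only; c_level is the norm of the reference (true size-effect) direction
# restricted to the visible epochs, so evidence is on a common scale across
# occlusion levels. A profile without a reference (e.g. hand-built weights)
# falls back to its own weights; a zero reference norm disables the scaling.
trial_decision_means <- function(profile, design, stimuli) {
  dk <- session_delta_matrix(design, stimuli)  # n_trials x (F*E), masked
  ref <- profile$reference
  if (is.null(ref)) ref <- profile$weights
  E <- dim(stimuli$features)[3]
  epoch_of <- rep(seq_len(E), times = dim(stimuli$features)[2])
  ev <- as.vector(dk %*% profile$weights)
  norms <- vapply(sort(unique(design$occlusion_level)), function(l) {
    nv <- sqrt(sum(ref[epoch_of <= l / 10]^2))
    if (nv < 1e-12) 1 else nv
  }, numeric(1))
  names(norms) <- sort(unique(design$occlusion_level))
  unname(ev / norms[as.character(design$occlusion_level)]) + profile$bias
}

#' Simulate one observer's session
#'
#' Completes a set of trial stubs with choices and confidence ratings
#' generated from an observer profile. Per trial the decision variable is
#' `d = dK . w + bias + eps`, `eps ~ N(0, noise_sd)`, with `dK` restricted to
#' the epochs visible at the trial's occlusion level; the choice is
#' `small first` iff `d > 0` (an exact tie predicts large-first), flipped
#' with probability `lapse`. Confidence is the quartile bin of
#' `confidence_gain * |d|`, with bin boundaries fixed once from the control
#' preset's |d| distribution so that all observers rate on a common scale;
#' within the observer's miscalibrated window (occlusion at or below
#' `confidence_miscalibrated_window_pct`), confidence is instead resampled
#' from the observer's own overall confidence distribution, independent of
#' the trial's evidence.
#'
#' @param profile a `kc_observer`.
#' @param design trial stubs from [make_design()].
#' @param stimuli the `kc_stimuli` the design references.
#' @param seed integer seed; identical inputs and seed give identical
#'   sessions.
#' @param observer_id label stored with every trial.
#' @return a `kc_session` data.frame: the design columns plus observer_id,
#'   group, response_interval, chose_small_first, correct, confidence.
#' @export
simulate_observer <- function(profile, design, stimuli, seed = 1L,
                              observer_id = "obs01") {
  stopifnot(inherits(profile, "kc_observer"), is.data.frame(design),
            inherits(stimuli, "kc_stimuli"))
  missing_stim <- setdiff(unique(c(design$first_stimulus_id,
                                   design$second_stimulus_id)),
                          stimuli$meta$stimulus_id)
  if (length(missing_stim) > 0)
    stop("design references stimuli absent from the set: ",
         paste(missing_stim, collapse = ", "))

  mu <- trial_decision_means(profile, design, stimuli)
  if (!all(is.finite(mu))) stop("non-finite decision variable")
  bins <- confidence_bins(design, stimuli)

  set.seed(seed)
  n <- nrow(design)
  d <- mu + stats::rnorm(n, sd = profile$noise_sd)
  chose_small <- d > 0
  flip <- stats::runif(n) < profile$lapse
  chose_small[flip] <- !chose_small[flip]

  conf <- 1L + findInterval(profile$confidence_gain * abs(d), bins)
  conf <- pmin(pmax(conf, 1L), 4L)
  win <- design$occlusion_level <= profile$confidence_miscalibrated_window_pct
  if (any(win)) conf[win] <- sample(conf, sum(win), replace = TRUE)

  small_first <- design$configuration == "small_first"
  # interval key: under report_small, "first" means small was seen first
  resp <- ifelse(design$instruction == "report_small",
                 ifelse(chose_small, "first", "second"),
                 ifelse(chose_small, "second", "first"))
  out <- design
  out$observer_id <- observer_id
  out$group <- profile$group
  out$response_interval <- resp
  out$chose_small_first <- chose_small
  out$correct <- chose_small == small_first
  out$confidence <- as.integer(conf)
  class(out) <- c("kc_session", class(out))
  out
}

#' Simulate a cohort of observers
#'
#' Convenience wrapper: one session per observer, seeds derived per observer
#' from a master seed.
#'
#' @param profiles list of `kc_observer` profiles (names become observer ids
#'   when present).
#' @param design,stimuli as in [simulate_observer()].
#' @param master_seed master seed; observer `i` uses
#'   `derive_seed(master_seed, "observers", i)`.
#' @return a single `kc_session` data.frame with all observers stacked.
#' @export
simulate_cohort <- function(profiles, design, stimuli, master_seed = 1L) {
  ids <- names(profiles)
  if (is.null(ids)) ids <- sprintf("obs%02d", seq_along(profiles))
  out <- lapply(seq_along(profiles), function(i) {
    simulate_observer(profiles[[i]], design, stimuli,
                      seed = derive_seed(master_seed, "observers", i),
                      observer_id = ids[i])
  })
  res <- do.call(rbind, out)
  class(res) <- c("kc_session", "data.frame")
  res
}
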