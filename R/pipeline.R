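#' Assemble a validated pipeline configuration
#'
#' A serialized configuration fully determines every output of
#' [run_pipeline()]: all stochastic stages draw their seed from
#' `master_seed` through the counter scheme in [derive_seed()], so adding a
#' stage never perturbs earlier streams.
#'
#' @param master_seed master integer seed.
#' @param n_control,n_patient observers per group (default 16 each).
#' @param gen_params generator parameters ([default_gen_params()]).
#' @param n_trials,n_blocks,occlusion_levels design settings
#'   ([design_spec()]).
#' @param candidates candidate change points for the piecewise fit.
#' @param cv_folds outer CV folds for encoding/readout fits.
#' @param n_perm permutations for chance levels (at least 100).
#' @param chance_null_levels occlusion levels at which permutation chance
#'   levels are computed (one shared null per level; default all levels; an
#'   empty vector skips them).
#' @param out_dir optional directory; when set, sessions, tables and the
#'   summary JSON are written there.
#' @return validated list of class `kc_config`.
#' @export
run_config <- function(master_seed = 1L, n_control = 16L, n_patient = 16L,
                       gen_params = default_gen_params(),
                       n_trials = 240L, n_blocks = 8L,
                       occlusion_levels = seq(10L, 80L, by = 10L),
                       candidates = c(10, 20, 30, 40, 50),
                       cv_folds = 10L, n_perm = 100L,
                       chance_null_levels = occlusion_levels,
                       out_dir = NULL) {
  if (n_perm < 100L) stop("n_perm must be at least 100 (unstable null mean below)")
  if (n_control < 0L || n_patient < 0L || n_control + n_patient < 2L)
    stop("need at least two observers in total")
  spec <- design_spec(n_trials, n_blocks, occlusion_levels, seed = 0L)
  if (n_trials / length(occlusion_levels) < 20L)
    stop("encoding/readout fits need at least 20 trials per occlusion level")
  stopifnot(all(chance_null_levels %in% occlusion_levels))
  structure(list(master_seed = as.integer(master_seed),
                 n_control = as.integer(n_control),
                 n_patient = as.integer(n_patient),
                 gen_params = gen_params, n_trials = as.integer(n_trials),
                 n_blocks = as.integer(n_blocks),
                 occlusion_levels = as.integer(occlusion_levels),
                 candidates = candidates, cv_folds = as.integer(cv_folds),
                 n_perm = as.integer(n_perm),
                 chance_null_levels = as.integer(chance_null_levels),
                 out_dir = out_dir),
            class = "kc_config")
}

#' Run the full simulation and analysis pipeline
#'
#' simulate stimuli and sessions, then fit the psychometric, encoding,
#' readout and alignment analyses, returning every fitted object plus a
#' summary list. Identical configurations give byte-identical summaries.
#'
#' Permutation chance levels are computed once per occlusion level (the
#' design matrix is shared by all observers at a level) and attached to each
#' observer's readout fit at that level.
#'
#' @param config a `kc_config` from [run_config()].
#' @param quiet suppress progress messages.
#' @return list of class `kc_run_report`.
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "kc_config"))
  say <- function(...) if (!quiet) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  say("simulating stimuli and sessions")
  stimuli <- stage("stimuli", make_stimulus_set(
    config$gen_params, seed = derive_seed(config$master_seed, "stimuli")))
  design <- stage("design", make_design(design_spec(
    config$n_trials, config$n_blocks, config$occlusion_levels,
    seed = derive_seed(config$master_seed, "design")), stimuli))
  profiles <- c(
    replicate(config$n_control,
              observer_preset("control", config$gen_params), simplify = FALSE),
    replicate(config$n_patient,
              observer_preset("patient", config$gen_params), simplify = FALSE))
  names(profiles) <- c(sprintf("ctl%02d", seq_len(config$n_control)),
                       sprintf("pat%02d", seq_len(config$n_patient)))
  sessions <- stage("observers", simulate_cohort(
    profiles, design, stimuli, master_seed = config$master_seed))

  say("psychometric analyses")
  curve <- stage("psychometrics", empirical_curve(sessions))
  two_groups <- config$n_control > 0 && config$n_patient > 0
  pw <- stage("psychometrics",
              fit_piecewise_psychometric(sessions, config$candidates))
  acc <- stage("psychometrics", accuracy_by_occlusion(sessions))
  inter <- if (two_groups) stage("psychometrics",
                                 group_interaction_test(sessions)) else NULL
  calib <- stage("psychometrics",
                 confidence_accuracy_ratio(sessions, pw$change_point))

  say("encoding models")
  enc <- stage("encoding", lapply(config$occlusion_levels, function(l)
    fit_encoding(design, stimuli, l, k = config$cv_folds,
                 seed = derive_seed(config$master_seed, "cv", l))))
  prof <- stage("encoding", encoding_profile(enc))

  say("readout models")
  reads <- list()
  for (id in unique(sessions$observer_id)) {
    one <- sessions[sessions$observer_id == id, ]
    for (l in config$occlusion_levels) {
      reads[[paste(id, l)]] <- stage("readout", fit_readout(
        one, stimuli, l, k = config$cv_folds,
        seed = derive_seed(config$master_seed, "cv",
                           1000L * l + match(id, unique(sessions$observer_id)))))
    }
  }
  chance <- list()
  for (l in config$chance_null_levels) {
    ref <- reads[[paste(unique(sessions$observer_id)[1], l)]]
    ref_fit <- ref
    ref_fit$labels <- design$configuration[design$occlusion_level == l] ==
      "small_first"
    nul <- stage("chance_null", readout_chance_null(
      ref_fit, n_perm = config$n_perm,
      seed = derive_seed(config$master_seed, "permutations", l),
      k = min(config$cv_folds, 5L)))
    chance[[as.character(l)]] <- nul$null_distribution
    for (nm in names(reads)) {
      if (reads[[nm]]$occlusion_level == l) {
        reads[[nm]]$chance_level <- mean(nul$null_distribution)
        reads[[nm]]$null_quantiles <- nul$null_quantiles
      }
    }
  }
  bias <- data.frame(
    observer_id = vapply(reads, function(f) f$observer_id, character(1)),
    group = vapply(reads, function(f) f$group, character(1)),
    occlusion_level = vapply(reads, function(f) f$occlusion_level, numeric(1)),
    bias_fraction = vapply(reads, bias_fraction, numeric(1)),
    row.names = NULL)
  preds <- stage("readout", readout_predictions(reads))
  align <- stage("alignment", alignment_profile(reads, enc))

  read_tab <- data.frame(
    observer_id = bias$observer_id, group = bias$group,
    occlusion_level = bias$occlusion_level,
    cv_accuracy = vapply(reads, function(f) f$cv_accuracy, numeric(1)),
    chance_level = vapply(reads, function(f) f$chance_level, numeric(1)),
    row.names = NULL)
  summary <- list(
    config = config[setdiff(names(config), c("gen_params", "out_dir"))],
    n_stimuli = nrow(stimuli$meta),
    change_point = pw$change_point,
    lrt_p = pw$lrt$p_value,
    slopes = pw$slopes,
    interaction = if (!is.null(inter)) as.data.frame(inter$coefficients) else NULL,
    calibration = stats::aggregate(ratio ~ group + period, data = calib$table,
                                   FUN = mean),
    encoding = data.frame(
      occlusion_level = config$occlusion_levels,
      cv_accuracy = vapply(enc, function(f) f$cv_accuracy, numeric(1)),
      cv_sem = vapply(enc, function(f) f$cv_sem, numeric(1))),
    readout = read_tab,
    bias = bias,
    feature_order = prof$feature_order)

  report <- structure(list(stimuli = stimuli, design = design,
                           sessions = sessions, curve = curve,
                           psychometric = pw, accuracy = acc,
                           interaction = inter, calibration = calib,
                           encoding = enc, encoding_profile = prof,
                           readout = reads, chance_nulls = chance,
                           bias = bias, predictions = preds,
                           alignment = align, summary = summary),
                      class = "kc_run_report")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_sessions(sessions, file.path(config$out_dir, "sessions.csv"))
    write_stimuli(stimuli, file.path(config$out_dir, "stimuli.csv"))
    utils::write.csv(curve, file.path(config$out_dir, "curve.csv"),
                     row.names = FALSE)
    utils::write.csv(align$cells, file.path(config$out_dir, "alignment.csv"),
                     row.names = FALSE)
    jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "columns", force = TRUE)
  }
  report
}

#' @export
print.kc_run_report <- function(x, ...) {
  cat(sprintf("<kc_run_report> %d observers x %d trials; change point +-%d%%\n",
              length(unique(x$sessions$observer_id)),
              max(x$sessions$trial_id), x$summary$change_point))
  cat("encoding CV accuracy by occlusion:\n")
  print(round(stats::setNames(x$summary$encoding$cv_accuracy,
                              paste0(x$summary$encoding$occlusion_level, "%")), 3))
  invisible(x)
}
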