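#' Write / read a stimulus set as long CSV
#'
#' Long format with one row per stimulus x feature x epoch: columns
#' stimulus_id, agent_id, exemplar, object_size, feature, epoch, value.
#'
#' @param stimuli a `kc_stimuli` object.
#' @param path CSV path.
#' @export
write_stimuli <- function(stimuli, path) {
  stopifnot(inherits(stimuli, "kc_stimuli"))
  F <- dim(stimuli$features)[2]; E <- dim(stimuli$features)[3]
  long <- do.call(rbind, lapply(seq_len(nrow(stimuli$meta)), function(i) {
    data.frame(stimuli$meta[i, c("stimulus_id", "agent_id", "exemplar",
                                 "object_size")],
               feature = rep(dimnames(stimuli$features)[[2]], each = E),
               epoch = rep(seq_len(E), times = F),
               value = as.vector(t(stimuli$features[i, , ])),
               row.names = NULL)
  }))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stimuli
#' @param params optionally, the `kc_params` to re-attach (readers of
#'   external data will not have one; presets then need explicit params).
#' @return `read_stimuli` returns a `kc_stimuli` object.
#' @export
read_stimuli <- function(path, params = NULL) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("stimulus_id", "agent_id", "exemplar", "object_size", "feature",
            "epoch", "value")
  if (!all(need %in% names(long))) stop("missing stimulus columns")
  if (!all(is.finite(long$value))) stop("non-finite feature values")
  ids <- unique(long$stimulus_id)
  feats <- unique(long$feature)
  E <- max(long$epoch)
  arr <- array(NA_real_, dim = c(length(ids), length(feats), E),
               dimnames = list(ids, feats, NULL))
  idx <- cbind(match(long$stimulus_id, ids), match(long$feature, feats),
               long$epoch)
  arr[idx] <- long$value
  meta <- unique(long[c("stimulus_id", "agent_id", "exemplar", "object_size")])
  meta <- meta[match(ids, meta$stimulus_id), ]
  meta$duration_ms <- NA_real_
  rownames(meta) <- NULL
  structure(list(features = arr, meta = meta, params = params),
            class = "kc_stimuli")
}

#' Write / read observer sessions as CSV
#'
#' One row per trial with all trial fields plus observer_id and group.
#'
#' @param sessions a `kc_session` data.frame.
#' @param path CSV path.
#' @export
write_sessions <- function(sessions, path) {
  utils::write.csv(as.data.frame(sessions), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sessions
#' @return `read_sessions` returns a `kc_session` data.frame.
#' @export
read_sessions <- function(path) {
  s <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial_id", "block", "occlusion_level", "first_stimulus_id",
            "second_stimulus_id", "configuration", "instruction",
            "observer_id", "group", "chose_small_first", "correct",
            "confidence")
  if (!all(need %in% names(s)))
    stop("missing session columns: ", paste(setdiff(need, names(s)), collapse = ", "))
  s$chose_small_first <- as.logical(s$chose_small_first)
  s$correct <- as.logical(s$correct)
  class(s) <- c("kc_session", class(s))
  s
}
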