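#' Alignment of readout weights against encoding weights
#'
#' For every observer and occlusion level, each feature-by-epoch cell gets a
#' readout weight fraction `|beta_read[f,e]| / sum(|beta_read|)` and an
#' alignment sign: positive when the readout and encoding coefficients agree
#' in sign, negative when they disagree, and null when either coefficient's
#' magnitude falls below `magnitude_floor` times its vector's total absolute
#' weight (near-zero weights carry no interpretable direction). Fractions
#' sum to 1 per observer and level; group averages are means of per-observer
#' fractions, with the group sign taken from the group-mean readout
#' coefficient. Features are ordered by their encoding weight at the highest
#' fitted level, descending.
#'
#' @param read_fits list of `kc_readout_fit` objects.
#' @param enc_fits list of `kc_encoding_fit` objects covering the readout
#'   fits' occlusion levels.
#' @param magnitude_floor fraction of total absolute weight below which a
#'   cell's sign is "null" (default 0.01).
#' @return list of class `kc_alignment`: `cells` (per-observer tidy
#'   data.frame), `group` (group-averaged tidy data.frame),
#'   `feature_order`, `n_excluded` (all-zero readout vectors).
#' @export
alignment_profile <- function(read_fits, enc_fits, magnitude_floor = 0.01) {
  enc_levels <- vapply(enc_fits, function(f) f$occlusion_level, numeric(1))
  rows <- list(); n_excluded <- 0L
  for (rf in read_fits) {
    j <- match(rf$occlusion_level, enc_levels)
    if (is.na(j)) stop("no encoding fit at occlusion level ", rf$occlusion_level)
    ef <- enc_fits[[j]]
    br <- rf$beta_read; be <- ef$beta_enc[names(br)]
    tot_r <- sum(abs(br)); tot_e <- sum(abs(be))
    if (tot_r < 1e-12) { n_excluded <- n_excluded + 1L; next }
    frac <- abs(br) / tot_r
    null_cell <- abs(br) < magnitude_floor * tot_r |
                 abs(be) < magnitude_floor * tot_e
    sgn <- ifelse(null_cell, "null",
                  ifelse(br * be > 0, "positive", "negative"))
    fe <- do.call(rbind, strsplit(names(br), "_e"))
    rows[[length(rows) + 1L]] <- data.frame(
      observer_id = rf$observer_id, group = rf$group,
      occlusion_level = rf$occlusion_level,
      feature = fe[, 1], epoch = as.integer(fe[, 2]),
      fraction = unname(frac), alignment = unname(sgn),
      beta_read = unname(br), beta_enc = unname(be),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) stop("all readout vectors were zero; nothing to align")
  cells <- do.call(rbind, rows)

  grp <- stats::aggregate(cbind(fraction, beta_read) ~
                            group + occlusion_level + feature + epoch,
                          data = cells, FUN = mean)
  enc_lookup <- cells[!duplicated(cells[c("occlusion_level", "feature", "epoch")]),
                      c("occlusion_level", "feature", "epoch", "beta_enc")]
  grp <- merge(grp, enc_lookup, by = c("occlusion_level", "feature", "epoch"))
  tot <- stats::aggregate(list(tot = abs(grp$beta_read)),
                          grp[c("group", "occlusion_level")], FUN = sum)
  grp <- merge(grp, tot, by = c("group", "occlusion_level"))
  grp$alignment <- ifelse(
    abs(grp$beta_read) < magnitude_floor * grp$tot, "null",
    ifelse(grp$beta_read * grp$beta_enc > 0, "positive", "negative"))
  grp$tot <- NULL

  top <- enc_fits[[which.max(enc_levels)]]
  feat <- unique(cells$feature)
  enc_mag <- vapply(feat, function(f) {
    sum(abs(top$beta_enc[grepl(paste0("^", f, "_e"), names(top$beta_enc))]))
  }, numeric(1))
  structure(list(cells = cells, group = grp,
                 feature_order = feat[order(enc_mag, decreasing = TRUE)],
                 magnitude_floor = magnitude_floor, n_excluded = n_excluded),
            class = "kc_alignment")
}

#' @export
print.kc_alignment <- function(x, ...) {
  cat(sprintf("<kc_alignment> %d observer-level cells, %d group rows; floor=%g; %d observer/level profiles excluded\n",
              nrow(x$cells), nrow(x$group), x$magnitude_floor, x$n_excluded))
  cat("feature order (by encoding weight at the highest level):",
      paste(x$feature_order, collapse = " "), "\n")
  invisible(x)
}

#' Per-observer readout strength
#'
#' Scalar summary used for covariate screens: mean over occlusion levels of
#' cross-validated readout accuracy minus the permutation chance level
#' (which must have been attached with [readout_chance_null()]; levels
#' without a chance level fall back to 0.5).
#'
#' @param fits list of `kc_readout_fit` objects.
#' @return data.frame observer_id, group, readout_strength.
#' @export
readout_strength <- function(fits) {
  d <- do.call(rbind, lapply(fits, function(f) data.frame(
    observer_id = f$observer_id, group = f$group,
    excess = f$cv_accuracy -
      (if (is.finite(f$chance_level)) f$chance_level else 0.5),
    stringsAsFactors = FALSE)))
  out <- stats::aggregate(excess ~ observer_id + group, data = d, FUN = mean)
  names(out)[names(out) == "excess"] <- "readout_strength"
  out
}

#' Correlation screen of behavioural metrics against covariates
#'
#' Pearson and Spearman correlations (two-sided p) of each per-observer
#' metric against each covariate (e.g. illness duration, medication dose,
#' symptom scores), merged on observer_id.
#'
#' @param metrics data.frame with observer_id and one or more numeric metric
#'   columns.
#' @param covariates data.frame with observer_id and one or more numeric
#'   covariate columns.
#' @return tidy data.frame: metric, covariate, n, pearson_r, pearson_p,
#'   spearman_r (rho), spearman_p; constant vectors give NA with a flag
#'   column `defined`.
#' @export
covariate_correlations <- function(metrics, covariates) {
  m <- merge(metrics, covariates, by = "observer_id")
  met_cols <- setdiff(names(metrics), c("observer_id", "group"))
  cov_cols <- setdiff(names(covariates), c("observer_id", "group"))
  rows <- list()
  for (mc in met_cols) for (cc in cov_cols) {
    ok <- is.finite(m[[mc]]) & is.finite(m[[cc]])
    x <- m[[mc]][ok]; y <- m[[cc]][ok]
    if (sum(ok) < 4L) stop("need at least 4 observers with non-missing values")
    defined <- stats::sd(x) > 0 && stats::sd(y) > 0
    if (defined) {
      pe <- stats::cor.test(x, y, method = "pearson")
      sp <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
      rows[[paste(mc, cc)]] <- data.frame(
        metric = mc, covariate = cc, n = sum(ok), defined = TRUE,
        pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
        spearman_rho = unname(sp$estimate), spearman_p = sp$p.value)
    } else {
      rows[[paste(mc, cc)]] <- data.frame(
        metric = mc, covariate = cc, n = sum(ok), defined = FALSE,
        pearson_r = NA_real_, pearson_p = NA_real_,
        spearman_rho = NA_real_, spearman_p = NA_real_)
    }
  }
  out <- do.call(rbind, rows); rownames(out) <- NULL
  out
}
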