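signed_occlusion <- function(sessions) {
  ifelse(sessions$configuration == "small_first", 1, -1) * sessions$occlusion_level
}

#' Empirical psychometric curve
#'
#' P(respond "small first") as a function of signed occlusion (+o on trials
#' where the small object came first, -o otherwise), averaged first within
#' and then across participants, per group.
#'
#' @param sessions a `kc_session` data.frame (any number of observers).
#' @return data.frame with group, signed_occlusion, p_small_first, sem,
#'   n_observers; cells with no trials are NA, not 0.
#' @export
empirical_curve <- function(sessions) {
  stopifnot(nrow(sessions) > 0)
  s <- data.frame(group = sessions$group, observer_id = sessions$observer_id,
                  x = signed_occlusion(sessions),
                  y = as.numeric(sessions$chose_small_first))
  lv <- sort(unique(abs(s$x)))
  grid <- expand.grid(group = unique(s$group),
                      signed_occlusion = c(-rev(lv), lv),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  per_obs <- stats::aggregate(y ~ group + observer_id + x, data = s, FUN = mean)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    v <- per_obs$y[per_obs$group == grid$group[i] &
                   per_obs$x == grid$signed_occlusion[i]]
    data.frame(grid[i, , drop = FALSE],
               p_small_first = if (length(v)) mean(v) else NA_real_,
               sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
               n_observers = length(v))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$group, out$signed_occlusion), ]
}

# basis on the decades-of-percent scale to keep the GLMM well conditioned;
# reported slopes are converted back to logit per percent
piecewise_basis <- function(x, cp) {
  list(b1 = sign(x) * pmin(abs(x), cp) / 10,
       b2 = sign(x) * pmax(abs(x) - cp, 0) / 10)
}

#' Piecewise (change-point) psychometric fit
#'
#' For each candidate change point c, fits a binomial mixed model of the
#' "small first" response on a continuous two-segment piecewise-linear basis
#' of signed occlusion (knots at -c and +c, odd-symmetric about 0: one early
#' and one late slope), with a participant random intercept and, when both
#' groups are present, group main effects and group-by-segment-slope
#' interactions. The change point minimizing AIC is selected; a
#' likelihood-ratio test compares the two-segment model against the
#' single-slope model at the selected knot.
#'
#' Estimation is by maximum likelihood with lme4's Laplace approximation
#' (`engine = "glmm"`). The documented fallback `engine = "fixed"` replaces
#' the random intercept with fixed per-participant intercepts in an ordinary
#' logistic regression.
#'
#' @param sessions a `kc_session` data.frame with two or more participants.
#' @param candidates candidate change points (percent), a subset of 10..70.
#' @param engine `"glmm"` (default) or `"fixed"`.
#' @param group_terms include group interactions when both groups are
#'   present (default TRUE).
#' @return object of class `kc_psychometric_fit`: selected `change_point`,
#'   `slopes` (per segment and group, logit per percent, with SE),
#'   `group_terms` coefficient table, `candidate_table`, `lrt`
#'   (two-segment vs single slope), `random_effect_sd`, `aic`, `loglik`.
#' @export
fit_piecewise_psychometric <- function(sessions, candidates = c(10, 20, 30, 40, 50),
                                       engine = c("glmm", "fixed"),
                                       group_terms = TRUE) {
  engine <- match.arg(engine)
  if (length(unique(sessions$observer_id)) < 2L)
    stop("need at least two participants")
  if (!all(candidates %in% seq(10, 70, by = 10)))
    stop("candidates must lie in 10..70 on the 10% grid")
  d <- data.frame(y = as.numeric(sessions$chose_small_first),
                  x = signed_occlusion(sessions),
                  observer_id = factor(sessions$observer_id),
                  group = factor(sessions$group))
  d$xs <- d$x / 10
  two_groups <- group_terms && nlevels(d$group) > 1L

  fit_one <- function(formula, data) {
    if (engine == "glmm")
      lme4::glmer(formula, data = data, family = stats::binomial)
    else
      stats::glm(formula, data = data, family = stats::binomial)
  }
  rhs_piece <- if (two_groups) "group + b1 + b2 + b1:group + b2:group"
               else "b1 + b2"
  rhs_line  <- if (two_groups) "group + xs + xs:group" else "xs"
  re <- if (engine == "glmm") " + (1 | observer_id)" else " + observer_id"

  fits <- list(); aics <- rep(NA_real_, length(candidates))
  for (i in seq_along(candidates)) {
    bb <- piecewise_basis(d$x, candidates[i])
    di <- cbind(d, b1 = bb$b1, b2 = bb$b2)
    f <- tryCatch(fit_one(stats::as.formula(paste0("y ~ ", rhs_piece, re)), di),
                  error = function(e) NULL)
    if (is.null(f)) {
      warning("candidate change point ", candidates[i],
              " dropped (non-convergence)")
      next
    }
    fits[[i]] <- f
    aics[i] <- stats::AIC(f)
  }
  if (all(is.na(aics))) stop("no candidate change point converged")
  best <- which.min(aics)
  cp <- candidates[best]
  fit <- fits[[best]]

  bb <- piecewise_basis(d$x, cp)
  di <- cbind(d, b1 = bb$b1, b2 = bb$b2)
  fit_line <- fit_one(stats::as.formula(paste0("y ~ ", rhs_line, re)), di)
  lrt_stat <- as.numeric(2 * (stats::logLik(fit) - stats::logLik(fit_line)))
  lrt_df <- attr(stats::logLik(fit), "df") - attr(stats::logLik(fit_line), "df")
  lrt_p <- stats::pchisq(lrt_stat, df = lrt_df, lower.tail = FALSE)

  co <- if (engine == "glmm") summary(fit)$coefficients
        else summary(fit)$coefficients
  keep <- grepl("^b1|^b2|group", rownames(co)) & !grepl("observer_id", rownames(co))
  coefs <- co[keep, , drop = FALSE]

  slopes <- slope_table(co, d, cp)
  structure(list(
    change_point = cp,
    slopes = slopes,
    group_terms = coefs,
    candidate_table = data.frame(change_point = candidates, aic = aics),
    lrt = list(statistic = lrt_stat, df = lrt_df, p_value = lrt_p),
    random_effect_sd = if (engine == "glmm")
      sqrt(unlist(lme4::VarCorr(fit))[1]) else NA_real_,
    aic = aics[best], loglik = as.numeric(stats::logLik(fit)),
    engine = engine, model = fit),
    class = "kc_psychometric_fit")
}

# early/late slope estimates (logit per percent) per group from the
# coefficient table; treatment coding, first group level is the reference
slope_table <- function(co, d, cp) {
  est <- co[, 1]; se <- co[, 2]
  groups <- levels(d$group)
  rows <- list()
  for (g in groups) {
    for (seg in c("b1", "b2")) {
      base <- est[seg]; var_tot <- se[seg]^2
      inter <- paste0(seg, ":group", g)
      if (inter %in% names(est)) {
        base <- base + est[inter]
        var_tot <- var_tot + se[inter]^2  # ignores covariance; Wald per-term
      }
      rows[[paste(g, seg)]] <- data.frame(
        group = g, segment = if (seg == "b1") "early" else "late",
        slope = unname(base) / 10, se = sqrt(var_tot) / 10)
    }
  }
  out <- do.call(rbind, rows); rownames(out) <- NULL
  out
}

#' @export
print.kc_psychometric_fit <- function(x, ...) {
  cat(sprintf("<kc_psychometric_fit> change point +-%d%% (AIC %.1f), LRT p=%.3g, engine=%s\n",
              x$change_point, x$aic, x$lrt$p_value, x$engine))
  print(x$slopes, row.names = FALSE)
  invisible(x)
}

#' Prediction accuracy by occlusion level
#'
#' Fraction of correct responses per occlusion level, averaged first within
#' participants (so unbalanced missingness cannot bias the mean), then
#' across participants per group. With `by_stimulus = TRUE`, accuracy is
#' additionally resolved per stimulus pair, which can expose above-chance
#' individual movements inside an at-chance period.
#'
#' @param sessions a `kc_session` data.frame.
#' @param by_stimulus resolve accuracy per stimulus pair.
#' @return data.frame with group, occlusion_level, accuracy, sem,
#'   n_observers (plus pair when `by_stimulus`).
#' @export
accuracy_by_occlusion <- function(sessions, by_stimulus = FALSE) {
  stopifnot(nrow(sessions) > 0)
  s <- data.frame(group = sessions$group, observer_id = sessions$observer_id,
                  occlusion_level = sessions$occlusion_level,
                  correct = as.numeric(sessions$correct))
  if (by_stimulus) {
    s$pair <- paste(pmin(sessions$first_stimulus_id, sessions$second_stimulus_id),
                    pmax(sessions$first_stimulus_id, sessions$second_stimulus_id))
    agg <- stats::aggregate(correct ~ group + occlusion_level + pair, data = s,
                            FUN = mean)
    n <- stats::aggregate(correct ~ group + occlusion_level + pair, data = s,
                          FUN = length)
    agg$n_trials <- n$correct
    names(agg)[names(agg) == "correct"] <- "accuracy"
    return(agg)
  }
  per_obs <- stats::aggregate(correct ~ group + observer_id + occlusion_level,
                              data = s, FUN = mean)
  agg <- stats::aggregate(correct ~ group + occlusion_level, data = per_obs,
                          FUN = function(v) c(mean(v), stats::sd(v) / sqrt(length(v)),
                                              length(v)))
  out <- data.frame(group = agg$group, occlusion_level = agg$occlusion_level,
                    accuracy = agg$correct[, 1], sem = agg$correct[, 2],
                    n_observers = agg$correct[, 3])
  out[order(out$group, out$occlusion_level), ]
}

#' Group-by-occlusion interaction on choice probability
#'
#' Binomial mixed model of the "small first" response on group, signed
#' occlusion (linear trend in decades of percent: +o/10 on small-first
#' trials, -o/10 on large-first trials) and their interaction, with a
#' participant random intercept. The signed-occlusion slope is the rate of
#' evidence integration; group coding is treatment coding with `control` as
#' the reference level when present, so a patient integration-rate deficit
#' appears as a negative group-by-occlusion estimate.
#'
#' @param sessions a `kc_session` data.frame containing both groups.
#' @param engine `"glmm"` or `"fixed"` (fixed per-participant intercepts).
#' @return coefficient table (estimate, SE, Wald z, p) of class
#'   `kc_interaction_test` with the fitted model attached.
#' @export
group_interaction_test <- function(sessions, engine = c("glmm", "fixed")) {
  engine <- match.arg(engine)
  groups <- unique(sessions$group)
  if (length(groups) < 2L)
    stop("both observer groups must be present for an interaction test")
  lev <- if ("control" %in% groups) c("control", setdiff(groups, "control"))
         else sort(groups)
  d <- data.frame(y = as.numeric(sessions$chose_small_first),
                  group = factor(sessions$group, levels = lev),
                  occ = signed_occlusion(sessions) / 10,
                  observer_id = factor(sessions$observer_id))
  fit <- if (engine == "glmm")
    lme4::glmer(y ~ group * occ + (1 | observer_id), data = d,
                family = stats::binomial)
  else
    stats::glm(y ~ group * occ + observer_id, data = d,
               family = stats::binomial)
  co <- summary(fit)$coefficients
  co <- co[!grepl("observer_id", rownames(co)), , drop = FALSE]
  structure(list(coefficients = co, engine = engine, model = fit),
            class = "kc_interaction_test")
}

#' @export
print.kc_interaction_test <- function(x, ...) {
  cat("<kc_interaction_test> fixed effects (binomial", x$engine, "fit):\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Confidence-accuracy calibration ratio by integration period
#'
#' Confidence is normalized to [0, 1] as (c - 1)/3; within each observer and
#' integration period (early: occlusion at or below the change point; late:
#' above it) the calibration ratio is mean normalized confidence divided by
#' mean accuracy. A linear mixed model of the ratio on group x period with a
#' participant random intercept tests whether calibration differs between
#' groups across periods.
#'
#' @param sessions a `kc_session` data.frame (confidence must be present).
#' @param change_point period boundary in percent (default 20).
#' @return list of class `kc_calibration`: `table` (observer x period means,
#'   ratio), `periods`, `test` (fixed-effect table of the mixed model, NULL
#'   when only one group), `n_excluded` (zero-accuracy cells).
#' @export
confidence_accuracy_ratio <- function(sessions, change_point = 20) {
  stopifnot(any(is.finite(sessions$confidence)))
  s <- sessions[is.finite(sessions$confidence), ]
  s$period <- factor(ifelse(s$occlusion_level <= change_point, "early", "late"),
                     levels = c("early", "late"))
  s$conf_norm <- (s$confidence - 1) / 3
  acc <- stats::aggregate(cbind(accuracy = as.numeric(correct),
                                confidence = conf_norm) ~
                            group + observer_id + period, data = s, FUN = mean)
  acc$ratio <- ifelse(acc$accuracy > 0, acc$confidence / acc$accuracy, NA_real_)
  n_excluded <- sum(!is.finite(acc$ratio))
  tab <- acc[is.finite(acc$ratio), ]
  test <- NULL
  if (length(unique(tab$group)) > 1L) {
    lev <- if ("control" %in% tab$group)
      c("control", setdiff(unique(tab$group), "control")) else sort(unique(tab$group))
    tab$group <- factor(tab$group, levels = lev)
    m <- lmerTest::lmer(ratio ~ group * period + (1 | observer_id), data = tab)
    test <- summary(m)$coefficients
  }
  structure(list(table = tab,
                 periods = c(early = paste0("10-", change_point, "%"),
                             late = paste0(change_point + 10, "-max%")),
                 test = test, n_excluded = n_excluded),
            class = "kc_calibration")
}

#' @export
print.kc_calibration <- function(x, ...) {
  cat("<kc_calibration> per-period group means of confidence/accuracy ratio:\n")
  print(stats::aggregate(ratio ~ group + period, data = x$table, FUN = mean))
  if (!is.null(x$test)) {
    cat("group x period fixed effects:\n")
    print(round(x$test, 4))
  }
  invisible(x)
}
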