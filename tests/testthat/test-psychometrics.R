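make_two_group_sessions <- function(n_per_group = 4, master = 9) {
  fix_memo(sprintf("two_group_%d_%d", n_per_group, master), {
    params <- fix_params()
    st <- fix_stimuli(); de <- fix_design()
    profs <- c(replicate(n_per_group, observer_preset("control", params),
                         simplify = FALSE),
               replicate(n_per_group, observer_preset("patient", params),
                         simplify = FALSE))
    names(profs) <- c(sprintf("ctl%02d", 1:n_per_group),
                      sprintf("pat%02d", 1:n_per_group))
    simulate_cohort(profs, de, st, master_seed = master)
  })
}

test_that("empirical curve covers all signed levels and respects perfect observers", {
  s <- fix_control_session()
  cv <- empirical_curve(s)
  expect_equal(sort(unique(cv$signed_occlusion)),
               c(-seq(80, 10, -10), seq(10, 80, 10)))
  expect_true(all(cv$p_small_first >= 0 & cv$p_small_first <= 1, na.rm = TRUE))
  # noiseless observer of noiseless stimuli: 0 at every negative, 1 at
  # every positive signed occlusion
  p0 <- default_gen_params(agent_sd = 0, noise_sd = 0)
  st0 <- make_stimulus_set(p0, seed = 4)
  de0 <- make_design(design_spec(seed = 5), st0)
  nl <- simulate_observer(observer_preset("control", p0,
                                          noise_sd = 0, lapse = 0),
                          de0, st0, seed = 3)
  cvn <- empirical_curve(nl)
  expect_true(all(cvn$p_small_first[cvn$signed_occlusion > 0] == 1))
  expect_true(all(cvn$p_small_first[cvn$signed_occlusion < 0] == 0))
})

test_that("relabeling small and large maps the curve to its mirror exactly", {
  s <- fix_control_session()
  flip <- s
  flip$configuration <- ifelse(s$configuration == "small_first",
                               "large_first", "small_first")
  flip$chose_small_first <- !s$chose_small_first
  a <- empirical_curve(s)
  b <- empirical_curve(flip)
  m <- merge(a, b, by = "group", suffixes = c("", ".flip"))
  m <- m[m$signed_occlusion == -m$signed_occlusion.flip, ]
  expect_equal(m$p_small_first, 1 - m$p_small_first.flip)
})

test_that("patient cohorts recover a change point of 20 with a near-zero early slope", {
  st <- fix_stimuli(); de <- fix_design()
  profs <- replicate(12, observer_preset("patient", fix_params()),
                     simplify = FALSE)
  names(profs) <- sprintf("pat%02d", 1:12)
  ses <- simulate_cohort(profs, de, st, master_seed = 5)
  fit <- fit_piecewise_psychometric(ses, c(10, 20, 30, 40, 50))
  expect_equal(fit$change_point, 20)
  expect_lt(fit$lrt$p_value, 0.05)
  early <- fit$slopes[fit$slopes$segment == "early", ]
  late <- fit$slopes[fit$slopes$segment == "late", ]
  # early segment is flat relative to the rising late segment
  expect_lt(abs(early$slope), 0.25 * late$slope)
  expect_gt(late$slope, 2 * late$se)
  expect_true(all(fit$candidate_table$change_point == c(10, 20, 30, 40, 50)))
  expect_equal(min(fit$candidate_table$aic), fit$aic)
})

test_that("random responders produce flat slopes within noise", {
  st <- fix_stimuli(); de <- fix_design()
  rnd <- observer_preset("control", fix_params())
  rnd$weights[] <- 0  # evidence-free responder
  profs <- replicate(6, rnd, simplify = FALSE)
  ses <- simulate_cohort(profs, de, st, master_seed = 8)
  fit <- suppressMessages(fit_piecewise_psychometric(ses, c(20, 40)))
  # each slope is a null draw; 3 SE bounds the joint check
  expect_true(all(abs(fit$slopes$slope) < 3 * fit$slopes$se))
})

test_that("the fixed-intercept fallback agrees with the mixed fit", {
  ses <- make_two_group_sessions()
  g <- fit_piecewise_psychometric(ses, c(20, 40))
  f <- fit_piecewise_psychometric(ses, c(20, 40), engine = "fixed")
  expect_equal(f$change_point, g$change_point)
  expect_equal(sign(f$slopes$slope), sign(g$slopes$slope))
  expect_true(is.na(f$random_effect_sd))
})

test_that("candidate validation and trial-order invariance hold", {
  ses <- make_two_group_sessions()
  expect_error(fit_piecewise_psychometric(ses, c(20, 80)), "10..70")
  one <- fix_control_session()
  expect_error(fit_piecewise_psychometric(one, 20), "two participants")
  set.seed(33)
  perm <- ses[sample(nrow(ses)), ]
  a <- fit_piecewise_psychometric(ses, c(20, 40))
  b <- fit_piecewise_psychometric(perm, c(20, 40))
  expect_equal(a$change_point, b$change_point)
  expect_equal(a$aic, b$aic, tolerance = 1e-6)
})

test_that("accuracy tables average within participants first", {
  # two observers, one contributing many more trials to a cell: the group
  # mean must weight observers equally, not trials
  s1 <- fix_control_session()
  s2 <- fix_patient_session()
  s2$observer_id <- "ctl02"; s2$group <- "control"
  sub <- rbind(s1, s2[s2$occlusion_level == 40, ][1:6, ])
  acc <- accuracy_by_occlusion(sub)
  a40 <- acc[acc$occlusion_level == 40, ]
  per1 <- mean(s1$correct[s1$occlusion_level == 40])
  per2 <- mean(s2$correct[s2$occlusion_level == 40][1:6])
  expect_equal(a40$accuracy, mean(c(per1, per2)))
  expect_equal(a40$n_observers, 2)
  # all-correct sessions give accuracy 1 everywhere
  s1$correct <- TRUE
  expect_true(all(accuracy_by_occlusion(s1)$accuracy == 1))
})

test_that("per-stimulus-pair accuracy exposes discernible movements", {
  s <- fix_patient_session()
  acc <- accuracy_by_occlusion(s, by_stimulus = TRUE)
  expect_true(all(c("pair", "accuracy", "n_trials") %in% names(acc)))
  expect_equal(sum(acc$n_trials), nrow(s))
})

test_that("group interaction is negative for the patient deficit and needs both groups", {
  ses <- make_two_group_sessions()
  it <- suppressMessages(group_interaction_test(ses))
  co <- it$coefficients
  expect_true("grouppatient:occ" %in% rownames(co))
  expect_lt(co["grouppatient:occ", "Estimate"], 0)
  expect_gt(co["occ", "Estimate"], 0)
  expect_error(group_interaction_test(fix_control_session()), "both observer groups")
  ff <- suppressMessages(group_interaction_test(ses, engine = "fixed"))
  expect_equal(sign(ff$coefficients["grouppatient:occ", "Estimate"]),
               sign(co["grouppatient:occ", "Estimate"]))
})

test_that("confidence-accuracy ratio is 1 for confident, correct sessions and splits periods", {
  s <- fix_control_session()
  s$confidence <- 4L; s$correct <- TRUE
  cal <- confidence_accuracy_ratio(s, 20)
  expect_true(all(cal$table$ratio == 1))
  expect_equal(levels(cal$table$period), c("early", "late"))
  expect_equal(sum(cal$table$period == "early"), 1L)
})

test_that("patient calibration exceeds control calibration early despite lower accuracy", {
  ses <- make_two_group_sessions()
  cal <- confidence_accuracy_ratio(ses, 20)
  m <- aggregate(cbind(ratio, accuracy) ~ group + period, data = cal$table,
                 FUN = mean)
  early <- m[m$period == "early", ]
  expect_gt(early$ratio[early$group == "patient"],
            early$ratio[early$group == "control"])
  expect_lt(early$accuracy[early$group == "patient"],
            early$accuracy[early$group == "control"])
  ctl <- m[m$group == "control", ]
  expect_gt(ctl$ratio[ctl$period == "late"], ctl$ratio[ctl$period == "early"])
  expect_true(!is.null(cal$test))
})
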