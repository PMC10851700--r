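test_that("presets encode the group structure", {
  ctl <- observer_preset("control", fix_params())
  pat <- observer_preset("patient", fix_params())
  expect_equal(ctl$null_window_pct, 0)
  expect_equal(ctl$confidence_miscalibrated_window_pct, 0)
  expect_equal(pat$null_window_pct, 20)
  expect_equal(pat$confidence_miscalibrated_window_pct, 20)
  # patient weights for epochs 1-2 are exactly zero, later epochs attenuated
  epoch <- as.integer(sub(".*_e", "", names(pat$weights)))
  expect_true(all(pat$weights[epoch <= 2] == 0))
  late <- epoch > 2
  expect_equal(pat$weights[late], 0.7 * ctl$weights[late])
  expect_error(observer_preset("other"), "arg")
  expect_error(observer_preset("control", fix_params(), lapse = 0.5), "lapse")
})

test_that("sessions are reproducible and internally consistent", {
  a <- simulate_observer(observer_preset("control", fix_params()),
                         fix_design(), fix_stimuli(), seed = 11)
  b <- simulate_observer(observer_preset("control", fix_params()),
                         fix_design(), fix_stimuli(), seed = 11)
  expect_identical(a, b)
  # correct <=> (chose_small_first <=> configuration == small_first)
  expect_equal(a$correct,
               a$chose_small_first == (a$configuration == "small_first"))
  # response interval consistent with instruction and choice
  expect_equal(a$response_interval,
               ifelse(a$instruction == "report_small",
                      ifelse(a$chose_small_first, "first", "second"),
                      ifelse(a$chose_small_first, "second", "first")))
  expect_true(all(a$confidence %in% 1:4))
})

test_that("noiseless observers recover the sign of the weighted evidence exactly", {
  prof <- observer_preset("control", fix_params(), noise_sd = 0, lapse = 0)
  s <- simulate_observer(prof, fix_design(), fix_stimuli(), seed = 2)
  mu <- kinecode:::trial_decision_means(prof, fix_design(), fix_stimuli())
  expect_equal(s$chose_small_first, mu > 0)
})

test_that("a noiseless observer of noiseless stimuli is perfectly accurate", {
  p0 <- default_gen_params(agent_sd = 0, noise_sd = 0)
  st <- make_stimulus_set(p0, seed = 1)
  de <- make_design(design_spec(seed = 2), st)
  prof <- observer_preset("control", p0, noise_sd = 0, lapse = 0)
  s <- simulate_observer(prof, de, st, seed = 3)
  expect_true(all(s$correct))
  expect_true(all(tapply(s$correct, s$occlusion_level, mean) == 1))
})

test_that("patient choices at fully-nulled occlusions are evidence-free", {
  pat <- observer_preset("patient", fix_params())
  s <- fix_patient_session()
  mu <- kinecode:::trial_decision_means(pat, fix_design(), fix_stimuli())
  expect_true(all(mu[s$occlusion_level <= 20] == 0))
  # long-run accuracy converges to one half on those trials
  many <- do.call(rbind, lapply(1:20, function(i)
    simulate_observer(pat, fix_design(), fix_stimuli(), seed = 300 + i)))
  early <- many[many$occlusion_level <= 20, ]
  expect_lt(abs(mean(early$correct) - 0.5), 3 * 0.5 / sqrt(nrow(early)))
})

test_that("confidence in the miscalibrated window is decoupled from evidence", {
  pat <- observer_preset("patient", fix_params())
  runs <- do.call(rbind, lapply(1:10, function(i)
    simulate_observer(pat, fix_design(), fix_stimuli(), seed = 500 + i)))
  win <- runs$occlusion_level <= 20
  # within the window: confidence uncorrelated with trial accuracy
  expect_lt(abs(cor(runs$confidence[win], as.numeric(runs$correct[win]))), 0.05)
  # no drop in confidence despite chance accuracy: window confidence tracks
  # the observer's session-wide distribution
  expect_gt(mean(runs$confidence[win]), mean(runs$confidence) - 0.15)
  expect_lt(mean(runs$correct[win]), 0.55)
  # a control's confidence at the same occlusions is evidence-driven and
  # correlates with accuracy there
  ctl_runs <- do.call(rbind, lapply(1:10, function(i)
    simulate_observer(observer_preset("control", fix_params()),
                      fix_design(), fix_stimuli(), seed = 600 + i)))
  cw <- ctl_runs$occlusion_level <= 20
  expect_gt(cor(ctl_runs$confidence[cw], as.numeric(ctl_runs$correct[cw])), 0.05)
})

test_that("simulation rejects designs that reference missing stimuli", {
  de <- fix_design()
  de$first_stimulus_id[1] <- "NOPE"
  expect_error(simulate_observer(observer_preset("control", fix_params()),
                                 de, fix_stimuli()), "absent")
})
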