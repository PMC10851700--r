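test_that("readout fit tracks a noiseless evidence-driven observer", {
  st <- fix_stimuli(); de <- fix_design()
  prof <- observer_preset("control", fix_params(), noise_sd = 0.01, lapse = 0)
  s <- simulate_observer(prof, de, st, seed = 21, observer_id = "nl")
  fit <- fit_readout(s, st, 60, seed = 2)
  expect_s3_class(fit, "kc_readout_fit")
  expect_gt(fit$cv_accuracy, 0.9)
  expect_false(fit$degenerate)
  expect_true(all(fit$predicted_confidence >= 0 & fit$predicted_confidence <= 0.5))
})

test_that("an observer with constant responses yields a degenerate fit", {
  s <- fix_control_session()
  s$chose_small_first <- TRUE
  fit <- fit_readout(s, st <- fix_stimuli(), 40, seed = 1)
  expect_true(fit$degenerate)
  expect_true(all(fit$beta_read == 0))
  expect_equal(fit$cv_accuracy, 1)  # base rate of the constant response
  expect_true(is.na(bias_fraction(fit)))
})

test_that("readout requires a single observer and enough trials", {
  two <- rbind(fix_control_session(), fix_patient_session())
  expect_error(fit_readout(two, fix_stimuli(), 40), "single observer")
  s <- fix_control_session()
  expect_error(fit_readout(s[s$occlusion_level == 40, ][1:10, ],
                           fix_stimuli(), 40), "15 trials")
})

test_that("permutation null is centered at chance, reproducible, and gated", {
  s <- fix_control_session(); st <- fix_stimuli()
  fit <- fit_readout(s, st, 10, seed = 5)
  expect_error(readout_chance_null(fit, n_perm = 50), "at least 100")
  n1 <- readout_chance_null(fit, n_perm = 100, seed = 9, k = 5)
  n2 <- readout_chance_null(fit, n_perm = 100, seed = 9, k = 5)
  expect_identical(n1$null_distribution, n2$null_distribution)
  expect_gt(n1$chance_level, 0.42)
  expect_lt(n1$chance_level, 0.58)
  expect_true(all(diff(n1$null_quantiles) >= 0))
})

test_that("the null mean does not depend on the true signal strength", {
  # same permutation machinery on strong-signal (level 60) and no-signal
  # (zero size effect) features; permuted labels erase the signal in both
  st <- fix_stimuli(); de <- fix_design()
  s <- fix_control_session()
  f_strong <- fit_readout(s, st, 60, seed = 3)
  p0 <- default_gen_params(size_effect_scale = 0)
  st0 <- make_stimulus_set(p0, seed = 31)
  de0 <- make_design(design_spec(seed = 32), st0)
  s0 <- simulate_observer(observer_preset("control", p0), de0, st0, seed = 33)
  f_zero <- fit_readout(s0, st0, 60, seed = 3)
  m1 <- readout_chance_null(f_strong, n_perm = 100, seed = 11, k = 5)$chance_level
  m2 <- readout_chance_null(f_zero, n_perm = 100, seed = 11, k = 5)$chance_level
  expect_lt(abs(m1 - m2), 0.04)
})

test_that("bias fraction implements its closed form on constructed fits", {
  base <- fit_readout(fix_control_session(), fix_stimuli(), 20, seed = 2)
  f0 <- base; f0$b_read <- 0
  expect_equal(bias_fraction(f0), 0)
  f1 <- base; f1$beta_read[] <- 0; f1$b_read <- 0.3
  expect_equal(bias_fraction(f1), 1)
  f2 <- base; f2$beta_read[] <- 0; f2$b_read <- 0
  expect_true(is.na(bias_fraction(f2)))
  # general case: |b| / (|b| + mean |dK beta|)
  ev <- mean(abs(as.vector(base$X %*% base$beta_read)))
  expect_equal(bias_fraction(base),
               abs(base$b_read) / (abs(base$b_read) + ev))
})

test_that("sign-flip test is calibrated on symmetric intercepts", {
  set.seed(4)
  fits <- lapply(rnorm(12, 0, 0.2), function(b) {
    f <- list(b_read = b); class(f) <- "kc_readout_fit"; f
  })
  out <- bias_sign_test(fits, n_flip = 500, seed = 5)
  expect_true(out$p_value > 0.0 && out$p_value <= 1)
  expect_equal(out$n, 12)
  expect_error(bias_sign_test(fits[1]), "two observers")
})

test_that("readout predictions correlate predicted with observed accuracy", {
  st <- fix_stimuli(); de <- fix_design()
  prof <- observer_preset("control", fix_params())
  fits <- list()
  for (i in 1:5) {
    s <- simulate_observer(prof, de, st, seed = 40 + i,
                           observer_id = sprintf("c%02d", i))
    for (l in c(20, 60)) fits[[paste(i, l)]] <- fit_readout(s, st, l, seed = l)
  }
  pr <- readout_predictions(fits)
  expect_equal(nrow(pr$accuracy_pairs), 10L)
  expect_gt(pr$accuracy_cor$r[1], 0.5)  # levels differ strongly in accuracy
  expect_true(all(pr$confidence_pairs$reported_confidence %in% 1:4))
  expect_gt(pr$confidence_cor$r[1], 0)
})

test_that("information read behaves at its anchors and pools levels", {
  st <- fix_stimuli(); de <- fix_design()
  enc <- fit_encoding(de, st, 60, seed = 1)
  read <- fit_readout(fix_control_session(), st, 60, seed = 1)
  # observer reproducing the encoding bound reads all the information
  r_all <- read; r_all$observed_accuracy <- enc$cv_accuracy
  expect_equal(information_read(enc, r_all), 1)
  r_none <- read; r_none$observed_accuracy <- 0.5
  expect_equal(information_read(enc, r_none), 0)
  r_below <- read; r_below$observed_accuracy <- 0.4
  expect_equal(information_read(enc, r_below), 0)  # clipped at zero
  e_chance <- enc; e_chance$cv_accuracy <- 0.5
  expect_true(is.na(information_read(e_chance, read)))
  # pooling averages accuracies over matched levels
  enc2 <- fit_encoding(de, st, 20, seed = 2)
  read2 <- fit_readout(fix_control_session(), st, 20, seed = 2)
  pooled <- information_read(list(enc, enc2), list(read, read2))
  byhand <- max(0, (mean(c(read$observed_accuracy, read2$observed_accuracy)) - 0.5) /
                   (mean(c(enc$cv_accuracy, enc2$cv_accuracy)) - 0.5))
  expect_equal(pooled, byhand)
  expect_error(information_read(enc, read2), "share the occlusion")
})
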