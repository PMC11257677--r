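test_that("VFA T1 fit inverts the SPGR forward model", {
  angles <- c(5, 15, 20, 25); tr <- 0.01
  t1_true <- c(0.8, 1.2, 1.6, 2.4)
  s <- t(sapply(t1_true, function(t1) spgr_signal(950, t1, angles, tr)))
  fit <- fit_t1_vfa(s, angles, tr)
  expect_equal(fit$t1, t1_true, tolerance = 1e-6)
  expect_equal(fit$m0, rep(950, 4), tolerance = 1e-6)

  flat <- fit_t1_vfa(matrix(rep(5, 4), 1), angles, tr)
  expect_true(is.nan(flat$t1))
  expect_error(fit_t1_vfa(matrix(1:4, 1), c(10, 10, 10, 10), tr),
               "distinct flip angles")
})

test_that("VFA T1 fit is accurate under 1% signal noise", {
  angles <- c(5, 15, 20, 25); tr <- 0.01
  s_clean <- spgr_signal(1000, 1.0, angles, tr)
  withr::with_seed(21, {
    s <- matrix(rep(s_clean, each = 1000), 1000, 4)
    s <- s + rnorm(length(s), sd = 0.01 * mean(s_clean))
    fit <- fit_t1_vfa(s, angles, tr)
    expect_lt(abs(median(fit$t1, na.rm = TRUE) - 1.0), 0.05)
  })
})

test_that("signal-to-concentration: baseline gives zero; linear ramp recovered; relative mode proportional", {
  t1_0 <- 1.2; m0 <- 1000; r1 <- 3.5; tr <- 0.004; flip <- 20
  nT <- 50; dt <- 10
  times <- (seq_len(nT) - 1) * dt
  c_true <- pmax(0.1 * (times - 50) / 1000, 0)  # 0 during 5 baseline reps
  t1_t <- 1 / (1 / t1_0 + r1 * c_true)
  sig <- spgr_signal(m0, t1_t, flip, tr)
  study <- list(signal = array(sig, dim = c(nT, 1, 1, 1)),
                dt = dt, baseline_reps = 5, flip_dyn_deg = flip, tr_s = tr)
  t1_fit <- list(t1 = array(t1_0, c(1, 1, 1)), m0 = array(m0, c(1, 1, 1)))

  conc <- signal_to_concentration(study, t1_fit, r1 = r1)
  expect_equal(as.vector(conc)[-(1:5)], c_true[-(1:5)], tolerance = 1e-6)
  expect_equal(as.vector(conc)[1:5], rep(0, 5), tolerance = 1e-9)

  rel <- signal_to_concentration(study, mode = "relative")
  sl_t1 <- fit_late_slope(conc, dt, late_window = 20:50)$raw_slope
  sl_rel <- fit_late_slope(rel, dt, late_window = 20:50)$raw_slope
  expect_gt(as.vector(sl_rel) / as.vector(sl_t1), 0)
})

test_that("late-phase slope equals the closed-form OLS solution", {
  nT <- 40; dt <- 10
  conc <- array(0, dim = c(nT, 2, 2, 1))
  conc[, 1, 1, 1] <- 3                      # constant -> slope 0
  times <- (seq_len(nT) - 1) * dt
  conc[, 2, 1, 1] <- 0.7 + 0.013 * times    # exact line -> slope b
  withr::with_seed(31, conc[, 1, 2, 1] <- rnorm(nT))
  withr::with_seed(32, conc[, 2, 2, 1] <- rnorm(nT, sd = 5))
  win <- 10:40
  sl <- fit_late_slope(conc, dt, late_window = win)$raw_slope
  expect_equal(sl[1, 1, 1], 0, tolerance = 1e-12)
  expect_equal(sl[2, 1, 1], 0.013, tolerance = 1e-12)
  for (ij in list(c(1, 2), c(2, 2))) {
    y <- conc[win, ij[1], ij[2], 1]
    lmfit <- stats::lm(y ~ times[win])
    expect_equal(sl[ij[1], ij[2], 1], unname(coef(lmfit)[2]),
                 tolerance = 1e-12)
  }
  expect_error(fit_late_slope(conc, dt, late_window = 1:2), "at least 3")
})

test_that("sinus normalization: unit at the sinus median, invariant to rescaling", {
  withr::with_seed(41, raw <- array(rnorm(4 * 4 * 4, 1e-3, 2e-4), c(4, 4, 4)))
  sinus <- array(FALSE, c(4, 4, 4)); sinus[1, 1, 1:3] <- TRUE
  n1 <- normalize_to_sinus(raw, sinus)
  expect_equal(median(n1$norm_slope[sinus]), 1)
  n2 <- normalize_to_sinus(2 * raw, sinus)
  expect_equal(n2$norm_slope, n1$norm_slope, tolerance = 1e-12)
  expect_error(normalize_to_sinus(raw * 0, sinus), "normalization undefined")
})

test_that("control threshold: empirical-quantile and degenerate-averaging fixtures", {
  thr <- control_threshold(list(as.numeric(1:100)))
  expect_lt(abs(thr$value - 95), 1)

  withr::with_seed(51, v <- rnorm(500))
  thr2 <- control_threshold(list(v, v, v))
  expect_equal(thr2$value, quantile(v, 0.95, names = FALSE),
               tolerance = 0.02)
  expect_error(control_threshold(list()), "at least one control")
  expect_error(control_threshold(list(rnorm(50))), "at least 100")
})

test_that("regional classification counts leaky voxels per parcel", {
  atlas <- default_dce_atlas(c(4, 32, 32))
  slopes <- array(0, c(4, 32, 32))
  cl0 <- classify_and_regionalize(slopes, 10, atlas)
  expect_true(all(cl0$regional$percent_leaky == 0))

  lab <- atlas$regions$label[atlas$regions$name == "MFG_i"]
  idx <- which(atlas$labels == lab)
  slopes[idx[1:30]] <- 5
  cl <- classify_and_regionalize(slopes, 1, atlas)
  row <- cl$regional[cl$regional$name == "MFG_i", ]
  expect_equal(row$n_leaky, 30)
  expect_equal(row$percent_leaky, 100 * 30 / length(idx))
})

test_that("co-localization statistics follow the overlap arithmetic", {
  a <- array(FALSE, c(2, 10, 10)); a[1, , ] <- TRUE
  same <- colocalize(a, a)
  expect_equal(same$dice, 1); expect_equal(same$percent_activated_leaky, 100)

  b <- array(FALSE, c(2, 10, 10)); b[2, , ] <- TRUE
  disj <- colocalize(a, b)
  expect_equal(disj$dice, 0); expect_equal(disj$percent_activated_leaky, 0)

  act <- array(FALSE, c(1, 20, 10)); act[1, 1:10, ] <- TRUE      # |A| = 100
  leak <- array(FALSE, c(1, 20, 10)); leak[1, 8:12, ] <- TRUE    # |L| = 50
  cc <- colocalize(leak, act)
  expect_equal(cc$n_overlap, 30)
  expect_equal(cc$percent_activated_leaky, 30)
  expect_equal(cc$dice, 2 * 30 / 150)
  empty <- colocalize(leak, array(FALSE, c(1, 20, 10)))
  expect_true(is.nan(empty$percent_activated_leaky))
})

test_that("noiseless subject pipeline recovers true normalized slopes through the T1 chain", {
  p <- dce_sim_params(noise_sd = 0, seed = 11)
  co <- gen_dce_cohort(p, n_task = 1, n_control = 1)
  st <- co$task[[1]]
  res <- dce_subject_slopes(st)
  tr <- co$truth$task[[1]]
  expect_lt(max(abs(res$norm_slope - tr$norm_slope)[st$brain_mask]), 1e-9)
  expect_equal(median(res$norm_slope[st$sinus_mask]), 1, tolerance = 1e-12)
})

test_that("leaky voxels are recovered from noisy studies at default settings", {
  p <- dce_sim_params(seed = 13)
  co <- gen_dce_cohort(p, n_task = 1, n_control = 3)
  ctrl <- lapply(seq_len(3), function(i)
    dce_subject_slopes(co$control[[i]])$norm_slope[co$control[[i]]$brain_mask])
  thr <- control_threshold(ctrl)
  res <- dce_subject_slopes(co$task[[1]])
  cl <- classify_and_regionalize(res$norm_slope, thr, co$task[[1]]$atlas)
  tr <- co$truth$task[[1]]
  recovery <- sum(cl$leak_mask & tr$leak_label) / sum(tr$leak_label)
  expect_gte(recovery, 0.95)
})
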