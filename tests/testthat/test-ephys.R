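test_that("band-pass filter: passband preserved, stopband attenuated, DC removed", {
  fs <- 1000; t <- seq(0, 10, by = 1 / fs)
  mid <- 2000:8000  # avoid filter edge transients
  s10 <- list(samples = sin(2 * pi * 10 * t), sampling_rate = fs)
  g10 <- sd(bandpass_filter(s10, 1, 45)$samples[mid]) / sd(s10$samples[mid])
  expect_lt(abs(g10 - 1), 0.01)

  s400 <- list(samples = sin(2 * pi * 400 * t), sampling_rate = fs)
  att <- 20 * log10(sd(bandpass_filter(s400, 1, 300)$samples[mid]) /
                      sd(s400$samples[mid]))
  expect_lt(att, -20)

  dc <- list(samples = rep(3, 5000), sampling_rate = fs)
  expect_lt(max(abs(bandpass_filter(dc, 1, 45)$samples)), 1e-6)
  expect_error(bandpass_filter(dc, 1, 600), "Nyquist")
})

test_that("epoching drops edge-overlapping sweeps and keeps the rest", {
  fs <- 1000
  trace <- list(samples = rep(0, 3 * fs), sampling_rate = fs, start_time = 0)
  stims <- c(0.02, 1, 2, 2.95)  # first and last overlap the edges
  expect_warning(sep <- epoch_and_average(trace, stims), "dropped")
  expect_equal(sep$n_sweeps, 2L)
  expect_error(suppressWarnings(epoch_and_average(trace, c(0.01))),
               "no complete epochs")
})

test_that("sweep averaging suppresses iid noise as 1/sqrt(n)", {
  fs <- 1000; n_sweeps <- 360; noise_sd <- 30
  tpl_ms <- seq(0, 160, by = 1)
  tpl <- bbbquant:::sep_template(tpl_ms)
  stims <- (seq_len(n_sweeps) - 1) * 0.5 + 0.2   # 2 Hz, no overlap
  n <- (tail(stims, 1) + 0.5) * fs
  withr::with_seed(61, {
    x <- rnorm(n, sd = noise_sd)
    for (st in stims) {
      i0 <- round(st * fs) + 1
      x[i0:(i0 + length(tpl) - 1)] <- x[i0:(i0 + length(tpl) - 1)] + tpl
    }
    sep <- epoch_and_average(list(samples = x, sampling_rate = fs,
                                  start_time = 0), stims,
                             window_ms = c(-50, 200))
    expected <- rep(0, length(sep$time_ms))
    in_tpl <- sep$time_ms >= 0 & sep$time_ms <= 160
    expected[in_tpl] <- tpl[match(sep$time_ms[in_tpl], tpl_ms)]
    rms <- sqrt(mean((sep$mean_uV - expected)^2))
    expect_lt(abs(rms / (noise_sd / sqrt(n_sweeps)) - 1), 0.2)
  })
})

test_that("SEP measures: triangle oracle, offset invariance, amplitude equivariance", {
  time_ms <- seq(-50, 300, by = 1)
  zero <- structure(list(time_ms = time_ms, mean_uV = rep(0, length(time_ms)),
                         n_sweeps = 1L, baseline_uV = 0),
                    class = "sep_waveform")
  m0 <- sep_measures(zero)
  expect_equal(m0$max_amp_uV, 0); expect_equal(m0$auc_uVms, 0)

  # triangular negative deflection: amplitude 100 uV, base 50 ms (50-100 ms)
  tri <- zero
  tri$mean_uV <- ifelse(time_ms >= 50 & time_ms <= 75,
                        -(time_ms - 50) * 4,
                        ifelse(time_ms > 75 & time_ms <= 100,
                               -(100 - time_ms) * 4, 0))
  m1 <- sep_measures(tri)
  expect_equal(m1$max_amp_uV, 100)
  expect_equal(m1$auc_uVms, 2500)

  shifted <- tri
  shifted$mean_uV <- tri$mean_uV + 10
  shifted$baseline_uV <- 10
  m2 <- sep_measures(shifted)
  expect_equal(m2$max_amp_uV, m1$max_amp_uV)
  expect_equal(m2$auc_uVms, m1$auc_uVms)

  scaled <- tri
  scaled$mean_uV <- 3 * tri$mean_uV
  m3 <- sep_measures(scaled)
  expect_equal(m3$max_amp_uV, 3 * m1$max_amp_uV)
  expect_equal(m3$auc_uVms, 3 * m1$auc_uVms)

  short <- zero
  short$time_ms <- seq(-50, 100, by = 1)
  short$mean_uV <- rep(0, length(short$time_ms))
  expect_error(sep_measures(short), "does not span")
})

test_that("percent change from baseline", {
  a <- list(max_amp_uV = 100, auc_uVms = 2000)
  expect_equal(percent_change(a, a)$amp_change_pct, 0)
  b <- list(max_amp_uV = 150, auc_uVms = 3000)
  pc <- percent_change(b, a)
  expect_equal(pc$amp_change_pct, 50)
  expect_equal(pc$auc_change_pct, 50)
  expect_warning(pcn <- percent_change(b, list(max_amp_uV = 0, auc_uVms = 1)),
                 "zero")
  expect_true(is.nan(pcn$amp_change_pct))
})

test_that("Welch PSD: Parseval, tone localization, paired band-power comparison", {
  fs <- 1000
  withr::with_seed(71, x <- rnorm(30 * fs))
  w <- psd_welch(x, fs)
  expect_lt(abs(sum(w$psd) * (w$freq[2] - w$freq[1]) / var(x) - 1), 0.1)

  tone <- sin(2 * pi * 20 * seq(0, 30, by = 1 / fs))
  wt <- psd_welch(tone, fs)
  expect_equal(wt$freq[which.max(wt$psd)], 20)

  withr::with_seed(72, {
    pre <- list(samples = rnorm(120 * fs), sampling_rate = fs)
    post <- list(samples = rnorm(120 * fs, sd = sqrt(2)), sampling_rate = fs)
  })
  cmp <- psd_compare(pre, post, segment_s = 120)
  expect_lt(abs(cmp$band_power_post / cmp$band_power_pre - 2), 0.2)
  expect_lt(cmp$p, 0.05)

  same <- psd_compare(pre, pre, segment_s = 120)
  expect_equal(same$p, 1); expect_equal(same$t, 0)
  expect_error(psd_compare(pre, post, segment_s = 600), "at least")
})

test_that("full session: potentiation recovered from filtered, epoched sweeps", {
  p <- ephys_sim_params(potentiation_factor = 1.5, seed = 5)
  s <- gen_lfp_session(p)
  tr <- bandpass_filter(s$trace, 1, 300)
  pre <- s$stim_log$stim_times[s$stim_log$stim_times < p$post_marker_s]
  post <- s$stim_log$stim_times[s$stim_log$stim_times >= p$post_marker_s]
  m_pre <- sep_measures(epoch_and_average(tr, pre))
  m_post <- sep_measures(epoch_and_average(tr, post))
  ratio <- m_post$max_amp_uV / m_pre$max_amp_uV
  expect_lt(abs(ratio - 1.5), 0.15)
})
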