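#' Zero-phase band-pass filter for LFP traces
#'
#' 4th-order Butterworth band-pass (default 1-45 Hz; 300 Hz is the wide
#' setting) applied forward and backward (`filtfilt`), so the filter is
#' zero-phase and DC is removed.
#'
#' @param trace list with `samples` (uV) and `sampling_rate` (Hz).
#' @param hp_hz,lp_hz high-pass and low-pass cut-offs; must satisfy
#'   `hp < lp < sampling_rate/2`.
#' @param order filter order.
#' @return the trace with filtered samples.
#' @export
bandpass_filter <- function(trace, hp_hz = 1, lp_hz = 45, order = 4L) {
  fs <- trace$sampling_rate
  if (!(hp_hz > 0 && hp_hz < lp_hz && lp_hz < fs / 2))
    stopf("cut-offs must satisfy 0 < hp < lp < Nyquist (%g Hz)", fs / 2)
  bf <- signal::butter(order, c(hp_hz, lp_hz) / (fs / 2), type = "pass")
  # remove the mean first so the filtfilt edge transient of a large DC
  # offset does not leak into the trace
  x <- trace$samples - mean(trace$samples)
  trace$samples <- as.numeric(signal::filtfilt(bf, x))
  trace
}

#' Epoch a trace around stimuli and average sweeps
#'
#' Cuts a window around every stimulus onset and averages across sweeps to
#' form the somatosensory evoked potential (SEP). Epochs that would extend
#' past the trace edges are dropped with a warning. The baseline is the
#' mean over the pre-stimulus part of the window.
#'
#' @param trace list with `samples` (uV), `sampling_rate`, `start_time`.
#' @param stim_log list with `stim_times` (s), or a numeric vector of
#'   stimulus times.
#' @param window_ms two-element window around stimulus onset (ms).
#' @return object of class `sep_waveform`: `time_ms`, `mean_uV`,
#'   `n_sweeps`, `baseline_uV`.
#' @export
epoch_and_average <- function(trace, stim_log, window_ms = c(-50, 300)) {
  fs <- trace$sampling_rate
  stims <- if (is.list(stim_log)) stim_log$stim_times else stim_log
  if (length(stims) < 1L) stopf("no stimuli in the log")
  start <- if (is.null(trace$start_time)) 0 else trace$start_time
  n <- length(trace$samples)
  rel <- seq(round(window_ms[1] * fs / 1000),
             round(window_ms[2] * fs / 1000))
  time_ms <- rel * 1000 / fs
  i0 <- round((stims - start) * fs) + 1L
  ok <- (i0 + rel[1]) >= 1L & (i0 + rel[length(rel)]) <= n
  if (!all(ok)) {
    warning(sprintf("%d epoch(s) overlapping trace edges dropped",
                    sum(!ok)))
    i0 <- i0[ok]
  }
  if (length(i0) == 0L) stopf("no complete epochs remain")
  acc <- rep(0, length(rel))
  for (i in i0) acc <- acc + trace$samples[i + rel]
  avg <- acc / length(i0)
  baseline <- mean(avg[time_ms < 0])
  if (!is.finite(baseline)) baseline <- 0
  structure(list(time_ms = time_ms, mean_uV = avg,
                 n_sweeps = length(i0), baseline_uV = baseline),
            class = "sep_waveform")
}

#' SEP plasticity measures
#'
#' Quantifies synaptic strength from an averaged SEP by (1) the maximal
#' amplitude of the dominant negative peak (absolute value of the global
#' minimum of the baseline-referenced waveform) and (2) the absolute area
#' under the curve, i.e. the trapezoidal integral of
#' `|waveform - baseline|`, both over the 10-160 ms post-stimulus window
#' (the 0-10 ms stimulus-artifact span is excluded).
#'
#' @param sep a `sep_waveform`.
#' @param window_ms measurement window (ms post-stimulus).
#' @return list with `max_amp_uV`, `auc_uVms`, `window_ms`.
#' @export
sep_measures <- function(sep, window_ms = c(10, 160)) {
  stopifnot(inherits(sep, "sep_waveform"))
  if (min(sep$time_ms) > window_ms[1] || max(sep$time_ms) < window_ms[2])
    stopf("waveform does not span the %g-%g ms window",
          window_ms[1], window_ms[2])
  sel <- sep$time_ms >= window_ms[1] & sep$time_ms <= window_ms[2]
  v <- sep$mean_uV[sel] - sep$baseline_uV
  list(max_amp_uV = abs(min(pmin(v, 0))),
       auc_uVms = pracma::trapz(sep$time_ms[sel], abs(v)),
       window_ms = window_ms)
}

#' Percent change of plasticity measures from baseline
#'
#' @param post,pre measure lists from [sep_measures()].
#' @return list with `amp_change_pct` and `auc_change_pct`
#'   (100 * (post - pre)/pre; NaN with a warning when the baseline
#'   measure is zero).
#' @export
percent_change <- function(post, pre) {
  pc <- function(a, b, what) {
    if (!is.finite(b) || b == 0) {
      warning(sprintf("baseline %s is zero; percent change undefined", what))
      return(NaN)
    }
    100 * (a - b) / b
  }
  list(amp_change_pct = pc(post$max_amp_uV, pre$max_amp_uV, "amplitude"),
       auc_change_pct = pc(post$auc_uVms, pre$auc_uVms, "AUC"))
}

#' Welch power spectral density
#'
#' Hann-windowed averaged periodogram with 50% overlap; one-sided, scaled
#' so that the integral of the PSD over frequency matches the signal
#' variance (Parseval).
#'
#' @param x numeric signal.
#' @param fs sampling rate (Hz).
#' @param window_s segment length (s).
#' @param overlap fractional overlap between segments.
#' @return list with `freq` (Hz) and `psd` (power per Hz).
#' @export
psd_welch <- function(x, fs, window_s = 2, overlap = 0.5) {
  L <- round(window_s * fs)
  if (length(x) < L) stopf("signal shorter than one Welch segment")
  step <- max(1L, round(L * (1 - overlap)))
  starts <- seq(1L, length(x) - L + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(L) / (L + 1)))
  scale <- 1 / (fs * sum(w^2))
  nf <- L %/% 2 + 1L
  acc <- rep(0, nf)
  for (s0 in starts) {
    seg <- x[s0:(s0 + L - 1L)]
    seg <- (seg - mean(seg)) * w
    p <- abs(fft(seg))^2 * scale
    acc <- acc + p[seq_len(nf)]
  }
  psd <- acc / length(starts)
  psd[2:(nf - 1L)] <- 2 * psd[2:(nf - 1L)]  # one-sided
  list(freq = (seq_len(nf) - 1) * fs / L, psd = psd)
}

#' Compare spontaneous-activity power spectra before and after treatment
#'
#' Welch PSDs (2 s windows, 50% overlap) over matched segments (default
#' 10 min) of the pre and post traces, and a paired t-test on log band
#' power (default 1-45 Hz) across consecutive 30 s blocks paired by index.
#' When the paired differences have zero variance the test statistic is 0
#' and p = 1 by convention.
#'
#' @param trace_pre,trace_post traces (lists with `samples`,
#'   `sampling_rate`).
#' @param segment_s length of the analyzed segment (s); both traces must
#'   be at least this long.
#' @param band frequency band (Hz) for the paired test.
#' @param block_s pairing-block length (s).
#' @return list with `freq`, `psd_pre`, `psd_post`, `band`,
#'   `band_power_pre`, `band_power_post`, `t`, `df`, `p`.
#' @export
psd_compare <- function(trace_pre, trace_post, segment_s = 600,
                        band = c(1, 45), block_s = 30) {
  fs <- trace_pre$sampling_rate
  if (trace_post$sampling_rate != fs)
    stopf("traces have different sampling rates")
  need <- round(segment_s * fs)
  if (length(trace_pre$samples) < need || length(trace_post$samples) < need)
    stopf("both traces must be at least %g s long", segment_s)
  xp <- trace_pre$samples[seq_len(need)]
  xq <- trace_post$samples[seq_len(need)]
  wp <- psd_welch(xp, fs); wq <- psd_welch(xq, fs)
  inband <- wp$freq >= band[1] & wp$freq <= band[2]
  df_hz <- wp$freq[2] - wp$freq[1]

  nb <- floor(segment_s / block_s)
  bl <- round(block_s * fs)
  bp <- function(x, k) {
    seg <- x[((k - 1L) * bl + 1L):(k * bl)]
    w <- psd_welch(seg, fs)
    sum(w$psd[w$freq >= band[1] & w$freq <= band[2]]) * df_hz
  }
  pow_pre <- vapply(seq_len(nb), function(k) bp(xp, k), 1)
  pow_post <- vapply(seq_len(nb), function(k) bp(xq, k), 1)
  d <- log(pow_post) - log(pow_pre)
  if (stats::sd(d) < 1e-12) {
    tstat <- 0; pval <- 1
  } else {
    tt <- t.test(log(pow_post), log(pow_pre), paired = TRUE)
    tstat <- unname(tt$statistic); pval <- tt$p.value
  }
  list(freq = wp$freq, psd_pre = wp$psd, psd_post = wq$psd, band = band,
       band_power_pre = sum(wp$psd[inband]) * df_hz,
       band_power_post = sum(wq$psd[inband]) * df_hz,
       t = tstat, df = nb - 1L, p = pval)
}
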