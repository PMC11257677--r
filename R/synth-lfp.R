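#' Stimulus train times
#'
#' Pulse onset times of a constant-frequency test stimulation: a train at
#' `frequency_hz` lasting `duration_s` contains `frequency_hz * duration_s`
#' pulses (e.g. 6 Hz for 60 s gives 360 pulses).
#'
#' @param frequency_hz pulse rate (Hz).
#' @param duration_s train duration (s).
#' @param start_s time of the first pulse (s).
#' @return numeric vector of pulse times (s).
#' @export
stim_train <- function(frequency_hz = 6, duration_s = 60, start_s = 0) {
  check_scalar(frequency_hz, "frequency_hz", lower = 1e-9)
  check_scalar(duration_s, "duration_s", lower = 0)
  n <- round(frequency_hz * duration_s)
  start_s + (seq_len(n) - 1) / frequency_hz
}

# Evoked-potential template: dominant negative peak plus a smaller positive
# late lobe, zero outside ~0-160 ms.
sep_template <- function(time_ms, neg_latency_ms = 20, neg_width_ms = 8,
                         neg_amp_uV = 150, pos_latency_ms = 60,
                         pos_frac = 0.3) {
  v <- -neg_amp_uV * exp(-(time_ms - neg_latency_ms)^2 / (2 * neg_width_ms^2)) +
    pos_frac * neg_amp_uV *
      exp(-(time_ms - pos_latency_ms)^2 / (2 * (2.5 * neg_width_ms)^2))
  v[time_ms < 0 | time_ms > 160] <- 0
  v
}

#' Parameters for the synthetic LFP/SEP session generator
#'
#' Emulates a somatosensory test-stimulation protocol: a baseline train of
#' pulses at 6 Hz (360 pulses in 60 s), a post marker, then a second train
#' whose evoked responses are scaled by `potentiation_factor` (long-term
#' potentiation by construction). The evoked template has a dominant
#' negative peak at ~20 ms; background noise follows a 1/f^gamma spectrum.
#'
#' @param sampling_rate Hz (signals digitized at 1 kHz by default).
#' @param stim_times pulse times (s); `NULL` builds the default two-train
#'   protocol (`pre` at 5 s, `post` at 75 s, 360 pulses each).
#' @param post_marker_s times at or after this marker receive the
#'   potentiated template.
#' @param duration_s total trace length (s).
#' @param template list of template parameters passed to the evoked shape
#'   (`neg_latency_ms`, `neg_width_ms`, `neg_amp_uV`, `pos_latency_ms`,
#'   `pos_frac`).
#' @param potentiation_factor multiplier applied to responses after the
#'   post marker.
#' @param noise_sd noise SD (uV); `noise_gamma` the 1/f exponent.
#' @param seed integer seed.
#' @export
ephys_sim_params <- function(sampling_rate = 1000, stim_times = NULL,
                             post_marker_s = 70, duration_s = 140,
                             template = list(), potentiation_factor = 1.5,
                             noise_sd = 20, noise_gamma = 1, seed = 1L) {
  check_scalar(sampling_rate, "sampling_rate", lower = 601)
  check_scalar(duration_s, "duration_s", lower = 1)
  check_scalar(potentiation_factor, "potentiation_factor", lower = 0)
  check_scalar(noise_sd, "noise_sd", lower = 0)
  if (is.null(stim_times))
    stim_times <- c(stim_train(6, 60, 5), stim_train(6, 60, 75))
  if (any(diff(stim_times) <= 0))
    stopf("stim_times must be strictly increasing")
  if (any(stim_times < 0) || any(stim_times + 0.160 > duration_s))
    stopf("a stimulus window (160 ms) extends past the trace end")
  tpl <- utils::modifyList(list(neg_latency_ms = 20, neg_width_ms = 8,
                                neg_amp_uV = 150, pos_latency_ms = 60,
                                pos_frac = 0.3), template)
  structure(list(sampling_rate = sampling_rate, stim_times = stim_times,
                 post_marker_s = post_marker_s, duration_s = duration_s,
                 template = tpl, potentiation_factor = potentiation_factor,
                 noise_sd = noise_sd, noise_gamma = noise_gamma,
                 seed = as.integer(seed)),
            class = "ephys_sim_params")
}

# Gaussian noise with a 1/f^gamma amplitude spectrum, rescaled to `sd`.
pink_noise <- function(n, gamma, sd) {
  if (sd == 0) return(rep(0, n))
  white <- rnorm(n)
  spec <- fft(white)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)  # symmetric frequency index, avoids f = 0
  spec <- spec * f^(-gamma / 2)
  x <- Re(fft(spec, inverse = TRUE)) / n
  x <- x - mean(x)
  x * sd / stats::sd(x)
}

#' Generate a synthetic LFP session with stimulus log and ground truth
#'
#' The trace is 1/f noise plus the evoked template inserted at every
#' stimulus time, scaled by `potentiation_factor` for stimuli at or after
#' the post marker. Ground truth stores the clean template and its
#' measures (dominant negative-peak amplitude and absolute AUC over
#' 10-160 ms) for the pre and post trains.
#'
#' @param params an [ephys_sim_params()] object.
#' @return list with `trace` (`samples` uV, `sampling_rate`, `start_time`),
#'   `stim_log` (`stim_times`, `pulse_width_ms`, `frequency_hz`,
#'   `current_ma`) and `truth`.
#' @export
gen_lfp_session <- function(params) {
  stopifnot(inherits(params, "ephys_sim_params"))
  fs <- params$sampling_rate
  n <- round(params$duration_s * fs)
  tpl_ms <- seq(0, 160, by = 1000 / fs)
  tpl <- do.call(sep_template, c(list(time_ms = tpl_ms), params$template))

  local_seed(params$seed, {
    x <- pink_noise(n, params$noise_gamma, params$noise_sd)
    for (st in params$stim_times) {
      i0 <- round(st * fs) + 1L
      idx <- i0:(i0 + length(tpl) - 1L)
      fac <- if (st >= params$post_marker_s) params$potentiation_factor else 1
      x[idx] <- x[idx] + fac * tpl
    }
    trace <- list(samples = x, sampling_rate = fs, start_time = 0)
    stim_log <- list(stim_times = params$stim_times, pulse_width_ms = 0.1,
                     frequency_hz = 6, current_ma = 2)

    meas_win <- tpl_ms >= 10 & tpl_ms <= 160
    pre_amp <- abs(min(tpl[meas_win]))
    pre_auc <- pracma::trapz(tpl_ms[meas_win], abs(tpl[meas_win]))
    truth <- list(template_time_ms = tpl_ms, template_uV = tpl,
                  pre_max_amp_uV = pre_amp, pre_auc_uVms = pre_auc,
                  post_max_amp_uV = params$potentiation_factor * pre_amp,
                  post_auc_uVms = params$potentiation_factor * pre_auc,
                  potentiation_factor = params$potentiation_factor,
                  post_marker_s = params$post_marker_s)
    list(trace = trace, stim_log = stim_log, truth = truth)
  })
}
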