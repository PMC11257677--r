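#!/usr/bin/env Rscript
# SEP plasticity quantification on simulated sessions: band-pass filter
# (1-300 Hz), epoch on the stimulus log, average the 360-sweep trains,
# measure the dominant negative peak and absolute AUC over 10-160 ms,
# and test the paired pre/post change (n = 6 sessions, exact Wilcoxon).
# Also: spontaneous-activity PSD comparison on a variance-doubled trace.

suppressMessages(library(bbbquant))
dir.create("results", showWarnings = FALSE)

n_sessions <- 6
rows <- list()
for (i in seq_len(n_sessions)) {
  s <- gen_lfp_session(ephys_sim_params(potentiation_factor = 1.5,
                                        seed = 9000 + i))
  tr <- bandpass_filter(s$trace, 1, 300)
  pre <- s$stim_log$stim_times[s$stim_log$stim_times < 70]
  post <- s$stim_log$stim_times[s$stim_log$stim_times >= 70]
  m_pre <- sep_measures(epoch_and_average(tr, pre))
  m_post <- sep_measures(epoch_and_average(tr, post))
  pc <- percent_change(m_post, m_pre)
  rows[[length(rows) + 1]] <- data.frame(
    session = i, amp_pre = m_pre$max_amp_uV, amp_post = m_post$max_amp_uV,
    auc_pre = m_pre$auc_uVms, auc_post = m_post$auc_uVms,
    amp_change_pct = pc$amp_change_pct, auc_change_pct = pc$auc_change_pct)
}
d <- do.call(rbind, rows)
write.csv(d, "results/sep_measures.csv", row.names = FALSE)

w_amp <- wilcoxon_signed_rank(d$amp_post, d$amp_pre)
w_auc <- wilcoxon_signed_rank(d$auc_post, d$auc_pre)
cat(sprintf("max amplitude: %.1f -> %.1f uV (+%.1f%%), Wilcoxon p = %.4f\n",
            mean(d$amp_pre), mean(d$amp_post), mean(d$amp_change_pct),
            w_amp$p_value))
cat(sprintf("absolute AUC: %.0f -> %.0f uV*ms (+%.1f%%), Wilcoxon p = %.4f\n",
            mean(d$auc_pre), mean(d$auc_post), mean(d$auc_change_pct),
            w_auc$p_value))

# PSD comparison: same 1/f background, doubled variance post
s1 <- gen_lfp_session(ephys_sim_params(stim_times = 1, post_marker_s = 1e6,
                                       duration_s = 600, seed = 9100))
s2 <- gen_lfp_session(ephys_sim_params(stim_times = 1, post_marker_s = 1e6,
                                       duration_s = 600, noise_sd = 20 * sqrt(2),
                                       seed = 9101))
cmp <- psd_compare(s1$trace, s2$trace, segment_s = 600)
cat(sprintf("band power 1-45 Hz: ratio %.2f, paired t(%d) = %.2f, p = %.3g\n",
            cmp$band_power_post / cmp$band_power_pre, cmp$df, cmp$t, cmp$p))
psd <- data.frame(freq = cmp$freq, psd_pre = cmp$psd_pre,
                  psd_post = cmp$psd_post)
write.csv(psd[psd$freq <= 100, ], "results/sep_psd.csv", row.names = FALSE)
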