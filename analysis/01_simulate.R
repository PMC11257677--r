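#!/usr/bin/env Rscript
# Generate one synthetic instance of every modality with stored ground
# truth, and write them in their interchange formats under
# results/simulated/. Downstream drivers regenerate cohorts themselves;
# this script documents the data contracts on disk.

suppressMessages(library(bbbquant))
out_dir <- "results/simulated"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

# Angiography: 30 s movie at 5 frames/s, injection after 5 s. A reduced
# 96 x 96 field keeps the example file small; the acquisition defaults
# (512 x 512, ~1 x 1 mm) live in angio_sim_params().
ang <- gen_angiography(angio_sim_params(
  image_height = 96, image_width = 96, n_frames = 150,
  injection_frame = 25, seed = 101))
write_angio_movie(ang$movie, file.path(out_dir, "angio_movie.tif"),
                  file.path(out_dir, "angio_movie.json"))
write_volume_nifti(array(ang$truth$leak_map, c(1, dim(ang$truth$leak_map))),
                   file.path(out_dir, "angio_leak_truth.nii.gz"))
cat(sprintf("angiography: %d frames, %d vessel px, %d leak px\n",
            dim(ang$movie$frames)[1], sum(ang$truth$vessel_mask),
            sum(ang$truth$leak_map > 0)))

# DCE-MRI: one task subject (100 reps x 10 s, injection after 5 reps).
dce <- gen_dce_cohort(dce_sim_params(seed = 102), n_task = 1, n_control = 1)
st <- dce$task[[1]]
write_volume_nifti(st$atlas$labels, file.path(out_dir, "dce_atlas.nii.gz"))
write_volume_nifti(st$sinus_mask * 1, file.path(out_dir, "dce_sinus.nii.gz"))
jsonlite::write_json(list(dt = st$dt, baseline_reps = st$baseline_reps,
                          flip_angles_deg = st$flip_angles_deg,
                          vfa_tr_s = st$vfa_tr_s, tr_s = st$tr_s,
                          flip_dyn_deg = st$flip_dyn_deg),
                     file.path(out_dir, "dce_acquisition.json"),
                     auto_unbox = TRUE, digits = NA)
cat(sprintf("dce: %s grid, %d reps, %d leak voxels seeded\n",
            paste(dim(st$brain_mask), collapse = "x"),
            dim(st$signal)[1], sum(dce$truth$task[[1]]$leak_label)))

# LFP session: two 360-pulse 6 Hz trains, 1.5x potentiation after 70 s.
lfp <- gen_lfp_session(ephys_sim_params(seed = 103))
write_lfp_csv(lfp$trace, file.path(out_dir, "lfp_trace.csv"))
write_stim_log_csv(lfp$stim_log$stim_times,
                   file.path(out_dir, "lfp_stims.csv"))
cat(sprintf("lfp: %d samples at %d Hz, %d stimuli\n",
            length(lfp$trace$samples), lfp$trace$sampling_rate,
            length(lfp$stim_log$stim_times)))

# Paired counts: 8 animals per timepoint, contra/ipsi hemispheres.
cnt <- gen_counts(counts_sim_params(n_genes = 2000, seed = 104))
write_counts_tsv(cnt$counts, cnt$sample_meta,
                 file.path(out_dir, "counts.tsv"),
                 file.path(out_dir, "counts_meta.json"))
cat(sprintf("counts: %d genes x %d samples, %d DE entries in truth\n",
            nrow(cnt$counts), ncol(cnt$counts), nrow(cnt$truth)))
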