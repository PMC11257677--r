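#' Spoiled gradient-echo steady-state signal
#'
#' `S = M0 sin(a) (1 - E1) / (1 - E1 cos(a))` with `E1 = exp(-TR/T1)`.
#' Used both as the forward model of the DCE simulator and as the equation
#' the variable-flip-angle T1 fit inverts.
#'
#' @param m0 equilibrium magnetization (a.u.).
#' @param t1 longitudinal relaxation time (s).
#' @param flip_deg flip angle in degrees.
#' @param tr_s repetition time (s).
#' @export
spgr_signal <- function(m0, t1, flip_deg, tr_s) {
  a <- flip_deg * pi / 180
  e1 <- exp(-tr_s / t1)
  m0 * sin(a) * (1 - e1) / (1 - e1 * cos(a))
}

#' Parameters for the synthetic DCE-MRI cohort generator
#'
#' Emulates a dynamic contrast-enhanced acquisition over a small labeled
#' brain: 100 dynamic repetitions at 10 s spacing with contrast injection
#' after the fifth, a variable-flip-angle T1 series at 5/15/20/25 degrees,
#' a transverse-sinus blood-pool compartment, and a piecewise concentration
#' model per voxel (flat baseline, bolus ramp, then a linear late phase
#' whose normalized slope is drawn per voxel). Task subjects receive leaky
#' voxels (elevated normalized slope) in configured atlas regions; control
#' subjects draw all slopes from the null distribution.
#'
#' @param grid `(Z, Y, X)` voxel grid; the default small grid keeps a full
#'   cohort tractable while preserving all structure (8 region x hemisphere
#'   parcels plus a sinus strip).
#' @param n_reps,dt,baseline_reps dynamic repetitions, spacing (s), and
#'   number of pre-injection repetitions.
#' @param flip_angles_deg VFA flip angles; `vfa_tr_s` their TR.
#' @param flip_dyn_deg,tr_s dynamic scan flip angle and TR.
#' @param t10_tissue_s,t10_blood_s pre-contrast T1 of tissue and sinus blood.
#' @param r1 contrast agent relaxivity, 1/(mM s); literature value for a
#'   gadolinium chelate at 3T.
#' @param m0 equilibrium magnetization (a.u.).
#' @param bolus_reps repetitions of the bolus ramp after injection.
#' @param c_plateau_tissue_mM,c_plateau_blood_mM post-bolus plateau
#'   concentration in tissue and in the sinus.
#' @param sinus_slope raw late-phase concentration slope in the sinus
#'   (mM/s); voxel slopes are drawn in units of this normalizer.
#' @param control_slope_sd SD of normalized slopes under the null.
#' @param leak_slope_mean,leak_slope_sd normalized slope distribution of
#'   leaky voxels.
#' @param leak_fraction_by_region named vector of per-parcel leak fractions
#'   applied to task subjects (names like "PoG_c").
#' @param noise_sd Gaussian signal noise as a fraction of the baseline
#'   signal.
#' @param seed integer seed.
#' @return an object of class `dce_sim_params`.
#' @export
dce_sim_params <- function(grid = c(4L, 32L, 32L),
                           n_reps = 100L, dt = 10, baseline_reps = 5L,
                           flip_angles_deg = c(5, 15, 20, 25),
                           vfa_tr_s = 0.010,
                           flip_dyn_deg = 20, tr_s = 0.004,
                           t10_tissue_s = 1.2, t10_blood_s = 1.6,
                           r1 = 3.5, m0 = 1000,
                           bolus_reps = 3L,
                           c_plateau_tissue_mM = 0.1,
                           c_plateau_blood_mM = 1.0,
                           sinus_slope = 5e-4,
                           control_slope_sd = 0.02,
                           leak_slope_mean = 0.15, leak_slope_sd = 0.05,
                           leak_fraction_by_region = c(PoG_c = 0.2),
                           noise_sd = 0.005, seed = 1L) {
  check_scalar(n_reps, "n_reps", lower = 3)
  check_scalar(baseline_reps, "baseline_reps", lower = 1)
  if (baseline_reps >= n_reps) stopf("n_reps must exceed baseline_reps")
  check_scalar(dt, "dt", lower = 1e-9)
  check_scalar(r1, "r1", lower = 1e-9)
  check_scalar(noise_sd, "noise_sd", lower = 0)
  check_scalar(sinus_slope, "sinus_slope", lower = 1e-12)
  if (length(grid) != 3L) stopf("grid must be (Z, Y, X)")
  if (any(leak_fraction_by_region < 0 | leak_fraction_by_region > 1))
    stopf("leak fractions must lie in [0, 1]")
  if (length(flip_angles_deg) < 2L)
    stopf("at least two flip angles are required")
  structure(list(grid = as.integer(grid), n_reps = as.integer(n_reps),
                 dt = dt, baseline_reps = as.integer(baseline_reps),
                 flip_angles_deg = flip_angles_deg, vfa_tr_s = vfa_tr_s,
                 flip_dyn_deg = flip_dyn_deg, tr_s = tr_s,
                 t10_tissue_s = t10_tissue_s, t10_blood_s = t10_blood_s,
                 r1 = r1, m0 = m0, bolus_reps = as.integer(bolus_reps),
                 c_plateau_tissue_mM = c_plateau_tissue_mM,
                 c_plateau_blood_mM = c_plateau_blood_mM,
                 sinus_slope = sinus_slope,
                 control_slope_sd = control_slope_sd,
                 leak_slope_mean = leak_slope_mean,
                 leak_slope_sd = leak_slope_sd,
                 leak_fraction_by_region = leak_fraction_by_region,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "dce_sim_params")
}

#' Build the default labeled atlas for the simulated brain
#'
#' Four cortical parcels (PrG, PoG, MFG, MOG) split into contralateral
#' ("c") and ipsilateral ("i") hemispheres, plus a transverse-sinus strip
#' outside the brain parcels. Labels are integers; `regions` maps label to
#' region name and hemisphere tag.
#'
#' @param grid `(Z, Y, X)` voxel grid (Y must be at least 30).
#' @return list with `labels` (Z x Y x X integer array, 0 = background),
#'   `regions` (data.frame: label, region, hemisphere, name) and
#'   `sinus_mask` (logical array).
#' @export
default_dce_atlas <- function(grid) {
  z <- grid[1]; y <- grid[2]; x <- grid[3]
  if (y < 30 || x < 4) stopf("grid too small for the default atlas")
  labels <- array(0L, dim = grid)
  region_names <- c("PrG", "PoG", "MFG", "MOG")
  hemi <- c("c", "i")
  band <- 7L
  regions <- data.frame(label = integer(), region = character(),
                        hemisphere = character(), name = character())
  lab <- 0L
  half <- x %/% 2
  for (ri in seq_along(region_names)) {
    ys <- ((ri - 1L) * band + 1L):(ri * band)
    for (hi in seq_along(hemi)) {
      lab <- lab + 1L
      xs <- if (hi == 1L) seq_len(half) else (half + 1L):x
      labels[, ys, xs] <- lab
      regions <- rbind(regions, data.frame(
        label = lab, region = region_names[ri], hemisphere = hemi[hi],
        name = paste0(region_names[ri], "_", hemi[hi])))
    }
  }
  sinus <- array(FALSE, dim = grid)
  sinus[, (4L * band + 2L):min(4L * band + 3L, y), ] <- TRUE
  list(labels = labels, regions = regions, sinus_mask = sinus)
}

# Piecewise concentration curve: 0 during baseline, linear ramp over the
# bolus, then plateau + slope * elapsed-time.
conc_curve <- function(times, t_inj, t_bolus_end, plateau, slope) {
  ramp <- pmin(pmax((times - t_inj) / max(t_bolus_end - t_inj, 1e-9), 0), 1)
  plateau * ramp + slope * pmax(times - t_bolus_end, 0)
}

#' Generate a synthetic DCE-MRI cohort with ground-truth slope maps
#'
#' Draws per-voxel normalized late-phase slopes (null distribution for
#' every control voxel, elevated distribution for the leak fraction of each
#' configured parcel in task subjects), synthesizes the dynamic SPGR signal
#' through the full T1 forward model, and attaches a matching
#' variable-flip-angle series. Ground truth records every voxel's true
#' normalized slope and leak label.
#'
#' @param params a [dce_sim_params()] object.
#' @param n_task,n_control number of task and control subjects.
#' @return list with `task` and `control` (lists of `dce_study` objects)
#'   and `truth` (per subject: `norm_slope`, `leak_label`).
#' @export
gen_dce_cohort <- function(params, n_task = 6L, n_control = 10L) {
  stopifnot(inherits(params, "dce_sim_params"))
  if (n_task < 1 || n_control < 1) stopf("need at least one subject per arm")
  atlas <- default_dce_atlas(params$grid)
  local_seed(params$seed, {
    task <- vector("list", n_task); control <- vector("list", n_control)
    truth <- list(task = vector("list", n_task),
                  control = vector("list", n_control))
    for (i in seq_len(n_task)) {
      sim <- simulate_dce_subject(params, atlas, leaky = TRUE)
      task[[i]] <- sim$study; truth$task[[i]] <- sim$truth
    }
    for (i in seq_len(n_control)) {
      sim <- simulate_dce_subject(params, atlas, leaky = FALSE)
      control[[i]] <- sim$study; truth$control[[i]] <- sim$truth
    }
    list(task = task, control = control, truth = truth)
  })
}

simulate_dce_subject <- function(params, atlas, leaky) {
  g <- params$grid
  nvox <- prod(g)
  brain <- atlas$labels > 0L
  sinus <- atlas$sinus_mask
  times <- (seq_len(params$n_reps) - 1) * params$dt
  t_inj <- params$baseline_reps * params$dt
  t_bolus_end <- (params$baseline_reps + params$bolus_reps) * params$dt

  norm_slope <- array(0, dim = g)
  norm_slope[brain] <- rnorm(sum(brain), 0, params$control_slope_sd)
  leak_label <- array(FALSE, dim = g)
  if (leaky && length(params$leak_fraction_by_region)) {
    for (nm in names(params$leak_fraction_by_region)) {
      frac <- params$leak_fraction_by_region[[nm]]
      row <- atlas$regions[atlas$regions$name == nm, ]
      if (nrow(row) == 0L) stopf("unknown atlas parcel '%s'", nm)
      idx <- which(atlas$labels == row$label)
      n_leak <- round(frac * length(idx))
      if (n_leak > 0) {
        pick <- sample(idx, n_leak)
        leak_label[pick] <- TRUE
        norm_slope[pick] <- rnorm(n_leak, params$leak_slope_mean,
                                  params$leak_slope_sd)
      }
    }
  }

  raw_slope <- norm_slope * params$sinus_slope
  plateau <- array(0, dim = g)
  plateau[brain] <- params$c_plateau_tissue_mM
  plateau[sinus] <- params$c_plateau_blood_mM
  raw_slope[sinus] <- params$sinus_slope
  norm_slope[sinus] <- 1  # normalized to itself by definition
  t10 <- array(params$t10_tissue_s, dim = g)
  t10[sinus] <- params$t10_blood_s

  # concentration then SPGR signal, voxels x time
  active <- brain | sinus
  idx <- which(active)
  ramp <- pmin(pmax((times - t_inj) / (t_bolus_end - t_inj), 0), 1)
  late <- pmax(times - t_bolus_end, 0)
  conc <- outer(plateau[idx], ramp) + outer(raw_slope[idx], late)
  t1_t <- 1 / (1 / t10[idx] + params$r1 * conc)
  sig_active <- spgr_signal(params$m0, t1_t, params$flip_dyn_deg, params$tr_s)

  signal <- array(0, dim = c(params$n_reps, g))
  flat <- matrix(0, nvox, params$n_reps)
  flat[idx, ] <- sig_active
  for (t in seq_len(params$n_reps)) signal[t, , , ] <- flat[, t]

  vfa <- array(0, dim = c(length(params$flip_angles_deg), g))
  vfa_flat <- matrix(0, nvox, length(params$flip_angles_deg))
  for (a in seq_along(params$flip_angles_deg))
    vfa_flat[idx, a] <- spgr_signal(params$m0, t10[idx],
                                    params$flip_angles_deg[a],
                                    params$vfa_tr_s)
  for (a in seq_along(params$flip_angles_deg)) vfa[a, , , ] <- vfa_flat[, a]

  if (params$noise_sd > 0) {
    s0 <- spgr_signal(params$m0, params$t10_tissue_s, params$flip_dyn_deg,
                      params$tr_s)
    signal <- signal + rnorm(length(signal), sd = params$noise_sd * s0)
    vfa <- vfa + rnorm(length(vfa), sd = params$noise_sd * s0)
  }

  activation <- array(FALSE, dim = g)
  act_labels <- atlas$regions$label[atlas$regions$name %in% c("PrG_c", "PoG_c")]
  activation[atlas$labels %in% act_labels] <- TRUE

  study <- structure(list(
    signal = signal, dt = params$dt, baseline_reps = params$baseline_reps,
    brain_mask = brain, sinus_mask = sinus, activation_mask = activation,
    atlas = atlas[c("labels", "regions")],
    vfa_signals = vfa, flip_angles_deg = params$flip_angles_deg,
    vfa_tr_s = params$vfa_tr_s, flip_dyn_deg = params$flip_dyn_deg,
    tr_s = params$tr_s), class = "dce_study")
  list(study = study,
       truth = list(norm_slope = norm_slope, leak_label = leak_label))
}
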