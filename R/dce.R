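#' Total DCE scan duration
#'
#' @param n_reps number of dynamic repetitions.
#' @param dt repetition spacing (s).
#' @return scan length in minutes (100 repetitions at 10 s give 16.7 min).
#' @export
dce_scan_duration <- function(n_reps = 100, dt = 10) {
  n_reps * dt / 60
}

#' Variable-flip-angle T1 fit
#'
#' Fits the spoiled-gradient-echo signal equation per voxel via the
#' standard linearization `S/sin(a) = E1 * S/tan(a) + M0 (1 - E1)`, with
#' `E1 = exp(-TR/T1)`; the regression slope gives `T1 = -TR / log(slope)`.
#' Voxels with a non-physical slope (<= 0 or >= 1) or a flat signal across
#' angles are NaN.
#'
#' @param vfa_signals array whose first dimension indexes flip angles
#'   (A x ... voxel grid), or a voxels x A matrix.
#' @param flip_angles_deg flip angles in degrees (>= 2 distinct).
#' @param tr_s repetition time of the VFA acquisition (s).
#' @return list with `t1` and `m0` shaped like one voxel volume.
#' @export
fit_t1_vfa <- function(vfa_signals, flip_angles_deg, tr_s) {
  check_scalar(tr_s, "tr_s", lower = 1e-9)
  if (length(unique(flip_angles_deg)) < 2L)
    stopf("at least two distinct flip angles are required")
  a <- flip_angles_deg * pi / 180
  if (is.matrix(vfa_signals) && ncol(vfa_signals) == length(a)) {
    s <- vfa_signals
    out_dim <- nrow(s)
  } else {
    d <- dim(vfa_signals)
    if (is.null(d) || d[1] != length(a))
      stopf("first dimension of vfa_signals must match flip_angles_deg")
    s <- t(matrix(vfa_signals, d[1], prod(d[-1])))
    out_dim <- d[-1]
  }
  y <- sweep(s, 2, sin(a), "/")
  x <- sweep(s, 2, tan(a), "/")
  nA <- length(a)
  sx <- rowSums(x); sy <- rowSums(y)
  sxx <- rowSums(x^2); sxy <- rowSums(x * y)
  denom <- nA * sxx - sx^2
  slope <- (nA * sxy - sx * sy) / denom
  intercept <- (sy - slope * sx) / nA
  flat <- apply(s, 1, function(v) stats::sd(v) < 1e-9 * max(abs(v), 1e-300))
  bad <- flat | !is.finite(slope) | slope <= 0 | slope >= 1
  slope_ok <- ifelse(bad, 0.5, slope)  # placeholder, masked below
  t1 <- -tr_s / log(slope_ok)
  m0 <- intercept / (1 - slope_ok)
  t1[bad] <- NaN; m0[bad] <- NaN
  if (length(out_dim) > 1L) {
    dim(t1) <- out_dim; dim(m0) <- out_dim
  }
  list(t1 = t1, m0 = m0)
}

#' Convert dynamic signal to contrast-agent concentration
#'
#' Primary mode ("t1") inverts the spoiled-gradient-echo equation at the
#' dynamic flip angle using the VFA M0 map to recover T1(t), then
#' `C(t) = (1/T1(t) - 1/T1(0)) / r1`. Fallback mode ("relative") returns
#' the relative enhancement `(S - S0)/S0` (proportional to concentration
#' in the linear regime), with S0 the baseline-repetition mean. Samples
#' outside the invertible SPGR range are NaN.
#'
#' @param study a `dce_study` (see [gen_dce_cohort()]) or any list with
#'   `signal` (T x Z x Y x X), `baseline_reps`, `flip_dyn_deg`, `tr_s`.
#' @param t1_fit result of [fit_t1_vfa()] on the study's VFA series.
#' @param r1 relaxivity in 1/(mM s).
#' @param mode "t1" or "relative".
#' @return concentration array, same shape as `study$signal` (mM in "t1"
#'   mode, unitless in "relative" mode).
#' @export
signal_to_concentration <- function(study, t1_fit = NULL, r1 = 3.5,
                                    mode = c("t1", "relative")) {
  mode <- match.arg(mode)
  d <- dim(study$signal)
  nT <- d[1]; nvox <- prod(d[-1])
  s <- matrix(study$signal, nT, nvox)
  if (mode == "relative") {
    s0 <- colMeans(s[seq_len(study$baseline_reps), , drop = FALSE])
    conc <- sweep(sweep(s, 2, s0, "-"), 2, ifelse(s0 > 0, s0, NaN), "/")
  } else {
    if (is.null(t1_fit)) stopf("t1_fit is required in \"t1\" mode")
    check_scalar(r1, "r1", lower = 1e-12)
    alpha <- study$flip_dyn_deg * pi / 180
    m0 <- as.vector(t1_fit$m0)
    t10 <- as.vector(t1_fit$t1)
    ms <- m0 * sin(alpha)
    num <- sweep(-s, 2, ms, "+")           # M0 sin(a) - S
    den <- sweep(-s * cos(alpha), 2, ms, "+")  # M0 sin(a) - S cos(a)
    e1 <- num / den
    e1[!is.finite(e1) | e1 <= 0 | e1 >= 1] <- NaN
    t1t <- -study$tr_s / log(e1)
    conc <- sweep(1 / t1t, 2, 1 / t10, "-") / r1
  }
  array(conc, dim = d)
}

#' Fit the late-phase linear slope per voxel
#'
#' Ordinary least-squares slope of concentration against time over the
#' late window. When `late_window` is NULL it is chosen automatically as
#' the final two-thirds of the post-bolus repetitions. The bolus end is
#' detected from the brain-mean concentration curve as the first
#' repetition (after the steepest rise) whose increment falls below 10%
#' of the peak increment; this also covers curves that keep accumulating
#' slowly after the bolus, where the curve maximum itself would sit at
#' the end of the scan.
#'
#' @param conc T x Z x Y x X concentration array.
#' @param dt repetition spacing (s).
#' @param late_window integer vector of repetition indices (>= 3), or NULL
#'   for automatic selection.
#' @param brain_mask logical volume used for the automatic bolus-end
#'   detection (required when `late_window` is NULL).
#' @return list with `raw_slope` (volume, concentration per second) and
#'   `late_window` (indices used).
#' @export
fit_late_slope <- function(conc, dt, late_window = NULL, brain_mask = NULL) {
  d <- dim(conc)
  nT <- d[1]
  y <- matrix(conc, nT, prod(d[-1]))
  if (is.null(late_window)) {
    if (is.null(brain_mask))
      stopf("brain_mask is required for automatic late-window selection")
    mean_curve <- rowMeans(y[, as.vector(brain_mask), drop = FALSE],
                           na.rm = TRUE)
    inc <- diff(mean_curve)
    steepest <- which.max(inc)
    settled <- which(seq_along(inc) > steepest & inc < 0.1 * inc[steepest])
    bolus_end <- if (length(settled)) settled[1] else which.max(mean_curve)
    if (bolus_end >= nT - 3L)
      stopf("could not identify a post-bolus phase; pass late_window")
    post <- (bolus_end + 1L):nT
    late_window <- post[-seq_len(floor(length(post) / 3))]
  }
  late_window <- as.integer(late_window)
  if (length(late_window) < 3L)
    stopf("late window must contain at least 3 repetitions")
  if (any(late_window < 1L | late_window > nT))
    stopf("late window outside the scan")
  tt <- (late_window - 1) * dt
  yw <- y[late_window, , drop = FALSE]
  tc <- tt - mean(tt)
  slope <- colSums(yw * tc) / sum(tc^2)
  vol <- array(slope, dim = d[-1])
  list(raw_slope = vol, late_window = late_window)
}

#' Normalize voxel slopes to the transverse sinus
#'
#' Divides every voxel's raw late-phase slope by the median slope inside
#' the sinus mask, canceling injection-rate and physiological variability
#' between subjects. The median is used as the sinus summary because it is
#' robust to partial-volume voxels.
#'
#' @param raw_slope slope volume from [fit_late_slope()].
#' @param sinus_mask logical volume of the transverse sinus.
#' @param epsilon minimum admissible sinus slope.
#' @return list with `norm_slope` (unitless volume) and `sinus_slope`
#'   (the raw normalizer).
#' @export
normalize_to_sinus <- function(raw_slope, sinus_mask, epsilon = 1e-12) {
  if (!any(sinus_mask)) stopf("sinus mask is empty")
  med <- median(raw_slope[sinus_mask], na.rm = TRUE)
  if (!is.finite(med) || med <= epsilon)
    stopf("sinus slope (%.3g) is below epsilon; normalization undefined", med)
  list(norm_slope = raw_slope / med, sinus_slope = med)
}

#' Leak threshold from a control cohort's mean cumulative distribution
#'
#' Each control subject's normalized slopes form an empirical CDF; the
#' CDFs are averaged on a common value grid spanning the pooled range, and
#' the threshold is the smallest value at which the mean CDF reaches the
#' requested percentile (linear interpolation between grid points).
#'
#' @param controls list of numeric vectors (one per control subject,
#'   normalized slopes of brain voxels; at least 100 values each).
#' @param percentile CDF level defining "modulated BBB" (default 0.95).
#' @param n_grid number of grid points for the common value grid.
#' @return object of class `leak_threshold` with `value`, `percentile`,
#'   `n_controls`, `grid`, `mean_cdf`.
#' @export
control_threshold <- function(controls, percentile = 0.95, n_grid = 1000L) {
  if (!is.list(controls) || length(controls) < 1L)
    stopf("need at least one control subject")
  controls <- lapply(controls, function(v) v[is.finite(v)])
  if (any(vapply(controls, length, 1L) < 100L))
    stopf("each control must contribute at least 100 voxels")
  check_scalar(percentile, "percentile", lower = 0, upper = 1)
  pooled <- unlist(controls)
  grid <- seq(min(pooled), max(pooled), length.out = n_grid)
  cdfs <- vapply(controls, function(v) stats::ecdf(v)(grid),
                 numeric(n_grid))
  mean_cdf <- rowMeans(cdfs)
  k <- which(mean_cdf >= percentile)[1]
  if (is.na(k)) stopf("mean CDF never reaches the requested percentile")
  value <- if (k == 1L) grid[1] else {
    f0 <- mean_cdf[k - 1]; f1 <- mean_cdf[k]
    if (f1 > f0) grid[k - 1] + (percentile - f0) / (f1 - f0) *
        (grid[k] - grid[k - 1]) else grid[k]
  }
  structure(list(value = value, percentile = percentile,
                 n_controls = length(controls), grid = grid,
                 mean_cdf = mean_cdf), class = "leak_threshold")
}

#' Classify leaky voxels and tabulate per atlas parcel
#'
#' Voxels with normalized slope strictly above the threshold (inside the
#' brain mask) are flagged as reflecting modulated BBB; per region and
#' hemisphere the percentage of leaky voxels is reported.
#'
#' @param norm_slope normalized slope volume.
#' @param threshold a `leak_threshold` or a plain number.
#' @param atlas list with `labels` (integer volume) and `regions`
#'   (data.frame: label, region, hemisphere, name).
#' @param brain_mask logical volume; defaults to `atlas$labels > 0`.
#' @return list with `leak_mask` (logical volume) and `regional`
#'   (data.frame: region, hemisphere, name, n_voxels, n_leaky,
#'   percent_leaky).
#' @export
classify_and_regionalize <- function(norm_slope, threshold, atlas,
                                     brain_mask = NULL) {
  thr <- if (inherits(threshold, "leak_threshold")) threshold$value
         else threshold
  if (is.null(brain_mask)) brain_mask <- atlas$labels > 0L
  if (!all(dim(norm_slope) == dim(atlas$labels)))
    stopf("slope map and atlas grids differ")
  leak <- !is.na(norm_slope) & norm_slope > thr & brain_mask
  reg <- atlas$regions
  regional <- do.call(rbind, lapply(seq_len(nrow(reg)), function(i) {
    in_reg <- atlas$labels == reg$label[i]
    n <- sum(in_reg)
    nl <- sum(leak & in_reg)
    data.frame(region = reg$region[i], hemisphere = reg$hemisphere[i],
               name = reg$name[i], n_voxels = n, n_leaky = nl,
               percent_leaky = if (n > 0) 100 * nl / n else NaN)
  }))
  list(leak_mask = leak, regional = regional)
}

#' Co-localization of BBB leakage with functional activation
#'
#' @param leak_mask logical volume of leaky voxels.
#' @param activation_mask logical volume of activated voxels (input; e.g.
#'   a thresholded fMRI statistic map).
#' @return list with `n_activated`, `n_leaky`, `n_overlap`,
#'   `percent_activated_leaky` (NaN when no activated voxels) and `dice`.
#' @export
colocalize <- function(leak_mask, activation_mask) {
  if (!all(dim(leak_mask) == dim(activation_mask)))
    stopf("mask grids differ")
  na <- sum(activation_mask); nl <- sum(leak_mask)
  no <- sum(leak_mask & activation_mask)
  list(n_activated = na, n_leaky = nl, n_overlap = no,
       percent_activated_leaky = if (na > 0) 100 * no / na else NaN,
       dice = if (na + nl > 0) 2 * no / (na + nl) else NaN)
}

#' Normalized slope map for one subject, end to end
#'
#' Convenience wrapper chaining [fit_t1_vfa()], [signal_to_concentration()],
#' [fit_late_slope()] and [normalize_to_sinus()].
#'
#' @param study a `dce_study`.
#' @param r1 relaxivity (1/(mM s)).
#' @param mode concentration conversion mode ("t1" or "relative").
#' @param late_window optional explicit late window.
#' @return list with `norm_slope`, `raw_slope`, `sinus_slope`,
#'   `late_window`.
#' @export
dce_subject_slopes <- function(study, r1 = 3.5, mode = "t1",
                               late_window = NULL) {
  t1_fit <- if (mode == "t1")
    fit_t1_vfa(study$vfa_signals, study$flip_angles_deg, study$vfa_tr_s)
  else NULL
  conc <- signal_to_concentration(study, t1_fit, r1 = r1, mode = mode)
  sl <- fit_late_slope(conc, study$dt, late_window = late_window,
                       brain_mask = study$brain_mask | study$sinus_mask)
  nrm <- normalize_to_sinus(sl$raw_slope, study$sinus_mask)
  list(norm_slope = nrm$norm_slope, raw_slope = sl$raw_slope,
       sinus_slope = nrm$sinus_slope, late_window = sl$late_window)
}
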