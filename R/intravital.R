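#' Construct an angiography movie object
#'
#' @param frames T x H x W numeric array of intensities (a.u.).
#' @param frame_rate frames per second.
#' @param injection_frame 1-based index of the frame at which tracer
#'   injection starts; frames before it define the pre-injection baseline.
#' @param pixel_size_um physical pixel size (microns).
#' @return an object of class `angio_movie`.
#' @export
angio_movie <- function(frames, frame_rate, injection_frame,
                        pixel_size_um = 1) {
  if (length(dim(frames)) != 3L || dim(frames)[1] < 2L)
    stopf("frames must be a T x H x W array with T >= 2")
  if (!all(is.finite(frames))) stopf("frame intensities must be finite")
  check_scalar(frame_rate, "frame_rate", lower = 1e-9)
  check_scalar(injection_frame, "injection_frame", lower = 1,
               upper = dim(frames)[1])
  structure(list(frames = frames, frame_rate = frame_rate,
                 injection_frame = as.integer(injection_frame),
                 pixel_size_um = pixel_size_um), class = "angio_movie")
}

movie_times <- function(movie) {
  (seq_len(dim(movie$frames)[1]) - 1) / movie$frame_rate
}

#' Register an angiography movie by translation
#'
#' Each frame is aligned to the reference frame by the integer translation
#' that maximizes their cross-correlation (computed via FFT on
#' mean-subtracted images). Pixels shifted in from outside the field are
#' filled with the frame median. Cranial-window movies are near-rigid, so
#' rotation is not modeled.
#'
#' @param movie an [angio_movie()].
#' @param reference_frame index of the reference frame (default 1).
#' @return list with `movie` (registered) and `shifts` (T x 2 matrix of
#'   detected (dy, dx) motion relative to the reference).
#' @export
register_movie <- function(movie, reference_frame = 1L) {
  stopifnot(inherits(movie, "angio_movie"))
  nT <- dim(movie$frames)[1]
  check_scalar(reference_frame, "reference_frame", lower = 1, upper = nT)
  ref <- movie$frames[reference_frame, , ]
  if (stats::sd(ref) == 0)
    stopf("reference frame is constant; registration is undefined")
  h <- nrow(ref); w <- ncol(ref)
  fref <- fft(ref - mean(ref))
  out <- movie$frames
  shifts <- matrix(0L, nT, 2)
  for (t in seq_len(nT)) {
    fr <- movie$frames[t, , ]
    if (stats::sd(fr) == 0)
      stopf("frame %d is constant; registration is undefined", t)
    cc <- Re(fft(fft(fr - mean(fr)) * Conj(fref), inverse = TRUE))
    peak <- arrayInd(which.max(cc), dim(cc)) - 1L
    dy <- if (peak[1] > h / 2) peak[1] - h else peak[1]
    dx <- if (peak[2] > w / 2) peak[2] - w else peak[2]
    shifts[t, ] <- c(dy, dx)
    if (dy != 0 || dx != 0)
      out[t, , ] <- shift_image(fr, -dy, -dx, fill = median(fr))
  }
  reg <- movie
  reg$frames <- out
  list(movie = reg, shifts = shifts)
}

#' Segment vessels from the temporal intensity projection
#'
#' Vessels carry the full bolus transient, so their temporal
#' 95th-percentile intensity is far above extravascular tissue. The
#' projection is computed over the early post-injection window (bolus
#' transit), before extravasated tracer accumulates enough to make strong
#' leakage foci vessel-bright; it is then thresholded automatically (Otsu)
#' and connected components smaller than `min_area` pixels are discarded.
#'
#' @param movie an [angio_movie()] (assumed registered).
#' @param polarity "bright" when vessels are brighter than tissue, "dark"
#'   for inverted contrast.
#' @param prob temporal quantile used for the projection.
#' @param min_area minimum vessel component area in pixels.
#' @param frames frame indices for the projection; default is the first
#'   quarter of the post-injection frames (at least 5).
#' @return logical H x W matrix, `TRUE` on vessel lumen.
#' @export
segment_vessels <- function(movie, polarity = c("bright", "dark"),
                            prob = 0.95, min_area = 10L, frames = NULL) {
  stopifnot(inherits(movie, "angio_movie"))
  polarity <- match.arg(polarity)
  d <- dim(movie$frames)
  if (is.null(frames)) {
    inj <- movie$injection_frame
    frames <- inj:min(d[1], inj + max(5L, ceiling(0.25 * (d[1] - inj))))
  }
  if (any(frames < 1 | frames > d[1])) stopf("projection frames out of range")
  flat <- matrix(movie$frames[frames, , , drop = FALSE],
                 length(frames), d[2] * d[3])
  if (polarity == "dark") flat <- -flat
  proj <- matrix(apply(flat, 2, quantile, probs = prob, names = FALSE),
                 d[2], d[3])
  rng <- range(proj)
  if (diff(rng) <= 0)
    stopf("projection image is uniform; segmentation threshold undefined")
  norm <- (proj - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  mask <- norm > th
  lab <- EBImage::bwlabel(EBImage::Image(mask))
  lab <- EBImage::imageData(lab)
  keep <- as.integer(names(which(table(lab[lab > 0]) >= min_area)))
  mask <- matrix(lab %in% keep, d[2], d[3])
  if (!any(mask) || all(mask))
    stopf("segmentation produced a single class; check contrast/polarity")
  mask
}

#' Extract a mean-intensity time curve over a pixel ROI
#'
#' @param movie an [angio_movie()].
#' @param roi logical H x W mask, or an n x 2 matrix of (row, col) pixel
#'   coordinates (1-based).
#' @return list with `times` (s) and `values` (a.u., ROI mean per frame).
#' @export
extract_curve <- function(movie, roi) {
  stopifnot(inherits(movie, "angio_movie"))
  d <- dim(movie$frames)
  if (is.logical(roi)) {
    if (!all(dim(roi) == d[2:3])) stopf("roi mask shape mismatch")
    idx <- which(roi)
  } else {
    roi <- as.matrix(roi)
    if (ncol(roi) != 2L) stopf("roi must be a mask or an n x 2 matrix")
    if (any(roi[, 1] < 1 | roi[, 1] > d[2] | roi[, 2] < 1 | roi[, 2] > d[3]))
      stopf("roi pixel outside the frame")
    idx <- (roi[, 2] - 1L) * d[2] + roi[, 1]
  }
  if (length(idx) == 0L) stopf("roi is empty")
  flat <- matrix(movie$frames, d[1], d[2] * d[3])
  list(times = movie_times(movie),
       values = rowMeans(flat[, idx, drop = FALSE]))
}

#' Compute the per-pixel BBB permeability index map
#'
#' For each extravascular pixel, the permeability index (PI) is the ratio
#' of the pixel's baseline-subtracted intensity to the baseline-subtracted
#' arterial input function (AIF), both averaged over a late analysis
#' window (default: last 20% of frames). The pre-injection baseline is the
#' mean over frames before `injection_frame`. Pixels whose tracer content
#' tracks the artery get PI = 1; accumulating pixels exceed 1. Vessel
#' pixels are NaN.
#'
#' @param movie an [angio_movie()] (registered).
#' @param mask logical vessel mask from [segment_vessels()].
#' @param aif arterial input function as returned by [extract_curve()] on
#'   the feeding artery.
#' @param window_frac fraction of frames (from the end) forming the
#'   analysis window.
#' @param epsilon minimum admissible AIF excess over baseline.
#' @return object of class `permeability_map`: `pi` (H x W, NaN on
#'   vessels), `analysis_window` (frame index range), `threshold`.
#' @export
compute_pi_map <- function(movie, mask, aif, window_frac = 0.2,
                           epsilon = 1e-6) {
  stopifnot(inherits(movie, "angio_movie"))
  d <- dim(movie$frames)
  if (!all(dim(mask) == d[2:3])) stopf("vessel mask shape mismatch")
  check_scalar(window_frac, "window_frac", lower = 1e-6, upper = 1)
  if (movie$injection_frame < 2L)
    stopf("no pre-injection frames: injection_frame must be >= 2")
  pre <- seq_len(movie$injection_frame - 1L)
  n_win <- max(1L, ceiling(window_frac * d[1]))
  win <- (d[1] - n_win + 1L):d[1]
  if (win[1] <= max(pre))
    stopf("analysis window overlaps the pre-injection baseline")

  aif_excess <- mean(aif$values[win]) - mean(aif$values[pre])
  if (!is.finite(aif_excess) || aif_excess <= epsilon)
    stopf("AIF excess over baseline (%.3g) is below epsilon; cannot form PI",
          aif_excess)

  flat <- matrix(movie$frames, d[1], d[2] * d[3])
  late_mean <- colMeans(flat[win, , drop = FALSE])
  base_mean <- colMeans(flat[pre, , drop = FALSE])
  pi_map <- matrix((late_mean - base_mean) / aif_excess, d[2], d[3])
  pi_map[mask] <- NaN
  structure(list(pi = pi_map, analysis_window = range(win), threshold = 1),
            class = "permeability_map")
}

#' Summarize a permeability map
#'
#' Extravascular pixels with PI strictly above the threshold (default 1)
#' are counted as leaking (tracer accumulation due to BBB permeability).
#'
#' @param pmap a `permeability_map`.
#' @param threshold PI threshold (strict inequality).
#' @return list with `leak_fraction`, `n_leak`, `n_extravascular`,
#'   `mean_pi`, `pi_p95`, `threshold`.
#' @export
summarize_permeability <- function(pmap, threshold = pmap$threshold) {
  stopifnot(inherits(pmap, "permeability_map"))
  v <- pmap$pi[!is.nan(pmap$pi)]
  n_leak <- sum(v > threshold)
  list(leak_fraction = n_leak / length(v), n_leak = n_leak,
       n_extravascular = length(v), mean_pi = mean(v),
       pi_p95 = quantile(v, 0.95, names = FALSE), threshold = threshold)
}

# Bilinear interpolation of img at fractional (y, x) coordinates.
bilinear_sample <- function(img, y, x) {
  h <- nrow(img); w <- ncol(img)
  y <- pmin(pmax(y, 1), h); x <- pmin(pmax(x, 1), w)
  y0 <- pmin(floor(y), h - 1); x0 <- pmin(floor(x), w - 1)
  fy <- y - y0; fx <- x - x0
  img[cbind(y0, x0)] * (1 - fy) * (1 - fx) +
    img[cbind(y0 + 1, x0)] * fy * (1 - fx) +
    img[cbind(y0, x0 + 1)] * (1 - fy) * fx +
    img[cbind(y0 + 1, x0 + 1)] * fy * fx
}

#' Track vessel diameter along a cross-section
#'
#' Per frame, the intensity profile along the cross-section is sampled by
#' bilinear interpolation, background-subtracted (profile minimum), and
#' the full width at half maximum is measured with sub-pixel linear
#' interpolation at the half-max crossings, then converted to microns.
#' Frames whose profile never crosses half maximum yield NaN.
#'
#' @param movie an [angio_movie()].
#' @param cross_section list with `p0` and `p1`, the (row, col) endpoints
#'   of the sampling line.
#' @param step_px sampling step along the line, in pixels.
#' @return list with `times` (s), `diameter_um`, `cross_section`.
#' @export
measure_diameter <- function(movie, cross_section, step_px = 0.25) {
  stopifnot(inherits(movie, "angio_movie"))
  p0 <- cross_section$p0; p1 <- cross_section$p1
  len <- sqrt(sum((p1 - p0)^2))
  if (len <= 0) stopf("cross-section endpoints coincide")
  s <- seq(0, 1, by = step_px / len)
  ys <- p0[1] + s * (p1[1] - p0[1])
  xs <- p0[2] + s * (p1[2] - p0[2])
  nT <- dim(movie$frames)[1]
  diam <- rep(NaN, nT)
  for (t in seq_len(nT)) {
    prof <- bilinear_sample(movie$frames[t, , ], ys, xs)
    prof <- prof - min(prof)
    half <- max(prof) / 2
    if (half <= 0) next
    above <- prof >= half
    if (!any(above)) next
    i1 <- which(above)[1]; i2 <- rev(which(above))[1]
    # sub-pixel crossings via linear interpolation
    left <- if (i1 == 1) s[1] else {
      f <- (half - prof[i1 - 1]) / (prof[i1] - prof[i1 - 1])
      s[i1 - 1] + f * (s[i1] - s[i1 - 1])
    }
    right <- if (i2 == length(s)) s[length(s)] else {
      f <- (half - prof[i2 + 1]) / (prof[i2] - prof[i2 + 1])
      s[i2 + 1] - f * (s[i2 + 1] - s[i2])
    }
    diam[t] <- (right - left) * len * movie$pixel_size_um
  }
  list(times = movie_times(movie), diameter_um = diam,
       cross_section = cross_section)
}
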