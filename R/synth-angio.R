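#' Parameters for the synthetic fluorescence angiography generator
#'
#' Describes a cranial-window angiography acquisition: a field of cortical
#' surface vessels imaged before, during and after an intravenous bolus of a
#' fluorescent tracer. Defaults follow the acquisition geometry used for
#' sodium-fluorescein imaging (512 x 512 pixels covering ~1 x 1 mm at
#' 5 frames/s); kinetic parameters are a gamma-variate bolus with a
#' recirculation plateau and Patlak-like unidirectional extravasation.
#'
#' @param image_height,image_width frame size in pixels.
#' @param frame_rate frames per second.
#' @param n_frames number of frames; must be at least `injection_frame + 2`.
#' @param injection_frame 1-based frame index at which the bolus starts.
#' @param vessel_tree list of segments, each
#'   `list(p0 = c(y, x), p1 = c(y, x), width_um = w)` in pixel coordinates;
#'   `NULL` uses a default two-branch arteriole crossing the field.
#' @param aif_params list with `amplitude` (a.u.), `t0` (delay after
#'   injection, s), `alpha` (shape), `beta` (scale, s) and `recirc_frac`
#'   (fraction of the bolus peak that persists as a recirculation plateau).
#' @param leak_map per-pixel Patlak influx constant K (1/s), H x W matrix, or
#'   `NULL` for a single circular leak focus next to the main vessel
#'   (radius 40 px, K = `leak_k`). K is forced to 0 on vessel pixels.
#' @param leak_k K inside the default leak focus (1/s).
#' @param baseline pre-injection intensity (a.u.).
#' @param texture_sd SD of a static per-pixel background texture (a.u.),
#'   present in every frame; gives the field the spatial structure that
#'   anchors registration.
#' @param noise_sd additive Gaussian noise SD (a.u.).
#' @param motion_shifts `NULL` (no motion), "random" (per-frame integer
#'   shifts, |shift| <= 3 px), or a T x 2 integer matrix of (dy, dx).
#' @param seed integer seed; the generator never touches the global RNG
#'   stream.
#' @return an object of class `angio_sim_params`.
#' @export
angio_sim_params <- function(image_height = 512L, image_width = 512L,
                             frame_rate = 5, n_frames = 150L,
                             injection_frame = 25L,
                             vessel_tree = NULL,
                             aif_params = list(amplitude = 100, t0 = 0.4,
                                               alpha = 3, beta = 1.5,
                                               recirc_frac = 0.3),
                             leak_map = NULL, leak_k = 0.05,
                             baseline = 100, texture_sd = 5, noise_sd = 1,
                             motion_shifts = NULL, seed = 1L) {
  check_scalar(image_height, "image_height", lower = 8)
  check_scalar(image_width, "image_width", lower = 8)
  check_scalar(frame_rate, "frame_rate", lower = 1e-6)
  check_scalar(n_frames, "n_frames", lower = 3)
  check_scalar(injection_frame, "injection_frame", lower = 1)
  check_scalar(noise_sd, "noise_sd", lower = 0)
  check_scalar(texture_sd, "texture_sd", lower = 0)
  check_scalar(leak_k, "leak_k", lower = 0)
  if (injection_frame + 2 > n_frames)
    stopf("n_frames must be >= injection_frame + 2")
  if (is.null(vessel_tree)) vessel_tree <- default_vessel_tree(image_height,
                                                               image_width)
  pixel_size_um <- 1000 / image_width  # ~1 mm field of view
  for (seg in vessel_tree) {
    pts <- rbind(seg$p0, seg$p1)
    if (any(pts[, 1] < 1 | pts[, 1] > image_height |
            pts[, 2] < 1 | pts[, 2] > image_width))
      stopf("vessel segment endpoint outside the %d x %d frame",
            image_height, image_width)
  }
  if (!is.null(leak_map)) {
    if (!is.matrix(leak_map) ||
        !all(dim(leak_map) == c(image_height, image_width)))
      stopf("leak_map must be an image_height x image_width matrix")
    if (any(leak_map < 0)) stopf("leak_map must be nonnegative")
  }
  if (!is.null(motion_shifts) && !identical(motion_shifts, "random")) {
    motion_shifts <- as.matrix(motion_shifts)
    if (nrow(motion_shifts) != n_frames || ncol(motion_shifts) != 2L)
      stopf("motion_shifts must be an n_frames x 2 matrix of (dy, dx)")
  }
  structure(list(
    image_height = as.integer(image_height),
    image_width = as.integer(image_width),
    frame_rate = frame_rate, n_frames = as.integer(n_frames),
    injection_frame = as.integer(injection_frame),
    vessel_tree = vessel_tree, aif_params = aif_params,
    leak_map = leak_map, leak_k = leak_k, baseline = baseline,
    texture_sd = texture_sd, noise_sd = noise_sd,
    motion_shifts = motion_shifts,
    pixel_size_um = pixel_size_um, seed = as.integer(seed)
  ), class = "angio_sim_params")
}

default_vessel_tree <- function(h, w) {
  list(
    list(p0 = c(1, round(w * 0.30)), p1 = c(h, round(w * 0.55)),
         width_um = 60),
    list(p0 = c(round(h * 0.45), round(w * 0.42)),
         p1 = c(round(h * 0.75), round(w * 0.95)), width_um = 30)
  )
}

# Rasterize the vessel tree: a pixel is lumen when within width/2 of any
# segment (distances in microns).
rasterize_vessels <- function(params) {
  h <- params$image_height; w <- params$image_width
  px <- params$pixel_size_um
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  mask <- matrix(FALSE, h, w)
  for (seg in params$vessel_tree) {
    dy <- seg$p1[1] - seg$p0[1]; dx <- seg$p1[2] - seg$p0[2]
    len2 <- dy^2 + dx^2
    tt <- ((yy - seg$p0[1]) * dy + (xx - seg$p0[2]) * dx) / max(len2, 1e-12)
    tt <- pmin(pmax(tt, 0), 1)
    d2 <- (yy - (seg$p0[1] + tt * dy))^2 + (xx - (seg$p0[2] + tt * dx))^2
    mask <- mask | (sqrt(d2) * px <= seg$width_um / 2)
  }
  mask
}

# Gamma-variate bolus plus recirculation plateau, evaluated at times t
# (seconds from movie start). Zero before injection + t0.
aif_model <- function(t, injection_time, p) {
  tau <- t - injection_time - p$t0
  a <- ifelse(tau > 0,
              p$amplitude * (tau / p$beta)^p$alpha * exp(-tau / p$beta) /
                (p$alpha^p$alpha * exp(-p$alpha)),  # peak-normalized shape
              0)
  plateau <- p$recirc_frac * p$amplitude *
    ifelse(tau > 0, 1 - exp(-tau / (4 * p$beta)), 0)
  a + plateau
}

#' Generate a synthetic angiography movie with ground truth
#'
#' Vessel pixels follow `baseline + AIF(t)`; extravascular pixels follow
#' `baseline + K * integral(AIF)` (unidirectional Patlak-like influx), with
#' optional rigid per-frame translation and additive Gaussian noise. The
#' returned ground truth carries the vessel mask, the noiseless arterial
#' input function (as excess over baseline), the K map and the applied
#' shifts, so registration, segmentation and permeability mapping can be
#' scored exactly.
#'
#' @param params an [angio_sim_params()] object.
#' @return list with `movie` (class `angio_movie`: `frames` T x H x W array,
#'   `frame_rate`, `injection_frame`, `pixel_size_um`) and `truth`
#'   (`vessel_mask`, `aif_curve`, `baseline`, `leak_map`, `applied_shifts`,
#'   `times`).
#' @export
gen_angiography <- function(params) {
  stopifnot(inherits(params, "angio_sim_params"))
  h <- params$image_height; w <- params$image_width; nT <- params$n_frames
  times <- (seq_len(nT) - 1) / params$frame_rate
  injection_time <- (params$injection_frame - 1) / params$frame_rate
  vessel <- rasterize_vessels(params)

  K <- params$leak_map
  if (is.null(K)) {
    K <- matrix(0, h, w)
    cy <- round(h * 0.40); cx <- round(w * 0.62); r <- min(40, h %/% 4)
    yy <- matrix(seq_len(h), h, w)
    xx <- matrix(seq_len(w), h, w, byrow = TRUE)
    K[(yy - cy)^2 + (xx - cx)^2 <= r^2] <- params$leak_k
  }
  K[vessel] <- 0

  aif <- aif_model(times, injection_time, params$aif_params)
  cum_aif <- cumtrapz1(times, aif)

  local_seed(params$seed, {
    shifts <- params$motion_shifts
    if (identical(shifts, "random")) {
      shifts <- matrix(sample(-3:3, 2 * nT, replace = TRUE), nT, 2)
      shifts[1, ] <- 0L
    } else if (is.null(shifts)) {
      shifts <- matrix(0L, nT, 2)
    }
    storage.mode(shifts) <- "integer"

    texture <- if (params$texture_sd > 0)
      matrix(rnorm(h * w, sd = params$texture_sd), h, w)
    else matrix(0, h, w)

    frames <- array(0, dim = c(nT, h, w))
    for (t in seq_len(nT)) {
      img <- matrix(params$baseline, h, w) + texture
      img[vessel] <- img[vessel] + aif[t]
      img[!vessel] <- img[!vessel] + K[!vessel] * cum_aif[t]
      img <- shift_image(img, shifts[t, 1], shifts[t, 2],
                         fill = params$baseline)
      frames[t, , ] <- img
    }
    if (params$noise_sd > 0)
      frames <- frames + rnorm(length(frames), sd = params$noise_sd)

    movie <- structure(list(frames = frames, frame_rate = params$frame_rate,
                            injection_frame = params$injection_frame,
                            pixel_size_um = params$pixel_size_um),
                       class = "angio_movie")
    truth <- list(vessel_mask = vessel, aif_curve = aif,
                  baseline = params$baseline, texture = texture,
                  leak_map = K, applied_shifts = shifts, times = times)
    list(movie = movie, truth = truth)
  })
}

# Integer translation with constant fill; dy > 0 moves content down,
# dx > 0 moves content right.
shift_image <- function(img, dy, dx, fill = 0) {
  h <- nrow(img); w <- ncol(img)
  out <- matrix(fill, h, w)
  ys <- max(1, 1 + dy):min(h, h + dy)
  xs <- max(1, 1 + dx):min(w, w + dx)
  if (length(ys) && length(xs))
    out[ys, xs] <- img[ys - dy, xs - dx]
  out
}
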