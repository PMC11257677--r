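test_that("registration: identity on aligned movies, exact recovery of integer shifts", {
  g <- noiseless_angio(h = 48, w = 48, n_frames = 12, injection_frame = 4,
                       texture_sd = 5)
  r <- register_movie(g$movie)
  expect_true(all(r$shifts == 0L))
  expect_equal(r$movie$frames, g$movie$frames)

  shifts <- cbind(c(0, 3, -2, rep(0, 9)), c(0, -2, 1, rep(0, 9)))
  gs <- gen_angiography(angio_sim_params(
    image_height = 48, image_width = 48, n_frames = 12, injection_frame = 4,
    noise_sd = 0, motion_shifts = shifts, seed = 5))
  rs <- register_movie(gs$movie)
  expect_identical(rs$shifts, gs$truth$applied_shifts)
})

test_that("registration: constructed (3, -2) shift on a textured image", {
  set.seed(10)
  base <- matrix(rnorm(40 * 40), 40, 40)
  frames <- array(0, dim = c(2, 40, 40))
  frames[1, , ] <- base
  frames[2, , ] <- bbbquant:::shift_image(base, 3, -2, fill = median(base))
  mv <- angio_movie(frames, 5, 1)
  r <- register_movie(mv)
  expect_equal(r$shifts[2, ], c(3L, -2L))
  expect_error(register_movie(angio_movie(array(1, c(2, 8, 8)), 5, 1)),
               "registration is undefined")
})

test_that("segmentation separates vessels with near-perfect Dice and rejects degenerate input", {
  g <- noiseless_angio(h = 96, w = 96)
  mask <- segment_vessels(g$movie)
  truth <- g$truth$vessel_mask
  dice <- 2 * sum(mask & truth) / (sum(mask) + sum(truth))
  expect_gte(dice, 0.99)

  flat <- g$movie
  flat$frames[] <- 7
  expect_error(segment_vessels(flat), "uniform")

  inv <- g$movie
  inv$frames <- max(g$movie$frames) - g$movie$frames
  expect_identical(segment_vessels(inv, polarity = "dark"), mask)
})

test_that("curve extraction averages the ROI and matches the stored AIF", {
  g <- noiseless_angio(h = 48, w = 48, n_frames = 30, injection_frame = 6)
  yx <- which(!g$truth$vessel_mask & g$truth$leak_map > 0, arr.ind = TRUE)
  one <- extract_curve(g$movie, yx[1, , drop = FALSE])
  expect_equal(one$values, g$movie$frames[, yx[1, 1], yx[1, 2]])

  # averaging: rois of x and 3x give 2x
  frames <- array(0, dim = c(4, 4, 4))
  x <- c(1, 2, 3, 4)
  frames[, 1, 1] <- x; frames[, 2, 2] <- 3 * x
  mv <- angio_movie(frames, 1, 1)
  two <- extract_curve(mv, rbind(c(1, 1), c(2, 2)))
  expect_equal(two$values, 2 * x)
  expect_error(extract_curve(mv, matrix(numeric(0), 0, 2)), "empty")

  aif <- extract_curve(g$movie, g$truth$vessel_mask)
  expect_equal(aif$values - aif$values[1], g$truth$aif_curve,
               tolerance = 1e-9)
})

test_that("PI map: self-ratio gives 1, flat pixel gives 0, k-scaled excess gives k", {
  g <- noiseless_angio(h = 48, w = 48)
  truth <- g$truth
  mv <- g$movie
  # construct pixels with excess = k * AIF excess
  ks <- c(1, 0, 0.37, 2.5)
  for (j in seq_along(ks))
    mv$frames[, 1, j] <- truth$baseline + ks[j] * truth$aif_curve
  mask <- truth$vessel_mask
  mask[1, seq_along(ks)] <- FALSE
  aif <- extract_curve(mv, truth$vessel_mask)
  pm <- compute_pi_map(mv, mask, aif)
  for (j in seq_along(ks))
    expect_equal(pm$pi[1, j], ks[j], tolerance = 1e-9)
  expect_true(all(is.nan(pm$pi[truth$vessel_mask & mask])))

  # AIF too weak: pre-injection-only movie
  weak <- mv
  weak$frames <- array(100, dim = dim(mv$frames))
  expect_error(compute_pi_map(weak, mask, extract_curve(weak, truth$vessel_mask)),
               "AIF excess")
})

test_that("PI summary counts strictly above threshold", {
  pm <- structure(list(pi = matrix(1, 10, 20), analysis_window = c(1, 2),
                       threshold = 1), class = "permeability_map")
  s <- summarize_permeability(pm)
  expect_equal(s$n_leak, 0L)

  pm$pi[1:50] <- 2
  s2 <- summarize_permeability(pm)
  expect_equal(s2$leak_fraction, 0.25)
  expect_equal(s2$n_leak, 50L)
})

test_that("leak burden grows monotonically with the influx constant", {
  res <- sapply(c(0.01, 0.05, 0.15), function(k) {
    g <- noiseless_angio(h = 48, w = 48, leak_k = k)
    aif <- extract_curve(g$movie, g$truth$vessel_mask)
    pm <- compute_pi_map(g$movie, g$truth$vessel_mask, aif)
    s <- summarize_permeability(pm)
    c(s$leak_fraction, s$mean_pi)
  })
  expect_true(all(diff(res[1, ]) >= 0))
  expect_true(all(diff(res[2, ]) > 0))
})

test_that("paired post-stimulation cohorts show higher leak fraction than baseline", {
  n_higher <- 0
  reps <- 30
  for (i in seq_len(reps)) {
    lf <- sapply(c(0.01, 0.05), function(k) {
      g <- gen_angiography(angio_sim_params(
        image_height = 48, image_width = 48, n_frames = 150,
        injection_frame = 25, leak_k = k, noise_sd = 1, seed = 1000 + i))
      aif <- extract_curve(g$movie, g$truth$vessel_mask)
      summarize_permeability(
        compute_pi_map(g$movie, g$truth$vessel_mask, aif))$leak_fraction
    })
    n_higher <- n_higher + (lf[2] > lf[1])
  }
  expect_gte(n_higher / reps, 0.95)
})

test_that("diameter: rectangular width is exact, Gaussian FWHM within 2%, absent vessel NaN", {
  w_px <- 7
  img <- matrix(0, 40, 40)
  img[, 15:(15 + w_px - 1)] <- 100
  frames <- array(0, dim = c(2, 40, 40))
  frames[1, , ] <- img  # frame 2 left empty -> NaN
  mv <- angio_movie(frames + 0.0, 5, 1, pixel_size_um = 2)
  dt <- measure_diameter(mv, list(p0 = c(20, 2), p1 = c(20, 38)))
  expect_equal(dt$diameter_um[1], w_px * 2, tolerance = 1e-6)
  expect_true(is.nan(dt$diameter_um[2]))

  sigma <- 3
  prof <- 100 * exp(-((1:40) - 20)^2 / (2 * sigma^2))
  frames2 <- array(0, dim = c(2, 40, 40))
  frames2[1, , ] <- matrix(prof, 40, 40, byrow = TRUE)  # vertical vessel
  frames2[2, , ] <- frames2[1, , ]
  mv2 <- angio_movie(frames2, 5, 1, pixel_size_um = 2)
  dt2 <- measure_diameter(mv2, list(p0 = c(20, 2), p1 = c(20, 38)))
  expect_equal(dt2$diameter_um[1], 2.3548 * sigma * 2, tolerance = 0.02)
})
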