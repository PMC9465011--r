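test_that("identical seeds reproduce byte-identical scenes", {
  s1 <- small_scene(seed = 11)
  s2 <- small_scene(seed = 11)
  expect_identical(s1$raw$data, s2$raw$data)
  expect_identical(s1$white$data, s2$white$data)
  expect_identical(s1$truth$bruise_mask, s2$truth$bruise_mask)
  s3 <- small_scene(seed = 12)
  expect_false(identical(s1$raw$data, s3$raw$data))
})

test_that("scene truth is geometrically consistent", {
  sc <- small_scene("medium", seed = 3)
  tr <- sc$truth
  expect_true(all(tr$apple_mask[tr$bruise_mask]))       # bruise inside apple
  expect_true(all(tr$bruise_mask[tr$bruise_core_mask]))
  snd <- small_scene("sound", seed = 3)
  expect_false(any(snd$truth$bruise_mask))
})

test_that("bruised regions are darker over 550-600 and 750-1000 nm", {
  ax <- spectral_axis()
  m <- apple_spectral_model(ax)
  wl <- ax$wavelengths_nm
  win <- (wl >= 550 & wl <= 600) | wl >= 750
  for (sev in c("low", "medium", "high")) {
    sc <- make_apple_scene(m, bruise_effect(sev), seed = 5)
    rc <- flat_field(sc$raw, sc$white, sc$dark)
    X <- matrix(rc$data, ncol = length(wl))
    snd <- colMeans(X[as.vector(sc$truth$apple_mask &
                                  !sc$truth$bruise_mask), ])
    bru <- colMeans(X[as.vector(sc$truth$bruise_mask), ])
    expect_true(all(bru[win] < snd[win]), label = sev)
  }
})

test_that("group mean reflectance at 550-600 nm orders with severity", {
  ax <- spectral_axis()
  m <- apple_spectral_model(ax)
  wl <- ax$wavelengths_nm
  win <- wl >= 550 & wl <= 600
  group_mean <- function(sev) {
    mean(vapply(1:10, function(s) {
      sc <- make_apple_scene(m, bruise_effect(sev), lines = 48,
                             samples = 48, apple_radius_px = 19,
                             seed = 200 + s)
      rc <- flat_field(sc$raw, sc$white, sc$dark)
      msk <- if (sev == "sound") sc$truth$apple_mask else
        sc$truth$bruise_mask
      mean(matrix(rc$data, ncol = length(wl))[as.vector(msk), win])
    }, numeric(1)))
  }
  g <- vapply(c("high", "medium", "low", "sound"), group_mean, numeric(1))
  expect_true(all(diff(g) > 0))          # high < medium < low < sound
})

test_that("raw apple signal sits between the dark and white references", {
  sc <- small_scene("sound", seed = 9)
  d <- dim(sc$raw$data)
  dark_mean <- apply(sc$dark$data, 3, mean)
  white_mean <- apply(sc$white$data, 3, mean)
  raw_mean <- vapply(seq_len(d[3]), function(b) {
    sl <- sc$raw$data[, , b]
    mean(sl[sc$truth$apple_mask])
  }, numeric(1))
  expect_true(all(raw_mean > dark_mean))
  expect_true(all(raw_mean < white_mean))
})

test_that("noiseless generator with fixed weights is band-wise flat", {
  ax <- spectral_axis()
  m <- apple_spectral_model(ax, latent_sds = rep(1e-12, 4), noise_sd = 0)
  cam <- camera_model(shot_noise = FALSE, read_noise_dn = 0)
  sc <- make_apple_scene(m, bruise_effect("sound"), cam = cam,
                         lines = 48, samples = 48, apple_radius_px = 19,
                         seed = 1)
  rc <- flat_field(sc$raw, sc$white, sc$dark)
  X <- matrix(rc$data, ncol = length(ax$wavelengths_nm))
  X <- X[as.vector(sc$truth$apple_mask), ]
  # every apple pixel carries the same spectrum up to the shading profile:
  # dividing out each pixel's brightness collapses the spread to A/D
  # quantization
  shape <- X / rowMeans(X)
  expect_lt(max(apply(shape, 2, stats::sd)), 0.01)
})

test_that("severity maps to ordered, admissible depression factors", {
  effs <- lapply(c("sound", "low", "medium", "high"), bruise_effect)
  br <- vapply(effs, `[[`, numeric(1), "browning_depression")
  expect_true(all(diff(br) < 0))                 # deeper with severity
  expect_true(all(br > 0 & br <= 1))
  expect_error(bruise_effect("high", impact_energy_J = 10), "lower")
})

test_that("cohort generation is reproducible and sized correctly", {
  co <- generate_cohort(2, groups = c("sound", "high"), seed = 42,
                        lines = 48, samples = 48, apple_radius_px = 19)
  expect_length(co, 4)
  co2 <- generate_cohort(2, groups = c("sound", "high"), seed = 42,
                         lines = 48, samples = 48, apple_radius_px = 19)
  expect_identical(lapply(co, function(s) s$raw$data),
                   lapply(co2, function(s) s$raw$data))
  expect_error(generate_cohort(1, groups = character(0)), "non-empty")
  one <- generate_cohort(1, groups = "sound", seed = 1, lines = 48,
                         samples = 48, apple_radius_px = 19)
  expect_false(any(one[[1]]$truth$bruise_mask))
})

test_that("out-of-range reflectance is rejected as misconfiguration", {
  ax <- spectral_axis()
  m <- apple_spectral_model(ax)
  m$baseline <- m$baseline * 1.4                 # push towards 1
  expect_error(make_apple_scene(m, bruise_effect("sound"), seed = 1),
               "misconfigured")
})
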