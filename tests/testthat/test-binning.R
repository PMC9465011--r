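combo_for <- function(cube, cam, rois) {
  structure(list(id = 1L, exposure_s = 0.01, rois = rois,
                 centers_nm = vapply(rois, `[[`, numeric(1), "center_nm"),
                 cam = cam, axis = cube$axis),
            class = "binning_combination")
}

test_that("raw-domain binning equals brute-force row sums", {
  cube <- random_cube(8, 8, 32, seed = 11, kind = "raw")
  cam <- flat_camera()
  wl <- cube$axis$wavelengths_nm
  rois <- list(band_roi(wl[4], 0), band_roi(wl[16], 40),
               band_roi(wl[28], 20))
  ms <- bin_cube(cube, combo_for(cube, cam, rois))
  for (b in seq_along(rois)) {
    idx <- roi_bands(cube$axis, rois[[b]]$center_nm,
                     rois[[b]]$roi_width_nm)
    # per-pixel loop oracle
    oracle <- matrix(0, 8, 8)
    for (i in 1:8) for (j in 1:8)
      oracle[i, j] <- sum(cube$data[i, j, idx])
    expect_equal(ms$data[, , b], oracle, tolerance = 1e-12)
  }
})

test_that("a single-row ROI reproduces the original band exactly", {
  cube <- random_cube(6, 6, 16, seed = 12, kind = "reflectance")
  cam <- camera_model()
  wl <- cube$axis$wavelengths_nm
  ms <- bin_cube(cube, combo_for(cube, cam, list(band_roi(wl[5], 0))))
  expect_equal(ms$data[, , 1], cube$data[, , 5], tolerance = 1e-12)
})

test_that("reflectance binning of a constant cube returns the constant", {
  ax <- tiny_axis(16)
  cube <- hyper_cube(array(0.42, c(5, 5, 16)), ax, "reflectance")
  ms <- bin_cube(cube, combo_for(cube, camera_model(),
                                 list(band_roi(ax$wavelengths_nm[8], 60))))
  expect_equal(ms$data[, , 1], matrix(0.42, 5, 5), tolerance = 1e-12)
})

test_that("raw binning clips at full scale and flags saturation", {
  ax <- tiny_axis(10)
  cam <- camera_model()
  cube <- hyper_cube(array(9000, c(3, 3, 10)), ax, "raw")
  ms <- bin_cube(cube, combo_for(cube, cam,
                                 list(band_roi(ax$wavelengths_nm[5], 40))))
  expect_true(all(ms$data[, , 1] == cam$full_scale_dn))
  expect_true(ms$saturated[1])
})

test_that("bin_spectra matches reflectance-domain bin_cube", {
  cube <- random_cube(4, 4, 20, seed = 13, kind = "reflectance")
  cam <- camera_model()
  wl <- cube$axis$wavelengths_nm
  rois <- list(band_roi(wl[3], 20), band_roi(wl[15], 30))
  cb <- combo_for(cube, cam, rois)
  ms <- bin_cube(cube, cb)
  X <- matrix(cube$data, ncol = 20)
  Xb <- bin_spectra(X, cube$axis, cb)
  expect_equal(as.vector(Xb[, 1]), as.vector(ms$data[, , 1]),
               tolerance = 1e-12)
  expect_equal(as.vector(Xb[, 2]), as.vector(ms$data[, , 2]),
               tolerance = 1e-12)
})

test_that("binning averages down additive noise roughly as 1/W", {
  ax <- tiny_axis(64, from = 500, by = 5)
  set.seed(14)
  noise <- array(rnorm(40 * 40 * 64, 0, 0.05), c(40, 40, 64))
  cube <- hyper_cube(0.5 + noise, ax, "reflectance")
  cam <- flat_camera()                            # equal weights
  wl <- ax$wavelengths_nm
  W <- 9                                          # 40 nm window at 5 nm
  ms <- bin_cube(cube, combo_for(cube, cam, list(band_roi(wl[32], 40))))
  v1 <- stats::var(as.vector(cube$data[, , 32]))
  vW <- stats::var(as.vector(ms$data[, , 1]))
  expect_equal(vW, v1 / W, tolerance = 0.2)
})

test_that("the combination grid mirrors the acquisition design", {
  cam <- camera_model()
  ax <- spectral_axis()
  combos <- suppressWarnings(
    enumerate_combinations(cam, ax, c(774.2, 553.9, 424.5)))
  expect_gte(length(combos), 6)
  for (cb in combos) {
    # exactly one ROI per key wavelength; the reference held at 90%
    expect_length(cb$rois, 3)
    ref <- cb$rois[[which(cb$centers_nm == 553.9)]]
    expect_equal(ref$target_fraction, 0.90)
    for (r in cb$rois) {
      expect_gte(r$achieved_fraction, r$target_fraction - 1e-9)
      expect_lte(r$achieved_fraction, 1)
    }
  }
  # wider reference bandwidth at lower rungs means shorter exposure
  expect_true(all(diff(vapply(combos, `[[`, numeric(1),
                              "exposure_s")) <= 1e-12))
  one <- enumerate_combinations(cam, ax, c(774.2, 553.9),
                                exposure_levels = 0.17,
                                fraction_grid = 0.9)
  expect_length(one, 1)
})

test_that("achieved fraction grows with ROI width at fixed exposure", {
  cam <- camera_model()
  ax <- spectral_axis()
  fr <- vapply(c(0, 20, 40, 80), function(w)
    predict_signal(cam, ax, band_roi(774.2, w), 0.01,
                   cam$white_reflectance)$fraction, numeric(1))
  expect_true(all(diff(fr) > 0))
})

test_that("re-imaging at a combination is seeded and faithful", {
  sc <- small_scene("high", seed = 31)
  rc <- flat_field(sc$raw, sc$white, sc$dark)
  cam <- sc$cam
  combos <- enumerate_combinations(cam, rc$axis, c(774.2, 553.9, 424.5),
                                   exposure_levels = 0.02,
                                   fraction_grid = 0.5)
  ms1 <- acquire_multispectral(rc, combos[[1]], seed = 5)
  ms2 <- acquire_multispectral(rc, combos[[1]], seed = 5)
  expect_identical(ms1$data, ms2$data)
  # binned reflectance tracks the throughput-weighted mean of the cube
  ref <- bin_cube(rc, combos[[1]])
  msk <- rep(sc$truth$apple_mask, 3)
  expect_lt(mean(abs(ms1$data[msk] - ref$data[msk])), 0.02)
})
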