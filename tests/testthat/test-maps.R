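test_that("background masking recovers the apple disk", {
  sc <- small_scene("high", seed = 41)
  rc <- flat_field(sc$raw, sc$white, sc$dark)
  mask <- mask_background(rc)
  truth <- sc$truth$apple_mask
  iou <- sum(mask & truth) / sum(mask | truth)
  expect_gte(iou, 0.98)
  # threshold below the minimum: degenerate full-frame mask with warning
  expect_warning(full <- mask_background(rc, threshold = -1),
                 "full-frame")
  expect_true(all(full))
})

test_that("classification maps stay inside the apple mask", {
  sc <- small_scene("high", seed = 42)
  rc <- flat_field(sc$raw, sc$white, sc$dark)
  cam <- sc$cam
  cb <- enumerate_combinations(cam, rc$axis, c(774.2, 553.9, 424.5),
                               exposure_levels = 0.02,
                               fraction_grid = 0.5)[[1]]
  ms <- acquire_multispectral(rc, cb, seed = 1)
  # train on this scene's own truth pixels
  X <- matrix(ms$data, ncol = 3)
  y <- factor(ifelse(sc$truth$bruise_mask[sc$truth$apple_mask],
                     "bruise", "sound"),
              levels = c("bruise", "sound"))
  Xa <- X[as.vector(sc$truth$apple_mask), ]
  fit <- fit_classifier(Xa, y, "qda")
  amask <- mask_background(ms)
  cmap <- classify_pixels(ms, fit, amask)
  expect_true(all(cmap$map[!amask] == 0))
  expect_gt(mean((cmap$map[sc$truth$apple_mask] == 1) ==
                   sc$truth$bruise_mask[sc$truth$apple_mask]), 0.9)
  expect_error(classify_pixels(ms, fit, amask & FALSE), "empty")
})

test_that("open-close removes specks, keeps blocks, preserves emptiness", {
  m <- matrix(0L, 20, 20)
  m[5, 5] <- 1L                                   # isolated positive
  m[10:19, 10:19] <- 1L                           # solid block
  cl <- clean_map(m)
  expect_equal(cl[5, 5], 0L)
  expect_true(all(cl[11:18, 11:18] == 1L))        # interior preserved
  expect_identical(clean_map(matrix(0L, 8, 8)), matrix(0L, 8, 8))
})

test_that("morphology is monotone: open never adds, close never removes", {
  set.seed(43)
  m <- matrix(rbinom(900, 1, 0.3), 30, 30)
  opened <- EBImage::opening(matrix(as.double(m), 30),
                             EBImage::makeBrush(3, "disc"))
  cleaned <- clean_map(m)
  expect_true(all(opened <= m))                   # opening only removes
  expect_true(all(cleaned >= (opened > 0.5)))     # closing only adds
})

test_that("overlays paint positives red and round-trip the mask", {
  set.seed(44)
  img <- matrix(runif(400), 20, 20)
  m <- matrix(0L, 20, 20); m[8:12, 4:7] <- 1L
  ov <- render_overlay(img, m)
  expect_identical(overlay_mask(ov), m)
  empty <- render_overlay(img, matrix(0L, 20, 20))
  rng <- range(img)
  expect_equal(empty[, , 1], (img - rng[1]) / diff(rng))
  expect_equal(empty[, , 1], empty[, , 2])
  expect_error(render_overlay(img, m[1:10, ]), "shapes")
})

test_that("apple-level decisions follow the minimum-area rule", {
  m <- matrix(0L, 30, 30)
  expect_false(apple_decision(m)$bruised)
  m[4, 4] <- 1L                                   # below min area
  expect_false(apple_decision(m, min_area = 10)$bruised)
  m[20:24, 20:24] <- 1L                           # 25-pixel component
  dec <- apple_decision(m, min_area = 10)
  expect_true(dec$bruised)
  expect_equal(dec$largest_component, 25L)
})

test_that("scene scoring confines confusion counts to the apple", {
  sc <- small_scene("high", seed = 45)
  cmap <- structure(list(map = sc$truth$bruise_mask * 1L,
                         apple_mask = sc$truth$apple_mask,
                         cleaned = sc$truth$bruise_mask * 1L),
                    class = "classification_map")
  res <- score_scene(cmap, sc$truth)
  expect_equal(res$tp + res$fp + res$fn + res$tn,
               sum(sc$truth$apple_mask))
  expect_equal(res$pixel_accuracy, 1)
  expect_true(res$correct)
  # a sound apple with an empty map is called sound
  snd <- small_scene("sound", seed = 45)
  cm0 <- structure(list(map = snd$truth$bruise_mask * 0L,
                        apple_mask = snd$truth$apple_mask,
                        cleaned = snd$truth$bruise_mask * 0L),
                   class = "classification_map")
  expect_true(score_scene(cm0, snd$truth)$correct)
})
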