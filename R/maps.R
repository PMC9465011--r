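#' Segment the apple from the background
#'
#' Otsu threshold on the 553.9 nm (or nearest available) waveband image:
#' the apple is far brighter than the matte sample plate, so the upper
#' mode is the fruit. Classification is later applied only inside this
#' mask.
#'
#' @param image A `multispectral_image` or reflectance [hyper_cube()].
#' @param wavelength_nm Masking waveband, nm.
#' @param threshold Override threshold on the band values; `NULL` uses
#'   Otsu. A threshold at or below the image minimum yields a degenerate
#'   full-frame mask and warns.
#' @return Logical lines x samples matrix.
#' @export
mask_background <- function(image, wavelength_nm = 553.9, threshold = NULL) {
  if (inherits(image, "multispectral_image")) {
    b <- which.min(abs(image$centers_nm - wavelength_nm))
    img <- image$data[, , b]
  } else if (inherits(image, "hyper_cube")) {
    b <- nearest_band(image$axis, wavelength_nm)
    img <- image$data[, , b]
  } else stop("image must be a multispectral_image or hyper_cube")
  v <- img[is.finite(img)]
  if (length(v) == 0) stop("masking band has no finite values")
  if (is.null(threshold)) threshold <- otsu_threshold(v)
  mask <- is.finite(img) & img > threshold
  if (all(mask)) warning("threshold below image minimum: full-frame mask")
  if (!any(mask)) stop("background mask is empty at this threshold")
  mask
}

#' Pixel-wise bruise classification of a multispectral image
#'
#' Applies a trained classifier to the apple pixels of a binned image;
#' background pixels are never scored.
#'
#' @param image A reflectance-domain `multispectral_image`.
#' @param model A `bruise_classifier` trained on the same band definition.
#' @param apple_mask Logical matrix from [mask_background()].
#' @return An object of class `classification_map`: binary `map` matrix
#'   (1 = bruise, 0 elsewhere), `apple_mask`.
#' @export
classify_pixels <- function(image, model, apple_mask) {
  stopifnot(inherits(image, "multispectral_image"),
            inherits(model, "bruise_classifier"), is.logical(apple_mask))
  d <- dim(image$data)
  if (d[3] != model$p)
    stop("image band count does not match the fitted model")
  if (!any(apple_mask)) stop("apple mask is empty")
  X <- matrix(image$data, nrow = d[1] * d[2])[as.vector(apple_mask), ,
                                              drop = FALSE]
  pred <- predict(model, X)
  map <- matrix(0L, d[1], d[2])
  map[apple_mask] <- as.integer(pred == "bruise")
  structure(list(map = map, apple_mask = apple_mask,
                 centers_nm = image$centers_nm),
            class = "classification_map")
}

#' Morphological open-close cleanup of a bruise map
#'
#' Opening with a disk structuring element removes scattered isolated
#' false-positive pixels; the subsequent closing fills small holes inside
#' genuine bruise regions. Opening never adds positives and closing never
#' removes positives that survived the opening.
#'
#' @param cmap A `classification_map` (or binary matrix).
#' @param opening_radius,closing_radius Disk radii in pixels (>= 1).
#' @return The map with a `cleaned` binary matrix added (input matrices
#'   return the cleaned matrix directly).
#' @export
clean_map <- function(cmap, opening_radius = 1, closing_radius = 1) {
  stopifnot(opening_radius >= 1, closing_radius >= 1)
  m <- if (inherits(cmap, "classification_map")) cmap$map else cmap
  storage.mode(m) <- "double"
  brush <- function(r) EBImage::makeBrush(2 * r + 1, shape = "disc")
  cleaned <- EBImage::closing(EBImage::opening(m, brush(opening_radius)),
                              brush(closing_radius))
  cleaned <- matrix(as.integer(cleaned > 0.5), nrow = nrow(m))
  if (inherits(cmap, "classification_map")) {
    cmap$cleaned <- cleaned
    cmap
  } else cleaned
}

#' Render a red-on-grayscale bruise overlay
#'
#' The reference-band image in grayscale with detected bruise pixels
#' painted pure red, so the mask round-trips losslessly from the overlay's
#' channels.
#'
#' @param reference_img Numeric matrix (reference-waveband image).
#' @param map Binary matrix of detected bruise pixels.
#' @return lines x samples x 3 RGB array in [0, 1].
#' @export
render_overlay <- function(reference_img, map) {
  if (!all(dim(reference_img) == dim(map)))
    stop("reference image and map shapes differ")
  g <- reference_img
  g[!is.finite(g)] <- 0
  rng <- range(g)
  if (diff(rng) > 0) g <- (g - rng[1]) / diff(rng)
  pos <- map > 0
  rgb <- array(rep(g, 3), c(dim(g), 3))
  r <- rgb[, , 1]; gr <- rgb[, , 2]; b <- rgb[, , 3]
  r[pos] <- 1; gr[pos] <- 0; b[pos] <- 0
  rgb[, , 1] <- r; rgb[, , 2] <- gr; rgb[, , 3] <- b
  rgb
}

#' Recover the bruise mask from an overlay
#'
#' @param overlay RGB array from [render_overlay()].
#' @return Binary matrix.
#' @export
overlay_mask <- function(overlay) {
  matrix(as.integer(overlay[, , 1] == 1 & overlay[, , 2] == 0 &
                      overlay[, , 3] == 0), nrow = dim(overlay)[1])
}

#' Apple-level bruised/sound decision
#'
#' An apple is called bruised when its largest connected positive
#' component in the cleaned map reaches `min_area` pixels.
#'
#' @param cleaned Binary matrix (post-morphology map).
#' @param min_area Minimum component area in pixels (>= 1).
#' @return List with `bruised` (logical), `largest_component` and
#'   `n_positive`.
#' @export
apple_decision <- function(cleaned, min_area = 10) {
  stopifnot(min_area >= 1)
  if (inherits(cleaned, "classification_map")) {
    if (is.null(cleaned$cleaned)) stop("run clean_map() first")
    cleaned <- cleaned$cleaned
  }
  if (!any(cleaned > 0))
    return(list(bruised = FALSE, largest_component = 0L, n_positive = 0L))
  lab <- EBImage::bwlabel(matrix(as.double(cleaned > 0), nrow(cleaned)))
  sizes <- tabulate(as.integer(lab[lab > 0]))
  list(bruised = max(sizes) >= min_area,
       largest_component = max(sizes), n_positive = sum(cleaned > 0))
}

#' Detection report for one scene against ground truth
#'
#' Pixel-level confusion counts are confined to the apple mask; background
#' is never counted.
#'
#' @param cmap A cleaned `classification_map`.
#' @param truth A `scene_truth`.
#' @param min_area Passed to [apple_decision()].
#' @return List with the apple decision, `correct` (decision matches the
#'   truth label), pixel confusion counts and pixel accuracy.
#' @export
score_scene <- function(cmap, truth, min_area = 10) {
  stopifnot(inherits(cmap, "classification_map"))
  if (is.null(cmap$cleaned)) stop("run clean_map() first")
  dec <- apple_decision(cmap$cleaned, min_area)
  m <- cmap$apple_mask
  pred <- cmap$cleaned[m] > 0
  tru <- truth$bruise_mask[m]
  tp <- sum(pred & tru); fp <- sum(pred & !tru)
  fn <- sum(!pred & tru); tn <- sum(!pred & !tru)
  truly_bruised <- truth$severity_level != "sound"
  list(bruised = dec$bruised, correct = dec$bruised == truly_bruised,
       tp = tp, fp = fp, fn = fn, tn = tn,
       pixel_accuracy = (tp + tn) / (tp + tn + fp + fn),
       false_positive_pixels = fp)
}
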