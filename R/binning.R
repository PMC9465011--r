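#' Enumerate exposure/bandwidth combinations for multispectral readout
#'
#' Mirrors the acquisition-parameter design of a Random-Track multispectral
#' readout: the reference band (the key wavelength with the highest
#' throughput, 553.9 nm) is held at 90% of the A/D dynamic range, which
#' fixes the exposure for a given reference bandwidth — the wider the
#' reference ROI, the shorter the exposure. At each exposure rung, the
#' remaining key wavebands are widened until they reach 25, 50 or 90% of
#' their dynamic range; a rung/fraction pair is skipped when a band's
#' minimum single-row readout already exceeds the target fraction.
#'
#' @param cam A [camera_model()].
#' @param axis A [spectral_axis()].
#' @param key_wavelengths Key waveband centers, nm (>= 2, one of which is
#'   the reference).
#' @param exposure_levels Exposure ladder in seconds, or `NULL` to derive
#'   one from `reference_widths_nm` via [solve_exposure()].
#' @param fraction_grid Dynamic-range targets for the non-reference bands.
#' @param reference_center Reference band, nm.
#' @param reference_fraction Dynamic-range target of the reference band.
#' @param reference_widths_nm Reference ROI widths (nm) used to derive the
#'   exposure ladder when `exposure_levels` is `NULL`.
#' @return List of `binning_combination` objects: `id`, `exposure_s`,
#'   `rois` (list of [band_roi()], reference included), plus the camera
#'   and axis used.
#' @export
enumerate_combinations <- function(cam, axis, key_wavelengths,
                                   exposure_levels = NULL,
                                   fraction_grid = c(0.25, 0.50, 0.90),
                                   reference_center = 553.9,
                                   reference_fraction = 0.90,
                                   reference_widths_nm = c(0, 25, 60, 120)) {
  stopifnot(inherits(cam, "camera_model"), inherits(axis, "spectral_axis"),
            length(key_wavelengths) >= 2)
  # reference band = highest-throughput key wavelength (553.9 nm whenever
  # it is among the keys); its ROI sets the exposure
  thr_keys <- throughput(cam, key_wavelengths)
  ri <- if (any(abs(key_wavelengths - reference_center) < 1e-6))
    which.min(abs(key_wavelengths - reference_center)) else
      which.max(thr_keys)
  ref <- key_wavelengths[ri]
  others <- key_wavelengths[-ri]
  if (is.null(exposure_levels))
    exposure_levels <- vapply(reference_widths_nm, function(w)
      solve_exposure(cam, axis, ref, w, reference_fraction), numeric(1))
  combos <- list()
  id <- 0L
  for (e in exposure_levels) {
    ref_roi <- tryCatch(
      solve_roi_width(cam, axis, ref, e, reference_fraction),
      error = function(err) { warning(conditionMessage(err)); NULL })
    if (is.null(ref_roi)) next
    for (f in sort(fraction_grid, decreasing = TRUE)) {
      rois <- vector("list", length(key_wavelengths))
      rois[[ri]] <- ref_roi
      ok <- TRUE
      for (j in seq_along(others)) {
        min_frac <- predict_signal(cam, axis, band_roi(others[j], 0), e,
                                   cam$white_reflectance)$fraction
        if (min_frac > f + 0.02) { ok <- FALSE; break }  # already past target
        roi <- tryCatch(solve_roi_width(cam, axis, others[j], e, f),
                        error = function(err) {
                          warning(conditionMessage(err)); NULL })
        if (is.null(roi)) { ok <- FALSE; break }
        rois[[which(key_wavelengths == others[j])]] <- roi
      }
      if (!ok) next
      id <- id + 1L
      combos[[id]] <- structure(
        list(id = id, exposure_s = e, rois = rois,
             centers_nm = key_wavelengths, cam = cam, axis = axis),
        class = "binning_combination")
    }
  }
  if (length(combos) == 0) warning("no feasible combinations")
  combos
}

#' @export
print.binning_combination <- function(x, ...) {
  cat(sprintf("<binning_combination #%d> exposure %.4g s\n", x$id,
              x$exposure_s))
  for (r in x$rois)
    cat(sprintf("  %7.1f nm  width %5.1f nm  target %3.0f%%  achieved %4.1f%%\n",
                r$center_nm, r$roi_width_nm, 100 * r$target_fraction,
                100 * r$achieved_fraction))
  invisible(x)
}

#' Combination table in the style of an acquisition-parameter sheet
#'
#' @param combos List of `binning_combination` objects.
#' @return A data frame with one row per combination and per-band ROI
#'   width / dynamic-range columns.
#' @export
combination_table <- function(combos) {
  do.call(rbind, lapply(combos, function(cb) {
    row <- data.frame(id = cb$id, exposure_s = cb$exposure_s)
    for (r in cb$rois) {
      nm <- sprintf("%.1fnm", r$center_nm)
      row[[paste0("roi_", nm)]] <- r$roi_width_nm
      row[[paste0("dr_", nm)]] <- r$achieved_fraction
    }
    row
  }))
}

#' Spectrally bin a cube into the bands of a combination
#'
#' Raw-domain cubes (DN) are binned the way the sensor does it: the rows of
#' each ROI are summed and the result clips at the A/D full scale (clipped
#' outputs are flagged). Reflectance cubes are binned as the
#' throughput-weighted mean over the ROI rows — the signal-weighted average
#' the flat-field of a binned acquisition would deliver. A single-row ROI
#' reproduces the original band exactly in both conventions.
#'
#' @param cube A [hyper_cube()] (any kind).
#' @param combo A `binning_combination`.
#' @return A `multispectral_image`: `data` (lines x samples x n bands),
#'   `centers_nm`, `kind`, `saturated` flag per band, `combo`.
#' @export
bin_cube <- function(cube, combo) {
  stopifnot(inherits(cube, "hyper_cube"),
            inherits(combo, "binning_combination"))
  d <- dim(cube$data)
  nb <- length(combo$rois)
  out <- array(NA_real_, c(d[1], d[2], nb))
  sat <- logical(nb)
  flat <- matrix(cube$data, nrow = d[1] * d[2])
  for (b in seq_len(nb)) {
    r <- combo$rois[[b]]
    idx <- roi_bands(cube$axis, r$center_nm, r$roi_width_nm)
    if (cube$kind == "reflectance") {
      w <- throughput(combo$cam, cube$axis$wavelengths_nm[idx])
      v <- flat[, idx, drop = FALSE] %*% (w / sum(w))
    } else {
      v <- rowSums(flat[, idx, drop = FALSE])
      sat[b] <- any(v > combo$cam$full_scale_dn, na.rm = TRUE)
      v <- pmin(v, combo$cam$full_scale_dn)
    }
    out[, , b] <- v
  }
  structure(list(data = out,
                 centers_nm = vapply(combo$rois, `[[`, numeric(1),
                                     "center_nm"),
                 kind = cube$kind, saturated = sat, combo = combo),
            class = "multispectral_image")
}

#' @export
print.multispectral_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<multispectral_image:%s> %dx%d px, bands %s nm\n", x$kind,
              d[1], d[2], paste(sprintf("%.1f", x$centers_nm),
                                collapse = "/")))
  invisible(x)
}

#' Bin pixel spectra into the bands of a combination
#'
#' Reflectance-domain binning of an n x bands spectra matrix:
#' throughput-weighted means over each ROI, matching [bin_cube()] on
#' reflectance cubes, so models trained on binned spectra apply directly
#' to binned images.
#'
#' @param spectra n x bands matrix.
#' @param axis The [spectral_axis()] of the columns.
#' @param combo A `binning_combination`.
#' @return n x (number of ROIs) matrix, columns named by band center.
#' @export
bin_spectra <- function(spectra, axis, combo) {
  spectra <- as.matrix(spectra)
  stopifnot(ncol(spectra) == length(axis$wavelengths_nm))
  out <- sapply(combo$rois, function(r) {
    idx <- roi_bands(axis, r$center_nm, r$roi_width_nm)
    w <- throughput(combo$cam, axis$wavelengths_nm[idx])
    as.vector(spectra[, idx, drop = FALSE] %*% (w / sum(w)))
  })
  out <- matrix(out, nrow = nrow(spectra))
  colnames(out) <- sprintf("%.1fnm", vapply(combo$rois, `[[`, numeric(1),
                                            "center_nm"))
  out
}

#' Emulate a Random-Track multispectral acquisition of a scene
#'
#' Re-images a calibrated scene at the exposure and spectral ROIs of a
#' combination: expected DN per output band are accumulated over the ROI
#' rows from the scene reflectance and the camera throughput, sensor noise
#' and 14-bit clipping are applied, matching white/dark references are
#' rendered the same way, and the binned frames are flat-fielded back to
#' reflectance. Saturation (for instance a white reference pushed past
#' full scale by an over-wide ROI) therefore degrades the output exactly
#' as it would on the sensor.
#'
#' @param refl A reflectance [hyper_cube()] (e.g. from [flat_field()]).
#' @param combo A `binning_combination`.
#' @param seed Seed for the sensor noise.
#' @return A reflectance-domain `multispectral_image`.
#' @export
acquire_multispectral <- function(refl, combo, seed = 1) {
  stopifnot(inherits(refl, "hyper_cube"), refl$kind == "reflectance",
            inherits(combo, "binning_combination"))
  cam <- combo$cam
  d <- dim(refl$data)
  set.seed(as.integer(seed))
  flat <- matrix(refl$data, nrow = d[1] * d[2])
  flat[is.na(flat)] <- 0
  nb <- length(combo$rois)
  raw <- array(NA_real_, c(d[1], d[2], nb))
  wht <- drk <- matrix(NA_real_, 1, nb)
  for (b in seq_len(nb)) {
    r <- combo$rois[[b]]
    idx <- roi_bands(refl$axis, r$center_nm, r$roi_width_nm)
    rate <- combo$exposure_s * throughput(cam, refl$axis$wavelengths_nm[idx])
    expected <- flat[, idx, drop = FALSE] %*% rate
    raw[, , b] <- apply_sensor_noise(cam, expected)
    wht[, b] <- apply_sensor_noise(cam, matrix(sum(rate) *
                                                 cam$white_reflectance))
    drk[, b] <- apply_sensor_noise(cam, matrix(0))
  }
  denom <- as.vector(wht) - as.vector(drk)
  out <- array(NA_real_, c(d[1], d[2], nb))
  for (b in seq_len(nb)) {
    if (denom[b] <= 0) next
    out[, , b] <- (raw[, , b] - drk[b]) / denom[b]
  }
  structure(list(data = out,
                 centers_nm = vapply(combo$rois, `[[`, numeric(1),
                                     "center_nm"),
                 kind = "reflectance", saturated = rep(NA, nb),
                 combo = combo),
            class = "multispectral_image")
}
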