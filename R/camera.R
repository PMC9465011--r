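#' Parametric EMCCD camera model
#'
#' Wavelength-dependent system throughput (quantum efficiency x halogen
#' illuminant x optics) of the line-scan imager, together with the A/D
#' converter and noise parameters needed to predict digital numbers (DN).
#' The throughput is a single broad peak: silicon CCD response combined with
#' halogen illumination is strongest in the green and falls off towards both
#' the blue end and the near infrared. The peak rate is calibrated so that a
#' single detector row at the peak wavelength reaches `peak_fraction` of the
#' 14-bit full scale on the ~99%-reflectance white standard at
#' `peak_exposure_s` seconds — the reference operating point of the
#' full-resolution acquisitions.
#'
#' @param peak_nm Wavelength of maximum throughput (nm).
#' @param sigma_nm Gaussian width of the throughput curve (nm).
#' @param adc_bits A/D converter bit depth.
#' @param peak_exposure_s,peak_fraction Reference operating point: exposure
#'   at which one row at `peak_nm` reaches `peak_fraction` of full scale on
#'   the white standard.
#' @param white_reflectance Reflectance of the white reference panel.
#' @param read_noise_dn Gaussian read noise, DN rms.
#' @param electrons_per_dn Sensor gain used for shot-noise scaling.
#' @param dark_level_dn Dark-current offset, DN.
#' @param shot_noise Logical; simulate Poisson shot noise.
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(peak_nm = 553.9, sigma_nm = 200, adc_bits = 14,
                         peak_exposure_s = 0.17, peak_fraction = 0.90,
                         white_reflectance = 0.99,
                         read_noise_dn = 2, electrons_per_dn = 20,
                         dark_level_dn = 100, shot_noise = TRUE) {
  stopifnot(sigma_nm > 0, adc_bits >= 1, peak_exposure_s > 0,
            peak_fraction > 0, peak_fraction <= 1,
            white_reflectance > 0, electrons_per_dn > 0)
  full_scale <- 2^adc_bits - 1
  peak_rate <- peak_fraction * full_scale /
    (peak_exposure_s * white_reflectance)
  structure(list(peak_nm = peak_nm, sigma_nm = sigma_nm,
                 adc_bits = adc_bits, full_scale_dn = full_scale,
                 peak_rate_dn_per_s = peak_rate,
                 white_reflectance = white_reflectance,
                 read_noise_dn = read_noise_dn,
                 electrons_per_dn = electrons_per_dn,
                 dark_level_dn = dark_level_dn, shot_noise = shot_noise),
            class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf(paste0("<camera_model> %d-bit (full scale %d DN), throughput ",
                     "peak %.1f nm (sigma %.0f nm), %.0f DN/s/row at peak\n"),
              x$adc_bits, x$full_scale_dn, x$peak_nm, x$sigma_nm,
              x$peak_rate_dn_per_s))
  invisible(x)
}

#' Relative system throughput at given wavelengths
#'
#' @param cam A [camera_model()].
#' @param wavelength_nm Wavelength(s), nm.
#' @return Signal rate in DN per detector row per second at unit reflectance.
#' @export
throughput <- function(cam, wavelength_nm) {
  stopifnot(inherits(cam, "camera_model"))
  cam$peak_rate_dn_per_s *
    exp(-0.5 * ((wavelength_nm - cam$peak_nm) / cam$sigma_nm)^2)
}

#' One spectral ROI of a multispectral readout
#'
#' @param center_nm Band center, nm.
#' @param roi_width_nm Full spectral width binned into the band, nm
#'   (0 = single detector row).
#' @param target_fraction Intended dynamic-range fraction at this band.
#' @param achieved_fraction Predicted white-reference signal as a fraction
#'   of full scale (filled in by the solvers).
#' @return An object of class `band_roi`.
#' @export
band_roi <- function(center_nm, roi_width_nm = 0, target_fraction = NA_real_,
                     achieved_fraction = NA_real_) {
  stopifnot(roi_width_nm >= 0)
  structure(list(center_nm = center_nm, roi_width_nm = roi_width_nm,
                 target_fraction = target_fraction,
                 achieved_fraction = achieved_fraction),
            class = "band_roi")
}

#' Predict the digital number read out from a spectral ROI
#'
#' The signal is linear in exposure and in the summed throughput of the
#' detector rows inside the ROI, and clips at the A/D full scale.
#'
#' @param cam A [camera_model()].
#' @param axis A [spectral_axis()].
#' @param roi A [band_roi()].
#' @param exposure_s Exposure time, s.
#' @param reference_reflectance Scene reflectance used for the prediction
#'   (default 1; use `cam$white_reflectance` for the white standard).
#' @return List with `dn` (clipped at full scale), `saturated` flag and
#'   `fraction` of full scale.
#' @export
predict_signal <- function(cam, axis, roi, exposure_s,
                           reference_reflectance = 1) {
  stopifnot(inherits(cam, "camera_model"), inherits(roi, "band_roi"),
            exposure_s > 0)
  idx <- roi_bands(axis, roi$center_nm, roi$roi_width_nm)
  rate <- sum(throughput(cam, axis$wavelengths_nm[idx]))
  if (rate <= 0) stop("ROI has zero throughput")
  dn_raw <- exposure_s * rate * reference_reflectance
  saturated <- dn_raw > cam$full_scale_dn
  dn <- min(dn_raw, cam$full_scale_dn)
  list(dn = dn, saturated = saturated, fraction = dn / cam$full_scale_dn)
}

#' Solve the ROI width reaching a dynamic-range target
#'
#' Finds the smallest symmetric-about-center spectral width whose predicted
#' white-reference signal reaches `target_fraction` of the A/D full scale at
#' the given exposure. Widths grow one detector row at a time (rows are
#' added in order of distance from the center), mirroring how a spectral ROI
#' is widened on the sensor.
#'
#' @param cam A [camera_model()].
#' @param axis A [spectral_axis()].
#' @param center_nm Band center, nm.
#' @param exposure_s Exposure time, s.
#' @param target_fraction Required fraction of full scale on the white
#'   reference, in (0, 1].
#' @return A [band_roi()] with `achieved_fraction` recorded.
#' @export
solve_roi_width <- function(cam, axis, center_nm, exposure_s,
                            target_fraction) {
  stopifnot(target_fraction > 0, target_fraction <= 1, exposure_s > 0)
  wl <- axis$wavelengths_nm
  ord <- order(abs(wl - center_nm))
  rate <- 0
  target_dn <- target_fraction * cam$full_scale_dn
  for (k in seq_along(ord)) {
    rate <- rate + throughput(cam, wl[ord[k]])
    dn <- exposure_s * rate * cam$white_reflectance
    if (dn >= target_dn * (1 - 1e-9)) {
      if (dn > cam$full_scale_dn * (1 + 1e-9))
        stop(sprintf(paste0("white reference saturates at %.3g nm before ",
                            "reaching fraction %.2f (row granularity)"),
                     center_nm, target_fraction))
      width <- 2 * max(abs(wl[ord[seq_len(k)]] - center_nm))
      return(band_roi(center_nm, width, target_fraction,
                      dn / cam$full_scale_dn))
    }
  }
  max_frac <- exposure_s * rate * cam$white_reflectance / cam$full_scale_dn
  stop(sprintf(
    "target fraction %.2f unreachable at %.3g nm (max achievable %.3f)",
    target_fraction, center_nm, max_frac))
}

#' Solve the exposure that puts the reference band at its target fraction
#'
#' The reference band (highest throughput among the key wavelengths, 553.9
#' nm by default) is held at `target_fraction` of the dynamic range; the
#' required exposure is inversely proportional to the summed throughput of
#' the ROI, so wider reference bandwidths permit shorter exposures.
#'
#' @param cam A [camera_model()].
#' @param axis A [spectral_axis()].
#' @param reference_center Reference band center, nm.
#' @param roi_width_nm Spectral width of the reference ROI, nm.
#' @param target_fraction Fraction of full scale to reach, default 0.90.
#' @return Exposure time in seconds.
#' @export
solve_exposure <- function(cam, axis, reference_center = 553.9,
                           roi_width_nm = 0, target_fraction = 0.90) {
  stopifnot(target_fraction > 0, target_fraction <= 1)
  idx <- roi_bands(axis, reference_center, roi_width_nm)
  rate <- sum(throughput(cam, axis$wavelengths_nm[idx]))
  if (rate <= 0) stop("reference ROI has zero throughput")
  target_fraction * cam$full_scale_dn / (rate * cam$white_reflectance)
}
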