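#' Spectral axis of a line-scan VIS-NIR imager
#'
#' Builds the wavelength axis of the simulated pushbroom imager: a uniform
#' grid over the visible/near-infrared range whose band centers nearest to a
#' set of anchor wavelengths are snapped onto those anchors exactly, so that
#' the key wavebands used throughout the bruise-detection workflow (424.5,
#' 553.9, 774.2 and 812.5 nm) are addressable band centers rather than
#' between-band positions. The snap displaces each affected center by less
#' than half the sampling interval, so the axis stays strictly increasing.
#'
#' @param from,to Range covered, in nm. Defaults span 400-1000 nm.
#' @param by Nominal sampling interval between detector rows, in nm.
#' @param anchors Wavelengths (nm) that must be exact band centers. Set to
#'   `NULL` for a plain uniform grid.
#' @return An object of class `spectral_axis`: a list with `wavelengths_nm`
#'   (strictly increasing numeric vector) and `sampling_interval_nm`.
#' @examples
#' ax <- spectral_axis()
#' 553.9 %in% ax$wavelengths_nm
#' @export
spectral_axis <- function(from = 400, to = 1000, by = 5,
                          anchors = c(424.5, 553.9, 774.2, 812.5)) {
  stopifnot(is.numeric(from), is.numeric(to), to > from, by > 0)
  wl <- seq(from, to, by = by)
  if (!is.null(anchors)) {
    anchors <- sort(anchors)
    if (any(anchors < from | anchors > to))
      stop("anchor wavelengths must lie within [from, to]")
    for (a in anchors) {
      i <- which.min(abs(wl - a))
      wl[i] <- a
    }
    if (any(diff(wl) <= 0))
      stop("anchors too close together for this sampling interval")
  }
  structure(list(wavelengths_nm = wl, sampling_interval_nm = by),
            class = "spectral_axis")
}

#' @export
print.spectral_axis <- function(x, ...) {
  wl <- x$wavelengths_nm
  cat(sprintf("<spectral_axis> %d bands, %.1f-%.1f nm, %.1f nm sampling\n",
              length(wl), min(wl), max(wl), x$sampling_interval_nm))
  invisible(x)
}

#' Index of the band center nearest a wavelength
#'
#' @param axis A [spectral_axis()].
#' @param wavelength_nm Target wavelength(s), nm.
#' @return Integer index (or vector of indices) into `axis$wavelengths_nm`.
#' @export
nearest_band <- function(axis, wavelength_nm) {
  stopifnot(inherits(axis, "spectral_axis"))
  vapply(wavelength_nm,
         function(w) which.min(abs(axis$wavelengths_nm - w)), integer(1))
}

#' Indices of the bands inside a symmetric spectral ROI
#'
#' A spectral region of interest is the contiguous run of detector rows
#' whose centers fall within `width_nm/2` of `center_nm`. A width of 0
#' denotes the minimum readout of a single detector row.
#'
#' @param axis A [spectral_axis()].
#' @param center_nm ROI center, nm.
#' @param width_nm Full spectral width of the ROI, nm (>= 0).
#' @return Integer vector of band indices, always non-empty.
#' @export
roi_bands <- function(axis, center_nm, width_nm = 0) {
  stopifnot(inherits(axis, "spectral_axis"), width_nm >= 0)
  wl <- axis$wavelengths_nm
  if (center_nm < min(wl) || center_nm > max(wl))
    stop("ROI center outside the spectral axis")
  idx <- which(abs(wl - center_nm) <= width_nm / 2 + 1e-9)
  if (length(idx) == 0) idx <- which.min(abs(wl - center_nm))
  idx
}

# unit-height Gaussian bump, used for absorption features and loadings
gauss_bump <- function(wl, center, sigma) exp(-0.5 * ((wl - center) / sigma)^2)
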