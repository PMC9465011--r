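#' Flat-field calibration to relative reflectance
#'
#' Converts a raw cube to relative reflectance band by band,
#' `R = (raw - dark) / (white - dark)`, using white and dark reference
#' frames. Line-scan systems acquire the references as a short stack of
#' lines; when the reference cubes have fewer lines than the raw cube they
#' are averaged over their lines and broadcast along the scan axis (one
#' reference value per sample per band). Entries where `white <= dark`
#' carry no radiometric information and are flagged invalid (set `NA`),
#' never silently clipped; values above 1 (for example specular glints) are
#' kept.
#'
#' @param raw,white,dark [hyper_cube()] objects on the same spectral axis;
#'   `white`/`dark` must match `raw` in samples and bands.
#' @return An object of class `reflectance_cube`: a [hyper_cube()] of kind
#'   `"reflectance"` carrying a `valid_mask` array (TRUE where the
#'   denominator was positive).
#' @export
flat_field <- function(raw, white, dark) {
  stopifnot(inherits(raw, "hyper_cube"), inherits(white, "hyper_cube"),
            inherits(dark, "hyper_cube"))
  if (!isTRUE(all.equal(raw$axis$wavelengths_nm, white$axis$wavelengths_nm)) ||
      !isTRUE(all.equal(raw$axis$wavelengths_nm, dark$axis$wavelengths_nm)))
    stop("raw, white and dark cubes must share one spectral axis")
  d <- dim(raw$data)
  ref <- function(cube, label) {
    dd <- dim(cube$data)
    if (dd[2] != d[2] || dd[3] != d[3])
      stop(label, " reference does not match raw in samples/bands")
    if (dd[1] == d[1]) return(cube$data)
    m <- apply(cube$data, c(2, 3), mean)          # average reference lines
    array(rep(m, each = d[1]), d)
  }
  w <- ref(white, "white")
  k <- ref(dark, "dark")
  denom <- w - k
  valid <- denom > 0
  if (!any(valid)) stop("white reference nowhere exceeds dark reference")
  out <- (raw$data - k) / denom
  out[!valid] <- NA_real_
  cube <- hyper_cube(out, raw$axis, "reflectance")
  cube$valid_mask <- valid
  class(cube) <- c("reflectance_cube", class(cube))
  cube
}

#' Calibrate every scene of a cohort
#'
#' @param cohort List of `apple_scene` objects from [generate_cohort()].
#' @return List of [flat_field()] reflectance cubes, same order.
#' @export
calibrate_cohort <- function(cohort) {
  lapply(cohort, function(sc) flat_field(sc$raw, sc$white, sc$dark))
}
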