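#' Hyperspectral cube container
#'
#' A lines x samples x bands array of digital numbers or reflectance with
#' its wavelength axis. `kind` records the radiometric role of the cube.
#'
#' @param data 3-D numeric array, lines x samples x bands.
#' @param axis A [spectral_axis()] whose length matches `dim(data)[3]`.
#' @param kind One of `"raw"`, `"dark"`, `"white"`, `"reflectance"`.
#' @return An object of class `hyper_cube`.
#' @export
hyper_cube <- function(data, axis,
                       kind = c("raw", "dark", "white", "reflectance")) {
  kind <- match.arg(kind)
  stopifnot(is.array(data), length(dim(data)) == 3,
            inherits(axis, "spectral_axis"),
            dim(data)[3] == length(axis$wavelengths_nm))
  structure(list(data = data, axis = axis, kind = kind),
            class = "hyper_cube")
}

#' @export
print.hyper_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hyper_cube:%s> %d lines x %d samples x %d bands\n",
              x$kind, d[1], d[2], d[3]))
  invisible(x)
}

# ENVI data-type codes used here
.envi_types <- data.frame(code = c(2L, 4L, 5L, 12L),
                          what = c("integer", "numeric", "numeric",
                                   "integer"),
                          size = c(2L, 4L, 8L, 2L),
                          signed = c(TRUE, TRUE, TRUE, FALSE))

#' Write a cube as an ENVI raster
#'
#' Writes the binary raster (band-interleaved as requested) together with
#' an ASCII `.hdr` header carrying the image dimensions, data type, byte
#' order and the wavelength list. Integer rasters round-trip bit exactly;
#' reflectance cubes are stored as 8-byte floats and round-trip to full
#' precision.
#'
#' @param cube A [hyper_cube()].
#' @param path Path of the binary data file; the header is written next to
#'   it as `<path>.hdr`.
#' @param interleave `"bil"`, `"bsq"` or `"bip"`.
#' @param data_type ENVI data-type code: 2 (int16), 4 (float32), 5
#'   (float64) or 12 (uint16). Default: 12 for DN cubes, 5 for reflectance.
#' @return `path`, invisibly.
#' @export
write_envi <- function(cube, path, interleave = c("bil", "bsq", "bip"),
                       data_type = NULL) {
  stopifnot(inherits(cube, "hyper_cube"))
  interleave <- match.arg(interleave)
  if (is.null(data_type))
    data_type <- if (cube$kind == "reflectance") 5L else 12L
  ti <- match(data_type, .envi_types$code)
  if (is.na(ti)) stop("unsupported ENVI data type: ", data_type)
  d <- dim(cube$data)
  hdr <- c("ENVI",
           sprintf("samples = %d", d[2]),
           sprintf("lines = %d", d[1]),
           sprintf("bands = %d", d[3]),
           "header offset = 0",
           "file type = ENVI Standard",
           sprintf("data type = %d", data_type),
           sprintf("interleave = %s", interleave),
           "byte order = 0",
           sprintf("wavelength units = Nanometers"),
           sprintf("wavelength = { %s }",
                   paste(format(cube$axis$wavelengths_nm, trim = TRUE,
                                scientific = FALSE), collapse = " , ")))
  writeLines(hdr, paste0(path, ".hdr"))
  # reorder to the on-disk element order; fastest-varying first:
  #   bil: sample, band, line ; bsq: sample, line, band ; bip: band, sample, line
  perm <- switch(interleave,
                 bil = c(2, 3, 1), bsq = c(2, 1, 3), bip = c(3, 2, 1))
  vec <- as.vector(aperm(cube$data, perm))
  con <- file(path, "wb")
  on.exit(close(con))
  if (.envi_types$what[ti] == "integer") {
    if (any(vec != round(vec)))
      stop("non-integer values cannot be stored with integer data type")
    writeBin(as.integer(vec), con, size = .envi_types$size[ti],
             endian = "little")
  } else {
    writeBin(as.double(vec), con, size = .envi_types$size[ti],
             endian = "little")
  }
  invisible(path)
}

#' Read an ENVI raster into a cube
#'
#' @param path Path of the binary data file (header expected at
#'   `<path>.hdr` or with the `.hdr` extension replacing the data
#'   extension).
#' @param kind Radiometric role recorded on the cube; guessed as
#'   `"reflectance"` for float rasters and `"raw"` otherwise when omitted.
#' @return A [hyper_cube()].
#' @export
read_envi <- function(path, kind = NULL) {
  hdr_path <- paste0(path, ".hdr")
  if (!file.exists(hdr_path))
    hdr_path <- sub("\\.[^.]+$", ".hdr", path)
  if (!file.exists(hdr_path)) stop("ENVI header not found for ", path)
  lines_txt <- readLines(hdr_path, warn = FALSE)
  txt <- paste(lines_txt, collapse = "\n")
  get_num <- function(key) {
    m <- regmatches(txt, regexpr(paste0(key, "\\s*=\\s*[0-9]+"), txt))
    if (length(m) == 0) stop("ENVI header missing field: ", key)
    as.integer(sub(".*=\\s*", "", m))
  }
  ns <- get_num("samples"); nl <- get_num("lines"); nb <- get_num("bands")
  dt <- get_num("data type")
  il <- regmatches(txt, regexpr("interleave\\s*=\\s*[a-zA-Z]+", txt))
  if (length(il) == 0) stop("ENVI header missing field: interleave")
  il <- tolower(sub(".*=\\s*", "", il))
  if (!il %in% c("bil", "bsq", "bip"))
    stop("unsupported interleave: ", il)
  wl_m <- regmatches(txt, regexpr("wavelength\\s*=\\s*\\{[^}]*\\}", txt))
  if (length(wl_m) == 0)
    stop("ENVI header carries no wavelength list")
  wl <- as.numeric(strsplit(gsub(".*\\{|\\}", "", wl_m), ",")[[1]])
  if (length(wl) != nb)
    stop("wavelength list length does not match band count")
  ti <- match(dt, .envi_types$code)
  if (is.na(ti)) stop("unsupported ENVI data type: ", dt)
  n <- ns * nl * nb
  con <- file(path, "rb")
  on.exit(close(con))
  vec <- readBin(con, what = .envi_types$what[ti], n = n,
                 size = .envi_types$size[ti],
                 signed = .envi_types$signed[ti], endian = "little")
  if (length(vec) != n) stop("raster file shorter than header promises")
  dims <- switch(il,
                 bil = c(ns, nb, nl), bsq = c(ns, nl, nb),
                 bip = c(nb, ns, nl))
  inv <- switch(il, bil = c(3, 1, 2), bsq = c(2, 1, 3), bip = c(3, 2, 1))
  arr <- aperm(array(vec, dims), inv)
  sampling <- if (nb > 1) stats::median(diff(wl)) else NA_real_
  ax <- structure(list(wavelengths_nm = wl, sampling_interval_nm = sampling),
                  class = "spectral_axis")
  if (is.null(kind))
    kind <- if (.envi_types$what[ti] == "numeric") "reflectance" else "raw"
  hyper_cube(arr, ax, kind)
}
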