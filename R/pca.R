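#' Principal components of pixel spectra
#'
#' Mean-centered PCA (no variance scaling, so loadings stay in reflectance
#' units) of an n x bands spectra matrix. Scores satisfy
#' `score = (spectrum - mean) %*% loading` with unit-norm loading columns.
#'
#' @param spectra n x bands numeric matrix.
#' @param axis A [spectral_axis()] with one entry per column.
#' @param K Number of components to keep.
#' @return An object of class `pc_decomposition`: `loadings` (bands x K),
#'   `explained_variance_ratio` (length K, non-increasing, relative to the
#'   total variance over all components), `center`, `scores` (n x K) and
#'   the axis.
#' @export
pca_spectra <- function(spectra, axis, K = 4) {
  spectra <- as.matrix(spectra)
  stopifnot(inherits(axis, "spectral_axis"),
            ncol(spectra) == length(axis$wavelengths_nm))
  if (K > ncol(spectra)) stop("K exceeds the number of bands")
  if (nrow(spectra) <= K) stop("need more than K spectra")
  p <- stats::prcomp(spectra, center = TRUE, scale. = FALSE)
  evr <- p$sdev^2 / sum(p$sdev^2)
  structure(list(loadings = p$rotation[, seq_len(K), drop = FALSE],
                 explained_variance_ratio = evr[seq_len(K)],
                 center = p$center,
                 scores = p$x[, seq_len(K), drop = FALSE],
                 axis = axis),
            class = "pc_decomposition")
}

#' Principal-component score images of a reflectance cube
#'
#' Runs [pca_spectra()] on the spectra of the masked (apple) pixels and
#' rasterizes the scores back into per-component score images, the PC
#' images used to locate bruised regions.
#'
#' @param cube A reflectance [hyper_cube()].
#' @param apple_mask Logical lines x samples matrix; `NULL` uses all
#'   pixels.
#' @param K Number of components.
#' @return A `pc_decomposition` with an extra `score_images` element
#'   (list of K matrices, `NA` off the mask) and `mask`.
#' @export
pca_cube <- function(cube, apple_mask = NULL, K = 4) {
  stopifnot(inherits(cube, "hyper_cube"))
  d <- dim(cube$data)
  if (is.null(apple_mask)) apple_mask <- matrix(TRUE, d[1], d[2])
  if (!any(apple_mask)) stop("mask selects no pixels")
  X <- cube_spectra(cube, apple_mask)
  pc <- pca_spectra(X, cube$axis, K)
  pc$mask <- apple_mask
  pc$score_images <- lapply(seq_len(K), function(k) {
    img <- matrix(NA_real_, d[1], d[2])
    img[apple_mask] <- pc$scores[, k]
    img
  })
  pc
}

# pixel spectra of a cube at masked positions, one row per pixel
cube_spectra <- function(cube, mask) {
  d <- dim(cube$data)
  matrix(cube$data[rep(as.vector(mask), d[3])],
         nrow = sum(mask), ncol = d[3])
}
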