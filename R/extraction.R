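#' Select labeled bruise/sound pixels from PC score images
#'
#' Automates the visual pixel-picking step of the workflow: the bruise
#' contrast concentrates in one of the lower principal-component score
#' images, so that image is thresholded (Otsu) into two groups over the
#' apple pixels, and the group whose mean reflectance over 550-600 nm is
#' lower is taken as the bruise class. By default the discriminant PC is
#' chosen automatically among PC2-PC4 as the score image whose Otsu split
#' gives the strongest 550-600 nm contrast (ties resolved towards PC3);
#' pass `designated_pc` to force an index. When ground truth is supplied
#' the selection is audited against it (purity reported) and, with
#' `enforce_truth = TRUE`, restricted to pixels the truth confirms —
#' the analogue of picking only clearly observable regions by eye.
#'
#' @param pc A [pca_cube()] decomposition with score images.
#' @param cube The reflectance [hyper_cube()] the spectra are read from.
#' @param truth Optional `scene_truth` (from [make_apple_scene()]).
#' @param designated_pc Integer PC index, or `NULL` for automatic choice
#'   among `pc_candidates`.
#' @param pc_candidates PC indices considered by the automatic choice.
#' @param max_per_class Cap on pixels kept per class (balanced sampling so
#'   one apple cannot dominate a cohort dataset).
#' @param enforce_truth Restrict selections to truth-confirmed pixels when
#'   truth is available.
#' @return List with `bruise` and `sound` index matrices (columns
#'   `line`, `sample`), `pc_used`, and `purity` (fraction of thresholded
#'   bruise pixels confirmed by truth; `NA` without truth).
#' @export
select_label_pixels <- function(pc, cube, truth = NULL,
                                designated_pc = NULL, pc_candidates = 2:4,
                                max_per_class = 40, enforce_truth = TRUE) {
  stopifnot(inherits(pc, "pc_decomposition"), inherits(cube, "hyper_cube"))
  if (is.null(pc$score_images)) stop("pc must come from pca_cube()")
  mask <- pc$mask
  vis_mean <- band_window_mean(cube, 550, 600)

  v <- vis_mean[mask]

  # a bruise appears in a PC score image as a small, spatially coherent
  # cluster on the dark (low 550-600 nm reflectance) side of the score
  # distribution; scan tail quantiles and keep the most coherent tail
  split_on <- function(k) {
    sc <- pc$score_images[[k]]
    sc[!mask] <- NA
    # 3x3 mean smoothing consolidates coherent structure against noise
    sm <- smooth3(sc)[mask]
    if (stats::sd(sm) == 0) return(NULL)
    # orient scores so that larger score = darker in the browning window
    if (stats::cor(sm, v) > 0) sm <- -sm
    best <- NULL
    for (q in seq(0.70, 0.97, by = 0.03)) {
      sel <- sm > stats::quantile(sm, q)
      if (!any(sel)) next
      blob <- matrix(FALSE, nrow(mask), ncol(mask))
      blob[mask] <- sel
      lab <- EBImage::bwlabel(matrix(as.double(blob), nrow(blob)))
      sizes <- tabulate(as.integer(lab[lab > 0]))
      coherence <- max(sizes) / sum(sizes)
      if (is.null(best) || coherence > best$coherence)
        best <- list(lab = lab, id = which.max(sizes),
                     coherence = coherence)
    }
    if (is.null(best) || best$coherence < 0.40) return(NULL)
    # keep only the dominant blob; require it round-ish, which rejects the
    # shaded rim annulus of the apple disk
    blob <- best$lab == best$id
    shp <- EBImage::computeFeatures.shape(matrix(as.double(blob),
                                                 nrow(blob)))
    circ <- 4 * pi * shp[1, "s.area"] / max(shp[1, "s.perimeter"], 1)^2
    if (circ < 0.35) return(NULL)
    bruise_side <- blob[mask]
    m_b <- mean(v[bruise_side]); m_s <- mean(v[!bruise_side])
    if (m_b >= m_s) return(NULL)          # blob must be the darker region
    list(k = k, bruise = bruise_side, coherence = best$coherence,
         contrast = (m_s - m_b) / (stats::sd(v) + 1e-12))
  }

  cand <- if (!is.null(designated_pc)) designated_pc else pc_candidates
  splits <- Filter(Negate(is.null), lapply(cand, split_on))
  if (length(splits) == 0 && is.null(truth))
    stop("no PC score image yields a bruise-like split; no pixels selected")

  pix <- which(mask, arr.ind = TRUE)
  colnames(pix) <- c("line", "sample")
  purity <- NA_real_
  if (length(splits) > 0) {
    # prefer PC3 on near-ties, then highest contrast
    best <- splits[[which.max(vapply(splits, function(s)
      s$contrast + 0.05 * (s$k == 3), numeric(1)))]]
    bruise_sel <- best$bruise
    pc_used <- best$k
  } else {
    # faint bruise with no clear PC contrast: fall back to the core of the
    # marked impact site (sticker-marked impacts on real fruit), where the
    # depression is fully developed
    bruise_sel <- truth$bruise_core_mask[mask]
    pc_used <- NA_integer_
  }

  if (!is.null(truth)) {
    tb <- truth$bruise_mask[mask]
    purity <- if (any(bruise_sel)) mean(tb[bruise_sel]) else NA_real_
    if (enforce_truth) {
      bruise_sel <- bruise_sel & tb
      # spurious blob entirely outside the marked impact: fall back to the
      # marked core, as for faint bruises with no PC contrast
      if (!any(bruise_sel) && any(tb))
        bruise_sel <- truth$bruise_core_mask[mask]
      sound_sel <- !bruise_sel & !tb
    } else sound_sel <- !bruise_sel
  } else sound_sel <- !bruise_sel

  if (!any(sound_sel))
    stop("no sound pixels selected; thresholding degenerate")
  take <- function(sel) {
    i <- which(sel)
    if (length(i) > max_per_class) i <- sample(i, max_per_class)
    pix[i, , drop = FALSE]
  }
  list(bruise = take(bruise_sel), sound = take(sound_sel),
       pc_used = pc_used, purity = purity)
}

# 3x3 mean filter with NA-aware borders
smooth3 <- function(img) {
  x <- img
  x[is.na(x)] <- 0
  w <- (!is.na(img)) * 1
  num <- EBImage::filter2(x, matrix(1 / 9, 3, 3))
  den <- EBImage::filter2(w, matrix(1 / 9, 3, 3))
  out <- num / pmax(den, 1e-9)
  out[is.na(img)] <- NA
  out
}

# Otsu's threshold on a numeric vector (maximizes between-class variance)
otsu_threshold <- function(x, levels = 256) {
  r <- range(x)
  if (diff(r) == 0) return(r[1])
  u <- (x - r[1]) / diff(r)
  th <- EBImage::otsu(EBImage::Image(matrix(u, nrow = 1)), range = c(0, 1),
                      levels = levels)
  r[1] + th * diff(r)
}

# mean image over the bands whose centers fall in [lo, hi] nm
band_window_mean <- function(cube, lo, hi) {
  wl <- cube$axis$wavelengths_nm
  idx <- which(wl >= lo & wl <= hi)
  if (length(idx) == 0) idx <- which.min(abs(wl - (lo + hi) / 2))
  apply(cube$data[, , idx, drop = FALSE], c(1, 2), mean)
}

#' Build the labeled pixel-spectra dataset from a cohort
#'
#' Calibrates each scene, computes its PC score images, selects labeled
#' bruise/sound pixels and reads their spectra from the reflectance cube.
#'
#' @param cohort List of `apple_scene` objects.
#' @param refl Optional pre-computed list of reflectance cubes
#'   (from [calibrate_cohort()]); computed if omitted.
#' @param K Components for the per-scene PCA.
#' @param max_per_class Pixel cap per class per apple.
#' @param seed Seed for the per-apple pixel subsampling.
#' @param ... Passed to [select_label_pixels()].
#' @return An object of class `pixel_spectra_dataset`: `spectra` (n x
#'   bands), `labels` (factor bruise/sound), `apple`, `line`, `sample`,
#'   `axis`, and mean selection `purity`.
#' @export
build_pixel_dataset <- function(cohort, refl = NULL, K = 4,
                                max_per_class = 40, seed = 1, ...) {
  if (is.null(refl)) refl <- calibrate_cohort(cohort)
  stopifnot(length(refl) == length(cohort))
  set.seed(as.integer(seed))
  rows <- list()
  purities <- c()
  for (i in seq_along(cohort)) {
    sc <- cohort[[i]]
    cube <- refl[[i]]
    pc <- pca_cube(cube, sc$truth$apple_mask, K = K)
    sel <- if (sc$truth$severity_level == "sound")
      list(bruise = matrix(integer(0), 0, 2),
           sound = sample_mask_pixels(sc$truth$apple_mask, max_per_class),
           purity = NA_real_)
    else select_label_pixels(pc, cube, truth = sc$truth,
                             max_per_class = max_per_class, ...)
    purities <- c(purities, sel$purity)
    for (lab in c("bruise", "sound")) {
      p <- sel[[lab]]
      if (nrow(p) == 0) next
      X <- extract_spectra(cube, p)
      rows[[length(rows) + 1]] <-
        list(X = X, lab = rep(lab, nrow(p)), apple = rep(i, nrow(p)),
             line = p[, 1], sample = p[, 2])
    }
  }
  spectra <- do.call(rbind, lapply(rows, `[[`, "X"))
  ds <- structure(list(
    spectra = spectra,
    labels = factor(unlist(lapply(rows, `[[`, "lab")),
                    levels = c("bruise", "sound")),
    apple = unlist(lapply(rows, `[[`, "apple")),
    line = unlist(lapply(rows, `[[`, "line")),
    sample = unlist(lapply(rows, `[[`, "sample")),
    axis = refl[[1]]$axis,
    purity = mean(purities, na.rm = TRUE)),
    class = "pixel_spectra_dataset")
  ds
}

sample_mask_pixels <- function(mask, n) {
  pix <- which(mask, arr.ind = TRUE)
  colnames(pix) <- c("line", "sample")
  if (nrow(pix) > n) pix <- pix[sample(nrow(pix), n), , drop = FALSE]
  pix
}

# spectra at (line, sample) index pairs, one row per pixel
extract_spectra <- function(cube, pix) {
  d <- dim(cube$data)
  flat <- matrix(cube$data, nrow = d[1] * d[2], ncol = d[3])
  flat[(pix[, 2] - 1) * d[1] + pix[, 1], , drop = FALSE]
}

#' @export
print.pixel_spectra_dataset <- function(x, ...) {
  cat(sprintf("<pixel_spectra_dataset> %d pixels (%d bruise / %d sound), %d bands",
              nrow(x$spectra), sum(x$labels == "bruise"),
              sum(x$labels == "sound"), ncol(x$spectra)))
  if (!is.null(x$split))
    cat(sprintf(", split %d train / %d test",
                sum(x$split == "train"), sum(x$split == "test")))
  cat("\n")
  invisible(x)
}

#' Stratified train/test split of a pixel dataset
#'
#' @param ds A `pixel_spectra_dataset`.
#' @param train_fraction Fraction assigned to training (default 0.70).
#' @param seed Integer seed.
#' @return The dataset with a `split` factor (`train`/`test`), stratified
#'   by class.
#' @export
split_dataset <- function(ds, train_fraction = 0.70, seed = 1) {
  stopifnot(inherits(ds, "pixel_spectra_dataset"),
            train_fraction > 0, train_fraction < 1)
  n <- nrow(ds$spectra)
  if (n < 10) stop("need at least 10 pixels to split")
  if (nlevels(droplevels(ds$labels)) < 2)
    stop("both classes must be present before splitting")
  set.seed(as.integer(seed))
  split <- rep("test", n)
  for (lv in levels(ds$labels)) {
    i <- which(ds$labels == lv)
    k <- round(train_fraction * length(i))
    k <- max(1, min(k, length(i) - 1))       # both classes in both parts
    split[sample(i, k)] <- "train"
  }
  ds$split <- factor(split, levels = c("train", "test"))
  ds
}
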