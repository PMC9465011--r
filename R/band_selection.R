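#' Pre-select candidate wavelengths from PC loading extrema
#'
#' The peaks and valleys of each principal component's weighting
#' coefficients mark the wavelengths that contribute most to the linear
#' transformation, so they form the candidate pool for the wrapper
#' selection. An extremum is kept when its prominence (height above the
#' higher of its flanking saddles) exceeds a fraction of the loading's
#' maximum absolute value, so only a handful of dominant wavebands survive
#' per component, not every noise ripple.
#'
#' @param pc A `pc_decomposition` (from [pca_spectra()] or [pca_cube()]).
#' @param n_components Number of leading components scanned.
#' @param prominence Prominence threshold as a fraction of each loading's
#'   `max(abs(value))`.
#' @return An object of class `candidate_wavelengths`: `per_pc` (list of
#'   data frames with wavelength and polarity) and the pooled sorted
#'   unique `pool` (nm).
#' @export
preselect_candidates <- function(pc, n_components = 4, prominence = 0.10) {
  stopifnot(inherits(pc, "pc_decomposition"))
  K <- min(n_components, ncol(pc$loadings))
  wl <- pc$axis$wavelengths_nm
  per_pc <- vector("list", K)
  for (k in seq_len(K)) {
    v <- pc$loadings[, k]
    thr <- prominence * max(abs(v))
    if (max(v) - min(v) < 1e-12) {
      per_pc[[k]] <- data.frame(wavelength_nm = numeric(0),
                                polarity = character(0))
      next
    }
    peaks <- loading_extrema(v, thr)
    valleys <- loading_extrema(-v, thr)
    per_pc[[k]] <- rbind(
      if (length(peaks)) data.frame(wavelength_nm = wl[peaks],
                                    polarity = "peak"),
      if (length(valleys)) data.frame(wavelength_nm = wl[valleys],
                                      polarity = "valley"))
    if (is.null(per_pc[[k]]))
      per_pc[[k]] <- data.frame(wavelength_nm = numeric(0),
                                polarity = character(0))
  }
  names(per_pc) <- paste0("PC", seq_len(K))
  pool <- sort(unique(unlist(lapply(per_pc, `[[`, "wavelength_nm"))))
  if (length(pool) == 0)
    stop("no candidate wavelengths survive the prominence threshold")
  structure(list(per_pc = per_pc, pool = pool),
            class = "candidate_wavelengths")
}

# indices of local maxima of v with prominence >= thr (prominence measured
# against the higher flanking saddle reported by findpeaks)
loading_extrema <- function(v, thr) {
  p <- pracma::findpeaks(v, minpeakdistance = 2)
  if (is.null(p)) return(integer(0))
  keep <- vapply(seq_len(nrow(p)), function(i) {
    saddle <- max(v[p[i, 3]], v[p[i, 4]])
    (p[i, 1] - saddle) >= thr
  }, logical(1))
  sort(p[keep, 2])
}

#' Sequential forward selection of wavebands for one classifier
#'
#' Greedy wrapper selection on the training partition: at each step the
#' candidate waveband whose addition maximizes the mean stratified 5-fold
#' cross-validated accuracy is adopted (ties broken towards the lower
#' wavelength); the held-out test partition is scored once per step and
#' never used for selection.
#'
#' @param ds A split `pixel_spectra_dataset` (see [split_dataset()]).
#' @param candidates A `candidate_wavelengths` object or numeric vector of
#'   wavelengths (nm).
#' @param classifier Classifier id (`"lda"`, `"qda"`, `"svm"`,
#'   `"svm_rbf"`).
#' @param k_max Maximum number of wavebands selected.
#' @param folds Cross-validation folds.
#' @param seed Seed fixing the fold assignment.
#' @return An object of class `sfs_trajectory`: `wavelengths_nm` (in
#'   selection order), `cv_accuracy` and `test_accuracy` (per step),
#'   `classifier`.
#' @export
run_sfs <- function(ds, candidates, classifier, k_max = 5, folds = 5,
                    seed = 1) {
  stopifnot(inherits(ds, "pixel_spectra_dataset"))
  if (is.null(ds$split)) stop("dataset must be split before SFS")
  classifier <- match.arg(classifier, c("lda", "qda", "svm", "svm_rbf"))
  pool <- sort(if (inherits(candidates, "candidate_wavelengths"))
    candidates$pool else as.numeric(candidates))
  if (length(pool) < k_max)
    stop("need at least k_max candidate wavelengths")
  wl <- ds$axis$wavelengths_nm
  bands <- vapply(pool, function(w) which.min(abs(wl - w)), integer(1))
  tr <- ds$split == "train"
  Xtr <- ds$spectra[tr, bands, drop = FALSE]
  Xte <- ds$spectra[!tr, bands, drop = FALSE]
  ytr <- droplevels(ds$labels[tr]); yte <- droplevels(ds$labels[!tr])
  fold_id <- make_folds(ytr, folds, seed)

  sel <- integer(0)
  cv_acc <- test_acc <- numeric(k_max)
  for (k in seq_len(k_max)) {
    remaining <- setdiff(seq_along(pool), sel)
    best_j <- NA_integer_; best_a <- -Inf
    for (j in remaining) {          # ascending wavelength; strict > keeps ties low
      a <- cv_accuracy(Xtr[, c(sel, j), drop = FALSE], ytr, classifier,
                       fold_id = fold_id)
      if (a > best_a + 1e-12) { best_a <- a; best_j <- j }
    }
    sel <- c(sel, best_j)
    cv_acc[k] <- best_a
    m <- fit_classifier(Xtr[, sel, drop = FALSE], ytr, classifier)
    test_acc[k] <- mean(predict(m, Xte[, sel, drop = FALSE]) == yte)
  }
  structure(list(wavelengths_nm = pool[sel], cv_accuracy = cv_acc,
                 test_accuracy = test_acc, classifier = classifier,
                 candidate_pool = pool),
            class = "sfs_trajectory")
}

#' @export
print.sfs_trajectory <- function(x, ...) {
  cat(sprintf("<sfs_trajectory:%s> %s\n", x$classifier,
              paste(sprintf("%.1f", x$wavelengths_nm), collapse = " > ")))
  cat("  cv acc:  ", paste(sprintf("%.3f", x$cv_accuracy), collapse = " "),
      "\n  test acc:", paste(sprintf("%.3f", x$test_accuracy),
                             collapse = " "), "\n")
  invisible(x)
}

#' Optimal number of wavebands from the accuracy plateau
#'
#' Returns the smallest k at which adding a further waveband no longer
#' improves any classifier's cross-validated accuracy by `epsilon` or
#' more, while every classifier already meets the accuracy floor at k.
#' If no k qualifies, returns `k_max` with a `warning_flag` attribute.
#'
#' @param trajectories List of `sfs_trajectory` objects (one per
#'   classifier).
#' @param epsilon Minimum accuracy gain regarded as an improvement
#'   (default 1.5 percentage points, above the ~1-point resampling noise
#'   of 5-fold CV at the default dataset size).
#' @param accuracy_floor Minimum CV accuracy every classifier must reach
#'   at the chosen k.
#' @return Integer count, with attribute `warning_flag = TRUE` when the
#'   plateau rule found no qualifying k.
#' @export
choose_optimal_count <- function(trajectories, epsilon = 0.015,
                                 accuracy_floor = 0.94) {
  stopifnot(length(trajectories) >= 1)
  cv <- do.call(rbind, lapply(trajectories, `[[`, "cv_accuracy"))
  k_max <- ncol(cv)
  for (k in seq_len(k_max - 1)) {
    gains <- cv[, k + 1] - cv[, k]
    if (all(gains < epsilon) && all(cv[, k] >= accuracy_floor))
      return(k)
  }
  structure(k_max, warning_flag = TRUE)
}

#' Full key-waveband selection across the four classifiers
#'
#' Pools the dataset spectra, runs the PCA pre-selection, the per-classifier
#' sequential forward selections and the plateau rule.
#'
#' @param ds A split `pixel_spectra_dataset`.
#' @param classifiers Character vector of classifier ids.
#' @param n_components,prominence Passed to [preselect_candidates()].
#' @param k_max,folds,seed Passed to [run_sfs()].
#' @param epsilon,accuracy_floor Passed to [choose_optimal_count()].
#' @return An object of class `band_selection_result`: `candidates`,
#'   `trajectories` (named list), `optimal_count` and `key_wavelengths`
#'   (named list of the first `optimal_count` selections per classifier).
#' @export
select_bands <- function(ds, classifiers = c("lda", "qda", "svm", "svm_rbf"),
                         n_components = 4, prominence = 0.10, k_max = 5,
                         folds = 5, seed = 1, epsilon = 0.015,
                         accuracy_floor = 0.94) {
  stopifnot(inherits(ds, "pixel_spectra_dataset"), !is.null(ds$split))
  pc <- pca_spectra(ds$spectra, ds$axis, K = n_components)
  cand <- preselect_candidates(pc, n_components, prominence)
  traj <- lapply(classifiers, function(cl)
    run_sfs(ds, cand, cl, k_max = k_max, folds = folds, seed = seed))
  names(traj) <- classifiers
  n_opt <- choose_optimal_count(traj, epsilon, accuracy_floor)
  key <- lapply(traj, function(t) t$wavelengths_nm[seq_len(as.integer(n_opt))])
  structure(list(candidates = cand, trajectories = traj, pca = pc,
                 optimal_count = as.integer(n_opt),
                 warning_flag = isTRUE(attr(n_opt, "warning_flag")),
                 key_wavelengths = key),
            class = "band_selection_result")
}

#' @export
print.band_selection_result <- function(x, ...) {
  cat(sprintf("<band_selection_result> optimal count %d%s\n",
              x$optimal_count,
              if (x$warning_flag) " (plateau rule not satisfied)" else ""))
  for (cl in names(x$key_wavelengths))
    cat(sprintf("  %-8s %s nm\n", cl,
                paste(sprintf("%.1f", x$key_wavelengths[[cl]]),
                      collapse = ", ")))
  invisible(x)
}
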