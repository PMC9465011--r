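#' Score binning combinations on a cohort and pick the best
#'
#' For each combination: the training pixel spectra are binned into the
#' combination's bands, the classifier is retrained on them, every scene
#' of the evaluation cohort is re-imaged at the combination's exposure and
#' ROIs, masked, classified, cleaned and given an apple-level decision.
#' Combinations are ranked lexicographically: highest apple-level
#' accuracy, then fewest post-morphology false-positive pixels, then
#' shortest exposure (speed preference).
#'
#' @param combos List of `binning_combination` objects.
#' @param cohort Evaluation cohort of `apple_scene` objects.
#' @param ds Split `pixel_spectra_dataset` providing the training
#'   partition.
#' @param classifier Classifier id, see [fit_classifier()].
#' @param refl Optional pre-calibrated reflectance cubes for `cohort`.
#' @param opening_radius,closing_radius,min_area Map-cleaning parameters.
#' @param seed Seed for the re-imaging sensor noise.
#' @return An object of class `combination_ranking`: `scores` data frame
#'   (one row per combination), `best_id`, `best_model` and the per-best
#'   decisions.
#' @export
score_combinations <- function(combos, cohort, ds, classifier = "qda",
                               refl = NULL, opening_radius = 1,
                               closing_radius = 1, min_area = 10,
                               seed = 1) {
  stopifnot(length(combos) >= 1, inherits(ds, "pixel_spectra_dataset"),
            !is.null(ds$split))
  if (is.null(refl)) refl <- calibrate_cohort(cohort)
  tr <- ds$split == "train"
  ytr <- droplevels(ds$labels[tr])
  rows <- list(); models <- list(); decisions <- list()
  for (ci in seq_along(combos)) {
    cb <- combos[[ci]]
    Xtr <- bin_spectra(ds$spectra[tr, , drop = FALSE], ds$axis, cb)
    if (any(apply(Xtr, 2, stats::sd) <= 0)) {
      rows[[ci]] <- data.frame(id = cb$id, exposure_s = cb$exposure_s,
                               pixel_accuracy = NA, fp_pixels = NA,
                               apple_accuracy = NA, flagged = TRUE)
      next
    }
    model <- fit_classifier(Xtr, ytr, classifier)
    models[[as.character(cb$id)]] <- model
    res <- lapply(seq_along(cohort), function(i) {
      ms <- acquire_multispectral(refl[[i]], cb, seed = seed * 1000 + i)
      amask <- mask_background(ms)
      cmap <- clean_map(classify_pixels(ms, model, amask),
                        opening_radius, closing_radius)
      score_scene(cmap, cohort[[i]]$truth, min_area)
    })
    rows[[ci]] <- data.frame(
      id = cb$id, exposure_s = cb$exposure_s,
      pixel_accuracy = mean(vapply(res, `[[`, numeric(1),
                                   "pixel_accuracy")),
      fp_pixels = sum(vapply(res, `[[`, numeric(1),
                             "false_positive_pixels")),
      apple_accuracy = mean(vapply(res, `[[`, logical(1), "correct")),
      flagged = FALSE)
    decisions[[as.character(cb$id)]] <- res
  }
  scores <- do.call(rbind, rows)
  ok <- which(!scores$flagged)
  if (length(ok) == 0) stop("every combination was flagged as degenerate")
  ord <- ok[order(-scores$apple_accuracy[ok], scores$fp_pixels[ok],
                  scores$exposure_s[ok])]
  best <- scores$id[ord[1]]
  structure(list(scores = scores, best_id = best,
                 best_model = models[[as.character(best)]],
                 best_combo = combos[[which(vapply(combos, `[[`,
                                                   integer(1), "id") ==
                                              best)]],
                 best_decisions = decisions[[as.character(best)]],
                 classifier = classifier),
            class = "combination_ranking")
}

#' @export
print.combination_ranking <- function(x, ...) {
  cat(sprintf("<combination_ranking:%s> best combination #%d\n",
              x$classifier, x$best_id))
  print(x$scores, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Cohort-level detection report
#'
#' @param ranking A `combination_ranking`.
#' @param cohort The scored cohort (for severity labels).
#' @return Data frame with one row per apple (severity, decision,
#'   correctness, pixel counts) plus an `accuracy` attribute.
#' @export
detection_report <- function(ranking, cohort) {
  stopifnot(inherits(ranking, "combination_ranking"))
  res <- ranking$best_decisions
  df <- data.frame(
    apple = seq_along(res),
    severity = vapply(cohort, function(s) s$truth$severity_level,
                      character(1)),
    bruised_call = vapply(res, `[[`, logical(1), "bruised"),
    correct = vapply(res, `[[`, logical(1), "correct"),
    pixel_accuracy = vapply(res, `[[`, numeric(1), "pixel_accuracy"),
    fp_pixels = vapply(res, `[[`, numeric(1), "false_positive_pixels"))
  attr(df, "accuracy") <- mean(df$correct)
  df
}
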