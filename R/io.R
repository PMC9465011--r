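#' Write a synthetic scene to disk
#'
#' ENVI rasters (BIL interleave) for the raw, dark and white cubes, PNG
#' (0/255) masks for the ground truth, and a JSON sidecar with the
#' severity label and generator parameters.
#'
#' @param scene An `apple_scene`.
#' @param dir Output directory (created if missing).
#' @param name Base name for the files.
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir, name = "scene") {
  stopifnot(inherits(scene, "apple_scene"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (kind in c("raw", "dark", "white"))
    write_envi(scene[[kind]], file.path(dir, paste0(name, "_", kind, ".bil")),
               interleave = "bil")
  png::writePNG(scene$truth$apple_mask * 1,
                file.path(dir, paste0(name, "_apple_mask.png")))
  png::writePNG(scene$truth$bruise_mask * 1,
                file.path(dir, paste0(name, "_bruise_mask.png")))
  meta <- list(severity_level = scene$truth$severity_level,
               impact_energy_J = scene$truth$impact_energy_J,
               exposure_s = scene$exposure_s, seed = scene$seed,
               noise_sd = scene$model$noise_sd,
               latent_sds = scene$model$latent_sds,
               feature_depths = as.list(scene$model$feature_depths))
  jsonlite::write_json(meta, file.path(dir, paste0(name, ".json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write a pixel-spectra dataset as CSV plus JSON metadata
#'
#' One row per pixel: apple id, line, sample, label, split (if present),
#' then one column per wavelength.
#'
#' @param ds A `pixel_spectra_dataset`.
#' @param path CSV path; metadata is written next to it as `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(ds, path) {
  stopifnot(inherits(ds, "pixel_spectra_dataset"))
  df <- data.frame(apple = ds$apple, line = ds$line, sample = ds$sample,
                   label = as.character(ds$labels))
  if (!is.null(ds$split)) df$split <- as.character(ds$split)
  sp <- as.data.frame(ds$spectra)
  names(sp) <- sprintf("wl_%.1f", ds$axis$wavelengths_nm)
  utils::write.csv(cbind(df, sp), path, row.names = FALSE)
  jsonlite::write_json(list(n = nrow(ds$spectra),
                            wavelengths_nm = ds$axis$wavelengths_nm,
                            purity = ds$purity),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write a band-selection result as JSON
#'
#' @param sel A `band_selection_result`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_selection_json <- function(sel, path) {
  stopifnot(inherits(sel, "band_selection_result"))
  out <- list(optimal_count = sel$optimal_count,
              warning_flag = sel$warning_flag,
              candidates = sel$candidates$pool,
              key_wavelengths = sel$key_wavelengths,
              trajectories = lapply(sel$trajectories, function(t)
                list(wavelengths_nm = t$wavelengths_nm,
                     cv_accuracy = t$cv_accuracy,
                     test_accuracy = t$test_accuracy)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a combination ranking as CSV and the report as JSON
#'
#' @param ranking A `combination_ranking`.
#' @param cohort The scored cohort.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_ranking <- function(ranking, cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(ranking$scores, file.path(dir, "combination_scores.csv"),
                   row.names = FALSE)
  rep <- detection_report(ranking, cohort)
  utils::write.csv(rep, file.path(dir, "detection_report.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(best_id = ranking$best_id,
                            classifier = ranking$classifier,
                            apple_accuracy = attr(rep, "accuracy")),
                       file.path(dir, "detection_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
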