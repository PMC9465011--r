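# shared fixtures; heavy objects are built lazily and cached for the session

.fx <- new.env(parent = emptyenv())

# a camera with spectrally flat throughput: closed-form signal predictions
flat_camera <- function(rate = 1000, ...) {
  cam <- camera_model(sigma_nm = 1e9, ...)
  cam$peak_rate_dn_per_s <- rate
  cam
}

# small uniform axis without anchor snapping
tiny_axis <- function(n = 16, from = 500, by = 10)
  spectral_axis(from, from + (n - 1) * by, by = by, anchors = NULL)

# small scene for fast map/extraction tests
small_scene <- function(severity = "high", seed = 7, ...) {
  ax <- spectral_axis()
  make_apple_scene(apple_spectral_model(ax), bruise_effect(severity),
                   lines = 48, samples = 48, apple_radius_px = 19,
                   seed = seed, ...)
}

# default training cohort + dataset + selection (acceptance-scale, cached)
default_state <- function() {
  if (!is.null(.fx$state)) return(.fx$state)
  cohort <- generate_cohort(6, seed = 1)
  ds <- split_dataset(build_pixel_dataset(cohort, seed = 1), seed = 1)
  sel <- select_bands(ds, seed = 1)
  .fx$state <- list(cohort = cohort, ds = ds, sel = sel)
  .fx$state
}

random_cube <- function(lines = 8, samples = 8, bands = 32, seed = 1,
                        kind = "reflectance") {
  set.seed(seed)
  ax <- tiny_axis(bands, from = 400, by = 5)
  hyper_cube(array(runif(lines * samples * bands),
                   c(lines, samples, bands)), ax, kind)
}
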