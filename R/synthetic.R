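#' Spectral model of Golden Delicious apple skin
#'
#' Smooth baseline reflectance over 400-1000 nm with the four absorption
#' features visible in apple reflectance spectra: carotenoid pigments
#' (valley near 500 nm, spanning 450-550 nm), chlorophyll (sharp valley at
#' ~680 nm), sugar (shallow valley at ~820 nm) and water (broad depression
#' centered near 960 nm affecting 750-1000 nm). Pixel-to-pixel biological
#' variability is carried by exactly four orthonormal latent spectral
#' components with independent Gaussian per-pixel weights — the low-rank
#' structure that makes the first four principal components of extracted
#' pixel spectra carry essentially all of the variance.
#'
#' @param axis A [spectral_axis()].
#' @param feature_depths Named depths (reflectance units) of the
#'   `carotenoid`, `chlorophyll`, `sugar` and `water` absorption features.
#' @param latent_sds Standard deviations of the four latent-component
#'   weights (reflectance units along each unit-norm component).
#' @param noise_sd Additive per-pixel-per-band spectral noise, reflectance
#'   units, applied on top of the low-rank structure.
#' @return An object of class `apple_spectral_model` with the baseline
#'   vector, feature profiles and the orthonormal `latent_components`
#'   (bands x 4 matrix).
#' @export
apple_spectral_model <- function(axis,
                                 feature_depths = c(carotenoid = 0.16,
                                                    chlorophyll = 0.20,
                                                    sugar = 0.07,
                                                    water = 0.15),
                                 latent_sds = c(0.035, 0.095, 0.220, 0.030),
                                 noise_sd = 0.0015) {
  stopifnot(inherits(axis, "spectral_axis"), length(latent_sds) == 4)
  need <- c("carotenoid", "chlorophyll", "sugar", "water")
  if (!all(need %in% names(feature_depths)))
    stop("feature_depths must name carotenoid, chlorophyll, sugar and water")
  wl <- axis$wavelengths_nm
  # baseline: low in the blue, rising through the visible, high in the NIR
  base <- 0.52 + 0.26 / (1 + exp(-(wl - 520) / 45))
  dips <- feature_depths[["carotenoid"]]  * gauss_bump(wl, 500, 35) +
          feature_depths[["chlorophyll"]] * gauss_bump(wl, 680, 13) +
          feature_depths[["sugar"]]       * gauss_bump(wl, 820, 18) +
          feature_depths[["water"]]       * gauss_bump(wl, 960, 55)
  baseline <- base - dips
  if (any(baseline <= 0) || any(baseline >= 1))
    stop("feature depths push the baseline reflectance out of (0, 1)")
  # raw latent profiles: pigment amount, chlorophyll, water/sugar balance,
  # broadband tilt; orthonormalized by QR so exactly 4 orthogonal components
  raw <- cbind(gauss_bump(wl, 424.5, 18) + 0.5 * gauss_bump(wl, 500, 40),
               0.5 * gauss_bump(wl, 680, 16) + browning_profile(wl),
               water_profile(wl),
               (wl - mean(wl)) / diff(range(wl)))
  V <- qr.Q(qr(raw))
  V <- sweep(V, 2, sqrt(colSums(V^2)), "/")
  structure(list(axis = axis, baseline = baseline,
                 feature_depths = feature_depths,
                 latent_components = V, latent_sds = latent_sds,
                 noise_sd = noise_sd),
            class = "apple_spectral_model")
}

#' Bruise effect on apple reflectance
#'
#' A bruise lowers reflectance in two spectral regions: browning of the
#' damaged tissue depresses the visible region (concentrated in 550-600 nm,
#' with a secondary short-wavelength component from the increasing
#' absorption of brown pigment towards the blue), and the increased water
#' content of collapsed cells depresses the near infrared over 750-1000 nm.
#' Both depressions scale linearly with the impact energy, so the three
#' impact groups (1.11, 0.66 and 0.33 J for high/medium/low) are ordered
#' but overlap at the pixel level.
#'
#' @param severity_level One of `"sound"`, `"low"`, `"medium"`, `"high"`.
#' @param impact_energy_J Impact energy in joules. Defaults to the nominal
#'   energy of the severity level (0, 0.33, 0.66, 1.11 J).
#' @param browning_coef,nir_coef Linear coefficients mapping developed
#'   impact energy (J) to the peak fractional reflectance depression of the
#'   visible (browning) and NIR (water) parts of the bruise signature.
#' @param onset_J Development offset (J): after the 24 h storage period even
#'   the lightest impact has developed visible browning, so the depression
#'   scales with `E + onset_J` rather than through the origin.
#' @param footprint_axes Semi-axes of the elliptical bruise footprint in
#'   pixels at 1 J; the footprint scales with `(0.75 + 0.3 E)`.
#' @return An object of class `bruise_effect` with the depression factors
#'   `browning_depression` and `nir_depression` (multiplicative, in (0, 1])
#'   evaluated at the signature peaks.
#' @export
bruise_effect <- function(severity_level = c("sound", "low", "medium", "high"),
                          impact_energy_J = NULL,
                          browning_coef = 0.20, nir_coef = 0.22,
                          onset_J = 0.20, footprint_axes = c(8, 6)) {
  severity_level <- match.arg(severity_level)
  nominal <- c(sound = 0, low = 0.33, medium = 0.66, high = 1.11)
  if (is.null(impact_energy_J)) impact_energy_J <- nominal[[severity_level]]
  stopifnot(impact_energy_J >= 0)
  developed <- if (impact_energy_J > 0) impact_energy_J + onset_J else 0
  b <- browning_coef * developed
  n <- nir_coef * developed
  if (b >= 1 || n >= 1)
    stop("depression factors must stay in (0, 1]; lower the coefficients")
  structure(list(severity_level = severity_level,
                 impact_energy_J = impact_energy_J,
                 browning_amount = b, nir_amount = n,
                 browning_depression = 1 - b, nir_depression = 1 - n,
                 footprint_axes = footprint_axes *
                   (0.75 + 0.3 * impact_energy_J)),
            class = "bruise_effect")
}

# Spectral signature of a bruise: fractional depression profile, unit peak
# in the browning band. Components sit at the discriminative wavebands the
# workflow is designed to recover (brown pigment at 553.9 nm and towards
# 424.5 nm; water/sugar changes at 774.2 and 812.5 nm plus a broad NIR
# term), so that 550-600 nm and 750-1000 nm are depressed at every band.
bruise_signature <- function(axis, effect) {
  wl <- axis$wavelengths_nm
  effect$browning_amount * browning_profile(wl) +
    effect$nir_amount * water_profile(wl)
}

# Brown-pigment absorption profile: peaked in the green (553.9 nm), with a
# shoulder towards 600 nm and a secondary blue component at 424.5 nm. The
# same profile carries pixel-to-pixel peel-colour variability, so bruised
# and sound pixels overlap along it.
browning_profile <- function(wl) {
  gauss_bump(wl, 553.9, 14) + 0.70 * gauss_bump(wl, 424.5, 18) +
    0.35 * gauss_bump(wl, 600, 45)
}

# Water-related NIR absorption profile: narrow features at 774.2/812.5 nm
# on a broad rise towards 1000 nm. Shared between the water latent
# component and the bruise NIR depression.
water_profile <- function(wl) {
  gauss_bump(wl, 774.2, 12) + 0.85 * gauss_bump(wl, 812.5, 14) +
    0.9 / (1 + exp(-(wl - 800) / 45)) + 0.25 * gauss_bump(wl, 960, 55)
}

#' Synthesize one hyperspectral apple scene
#'
#' Renders a pushbroom acquisition of a single apple: an apple disk with
#' spherical shading, per-pixel latent spectral variability, an optional
#' elliptical bruise, and the camera's radiometric response (dark offset,
#' Poisson shot noise scaled by the sensor gain, Gaussian read noise, 14-bit
#' clipping). White and dark reference frames are rendered the way a
#' line-scan system acquires them: a short stack of reference lines that the
#' calibration averages and broadcasts along the scan axis.
#'
#' @param model An [apple_spectral_model()].
#' @param effect A [bruise_effect()].
#' @param cam A [camera_model()].
#' @param lines,samples Image size in pixels.
#' @param apple_radius_px Radius of the apple disk, pixels.
#' @param exposure_s Acquisition exposure (full-resolution reference
#'   acquisition), s.
#' @param n_reference_lines Number of lines in the white/dark reference
#'   stacks.
#' @param seed Integer seed; identical seeds give identical scenes.
#' @return An object of class `apple_scene`: list with `raw`, `dark`,
#'   `white` (hyper_cube objects), `truth` (apple/bruise masks plus labels)
#'   and the generating parameters.
#' @export
make_apple_scene <- function(model, effect, cam = camera_model(),
                             lines = 64, samples = 64,
                             apple_radius_px = 26, exposure_s = 0.17,
                             n_reference_lines = 8, seed = 1) {
  stopifnot(inherits(model, "apple_spectral_model"),
            inherits(effect, "bruise_effect"),
            inherits(cam, "camera_model"))
  if (2 * apple_radius_px > min(lines, samples))
    stop("apple disk does not fit in the image")
  axis <- model$axis
  wl <- axis$wavelengths_nm
  nb <- length(wl)
  set.seed(as.integer(seed))

  # geometry
  cx <- samples / 2 + 0.5
  cy <- lines / 2 + 0.5
  xg <- matrix(rep(seq_len(samples), each = lines), nrow = lines)
  yg <- matrix(rep(seq_len(lines), times = samples), nrow = lines)
  r2 <- ((xg - cx)^2 + (yg - cy)^2) / apple_radius_px^2
  apple_mask <- r2 <= 1

  # spherical Lambertian-like shading on the disk, 1 at center
  shade <- matrix(0, lines, samples)
  shade[apple_mask] <- pmax(1 - r2[apple_mask] / 1.6^2, 0)^0.3

  # bruise footprint: ellipse centered mid-radius at a random angle, with a
  # soft interior weight (full depression in the core, weaker at the rim)
  bruise_mask <- core_mask <- matrix(FALSE, lines, samples)
  bruise_w <- matrix(0, lines, samples)
  if (effect$severity_level != "sound") {
    ang <- stats::runif(1, 0, 2 * pi)
    rad <- stats::runif(1, 0.50, 0.68) * apple_radius_px
    bx <- cx + rad * cos(ang)
    by <- cy + rad * sin(ang)
    axes <- effect$footprint_axes
    e2 <- ((xg - bx) / axes[1])^2 + ((yg - by) / axes[2])^2
    bruise_mask <- e2 <= 1 & apple_mask
    core_mask <- e2 <= 0.5 & apple_mask      # full-depression interior
    bruise_w[bruise_mask] <- 0.75 + 0.25 * pmin(1, 2 * (1 - e2[bruise_mask]))
  }

  idx <- which(apple_mask)
  np <- length(idx)
  # per-pixel spectra: baseline * apple-scale + latent mixture - bruise
  apple_scale <- 1 + clamp_sd(stats::rnorm(1, 0, 0.03), 0.03)
  W <- clamp_sd(matrix(stats::rnorm(np * 4), np, 4), 1) %*%
    diag(model$latent_sds)
  spectra <- matrix(rep(model$baseline * apple_scale, each = np), np, nb) +
    W %*% t(model$latent_components)
  sig <- bruise_signature(axis, effect)
  in_bruise <- bruise_mask[idx]
  if (any(in_bruise))
    spectra[in_bruise, ] <- spectra[in_bruise, ] *
      (1 - bruise_w[idx][in_bruise] %o% sig)
  if (model$noise_sd > 0)
    spectra <- spectra + matrix(stats::rnorm(np * nb, 0, model$noise_sd),
                                np, nb)
  if (any(spectra <= 0) || any(spectra >= 1))
    stop("scene reflectance left (0, 1); model/effect misconfigured")

  # radiometric response
  thr <- throughput(cam, wl)
  rate <- exposure_s * thr                       # DN per unit reflectance
  expected <- matrix(0, lines * samples, nb)
  expected[idx, ] <- sweep(spectra, 1, shade[idx], "*") %*% diag(rate)
  # faint diffuse background (matte black plate, ~2% reflectance)
  bg <- setdiff(seq_len(lines * samples), idx)
  expected[bg, ] <- matrix(rep(0.02 * rate, each = length(bg)),
                           length(bg), nb)
  raw <- array(apply_sensor_noise(cam, expected), c(lines, samples, nb))

  white_exp <- matrix(rep(cam$white_reflectance * rate,
                          each = n_reference_lines * samples),
                      n_reference_lines * samples, nb)
  white <- array(apply_sensor_noise(cam, white_exp),
                 c(n_reference_lines, samples, nb))
  dark <- array(apply_sensor_noise(cam, white_exp * 0),
                c(n_reference_lines, samples, nb))

  truth <- structure(list(apple_mask = apple_mask, bruise_mask = bruise_mask,
                          bruise_core_mask = core_mask,
                          severity_level = effect$severity_level,
                          impact_energy_J = effect$impact_energy_J),
                     class = "scene_truth")
  structure(list(raw = hyper_cube(raw, axis, "raw"),
                 dark = hyper_cube(dark, axis, "dark"),
                 white = hyper_cube(white, axis, "white"),
                 truth = truth, model = model, effect = effect,
                 cam = cam, exposure_s = exposure_s, seed = seed),
            class = "apple_scene")
}

# truncate normal draws at +/- 2.5 sd: keeps reflectance inside (0, 1)
# for all admissible latent weights without changing means
clamp_sd <- function(x, sd) pmin(pmax(x, -2.5 * sd), 2.5 * sd)

# Poisson shot noise (scaled by the sensor gain) + Gaussian read noise +
# dark offset, quantized and clipped to the A/D range.
apply_sensor_noise <- function(cam, expected_dn) {
  x <- expected_dn
  if (cam$shot_noise) {
    e <- pmax(x, 0) * cam$electrons_per_dn
    x <- stats::rpois(length(e), as.vector(e)) / cam$electrons_per_dn
  }
  x <- x + cam$dark_level_dn
  if (cam$read_noise_dn > 0)
    x <- x + stats::rnorm(length(x), 0, cam$read_noise_dn)
  matrix(pmin(pmax(round(x), 0), cam$full_scale_dn), nrow = nrow(expected_dn))
}

#' @export
print.apple_scene <- function(x, ...) {
  d <- dim(x$raw$data)
  cat(sprintf("<apple_scene> %dx%d px, %d bands, severity %s (%.2f J)\n",
              d[1], d[2], d[3], x$truth$severity_level,
              x$truth$impact_energy_J))
  invisible(x)
}

#' Generate a cohort of synthetic apple scenes
#'
#' One scene per apple, `n_per_group` apples for each severity group, with
#' independent per-apple randomness that is reproducible under the seed.
#'
#' @param n_per_group Apples per severity group (>= 1).
#' @param groups Character vector of severity levels.
#' @param seed Integer master seed.
#' @param model An [apple_spectral_model()]; built on the default axis if
#'   omitted.
#' @param cam A [camera_model()].
#' @param ... Further arguments passed to [make_apple_scene()].
#' @return List of `apple_scene` objects of length
#'   `n_per_group * length(groups)`.
#' @export
generate_cohort <- function(n_per_group = 6,
                            groups = c("sound", "low", "medium", "high"),
                            seed = 1, model = NULL, cam = camera_model(),
                            ...) {
  stopifnot(n_per_group >= 1)
  if (length(groups) == 0) stop("groups must be non-empty")
  if (is.null(model)) model <- apple_spectral_model(spectral_axis())
  set.seed(as.integer(seed))
  n <- n_per_group * length(groups)
  scene_seeds <- sample.int(2^20, n)
  specs <- expand.grid(rep = seq_len(n_per_group), group = groups,
                       stringsAsFactors = FALSE)
  lapply(seq_len(n), function(i) {
    make_apple_scene(model, bruise_effect(specs$group[i]), cam = cam,
                     seed = scene_seeds[i], ...)
  })
}
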