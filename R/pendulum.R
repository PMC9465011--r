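#' Pendulum impact-energy model for controlled apple bruising
#'
#' The bruising rig is a steel ball mounted at the end of a pivoting steel
#' rod: released from an initial angle, the assembly swings down and strikes
#' the apple at its equator. The impact energy is the potential energy lost,
#' `E = m_b g h + m_r g h / 2`, where `h = L (1 - cos theta)` is the drop
#' height of the ball and the rod's center of mass falls `h / 2`.
#'
#' @param ball_mass_kg Mass of the steel ball (kg).
#' @param rod_mass_kg Mass of the steel rod (kg).
#' @param rod_length_m Rod length (m).
#' @param release_angle_deg Initial release angle from vertical, in (0, 90].
#' @param g Gravitational acceleration (m/s^2).
#' @return An object of class `pendulum_config`.
#' @examples
#' cfg <- pendulum_config(release_angle_deg = 50)
#' pendulum_energy(cfg)
#' @export
pendulum_config <- function(ball_mass_kg = 0.067, rod_mass_kg = 0.663,
                            rod_length_m = 0.68, release_angle_deg = 50,
                            g = 9.81) {
  if (any(c(ball_mass_kg, rod_mass_kg, rod_length_m, g) <= 0))
    stop("masses, rod length and g must all be positive")
  if (release_angle_deg < 0 || release_angle_deg > 90)
    stop("release angle must lie in [0, 90] degrees")
  structure(list(ball_mass_kg = ball_mass_kg, rod_mass_kg = rod_mass_kg,
                 rod_length_m = rod_length_m,
                 release_angle_deg = release_angle_deg, g = g),
            class = "pendulum_config")
}

#' Impact energy of a pendulum release
#'
#' @param cfg A [pendulum_config()].
#' @return Impact energy in joules.
#' @export
pendulum_energy <- function(cfg) {
  stopifnot(inherits(cfg, "pendulum_config"))
  h <- cfg$rod_length_m * (1 - cos(cfg$release_angle_deg * pi / 180))
  cfg$ball_mass_kg * cfg$g * h + cfg$rod_mass_kg * cfg$g * h / 2
}
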