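#' Continuous (liquid) phase of a blood suspension
#'
#' Defines the carrier fluid through which blood cells settle. For whole-blood
#' centrifugation the carrier is plasma; [blood_plasma()] returns the standard
#' values used throughout the package.
#'
#' @param density Fluid density in kg/m^3 (must be positive).
#' @param viscosity Dynamic viscosity in Pa.s (must be positive).
#' @return An object of class `"fluid_phase"`: a list with fields `density`
#'   and `viscosity`.
#' @seealso [particle_species()], [stokes_settling_velocity()]
#' @examples
#' blood_plasma()
#' fluid_phase(density = 1000, viscosity = 1e-3) # water-like
#' @export
fluid_phase <- function(density, viscosity) {
  stopifnot(is.numeric(density), length(density) == 1L,
            is.numeric(viscosity), length(viscosity) == 1L)
  if (!is.finite(density) || density <= 0)
    stop("'density' must be a positive finite number (kg/m^3)")
  if (!is.finite(viscosity) || viscosity <= 0)
    stop("'viscosity' must be a positive finite number (Pa.s)")
  structure(list(density = density, viscosity = viscosity),
            class = "fluid_phase")
}

#' @rdname fluid_phase
#' @details `blood_plasma()` uses density 1032 kg/m^3 and dynamic viscosity
#'   1.0 mPa.s, the standard literature values for human plasma.
#' @export
blood_plasma <- function() fluid_phase(density = 1032, viscosity = 1.0e-3)

#' Dispersed (particle) phase: a blood-cell species
#'
#' Blood cells are approximated as rigid spheres of uniform diameter and
#' density; this is the standard assumption in centrifugal cell-separation
#' models, with hindered-settling corrections absorbing shape effects.
#' Convenience constructors return the default red-blood-cell, white-blood-cell
#' and platelet properties.
#'
#' @param name Character label, e.g. `"RBC"`, `"WBC"`, `"PLT"`.
#' @param diameter Particle diameter in metres (must be positive).
#' @param density Particle density in kg/m^3 (must be positive).
#' @return An object of class `"particle_species"`.
#' @examples
#' rbc()       # d = 8 um, rho = 1125 kg/m^3
#' wbc()       # d = 10 um, rho = 1065 kg/m^3
#' platelet()  # d = 1 um, rho = 1050 kg/m^3
#' @export
particle_species <- function(name, diameter, density) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(diameter) || length(diameter) != 1L ||
      !is.finite(diameter) || diameter <= 0)
    stop("'diameter' must be a positive finite number (m)")
  if (!is.numeric(density) || length(density) != 1L ||
      !is.finite(density) || density <= 0)
    stop("'density' must be a positive finite number (kg/m^3)")
  structure(list(name = name, diameter = diameter, density = density),
            class = "particle_species")
}

#' @rdname particle_species
#' @export
rbc <- function() particle_species("RBC", diameter = 8e-6, density = 1125)

#' @rdname particle_species
#' @export
wbc <- function() particle_species("WBC", diameter = 10e-6, density = 1065)

#' @rdname particle_species
#' @export
platelet <- function() particle_species("PLT", diameter = 1e-6, density = 1050)

#' Hindered-settling (Richardson-Zaki) model
#'
#' Couples a reference terminal velocity with the Richardson-Zaki hindrance
#' exponent and the packing limit of the sediment. The batch flux density
#' function built from this model drives the kinematic-wave solver.
#'
#' @param u_inf Terminal settling velocity of an isolated particle under 1 g,
#'   in m/s. Usually computed with [stokes_settling_velocity()].
#' @param m_exponent Richardson-Zaki hindrance index (dimensionless, > 0).
#'   The value 5 is standard for rigid spheres at particle Reynolds numbers
#'   below about 0.2.
#' @param alpha_max Maximum packing volume fraction of the sediment, in (0, 1].
#'   0.8 is used for blood cells, which deform when packed.
#' @return An object of class `"settling_model"`.
#' @export
settling_model <- function(u_inf, m_exponent = 5, alpha_max = 0.8) {
  stopifnot(is.numeric(u_inf), length(u_inf) == 1L, is.finite(u_inf))
  if (!is.numeric(m_exponent) || length(m_exponent) != 1L || m_exponent <= 0)
    stop("'m_exponent' must be positive")
  if (!is.numeric(alpha_max) || length(alpha_max) != 1L ||
      alpha_max <= 0 || alpha_max > 1)
    stop("'alpha_max' must lie in (0, 1]")
  structure(list(u_inf = u_inf, m_exponent = m_exponent,
                 alpha_max = alpha_max),
            class = "settling_model")
}

#' Centrifugation protocol
#'
#' A single spin: centrifugal acceleration expressed in multiples of gravity
#' (a_c / g = omega^2 R_o / g) and spin duration.
#'
#' @param acceleration_g Centrifugal acceleration in g-multiples (> 0).
#' @param spin_time Spin duration in seconds (> 0).
#' @param gravity Gravitational acceleration in m/s^2 (default 9.81).
#' @return An object of class `"centrifuge_protocol"`.
#' @examples
#' centrifuge_protocol(acceleration_g = 900, spin_time = 5 * 60)
#' @export
centrifuge_protocol <- function(acceleration_g, spin_time, gravity = 9.81) {
  if (!is.numeric(acceleration_g) || length(acceleration_g) != 1L ||
      !is.finite(acceleration_g) || acceleration_g <= 0)
    stop("'acceleration_g' must be positive")
  if (!is.numeric(spin_time) || length(spin_time) != 1L ||
      !is.finite(spin_time) || spin_time <= 0)
    stop("'spin_time' must be positive (seconds)")
  if (!is.numeric(gravity) || length(gravity) != 1L || gravity <= 0)
    stop("'gravity' must be positive (m/s^2)")
  structure(list(acceleration_g = acceleration_g, spin_time = spin_time,
                 gravity = gravity),
            class = "centrifuge_protocol")
}

#' Stokes terminal settling velocity under gravity
#'
#' Terminal velocity of an isolated rigid sphere in a quiescent fluid,
#' u_inf = (rho_s - rho_l) d_s^2 g / (18 mu_l). Negative when the particle is
#' lighter than the fluid (it floats).
#'
#' @param species A [particle_species()].
#' @param fluid A [fluid_phase()].
#' @param gravity Acceleration in m/s^2 (default 9.81).
#' @return Settling velocity in m/s.
#' @examples
#' stokes_settling_velocity(rbc(), blood_plasma()) # ~3.24e-6 m/s
#' @export
stokes_settling_velocity <- function(species, fluid, gravity = 9.81) {
  stopifnot(inherits(species, "particle_species"),
            inherits(fluid, "fluid_phase"))
  if (fluid$viscosity <= 0) stop("fluid viscosity must be positive")
  if (species$diameter <= 0) stop("particle diameter must be positive")
  (species$density - fluid$density) * species$diameter^2 * gravity /
    (18 * fluid$viscosity)
}

#' Settling velocity under a centrifugal field
#'
#' U_o = u_inf * (a_c / g): the Stokes velocity scaled by the g-multiple of the
#' applied centrifugal acceleration (evaluated at the tube bottom radius).
#'
#' @inheritParams stokes_settling_velocity
#' @param protocol A [centrifuge_protocol()].
#' @return Velocity in m/s.
#' @export
centrifugal_settling_velocity <- function(species, fluid, protocol) {
  stopifnot(inherits(protocol, "centrifuge_protocol"))
  stokes_settling_velocity(species, fluid, protocol$gravity) *
    protocol$acceleration_g
}

#' Particle Reynolds number under centrifugation
#'
#' Re_p = rho_l |U_o| d_s / mu_l with U_o the centrifugal settling velocity.
#' The Richardson-Zaki exponent m = 5 is valid for Re_p < 0.2; a warning (not
#' an error) is emitted above that bound. For blood cells over clinical
#' centrifugation ranges Re_p is of order 1e-2 to 1e-1.
#'
#' @inheritParams centrifugal_settling_velocity
#' @return Dimensionless Reynolds number.
#' @export
particle_reynolds <- function(species, fluid, protocol) {
  u <- centrifugal_settling_velocity(species, fluid, protocol)
  re <- fluid$density * abs(u) * species$diameter / fluid$viscosity
  if (re >= 0.2)
    warning(sprintf(paste0(
      "particle Reynolds number %.3g exceeds 0.2; the m = 5 hindered-",
      "settling exponent may not be valid"), re))
  re
}

#' Kynch batch flux density function
#'
#' Richardson-Zaki hindered-settling flux
#' `f_bk(alpha) = -u_inf * alpha * (1 - alpha)^m` for `0 < alpha < alpha_max`
#' and exactly 0 otherwise. The sign convention is that of the
#' gravitational-settling literature (flux negative along an upward axis); the
#' packed bed (`alpha >= alpha_max`) is absorbing because its flux vanishes.
#'
#' @param alpha Particle volume fraction(s) in \[0, 1\] (vectorised).
#' @param model A [settling_model()].
#' @return Flux density in m/s, same length as `alpha`.
#' @examples
#' mod <- settling_model(u_inf = 1, m_exponent = 5, alpha_max = 0.8)
#' batch_flux(c(0, 0.4, 0.8), mod)
#' @export
batch_flux <- function(alpha, model) {
  stopifnot(inherits(model, "settling_model"), is.numeric(alpha))
  if (any(!is.finite(alpha)) || any(alpha < 0) || any(alpha > 1))
    stop("'alpha' must lie in [0, 1]")
  out <- -model$u_inf * alpha * (1 - alpha)^model$m_exponent
  out[alpha <= 0 | alpha >= model$alpha_max] <- 0
  out
}

#' @export
print.fluid_phase <- function(x, ...) {
  cat(sprintf("Fluid phase: density %g kg/m^3, viscosity %g Pa.s\n",
              x$density, x$viscosity))
  invisible(x)
}

#' @export
print.particle_species <- function(x, ...) {
  cat(sprintf("Particle species '%s': diameter %g um, density %g kg/m^3\n",
              x$name, x$diameter * 1e6, x$density))
  invisible(x)
}

#' @export
print.settling_model <- function(x, ...) {
  cat(sprintf(
    "Hindered-settling model: u_inf %.4g m/s, m = %g, alpha_max = %g\n",
    x$u_inf, x$m_exponent, x$alpha_max))
  invisible(x)
}

#' @export
print.centrifuge_protocol <- function(x, ...) {
  cat(sprintf("Centrifugation: %g g for %g s (%.3g min)\n",
              x$acceleration_g, x$spin_time, x$spin_time / 60))
  invisible(x)
}
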