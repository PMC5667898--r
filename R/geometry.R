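#' Centrifuge tube geometry
#'
#' Describes the tube that holds the whole blood: distance from the rotation
#' centre to the tube bottom (`rotor_radius`, R_o), straight-section
#' cross-sectional area `A`, nominal capacity, and the bottom shape. The
#' conical bottom is modelled as a frustum whose diameter tapers linearly from
#' the full tube diameter `D` at the cylinder-cone junction (a height
#' `cone_height` above the bottom) down to `cone_bottom_diameter` at the
#' bottom.
#'
#' All positions handled by the geometry functions are heights above the tube
#' bottom (the radial coordinate is `rotor_radius - height`).
#'
#' @param rotor_radius Distance from rotation centre to tube bottom, m.
#' @param area Straight-section cross-sectional area A, m^2.
#' @param capacity Tube capacity V_t, m^3.
#' @param bottom `"flat"` or `"conical"`.
#' @param cone_height Height of the conical section above the bottom, m
#'   (default 0.2 * rotor_radius; conical tubes only).
#' @param cone_bottom_diameter Frustum diameter at the tube bottom, m
#'   (default 0.25 * D; conical tubes only).
#' @return An object of class `"tube_geometry"`.
#' @examples
#' tube_geometry()                      # default flat 15 mL tube
#' tube_geometry(bottom = "conical")    # Falcon-like conical bottom
#' @export
tube_geometry <- function(rotor_radius = 0.150, area = 120e-6,
                          capacity = 15e-6, bottom = c("flat", "conical"),
                          cone_height = 0.2 * rotor_radius,
                          cone_bottom_diameter = NULL) {
  bottom <- match.arg(bottom)
  if (rotor_radius <= 0) stop("'rotor_radius' must be positive")
  if (area <= 0) stop("'area' must be positive")
  if (capacity <= 0) stop("'capacity' must be positive")
  diameter <- sqrt(4 * area / pi)
  if (bottom == "conical") {
    if (is.null(cone_bottom_diameter)) cone_bottom_diameter <- 0.25 * diameter
    if (cone_height <= 0 || cone_height >= rotor_radius)
      stop("'cone_height' must lie in (0, rotor_radius)")
    if (cone_bottom_diameter <= 0 || cone_bottom_diameter > diameter)
      stop("'cone_bottom_diameter' must lie in (0, tube diameter]")
  } else {
    cone_height <- 0
    cone_bottom_diameter <- diameter
  }
  structure(list(rotor_radius = rotor_radius, area = area,
                 tube_diameter = diameter, capacity = capacity,
                 bottom = bottom, cone_height = cone_height,
                 cone_bottom_diameter = cone_bottom_diameter),
            class = "tube_geometry")
}

#' @export
print.tube_geometry <- function(x, ...) {
  cat(sprintf("Tube: %s bottom, R_o = %g mm, A = %g mm^2, V_t = %g mL\n",
              x$bottom, x$rotor_radius * 1e3, x$area * 1e6, x$capacity * 1e6))
  if (x$bottom == "conical")
    cat(sprintf("  cone: height %g mm, bottom diameter %g mm\n",
                x$cone_height * 1e3, x$cone_bottom_diameter * 1e3))
  invisible(x)
}

tube_length <- function(geometry) {
  # nominal usable length implied by the capacity
  height_from_volume(geometry, geometry$capacity)
}

#' Cross-sectional area at a given height above the tube bottom
#'
#' Flat tubes have constant area. Conical tubes taper linearly in diameter
#' within the bottom cone and are cylindrical above it; the profile is
#' continuous at the junction.
#'
#' @param geometry A [tube_geometry()].
#' @param height Height(s) above the tube bottom, m (vectorised, must be
#'   non-negative and within the tube).
#' @return Area(s) in m^2.
#' @export
area_profile <- function(geometry, height) {
  stopifnot(inherits(geometry, "tube_geometry"), is.numeric(height))
  if (any(height < -1e-12) || any(height > geometry$rotor_radius + 1e-12))
    stop("'height' outside the tube")
  if (geometry$bottom == "flat") return(rep(geometry$area, length(height)))
  d <- ifelse(height < geometry$cone_height,
              geometry$cone_bottom_diameter +
                (geometry$tube_diameter - geometry$cone_bottom_diameter) *
                height / geometry$cone_height,
              geometry$tube_diameter)
  pi * d^2 / 4
}

# cumulative volume from the tube bottom up to height h (analytic, piecewise)
cumulative_volume <- function(geometry, height) {
  stopifnot(is.numeric(height))
  if (geometry$bottom == "flat") return(geometry$area * height)
  hc <- geometry$cone_height
  db <- geometry$cone_bottom_diameter
  D  <- geometry$tube_diameter
  # within the cone: d(h) = db + (D - db) h / hc, V = (pi/4) int d(h)^2 dh
  vol_cone <- function(h) {
    s <- (D - db) / hc
    (pi / 4) * (db^2 * h + db * s * h^2 + s^2 * h^3 / 3)
  }
  ifelse(height <= hc,
         vol_cone(pmax(height, 0)),
         vol_cone(hc) + geometry$area * (height - hc))
}

#' Volume between two heights above the tube bottom
#'
#' Exact analytic integral of the cross-sectional area profile.
#'
#' @param geometry A [tube_geometry()].
#' @param h_lo,h_hi Heights above the tube bottom, m, with `h_lo <= h_hi`.
#' @return Volume in m^3.
#' @export
volume_between <- function(geometry, h_lo, h_hi) {
  stopifnot(inherits(geometry, "tube_geometry"))
  if (any(h_hi < h_lo)) stop("'h_hi' must be >= 'h_lo'")
  if (any(h_lo < -1e-12)) stop("heights must be non-negative")
  cumulative_volume(geometry, h_hi) - cumulative_volume(geometry, h_lo)
}

#' Fill height for a given volume
#'
#' Inverts the cumulative volume profile: returns the height L above the tube
#' bottom such that the tube holds exactly `volume` below it. Closed form for
#' flat tubes; for conical tubes the monotone cubic is solved numerically to
#' a relative tolerance of 1e-12.
#'
#' @param geometry A [tube_geometry()].
#' @param volume Volume in m^3, `0 < volume <= capacity`.
#' @return Fill height L in m.
#' @examples
#' height_from_volume(tube_geometry(), 9e-6) # 0.075 m for the default tube
#' @export
height_from_volume <- function(geometry, volume) {
  stopifnot(inherits(geometry, "tube_geometry"), is.numeric(volume),
            length(volume) == 1L)
  if (volume <= 0) stop("'volume' must be positive")
  if (volume > geometry$capacity * (1 + 1e-9))
    stop(sprintf("volume %.3g mL exceeds tube capacity %.3g mL",
                 volume * 1e6, geometry$capacity * 1e6))
  if (geometry$bottom == "flat") return(volume / geometry$area)
  vc <- cumulative_volume(geometry, geometry$cone_height)
  if (volume >= vc)
    return(geometry$cone_height + (volume - vc) / geometry$area)
  f <- function(h) cumulative_volume(geometry, h) - volume
  stats::uniroot(f, c(0, geometry$cone_height), tol = 1e-15)$root
}

#' Whole-blood mixture column in a tube
#'
#' Converts a whole-blood volume into the column it occupies: fill height L,
#' and the radius of the free surface (`rotor_radius - L`).
#'
#' @param geometry A [tube_geometry()].
#' @param volume Whole-blood volume V_WB in m^3 (must not exceed capacity).
#' @return An object of class `"mixture_column"` with fields `fill_height`,
#'   `volume`, `top_radius`.
#' @export
mixture_column <- function(geometry, volume) {
  L <- height_from_volume(geometry, volume)
  structure(list(fill_height = L, volume = volume,
                 top_radius = geometry$rotor_radius - L),
            class = "mixture_column")
}

#' @export
print.mixture_column <- function(x, ...) {
  cat(sprintf("Mixture column: V_WB = %g mL, fill height L = %.4g mm\n",
              x$volume * 1e6, x$fill_height * 1e3))
  invisible(x)
}
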