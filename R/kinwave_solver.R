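#' Numerical grid for the sedimentation solver
#'
#' The solver discretises the mixture column (height 0 at the tube bottom up
#' to the fill height L) into `n_cells` uniform finite-volume cells. The
#' dimensionless cell width is `dr_star = (L / R_o) / n_cells` unless fixed
#' explicitly. The explicit time step is set by the CFL condition (see
#' [stable_timestep()]).
#'
#' @param n_cells Number of cells (>= 10, default 200).
#' @param cfl CFL safety factor in (0, 1], default 0.5.
#' @param dr_star Optional fixed dimensionless cell width; when `NULL` it is
#'   derived from the column height at solve time.
#' @return An object of class `"solver_grid"`.
#' @export
solver_grid <- function(n_cells = 200, cfl = 0.5, dr_star = NULL) {
  if (!is.numeric(n_cells) || n_cells < 10) stop("'n_cells' must be >= 10")
  if (!is.numeric(cfl) || cfl <= 0 || cfl > 1) stop("'cfl' must be in (0, 1]")
  if (!is.null(dr_star) && dr_star <= 0) stop("'dr_star' must be positive")
  structure(list(n_cells = as.integer(n_cells), cfl = cfl,
                 dr_star = dr_star),
            class = "solver_grid")
}

# dimensionless batch flux formula value (no clamping):
# f*(alpha) = -alpha (1 - alpha)^m
ftil <- function(alpha, m) -alpha * (1 - alpha)^m

# location of the interior extremum of alpha (1 - alpha)^m, capped at the
# packing limit when alpha_max < 1 / (m + 1)
flux_extremum <- function(m, alpha_max) min(1 / (m + 1), alpha_max)

# Engquist-Osher splitting of the clamped flux. Vectorised over alpha.
# fplus = integral of max(f', 0); fminus = integral of min(f', 0).
# The upward jump of the clamped flux at alpha_max contributes to fplus only.
eo_parts <- function(alpha, m, alpha_max) {
  ac <- flux_extremum(m, alpha_max)
  fac <- ftil(ac, m)
  b <- pmax(alpha, ac)
  vp <- ftil(b, m)
  vp[alpha >= alpha_max] <- 0
  fp <- vp - fac
  fm <- ftil(pmin(alpha, ac), m)
  list(fp = fp, fm = fm)
}

#' Engquist-Osher numerical flux at a cell face
#'
#' Monotone interface flux for the centrifugal sedimentation law with flux
#' `g(alpha) = r*_face * f_bk(alpha)`:
#' `F = g(0) + int_0^alpha_left max(g', 0) + int_0^alpha_right min(g', 0)`.
#' Because the hindered-settling flux has a single interior extremum (at
#' `alpha = 1/(m+1)`) the splitting is evaluated in closed form. The EO flux
#' coincides with the Godunov flux whenever the two states do not straddle
#' the extremum in the shock configuration; for transonic shocks
#' (`alpha_left` above the extremum, `alpha_right` below it) EO is the more
#' diffusive of the two monotone fluxes, exceeding the Godunov value by at
#' most `|f_bk(1/(m+1))|`. "Left" refers to the cell nearer the tube bottom
#' (the upwind side for the compacting bed).
#'
#' @param alpha_left,alpha_right Volume fractions in \[0, 1\] on either side
#'   of the face (left = below). Vectorised.
#' @param r_star_face Dimensionless radius (radial position over `R_o`) of
#'   the face.
#' @param model A [settling_model()]; `u_inf` scales the returned flux.
#' @return Numerical flux density in m/s (negative: settling toward the
#'   bottom on the height-above-bottom axis).
#' @export
eo_interface_flux <- function(alpha_left, alpha_right, r_star_face, model) {
  stopifnot(inherits(model, "settling_model"))
  if (any(alpha_left < 0 | alpha_left > 1) ||
      any(alpha_right < 0 | alpha_right > 1))
    stop("volume fractions must lie in [0, 1]")
  m <- model$m_exponent
  am <- model$alpha_max
  model$u_inf * r_star_face *
    (eo_parts(alpha_left, m, am)$fp + eo_parts(alpha_right, m, am)$fm)
}

#' CFL-stable dimensionless time step
#'
#' `dt* = cfl * dr* / max |d(r* f*_bk)/dalpha|`, where the maximum is taken
#' over the admissible concentration range and `r* <= 1` (the tube bottom).
#' The wave-speed bound is found by a brute-force scan of the flux derivative.
#' With the default parameters (m = 5, 200 cells over half the rotor radius)
#' the step is of order 1e-3.
#'
#' @param grid A [solver_grid()] with `dr_star` set.
#' @param model A [settling_model()].
#' @param t_star_end Returned when the wave speed is degenerate (zero flux),
#'   so that a single step covers the whole horizon. Default `Inf`.
#' @return Dimensionless time step.
#' @export
stable_timestep <- function(grid, model, t_star_end = Inf) {
  stopifnot(inherits(grid, "solver_grid"), inherits(model, "settling_model"))
  if (is.null(grid$dr_star))
    stop("grid has no 'dr_star'; set it or supply a column at solve time")
  m <- model$m_exponent
  am <- model$alpha_max
  a <- seq(0, am, length.out = 4001)
  # analytic derivative of alpha (1 - alpha)^m
  speed <- max(abs((1 - a)^(m - 1) * (1 - (m + 1) * a)))
  if (speed <= 0) return(t_star_end)
  grid$cfl * grid$dr_star / speed
}

# Dimensionless finite-volume march. alpha0: per-cell initial fractions,
# cell 1 at the tube bottom. Returns alpha at the last completed step before
# each requested t* (no temporal interpolation).
kinwave_march <- function(alpha0, dx, r_star_faces_int, m, alpha_max, cfl,
                          t_star_out, area_centers = NULL,
                          area_faces_int = NULL) {
  n <- length(alpha0)
  a <- seq(0, alpha_max, length.out = 4001)
  speed <- max(abs((1 - a)^(m - 1) * (1 - (m + 1) * a)))
  if (speed <= 0) {
    out <- matrix(rep(alpha0, length(t_star_out)), nrow = length(t_star_out),
                  byrow = TRUE)
    return(list(alpha = out, t_star = t_star_out))
  }
  dt <- cfl * dx / speed
  ord <- order(t_star_out)
  ks <- floor(t_star_out[ord] / dt + 1e-9)
  out <- matrix(NA_real_, nrow = length(t_star_out), ncol = n)
  tks <- numeric(length(t_star_out))
  conical <- !is.null(area_centers)
  if (conical) {
    wdown <- c(0, area_faces_int) / area_centers
    wup <- c(area_faces_int, 0) / area_centers
  }
  al <- alpha0
  ac <- flux_extremum(m, alpha_max)
  fac <- ftil(ac, m)
  step <- 0L
  for (j in seq_along(ks)) {
    while (step < ks[j]) {
      lo <- al[-n]                       # below each interior face
      hi <- al[-1L]                      # above each interior face
      b <- pmax(lo, ac)
      vp <- -b * (1 - b)^m
      vp[lo >= alpha_max] <- 0
      bm <- pmin(hi, ac)
      fint <- r_star_faces_int * (vp - fac - bm * (1 - bm)^m)
      if (conical) {
        al <- al - (dt / dx) * (wup * c(fint, 0) - wdown * c(0, fint))
      } else {
        al <- al - (dt / dx) * (c(fint, 0) - c(0, fint))
      }
      # Packing repair: the explicit step can push a compacting cell past
      # alpha_max by up to cfl * |f(alpha_max)| per step, because the batch
      # flux only shuts off once the limit is crossed. Excess solids are
      # returned conservatively to the cell above, enforcing the packing
      # bound without losing mass.
      guard <- 0L
      while (any(al > alpha_max) && guard < 16L) {
        ex <- pmax(al - alpha_max, 0)
        ex[n] <- 0                      # nothing above the top cell
        al <- al - ex
        if (conical) {
          al <- al + c(0, ex[-n] * area_centers[-n]) / area_centers
        } else {
          al <- al + c(0, ex[-n])
        }
        guard <- guard + 1L
      }
      step <- step + 1L
    }
    if (any(!is.finite(al)))
      stop(sprintf("numerical failure (non-finite concentration) at step %d",
                   step))
    out[ord[j], ] <- al
    tks[ord[j]] <- step * dt
  }
  list(alpha = out, t_star = tks, dt_star = dt)
}

#' Solve the centrifugal kinematic-wave sedimentation equation
#'
#' Integrates the dimensionless quasi-linear conservation law
#' `dalpha/dt* + d(r* f*_bk(alpha))/dr* = 0` over the mixture column with a
#' first-order explicit finite-volume scheme and the Engquist-Osher monotone
#' flux, with zero-flux boundaries at the free surface and the tube bottom.
#' For conical tubes the update is area-weighted so that total solids are
#' conserved. Dimensionless time is `t* = t * omega^2 * u_inf / g`; the radial
#' flux factor `r*` is evaluated at cell faces.
#'
#' @param alpha0 Initial particle volume fraction: a scalar (uniform column)
#'   or a vector with one value per cell, values in \[0, alpha_max\].
#' @param species A [particle_species()] (default [rbc()]).
#' @param fluid A [fluid_phase()] (default [blood_plasma()]).
#' @param geometry A [tube_geometry()].
#' @param volume Whole-blood volume V_WB in m^3.
#' @param protocol A [centrifuge_protocol()].
#' @param grid A [solver_grid()].
#' @param model Optional [settling_model()]; by default built from the Stokes
#'   velocity of `species` in `fluid` with m = 5, alpha_max = 0.8.
#' @param output_times Dimensional times (s) at which to record the field,
#'   each `<= protocol$spin_time`. The field at the last completed step before
#'   each requested time is stored. Default: the end of the spin.
#' @return An object of class `"concentration_field"`: list with `alpha`
#'   (matrix, one row per output time), `heights` (cell centres, m above the
#'   bottom), `r_centers`, `times` (actual sampled times, s), `t_star`,
#'   and the inputs.
#' @examples
#' f <- solve_sedimentation(alpha0 = 0.45, volume = 9e-6,
#'                          protocol = centrifuge_protocol(300, 600),
#'                          grid = solver_grid(n_cells = 50))
#' f
#' @export
solve_sedimentation <- function(alpha0, species = rbc(),
                                fluid = blood_plasma(),
                                geometry = tube_geometry(), volume,
                                protocol, grid = solver_grid(),
                                model = NULL, output_times = NULL) {
  stopifnot(inherits(geometry, "tube_geometry"),
            inherits(protocol, "centrifuge_protocol"),
            inherits(grid, "solver_grid"))
  if (is.null(model))
    model <- settling_model(
      stokes_settling_velocity(species, fluid, protocol$gravity))
  if (model$u_inf <= 0)
    stop("solver requires a positive settling velocity (denser-than-fluid ",
         "species)")
  column <- mixture_column(geometry, volume)
  n <- grid$n_cells
  lambda <- column$fill_height / geometry$rotor_radius
  dx <- if (is.null(grid$dr_star)) lambda / n else grid$dr_star
  if (dx * n > lambda * (1 + 1e-9))
    stop("grid spans more than the mixture column; reduce 'dr_star'")
  x_faces <- seq(0, n) * dx
  x_centers <- (x_faces[-1] + x_faces[-(n + 1)]) / 2
  r_faces_int <- 1 - x_faces[2:n]

  if (length(alpha0) == 1L) alpha0 <- rep(alpha0, n)
  if (length(alpha0) != n) stop("'alpha0' must be scalar or length n_cells")
  if (any(alpha0 < 0 | alpha0 > model$alpha_max + 1e-12))
    stop("'alpha0' must lie in [0, alpha_max]")

  if (is.null(output_times)) output_times <- protocol$spin_time
  if (any(output_times < 0) ||
      any(output_times > protocol$spin_time * (1 + 1e-9)))
    stop("'output_times' must lie within [0, spin_time]")

  tscale <- geometry$rotor_radius / (protocol$acceleration_g * model$u_inf)
  t_star_out <- output_times / tscale

  heights <- x_centers * geometry$rotor_radius
  conical <- geometry$bottom == "conical"
  area_centers <- if (conical) area_profile(geometry, heights) else NULL
  area_faces_int <- if (conical)
    area_profile(geometry, x_faces[2:n] * geometry$rotor_radius) else NULL

  res <- kinwave_march(alpha0, dx, r_faces_int, model$m_exponent,
                       model$alpha_max, grid$cfl, t_star_out,
                       area_centers, area_faces_int)

  structure(list(alpha = res$alpha,
                 heights = heights,
                 r_centers = geometry$rotor_radius - heights,
                 cell_width = dx * geometry$rotor_radius,
                 times = res$t_star * tscale,
                 requested_times = output_times,
                 t_star = res$t_star,
                 dt_star = res$dt_star,
                 alpha0 = alpha0,
                 species = species, model = model, geometry = geometry,
                 column = column, protocol = protocol, grid = grid),
            class = "concentration_field")
}

#' @export
print.concentration_field <- function(x, ...) {
  cat(sprintf(
    "Concentration field (%s): %d cells over L = %.4g mm, %d time(s)\n",
    x$species$name, ncol(x$alpha), x$column$fill_height * 1e3,
    nrow(x$alpha)))
  cat(sprintf("  protocol: %g g for %g s; alpha range [%.4g, %.4g]\n",
              x$protocol$acceleration_g, x$protocol$spin_time,
              min(x$alpha), max(x$alpha)))
  invisible(x)
}

#' Plot a concentration field
#'
#' One output time gives a concentration profile against height; several give
#' an iso-concentration contour plot over (time, height), the standard way of
#' displaying kinematic-wave sedimentation solutions.
#'
#' @param x A `"concentration_field"`.
#' @param levels Contour levels (volume fractions) for the multi-time plot.
#' @param ... Passed to the underlying plotting function.
#' @return Invisibly, `x`.
#' @export
plot.concentration_field <- function(x, levels = pretty(range(x$alpha), 8),
                                     ...) {
  if (nrow(x$alpha) == 1L) {
    graphics::plot(x$heights * 1e3, x$alpha[1, ], type = "l",
                   xlab = "height above tube bottom [mm]",
                   ylab = "volume fraction", ...)
  } else {
    graphics::contour(x$times, x$heights * 1e3, x$alpha,
                      levels = levels, xlab = "time [s]",
                      ylab = "height above tube bottom [mm]", ...)
  }
  invisible(x)
}

#' Export a concentration field as a long-format data frame
#'
#' @param field A `"concentration_field"`.
#' @return A data frame with columns `time_s`, `r_m`,
#'   `height_above_bottom_m`, `alpha`.
#' @export
field_as_data_frame <- function(field) {
  stopifnot(inherits(field, "concentration_field"))
  nt <- nrow(field$alpha)
  nc <- ncol(field$alpha)
  data.frame(time_s = rep(field$times, each = nc),
             r_m = rep(field$r_centers, nt),
             height_above_bottom_m = rep(field$heights, nt),
             alpha = as.vector(t(field$alpha)))
}
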