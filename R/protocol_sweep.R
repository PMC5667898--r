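#' Specification of a protocol parameter sweep
#'
#' Bundles the grids and blood/tube conditions over which recovery rates are
#' mapped. Defaults follow common clinical practice: accelerations 100-1500 g,
#' spin times 2-15 minutes, hematocrit 0.37-0.52 and WBC capture coefficient
#' 1e-3 to 1e-2. Accelerations below about 100 g trigger an extrapolation
#' warning: there the neglected gravitational component biases the model.
#'
#' @param acceleration_grid Accelerations in g-multiples (default
#'   `seq(100, 1500, by = 20)`).
#' @param time_grid Spin times in minutes (default the clinical set
#'   2-10, 12, 15).
#' @param hematocrit_set Hematocrit values averaged over (default
#'   `c(0.37, 0.45, 0.52)`).
#' @param c_w_set WBC capture coefficients averaged over (default
#'   `c(1e-3, 1e-2)`).
#' @param volume Whole-blood volume V_WB, m^3 (default 9 mL).
#' @param geometry A [tube_geometry()].
#' @param coeffs [correlation_coefficients()].
#' @param beta_o Initial WBC volume fraction.
#' @param alpha_max Packing limit.
#' @param grid A [solver_grid()].
#' @param fluid A [fluid_phase()].
#' @param rbc_species,wbc_species Species definitions.
#' @param eps_clear,eps_packed Interface thresholds.
#' @return An object of class `"sweep_spec"`.
#' @export
sweep_spec <- function(acceleration_grid = seq(100, 1500, by = 20),
                       time_grid = c(2:10, 12, 15),
                       hematocrit_set = c(0.37, 0.45, 0.52),
                       c_w_set = c(1e-3, 1e-2),
                       volume = 9e-6,
                       geometry = tube_geometry(),
                       coeffs = correlation_coefficients(),
                       beta_o = 0.01, alpha_max = 0.8,
                       grid = solver_grid(), fluid = blood_plasma(),
                       rbc_species = rbc(), wbc_species = wbc(),
                       eps_clear = 1e-3, eps_packed = 1e-3) {
  if (length(hematocrit_set) == 0L) stop("'hematocrit_set' must be non-empty")
  if (any(hematocrit_set <= 0 | hematocrit_set >= 1))
    stop("hematocrit values must lie in (0, 1)")
  if (length(acceleration_grid) &&
      any(acceleration_grid < 100 | acceleration_grid > 1500))
    warning("acceleration grid extends beyond the validated 100-1500 g ",
            "range (the model is unvalidated below ~100 g)")
  structure(list(acceleration_grid = sort(acceleration_grid),
                 time_grid = sort(time_grid),
                 hematocrit_set = hematocrit_set, c_w_set = c_w_set,
                 volume = volume, geometry = geometry, coeffs = coeffs,
                 beta_o = beta_o, alpha_max = alpha_max, grid = grid,
                 fluid = fluid, rbc_species = rbc_species,
                 wbc_species = wbc_species, eps_clear = eps_clear,
                 eps_packed = eps_packed),
            class = "sweep_spec")
}

# One dimensionless march for a uniform initial fraction, sampled at the
# requested dimensionless times; returns supernatant front heights and plasma
# recoveries. The field depends on the protocol only through t*, so a single
# march serves every (t_c, a_c) combination of a sweep.
march_summary <- function(alpha0, spec, t_star_out) {
  geometry <- spec$geometry
  column <- mixture_column(geometry, spec$volume)
  n <- spec$grid$n_cells
  lambda <- column$fill_height / geometry$rotor_radius
  dx <- lambda / n
  x_faces <- seq(0, n) * dx
  x_centers <- (x_faces[-1] + x_faces[-(n + 1)]) / 2
  heights <- x_centers * geometry$rotor_radius
  conical <- geometry$bottom == "conical"
  res <- kinwave_march(
    rep(alpha0, n), dx, 1 - x_faces[2:n], 5, spec$alpha_max, spec$grid$cfl,
    t_star_out,
    if (conical) area_profile(geometry, heights) else NULL,
    if (conical) area_profile(geometry, x_faces[2:n] * geometry$rotor_radius)
    else NULL)
  L <- column$fill_height
  I_ns <- I_sd <- E_plas <- numeric(length(t_star_out))
  for (i in seq_along(t_star_out)) {
    prof <- res$alpha[i, ]
    I_ns[i] <- interface_height(prof, heights, L, spec$eps_clear)$h
    I_sd[i] <- interface_height(prof, heights, L,
                                spec$alpha_max - spec$eps_packed)$h
    E_plas[i] <- min(max(volume_between(geometry, I_ns[i], L) /
                           (column$volume * (1 - alpha0)), 0), 1)
  }
  list(I_ns = I_ns, I_sd = I_sd, E_plas = E_plas, column = column)
}

#' Recovery rates along an acceleration sweep at fixed spin time
#'
#' For each acceleration the RBC field gives the plasma recovery, the
#' correlation gives the platelet recovery, and the WBC field (same crowd
#' concentration, WBC time scale) gives the buffy-coat recovery. Per-
#' hematocrit values are reported alongside their arithmetic mean; E_WBC is
#' additionally averaged over `c_w_set` (it is linear in c_w, so the mean
#' coefficient is used).
#'
#' @param spec A [sweep_spec()].
#' @param t_c Spin time in minutes.
#' @param include_wbc Compute E_WBC? Default TRUE.
#' @param gravity m/s^2.
#' @return A data frame of class `"prp_sweep"`: one row per acceleration with
#'   averaged `E_plas`, `E_PLT`, `E_WBC`, per-hematocrit columns and a
#'   `clipped` flag.
#' @export
recovery_curve <- function(spec, t_c, include_wbc = TRUE, gravity = 9.81) {
  stopifnot(inherits(spec, "sweep_spec"))
  acc <- spec$acceleration_grid
  if (length(acc) == 0L) {
    out <- data.frame(a_c_g = numeric(0), t_c_min = numeric(0),
                      E_plas = numeric(0), E_PLT = numeric(0),
                      E_WBC = numeric(0), clipped = logical(0))
    class(out) <- c("prp_sweep", "data.frame")
    return(out)
  }
  t_sec <- t_c * 60
  R_o <- spec$geometry$rotor_radius
  u_rbc <- stokes_settling_velocity(spec$rbc_species, spec$fluid, gravity)
  u_wbc <- stokes_settling_velocity(spec$wbc_species, spec$fluid, gravity)
  ts_rbc <- t_sec * acc * u_rbc / R_o
  ts_wbc <- t_sec * acc * u_wbc / R_o
  column <- mixture_column(spec$geometry, spec$volume)
  ratio <- vapply(acc, function(a)
    platelet_plasma_ratio(
      pi_groups(spec$geometry, column,
                centrifuge_protocol(a, t_sec, gravity), u_rbc),
      spec$coeffs), numeric(1))

  nH <- length(spec$hematocrit_set)
  E_plas_h <- E_plt_h <- E_wbc_h <- matrix(NA_real_, nrow = length(acc),
                                           ncol = nH)
  for (k in seq_len(nH)) {
    He <- spec$hematocrit_set[k]
    t_out <- if (include_wbc) c(ts_rbc, ts_wbc) else ts_rbc
    ms <- march_summary(He, spec, t_out)
    E_plas_h[, k] <- ms$E_plas[seq_along(acc)]
    E_plt_h[, k] <- pmin(ratio * E_plas_h[, k], 1)
    if (include_wbc) {
      I_ns_rbc <- ms$I_ns[seq_along(acc)]
      I_pW <- ms$I_ns[length(acc) + seq_along(acc)]
      h <- pmax(I_pW - I_ns_rbc, 0)
      layer_vol <- vapply(seq_along(acc), function(i)
        volume_between(spec$geometry, I_ns_rbc[i], I_ns_rbc[i] + h[i]),
        numeric(1))
      E_wbc_h[, k] <- mean(spec$c_w_set) * layer_vol /
        (spec$beta_o * spec$volume)
    }
  }
  out <- data.frame(a_c_g = acc, t_c_min = t_c,
                    E_plas = rowMeans(E_plas_h),
                    E_PLT = rowMeans(E_plt_h),
                    E_WBC = if (include_wbc) rowMeans(E_wbc_h) else NA_real_,
                    ratio = ratio,
                    clipped = apply(ratio * E_plas_h > 1, 1, any))
  for (k in seq_len(nH)) {
    out[[sprintf("E_plas_He%g", spec$hematocrit_set[k])]] <- E_plas_h[, k]
    out[[sprintf("E_PLT_He%g", spec$hematocrit_set[k])]] <- E_plt_h[, k]
    if (include_wbc)
      out[[sprintf("E_WBC_He%g", spec$hematocrit_set[k])]] <- E_wbc_h[, k]
  }
  class(out) <- c("prp_sweep", "data.frame")
  attr(out, "spec") <- spec
  out
}

#' Plot a recovery sweep
#'
#' @param x A `"prp_sweep"` from [recovery_curve()].
#' @param which Responses to draw (any of `"E_PLT"`, `"E_plas"`, `"E_WBC"`).
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, `x`.
#' @export
plot.prp_sweep <- function(x, which = c("E_PLT", "E_plas"), ...) {
  which <- intersect(which, names(x))
  graphics::matplot(x$a_c_g, as.matrix(x[, which, drop = FALSE]),
                    type = "l", lty = seq_along(which), col = 1,
                    xlab = "centrifugal acceleration [g]",
                    ylab = "recovery rate", ...)
  graphics::legend("bottomright", legend = which, lty = seq_along(which),
                   bty = "n")
  invisible(x)
}

#' Critical acceleration: the argmax of a recovery curve
#'
#' Finds the acceleration that maximises a response along a sweep. An
#' interior discrete maximum is refined by quadratic interpolation through
#' the peak and its neighbours (exact for parabolas). Maxima attained over a
#' plateau (for example where the platelet recovery is clipped at 1) return
#' the leftmost maximiser with a `tie` flag; maxima at the grid edge are
#' flagged `at_boundary`.
#'
#' @param curve A `"prp_sweep"` (or data frame with `a_c_g` and the
#'   response column), at least 3 rows.
#' @param response Column to maximise (default `"E_PLT"`).
#' @return List with `a_c` (g), `E_max`, and flags `tie`, `at_boundary`.
#' @export
critical_acceleration <- function(curve, response = "E_PLT") {
  if (nrow(curve) < 3L) stop("curve needs at least 3 points")
  a <- curve$a_c_g
  y <- curve[[response]]
  ymax <- max(y)
  idx <- which(y >= ymax - 1e-12)
  if (length(idx) > 1L)
    return(list(a_c = a[min(idx)], E_max = ymax, tie = TRUE,
                at_boundary = min(idx) == 1L || max(idx) == length(y)))
  j <- idx
  if (j == 1L || j == length(y))
    return(list(a_c = a[j], E_max = ymax, tie = FALSE, at_boundary = TRUE))
  x1 <- a[j - 1]; x2 <- a[j]; x3 <- a[j + 1]
  y1 <- y[j - 1]; y2 <- y[j]; y3 <- y[j + 1]
  denom <- (x2 - x1) * (y2 - y3) - (x2 - x3) * (y2 - y1)
  if (abs(denom) < 1e-300)
    return(list(a_c = x2, E_max = y2, tie = FALSE, at_boundary = FALSE))
  xv <- x2 - 0.5 * ((x2 - x1)^2 * (y2 - y3) - (x2 - x3)^2 * (y2 - y1)) / denom
  # parabola value at the vertex (Lagrange form)
  yv <- y1 * (xv - x2) * (xv - x3) / ((x1 - x2) * (x1 - x3)) +
    y2 * (xv - x1) * (xv - x3) / ((x2 - x1) * (x2 - x3)) +
    y3 * (xv - x1) * (xv - x2) / ((x3 - x1) * (x3 - x2))
  list(a_c = xv, E_max = yv, tie = FALSE, at_boundary = FALSE)
}

#' Platelet-against-plasma recovery pairs over protocols
#'
#' Emits (E_plas, E_PLT) pairs over the acceleration grid for each spin time.
#' Because both quantities depend on the protocol only through the product
#' `t_c * a_c`, pairs from different spin times collapse onto a single curve:
#' the near-linear rise below the platelet maximum and the fold-back beyond
#' it.
#'
#' @param spec A [sweep_spec()].
#' @param t_c_list Spin times in minutes (default: the time grid of `spec`).
#' @return Data frame with columns `t_c_min`, `a_c_g`, `E_plas`, `E_PLT`.
#' @export
polar_curve <- function(spec, t_c_list = spec$time_grid) {
  out <- lapply(t_c_list, function(tc) {
    cv <- recovery_curve(spec, tc, include_wbc = FALSE)
    data.frame(t_c_min = tc, a_c_g = cv$a_c_g, E_plas = cv$E_plas,
               E_PLT = cv$E_PLT)
  })
  do.call(rbind, out)
}

#' Gain-loss sensitivity budget along an acceleration sweep
#'
#' Decomposes `d(E_PLT)/da_c = ratio * dE_plas/da_c + E_plas * dratio/da_c`
#' into the plasma-gathering gain term and the correlation-decay loss term.
#' The ratio derivative is analytic; the plasma derivative is a central
#' difference on the solver curve. The acceleration where gain and loss
#' balance coincides with the critical acceleration of the platelet curve.
#'
#' @param spec A [sweep_spec()] whose acceleration grid has at least 5
#'   points.
#' @param t_c Spin time in minutes.
#' @param hematocrit Single hematocrit value.
#' @param gravity m/s^2.
#' @return Data frame (class `"prp_sensitivity"`) with per-acceleration
#'   `E_plas`, `ratio`, `dEplas_dac`, `dratio_dac`, `gain_term`,
#'   `loss_term`; the balance acceleration (or NA) is in the `balance_ac`
#'   attribute.
#' @export
sensitivity_budget <- function(spec, t_c, hematocrit, gravity = 9.81) {
  acc <- spec$acceleration_grid
  if (length(acc) < 5L) stop("need at least 5 grid points for derivatives")
  spec1 <- spec
  spec1$hematocrit_set <- hematocrit
  cv <- recovery_curve(spec1, t_c, include_wbc = FALSE, gravity = gravity)
  E <- cv$E_plas
  ratio <- cv$ratio
  dE <- c(NA, (E[-(1:2)] - E[1:(length(E) - 2)]) /
            (acc[-(1:2)] - acc[1:(length(acc) - 2)]), NA)
  cf <- spec$coeffs
  column <- mixture_column(spec$geometry, spec$volume)
  pg <- pi_groups(spec$geometry, column,
                  centrifuge_protocol(acc[1], t_c * 60, gravity),
                  stokes_settling_velocity(spec$rbc_species, spec$fluid,
                                           gravity))
  P <- pg$pi2^cf$e2 * pg$pi3^cf$e3
  dratio <- cf$c1 * P * cf$e4 * acc^(cf$e4 - 1) * ratio
  gain <- ratio * dE
  loss <- abs(dratio) * E
  bal <- gain - loss
  balance_ac <- NA_real_
  sgn <- sign(bal)
  chg <- which(diff(sgn[!is.na(sgn)]) != 0)
  if (length(chg)) {
    ii <- which(!is.na(bal))
    i1 <- ii[chg[1]]; i2 <- ii[chg[1] + 1]
    balance_ac <- acc[i1] + (acc[i2] - acc[i1]) *
      bal[i1] / (bal[i1] - bal[i2])
  }
  out <- data.frame(a_c_g = acc, E_plas = E, ratio = ratio,
                    dEplas_dac = dE, dratio_dac = dratio,
                    gain_term = gain, loss_term = loss)
  class(out) <- c("prp_sensitivity", "data.frame")
  attr(out, "balance_ac") <- balance_ac
  out
}

#' Acceleration where flat- and conical-tube recovery curves cross
#'
#' At gentle spins the flat tube yields more platelets; once the flat curve
#' has peaked and starts to decline the conical tube overtakes it. This
#' locates the first sign change of `E(flat) - E(conical)` at or beyond the
#' flat-curve maximum, by linear interpolation on a common acceleration
#' grid.
#'
#' @param flat_curve,conical_curve `"prp_sweep"` data frames on the same
#'   acceleration grid.
#' @param response Column compared (default `"E_PLT"`).
#' @return List with `a_c_cross` (NA if no crossing) and `found`.
#' @export
geometry_crossing <- function(flat_curve, conical_curve,
                              response = "E_PLT") {
  if (!isTRUE(all.equal(flat_curve$a_c_g, conical_curve$a_c_g)))
    stop("curves must share a common acceleration grid")
  a <- flat_curve$a_c_g
  d <- flat_curve[[response]] - conical_curve[[response]]
  if (all(abs(d) < 1e-12)) return(list(a_c_cross = NA_real_, found = FALSE))
  # scan from the flat peak onwards: the geometry trade-off is where the
  # flat curve has started to decline, whether or not the conical curve has
  # peaked yet
  start <- which.max(flat_curve[[response]])
  for (i in seq(start, length(a) - 1L)) {
    if (d[i] > 0 && d[i + 1] <= 0) {
      xc <- a[i] + (a[i + 1] - a[i]) * d[i] / (d[i] - d[i + 1])
      return(list(a_c_cross = xc, found = TRUE))
    }
  }
  list(a_c_cross = NA_real_, found = FALSE)
}

#' Recovery map over spin time and acceleration
#'
#' Grids the hematocrit-averaged platelet and WBC recoveries over the
#' (t_c, a_c) plane, in the form used to pick operating points: a
#' time-efficient point (high acceleration, short spin), an
#' integrity-preserving point (low acceleration, long spin) and a trade-off
#' point in between.
#'
#' @param spec A [sweep_spec()]; its `time_grid` and `acceleration_grid`
#'   define the map.
#' @param include_wbc Compute the E_WBC layer? Default TRUE.
#' @return An object of class `"prp_map"`: list with `t_c_min`, `a_c_g`,
#'   matrices `E_PLT` and `E_WBC` (time x acceleration), and
#'   `operating_points`.
#' @export
optimization_map <- function(spec, include_wbc = TRUE) {
  stopifnot(inherits(spec, "sweep_spec"))
  tg <- spec$time_grid
  ag <- spec$acceleration_grid
  if (length(tg) < 1L || length(ag) < 1L) stop("empty map grids")
  E_PLT <- matrix(NA_real_, length(tg), length(ag))
  E_WBC <- matrix(NA_real_, length(tg), length(ag))
  for (i in seq_along(tg)) {
    cv <- recovery_curve(spec, tg[i], include_wbc = include_wbc)
    E_PLT[i, ] <- cv$E_PLT
    E_WBC[i, ] <- cv$E_WBC
  }
  m <- structure(list(t_c_min = tg, a_c_g = ag, E_PLT = E_PLT,
                      E_WBC = E_WBC, spec = spec),
                 class = "prp_map")
  pts <- list(time_efficient = c(t_c_min = 2.5, a_c_g = 1500),
              integrity_preserving = c(t_c_min = 15, a_c_g = 240),
              trade_off = c(t_c_min = 4.5, a_c_g = 750))
  m$operating_points <- lapply(pts, function(p) {
    inside <- p["t_c_min"] >= min(tg) && p["t_c_min"] <= max(tg) &&
      p["a_c_g"] >= min(ag) && p["a_c_g"] <= max(ag)
    c(p, E_PLT = if (inside)
        map_query(m, p["t_c_min"], p["a_c_g"], "E_PLT") else NA_real_,
      E_WBC = if (inside && include_wbc)
        map_query(m, p["t_c_min"], p["a_c_g"], "E_WBC") else NA_real_)
  })
  m
}

#' Query a recovery map
#'
#' Bilinear interpolation of a mapped response at an arbitrary
#' (spin time, acceleration) point within the grid.
#'
#' @param map A `"prp_map"` from [optimization_map()].
#' @param t_c_min Spin time, minutes.
#' @param a_c_g Acceleration, g-multiples.
#' @param response `"E_PLT"` or `"E_WBC"`.
#' @return The interpolated recovery fraction.
#' @export
map_query <- function(map, t_c_min, a_c_g, response = "E_PLT") {
  stopifnot(inherits(map, "prp_map"))
  tg <- map$t_c_min; ag <- map$a_c_g
  z <- map[[response]]
  if (t_c_min < min(tg) || t_c_min > max(tg) ||
      a_c_g < min(ag) || a_c_g > max(ag))
    stop("query point outside the map grid")
  interp1 <- function(g, v) {
    if (length(g) == 1L) return(list(i = c(1L, 1L), w = c(1, 0)))
    j <- findInterval(v, g, rightmost.closed = TRUE)
    j <- min(max(j, 1L), length(g) - 1L)
    w2 <- (v - g[j]) / (g[j + 1] - g[j])
    list(i = c(j, j + 1L), w = c(1 - w2, w2))
  }
  it <- interp1(tg, t_c_min)
  ia <- interp1(ag, a_c_g)
  sum(outer(it$w, ia$w) * z[it$i, ia$i])
}

#' @export
print.prp_map <- function(x, ...) {
  cat(sprintf("Recovery map: %d spin times x %d accelerations (V_WB = %g mL)\n",
              length(x$t_c_min), length(x$a_c_g), x$spec$volume * 1e6))
  for (nm in names(x$operating_points)) {
    p <- x$operating_points[[nm]]
    cat(sprintf("  %s: %g min, %g g -> E_PLT %.3f%s\n", nm, p[["t_c_min"]],
                p[["a_c_g"]], p[[3]],
                if (!is.na(p[[4]])) sprintf(", E_WBC %.3f", p[[4]]) else ""))
  }
  invisible(x)
}

#' Plot a recovery map as contours
#'
#' @param x A `"prp_map"`.
#' @param response `"E_PLT"` or `"E_WBC"`.
#' @param ... Passed to [graphics::contour()].
#' @return Invisibly, `x`.
#' @export
plot.prp_map <- function(x, response = "E_PLT", ...) {
  graphics::contour(x$t_c_min, x$a_c_g, x[[response]],
                    xlab = "spin time [min]",
                    ylab = "centrifugal acceleration [g]", ...)
  invisible(x)
}

#' Export a recovery map as a long-format data frame
#'
#' @param map A `"prp_map"`.
#' @return Data frame with columns `t_c_min`, `a_c_g`, `E_PLT`, `E_WBC`.
#' @export
map_as_data_frame <- function(map) {
  stopifnot(inherits(map, "prp_map"))
  data.frame(t_c_min = rep(map$t_c_min, times = length(map$a_c_g)),
             a_c_g = rep(map$a_c_g, each = length(map$t_c_min)),
             E_PLT = as.vector(map$E_PLT),
             E_WBC = as.vector(map$E_WBC))
}
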