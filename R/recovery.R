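#' Locate the layer interfaces in a concentration field
#'
#' Classifies the column into clear liquid (alpha ~ 0), retarded settling
#' zone and packed bed (alpha ~ alpha_max), and returns the heights (above
#' the tube bottom) of the supernatant/suspension interface `I_ns` and the
#' suspension/sediment interface `I_sd`. Both are located by linear sub-cell
#' interpolation at the threshold levels, so they do not snap to the grid.
#'
#' Degenerate columns are flagged rather than erroring: an all-clear column
#' returns `I_ns = 0`, a column with no clear layer returns `I_ns = L`.
#'
#' @param field A `"concentration_field"` from [solve_sedimentation()].
#' @param t Time (s) at which to extract interfaces; matched to the nearest
#'   recorded output time.
#' @param eps_clear Threshold (absolute volume fraction) separating clear
#'   liquid from suspension. Default 1e-3.
#' @param eps_packed Offset below alpha_max defining the packed bed.
#'   Default 1e-3.
#' @return An object of class `"interface_set"`: list with `I_ns`, `I_sd`
#'   (m above the tube bottom), `time` (s), `fill_height` and logical flags
#'   `all_clear`, `no_clear`, `no_bed`.
#' @export
locate_interfaces <- function(field, t = NULL, eps_clear = 1e-3,
                              eps_packed = 1e-3) {
  stopifnot(inherits(field, "concentration_field"))
  if (is.null(t)) t <- field$requested_times[length(field$requested_times)]
  i <- which.min(abs(field$requested_times - t))
  if (abs(field$requested_times[i] - t) > max(1e-9, 1e-6 * t))
    stop("'t' does not match any recorded output time")
  prof <- field$alpha[i, ]
  x <- field$heights
  L <- field$column$fill_height
  amax <- field$model$alpha_max

  I_ns <- interface_height(prof, x, L, level = eps_clear)
  I_sd <- interface_height(prof, x, L, level = amax - eps_packed)

  structure(list(I_ns = I_ns$h, I_sd = I_sd$h, time = field$times[i],
                 fill_height = L,
                 all_clear = I_ns$below_all, no_clear = I_ns$above_all,
                 no_bed = I_sd$below_all),
            class = "interface_set")
}

# Height of the topmost crossing of `level`, linearly interpolated between
# the highest cell with alpha >= level and the cell above it. Cells are
# ordered bottom (index 1) to top.
interface_height <- function(prof, x, L, level) {
  idx <- which(prof >= level)
  if (length(idx) == 0L)
    return(list(h = 0, below_all = TRUE, above_all = FALSE))
  j <- max(idx)
  n <- length(prof)
  if (j == n)
    return(list(h = L, below_all = FALSE, above_all = TRUE))
  # prof[j] >= level > prof[j + 1]
  frac <- (prof[j] - level) / (prof[j] - prof[j + 1])
  list(h = x[j] + frac * (x[j + 1] - x[j]), below_all = FALSE,
       above_all = FALSE)
}

#' @export
print.interface_set <- function(x, ...) {
  cat(sprintf(
    "Interfaces at t = %.4g s: I_ns = %.4g mm, I_sd = %.4g mm (L = %.4g mm)\n",
    x$time, x$I_ns * 1e3, x$I_sd * 1e3, x$fill_height * 1e3))
  invisible(x)
}

#' Plasma recovery rate
#'
#' `E_plas = V_UL / (V_WB (1 - H_e))`, where `V_UL` is the clear upper-layer
#' volume above the supernatant/suspension interface (for a flat tube,
#' `(L - I_ns) A`). Clipped to \[0, 1\]; clipping is recorded in the
#' `"clipped"` attribute.
#'
#' @param interfaces An `"interface_set"` from [locate_interfaces()].
#' @param column A [mixture_column()].
#' @param geometry A [tube_geometry()].
#' @param hematocrit Initial red-cell volume fraction H_e, in (0, 1).
#' @return Plasma recovery fraction in \[0, 1\].
#' @export
plasma_recovery <- function(interfaces, column, geometry, hematocrit) {
  stopifnot(inherits(interfaces, "interface_set"),
            inherits(column, "mixture_column"),
            inherits(geometry, "tube_geometry"))
  if (hematocrit <= 0 || hematocrit >= 1)
    stop("'hematocrit' must lie in (0, 1)")
  V_UL <- volume_between(geometry, interfaces$I_ns, column$fill_height)
  e <- V_UL / (column$volume * (1 - hematocrit))
  clipped <- e > 1 || e < 0
  structure(min(max(e, 0), 1), clipped = clipped, V_UL = V_UL)
}

#' White-blood-cell recovery rate
#'
#' The WBC-rich (buffy-coat) layer lies between the supernatant front of the
#' WBC field (`I_pW`) and that of the RBC field (`I_ns`); WBCs settle more
#' slowly, so their front sits higher. The recovery is
#' `E_WBC = c_w * h * A / (beta_o * V_WB)` with `h = max(I_pW - I_ns, 0)` the
#' layer thickness, `c_w` an empirical capture coefficient of order
#' 1e-3 to 1e-2, and `beta_o` the initial WBC volume fraction in whole blood.
#'
#' @param rbc_interfaces,wbc_interfaces `"interface_set"` objects from
#'   matched RBC and WBC solves under the same protocol.
#' @param geometry A [tube_geometry()].
#' @param column A [mixture_column()].
#' @param beta_o Initial WBC volume fraction (default 0.01).
#' @param c_w Empirical coefficient (default 1e-2).
#' @return WBC recovery (>= 0).
#' @export
wbc_recovery <- function(rbc_interfaces, wbc_interfaces, geometry, column,
                         beta_o = 0.01, c_w = 1e-2) {
  stopifnot(inherits(rbc_interfaces, "interface_set"),
            inherits(wbc_interfaces, "interface_set"))
  if (beta_o <= 0) stop("'beta_o' must be positive")
  # the supernatant front of the WBC field is I_pW
  I_pW <- wbc_interfaces$I_pW %||% wbc_interfaces$I_ns
  h <- max(I_pW - rbc_interfaces$I_ns, 0)
  layer_volume <- volume_between(geometry, rbc_interfaces$I_ns,
                                 rbc_interfaces$I_ns + h)
  c_w * layer_volume / (beta_o * column$volume)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict all recovery rates for a single protocol
#'
#' The central one-call interface: solves the RBC kinematic-wave field (and a
#' WBC field when requested), extracts interfaces, applies the plasma
#' recovery balance and the Pi-group correlation for platelets, and the
#' buffy-coat formula for WBCs.
#'
#' The WBC field is solved with the same initial crowd concentration as the
#' RBC field (the hematocrit) but the WBC settling time scale: a white cell
#' sinks through, and is hindered by, the full cell suspension. The initial
#' WBC fraction `beta_o` only normalises the recovered amount.
#'
#' @param hematocrit Initial red-cell fraction H_e in (0, 1).
#' @param volume Whole-blood volume V_WB, m^3.
#' @param protocol A [centrifuge_protocol()].
#' @param geometry A [tube_geometry()].
#' @param coeffs [correlation_coefficients()] for the platelet correlation.
#' @param include_wbc Solve the WBC field and report E_WBC? Default TRUE.
#' @param beta_o Initial WBC volume fraction (default 0.01).
#' @param c_w WBC capture coefficient (default 1e-2).
#' @param grid A [solver_grid()].
#' @param fluid A [fluid_phase()].
#' @param rbc_species,wbc_species Species overrides.
#' @param alpha_max Packing limit (default 0.8).
#' @param eps_clear,eps_packed Interface thresholds, see
#'   [locate_interfaces()].
#' @return An object of class `"prp_recovery"`: list with `E_plas`, `E_PLT`,
#'   `E_WBC` (NA when not computed), `ratio`, interface sets, `V_UL`, clip
#'   flags and the inputs.
#' @examples
#' \donttest{
#' prp_recovery(hematocrit = 0.45, volume = 9e-6,
#'              protocol = centrifuge_protocol(900, 5 * 60))
#' }
#' @export
prp_recovery <- function(hematocrit, volume, protocol,
                         geometry = tube_geometry(),
                         coeffs = correlation_coefficients(),
                         include_wbc = TRUE, beta_o = 0.01, c_w = 1e-2,
                         grid = solver_grid(), fluid = blood_plasma(),
                         rbc_species = rbc(), wbc_species = wbc(),
                         alpha_max = 0.8, eps_clear = 1e-3,
                         eps_packed = 1e-3) {
  if (hematocrit <= 0 || hematocrit >= 1)
    stop("'hematocrit' must lie in (0, 1)")
  column <- mixture_column(geometry, volume)
  u_rbc <- stokes_settling_velocity(rbc_species, fluid, protocol$gravity)
  model_rbc <- settling_model(u_rbc, alpha_max = alpha_max)

  f_rbc <- solve_sedimentation(hematocrit, rbc_species, fluid, geometry,
                               volume, protocol, grid, model = model_rbc)
  ifc_rbc <- locate_interfaces(f_rbc, protocol$spin_time, eps_clear,
                               eps_packed)
  E_plas <- plasma_recovery(ifc_rbc, column, geometry, hematocrit)

  pg <- pi_groups(geometry, column, protocol, u_rbc)
  ratio <- platelet_plasma_ratio(pg, coeffs)
  E_PLT <- platelet_recovery(as.numeric(E_plas), ratio)

  E_WBC <- NA_real_
  ifc_wbc <- NULL
  if (include_wbc) {
    u_wbc <- stokes_settling_velocity(wbc_species, fluid, protocol$gravity)
    model_wbc <- settling_model(u_wbc, alpha_max = alpha_max)
    f_wbc <- solve_sedimentation(hematocrit, wbc_species, fluid, geometry,
                                 volume, protocol, grid, model = model_wbc)
    ifc_wbc <- locate_interfaces(f_wbc, protocol$spin_time, eps_clear,
                                 eps_packed)
    E_WBC <- wbc_recovery(ifc_rbc, ifc_wbc, geometry, column, beta_o, c_w)
  }

  structure(list(E_plas = as.numeric(E_plas),
                 E_PLT = as.numeric(E_PLT),
                 E_WBC = E_WBC,
                 ratio = ratio,
                 plas_clipped = isTRUE(attr(E_plas, "clipped")),
                 plt_clipped = isTRUE(attr(E_PLT, "clipped")),
                 V_UL = attr(E_plas, "V_UL"),
                 interfaces_rbc = ifc_rbc, interfaces_wbc = ifc_wbc,
                 hematocrit = hematocrit, beta_o = beta_o, c_w = c_w,
                 column = column, geometry = geometry, protocol = protocol,
                 coeffs = coeffs),
            class = "prp_recovery")
}

#' @export
print.prp_recovery <- function(x, ...) {
  cat(sprintf("PRP recovery at %g g, %.3g min (V_WB = %g mL, H_e = %g):\n",
              x$protocol$acceleration_g, x$protocol$spin_time / 60,
              x$column$volume * 1e6, x$hematocrit))
  cat(sprintf("  E_plas = %.3f%s   E_PLT = %.3f%s   E_WBC = %s\n",
              x$E_plas, if (x$plas_clipped) " (clipped)" else "",
              x$E_PLT, if (x$plt_clipped) " (clipped)" else "",
              if (is.na(x$E_WBC)) "not computed"
              else sprintf("%.3f (c_w = %g)", x$E_WBC, x$c_w)))
  cat(sprintf("  I_ns = %.3g mm, I_sd = %.3g mm, V_UL = %.3g mL\n",
              x$interfaces_rbc$I_ns * 1e3, x$interfaces_rbc$I_sd * 1e3,
              x$V_UL * 1e6))
  invisible(x)
}

#' @export
as.data.frame.prp_recovery <- function(x, ...) {
  data.frame(a_c_g = x$protocol$acceleration_g,
             t_c_min = x$protocol$spin_time / 60,
             V_WB_mL = x$column$volume * 1e6,
             hematocrit = x$hematocrit,
             c_w = x$c_w,
             E_plas = x$E_plas, E_PLT = x$E_PLT, E_WBC = x$E_WBC,
             ratio = x$ratio,
             I_ns_mm = x$interfaces_rbc$I_ns * 1e3,
             I_sd_mm = x$interfaces_rbc$I_sd * 1e3,
             I_pW_mm = if (is.null(x$interfaces_wbc)) NA_real_
                       else x$interfaces_wbc$I_ns * 1e3,
             V_UL_mL = x$V_UL * 1e6,
             plt_clipped = x$plt_clipped)
}
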