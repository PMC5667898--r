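#' Dimensionless Pi groups for the platelet-recovery correlation
#'
#' Buckingham-Pi analysis of platelet recovery yields three predictor groups:
#' `pi2 = V_t / (A L)` (tube capacity relative to the blood column),
#' `pi3 = t_c / (L / u_inf)` (spin time over the column settling time scale)
#' and `pi4 = omega^2 R_o / g` (the g-multiple of the acceleration). The
#' response group is `pi1 = ln(E_PLT / E_plas)`.
#'
#' The reference settling velocity `u_inf_ref` is the Stokes velocity of the
#' dominant dispersed phase, the red blood cell: only that choice puts the
#' product `pi2 pi3 pi4` in the range (order 10-100) over clinical protocols
#' that produces the observed decay of the recovery ratio.
#'
#' @param geometry A [tube_geometry()].
#' @param column A [mixture_column()].
#' @param protocol A [centrifuge_protocol()].
#' @param u_inf_ref Reference settling velocity (m/s); default the RBC Stokes
#'   velocity in plasma.
#' @return An object of class `"pi_groups"`: list with `pi2`, `pi3`, `pi4`
#'   and their `product`.
#' @examples
#' g <- tube_geometry()
#' pi_groups(g, mixture_column(g, 9e-6), centrifuge_protocol(1000, 600))
#' @export
pi_groups <- function(geometry, column, protocol,
                      u_inf_ref = stokes_settling_velocity(
                        rbc(), blood_plasma(), protocol$gravity)) {
  stopifnot(inherits(geometry, "tube_geometry"),
            inherits(column, "mixture_column"),
            inherits(protocol, "centrifuge_protocol"))
  L <- column$fill_height
  if (L <= 0) stop("column fill height must be positive")
  if (u_inf_ref <= 0) stop("'u_inf_ref' must be positive")
  pi2 <- geometry$capacity / (geometry$area * L)
  pi3 <- protocol$spin_time / (L / u_inf_ref)
  pi4 <- protocol$acceleration_g
  structure(list(pi2 = pi2, pi3 = pi3, pi4 = pi4,
                 product = pi2 * pi3 * pi4, u_inf_ref = u_inf_ref),
            class = "pi_groups")
}

#' @export
print.pi_groups <- function(x, ...) {
  cat(sprintf(
    "Pi groups: pi2 = %.4g, pi3 = %.4g, pi4 = %.4g (product %.4g)\n",
    x$pi2, x$pi3, x$pi4, x$product))
  invisible(x)
}

#' Coefficients of the platelet-plasma power-law correlation
#'
#' The correlation in log space is
#' `ln(E_PLT / E_plas) = c1 * pi2^e2 * pi3^e3 * pi4^e4 + c2`.
#' The defaults `(c1, c2) = (-0.0122, 0.5128)` with unit exponents come from
#' linear regression of clinical data; `exp(0.5128) = 1.67` is the
#' zero-argument recovery ratio. Natural logarithms throughout.
#'
#' @param c1 Slope of the log-ratio against the Pi-group product.
#' @param c2 Intercept (log of the limiting ratio).
#' @param e2,e3,e4 Exponents on pi2, pi3, pi4 (defaults 1).
#' @return An object of class `"correlation_coefficients"`.
#' @export
correlation_coefficients <- function(c1 = -0.0122, c2 = 0.5128,
                                     e2 = 1, e3 = 1, e4 = 1) {
  v <- c(c1 = c1, c2 = c2, e2 = e2, e3 = e3, e4 = e4)
  if (any(!is.finite(v))) stop("coefficients must be finite")
  structure(as.list(v), class = "correlation_coefficients")
}

#' @export
print.correlation_coefficients <- function(x, ...) {
  cat(sprintf(
    "Correlation: ln(ratio) = %.4g * pi2^%g pi3^%g pi4^%g + %.4g\n",
    x$c1, x$e2, x$e3, x$e4, x$c2))
  cat(sprintf("  limiting ratio exp(c2) = %.4g\n", exp(x$c2)))
  invisible(x)
}

#' Platelet-to-plasma recovery ratio from the correlation
#'
#' `E_PLT / E_plas = exp(c2) * exp(c1 * pi2^e2 * pi3^e3 * pi4^e4)`. With the
#' default coefficients this is `1.67 * exp(-0.0122 * pi2 * pi3 * pi4)`.
#'
#' @param pi A `"pi_groups"` object (pi1 not needed), or a list with fields
#'   `pi2`, `pi3`, `pi4`.
#' @param coeffs A [correlation_coefficients()].
#' @return The predicted ratio (> 0).
#' @export
platelet_plasma_ratio <- function(pi, coeffs = correlation_coefficients()) {
  stopifnot(inherits(coeffs, "correlation_coefficients"))
  exp(coeffs$c2 + coeffs$c1 * pi$pi2^coeffs$e2 * pi$pi3^coeffs$e3 *
        pi$pi4^coeffs$e4)
}

#' Platelet recovery from plasma recovery and the correlation ratio
#'
#' `E_PLT = min(ratio * E_plas, 1)`. The model can nominally exceed full
#' recovery near its optimum; values are clipped at 1 and the clipping is
#' recorded in the `"clipped"` attribute.
#'
#' @param E_plas Plasma recovery fraction in \[0, 1\].
#' @param ratio Ratio from [platelet_plasma_ratio()] (> 0).
#' @return Platelet recovery fraction, with attribute `clipped`.
#' @export
platelet_recovery <- function(E_plas, ratio) {
  if (any(E_plas < 0 | E_plas > 1)) stop("'E_plas' must lie in [0, 1]")
  if (any(ratio <= 0)) stop("'ratio' must be positive")
  raw <- ratio * E_plas
  structure(pmin(raw, 1), clipped = raw > 1)
}

# Pi groups for a data frame of correlation records (CSV schema with
# unit-suffixed columns V_t_mL, A_mm2, L_mm, t_c_min, a_c_g, u_inf_m_per_s).
record_pi_groups <- function(records) {
  need <- c("V_t_mL", "A_mm2", "L_mm", "t_c_min", "a_c_g", "u_inf_m_per_s")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("correlation records lack column(s): ", paste(miss, collapse = ", "))
  L <- records$L_mm * 1e-3
  data.frame(pi2 = (records$V_t_mL * 1e-6) / ((records$A_mm2 * 1e-6) * L),
             pi3 = (records$t_c_min * 60) / (L / records$u_inf_m_per_s),
             pi4 = records$a_c_g)
}

#' Fit the platelet-plasma correlation to observed recovery ratios
#'
#' With fixed unit exponents the fit is ordinary least squares of
#' `ln(ratio)` against the product `pi2 pi3 pi4` (slope `c1`, intercept
#' `c2`). With free exponents the model
#' `ln(ratio) = c1 * pi2^e2 * pi3^e3 * pi4^e4 + c2` is fitted by nonlinear
#' least squares started from the fixed-exponent solution.
#'
#' @param records A data frame of observations with unit-suffixed columns
#'   `V_t_mL`, `A_mm2`, `L_mm`, `t_c_min`, `a_c_g`, `u_inf_m_per_s`,
#'   `ratio` (observed E_PLT / E_plas, > 0). See
#'   [generate_correlation_fixture()] for the schema.
#' @param fix_exponents Keep `e2 = e3 = e4 = 1` (default TRUE)? At least two
#'   records are needed with fixed exponents, five with free exponents.
#' @return An object of class `"prp_corrfit"` with methods `coef`, `print`,
#'   `summary`, `predict` and `residuals`. `coef()` returns a
#'   [correlation_coefficients()] object in `$coeffs`.
#' @examples
#' rec <- generate_correlation_fixture(30, noise_sd = 0, seed = 1)
#' fit <- fit_correlation(rec)
#' coef(fit)
#' @export
fit_correlation <- function(records, fix_exponents = TRUE) {
  if (!is.data.frame(records)) stop("'records' must be a data frame")
  if (!"ratio" %in% names(records)) stop("records need a 'ratio' column")
  if (any(records$ratio <= 0)) stop("observed ratios must be positive")
  pg <- record_pi_groups(records)
  y <- log(records$ratio)
  x <- pg$pi2 * pg$pi3 * pg$pi4
  n_min <- if (fix_exponents) 2L else 5L
  if (nrow(records) < n_min)
    stop(sprintf("at least %d records required", n_min))
  if (stats::sd(x) == 0)
    stop("rank-deficient design: the Pi-group product is constant ",
         "across records")
  lin <- stats::lm(y ~ x)
  if (fix_exponents) {
    cf <- correlation_coefficients(c1 = unname(stats::coef(lin)[2]),
                                   c2 = unname(stats::coef(lin)[1]))
    fitted <- unname(stats::fitted(lin))
    se <- sqrt(diag(stats::vcov(lin)))
    std_err <- c(c1 = unname(se[2]), c2 = unname(se[1]))
  } else {
    dat <- data.frame(y = y, pi2 = pg$pi2, pi3 = pg$pi3, pi4 = pg$pi4)
    start <- list(c1 = unname(stats::coef(lin)[2]),
                  c2 = unname(stats::coef(lin)[1]),
                  e2 = 1, e3 = 1, e4 = 1)
    nl <- stats::nls(y ~ c1 * pi2^e2 * pi3^e3 * pi4^e4 + c2, data = dat,
                     start = start, algorithm = "port",
                     control = stats::nls.control(maxiter = 500,
                                                  warnOnly = TRUE))
    cfv <- stats::coef(nl)
    cf <- correlation_coefficients(c1 = cfv[["c1"]], c2 = cfv[["c2"]],
                                   e2 = cfv[["e2"]], e3 = cfv[["e3"]],
                                   e4 = cfv[["e4"]])
    fitted <- as.numeric(stats::fitted(nl))
    std_err <- tryCatch(sqrt(diag(stats::vcov(nl))),
                        error = function(e) rep(NA_real_, 5))
  }
  res <- y - fitted
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else NA_real_
  structure(list(coeffs = cf, std_errors = std_err, r_squared = r2,
                 residuals = res, fitted = fitted, log_ratio = y,
                 product = x, n = nrow(records),
                 fix_exponents = fix_exponents, records = records),
            class = "prp_corrfit")
}

#' @export
coef.prp_corrfit <- function(object, ...) {
  unlist(object$coeffs)
}

#' @export
residuals.prp_corrfit <- function(object, ...) object$residuals

#' @export
print.prp_corrfit <- function(x, ...) {
  cat(sprintf("Platelet-plasma correlation fit (%d records, %s exponents)\n",
              x$n, if (x$fix_exponents) "fixed" else "free"))
  print(x$coeffs)
  cat(sprintf("  R^2 (log space) = %.4f\n", x$r_squared))
  invisible(x)
}

#' @export
summary.prp_corrfit <- function(object, ...) {
  cf <- unlist(object$coeffs)
  se <- object$std_errors
  tab <- data.frame(estimate = cf[names(cf) %in% names(se)],
                    std_error = se[intersect(names(cf), names(se))])
  structure(list(coefficients = tab, r_squared = object$r_squared,
                 n = object$n, fix_exponents = object$fix_exponents,
                 residual_sd = stats::sd(object$residuals)),
            class = "summary.prp_corrfit")
}

#' @export
print.summary.prp_corrfit <- function(x, ...) {
  cat(sprintf("Correlation fit: n = %d, %s exponents\n", x$n,
              if (x$fix_exponents) "fixed" else "free"))
  print(x$coefficients)
  cat(sprintf("R^2 = %.4f, residual sd = %.4g (log space)\n",
              x$r_squared, x$residual_sd))
  invisible(x)
}

#' Predict recovery ratios from a fitted correlation
#'
#' @param object A `"prp_corrfit"`.
#' @param newdata Optional data frame in the correlation-record schema;
#'   defaults to the training records.
#' @param ... Unused.
#' @return Predicted `E_PLT / E_plas` ratios.
#' @export
predict.prp_corrfit <- function(object, newdata = NULL, ...) {
  rec <- if (is.null(newdata)) object$records else newdata
  pg <- record_pi_groups(rec)
  vapply(seq_len(nrow(pg)), function(i)
    platelet_plasma_ratio(pg[i, ], object$coeffs), numeric(1))
}
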