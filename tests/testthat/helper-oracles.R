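# Shared numerical oracles used by several test files. Everything here is an
# independent re-derivation (brute force or exact ODE), deliberately not
# sharing code with the package internals it checks.

# Clamped dimensionless batch flux: -a (1-a)^m on (0, alpha_max), 0 outside.
oracle_flux <- function(a, m, alpha_max) {
  f <- -a * (1 - a)^m
  f[a <= 0 | a >= alpha_max] <- 0
  f
}

# Godunov flux for the scalar law with flux g(a) = r_face * oracle_flux(a):
# min over [a_l, a_r] when a_l <= a_r, max over [a_r, a_l] otherwise,
# located by brute-force scan.
oracle_godunov_flux <- function(a_l, a_r, r_face, m, alpha_max,
                                n_scan = 20001) {
  lo <- min(a_l, a_r)
  hi <- max(a_l, a_r)
  # the candidate extrema of the clamped flux on an interval are its
  # endpoints, the interior stationary point 1/(m+1), and the clamp edges;
  # including them makes the scan exact, the dense grid is just a guard
  special <- c(a_l, a_r, 1 / (m + 1), alpha_max)
  special <- special[special >= lo & special <= hi]
  grid <- unique(c(seq(lo, hi, length.out = n_scan), special))
  vals <- r_face * oracle_flux(grid, m, alpha_max)
  if (a_l <= a_r) min(vals) else max(vals)
}

# Engquist-Osher flux straight from its definition,
#   F = g(0) + int_0^{a_l} max(g', 0) ds + int_0^{a_r} min(g', 0) ds,
# evaluated by telescoping the clamped flux over a dense grid (exact within
# monotone stretches; the upward clamp jump at alpha_max lands in the
# increasing part, matching the splitting convention). Independent of the
# package's closed-form evaluation.
oracle_eo_flux <- function(a_l, a_r, r_face, m, alpha_max, n_seg = 20000) {
  gpart <- function(u, take_max) {
    if (u <= 0) return(0)
    dv <- diff(oracle_flux(seq(0, u, length.out = n_seg + 1), m, alpha_max))
    if (take_max) sum(pmax(dv, 0)) else sum(pmin(dv, 0))
  }
  r_face * (gpart(a_l, TRUE) + gpart(a_r, FALSE))
}

# Slow reference EO march on the height-above-bottom axis (cell 1 at the
# bottom), zero-flux boundaries, constant-area column, with the same
# conservative packing repair as the production scheme (excess above
# alpha_max is returned to the cell above).
oracle_eo_march <- function(alpha0, dx, r_faces_int, m, alpha_max,
                            dt, n_steps) {
  al <- alpha0
  n <- length(al)
  for (s in seq_len(n_steps)) {
    fint <- vapply(seq_len(n - 1), function(i)
      oracle_eo_flux(al[i], al[i + 1], r_faces_int[i], m, alpha_max,
                     n_seg = 2000),
      numeric(1))
    flux_up <- c(fint, 0)
    flux_down <- c(0, fint)
    al <- al - (dt / dx) * (flux_up - flux_down)
    while (any(al > alpha_max)) {
      ex <- pmax(al - alpha_max, 0)
      ex[n] <- 0
      al <- al - ex + c(0, ex[-n])
    }
  }
  al
}

# Exact kinematic-wave solution before the descending front meets the rising
# bed: the suspension below the front stays spatially uniform and dilutes
# along d a/d t* = -a (1-a)^m, while the front (a shock against clear liquid)
# obeys d x/d t* = -(1-x) (1-a(t))^m on the dimensionless height axis
# x = height / R_o. RK2 integration at a step far finer than any solver grid.
oracle_front_ode <- function(t_star, lambda, alpha_o, m = 5,
                             n_steps = 100000) {
  dt <- t_star / n_steps
  x <- lambda
  a <- alpha_o
  for (i in seq_len(n_steps)) {
    k1x <- -(1 - x) * (1 - a)^m
    k1a <- -a * (1 - a)^m
    xm <- x + 0.5 * dt * k1x
    am <- a + 0.5 * dt * k1a
    x <- x + dt * (-(1 - xm) * (1 - am)^m)
    a <- a + dt * (-am * (1 - am)^m)
  }
  list(x_front = x, alpha_below = a)
}

# Numerical shock position of a monotone-in-height profile: the topmost
# downward crossing of `level`, linearly interpolated between cell centres.
# Measuring the discrete shock at mid-front is the standard convention for
# comparing a smeared numerical front against an exact discontinuity.
oracle_mid_front <- function(prof, heights, level) {
  idx <- which(prof >= level)
  j <- max(idx)
  if (j == length(prof)) return(heights[j])
  heights[j] + (heights[j + 1] - heights[j]) *
    (prof[j] - level) / (prof[j] - prof[j + 1])
}

# Construct a bare interface set for unit tests of the recovery formulas.
fake_interfaces <- function(I_ns, I_sd = I_ns, L = 0.075) {
  structure(list(I_ns = I_ns, I_sd = I_sd, time = 0, fill_height = L,
                 all_clear = FALSE, no_clear = FALSE, no_bed = FALSE),
            class = "interface_set")
}
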