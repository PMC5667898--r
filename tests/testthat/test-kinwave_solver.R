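mod1 <- settling_model(u_inf = 1, m_exponent = 5, alpha_max = 0.8)

test_that("solver grid validates its parameters", {
  expect_error(solver_grid(n_cells = 5), "n_cells")
  expect_error(solver_grid(cfl = 0), "cfl")
  expect_error(solver_grid(cfl = 1.5), "cfl")
  expect_error(solver_grid(dr_star = -1), "dr_star")
  g <- solver_grid()
  expect_equal(g$n_cells, 200L)
  expect_equal(g$cfl, 0.5)
})

test_that("EO interface flux: consistency and trivial states", {
  for (a in c(0, 0.05, 1 / 6, 0.4, 0.79)) {
    expect_lt(abs(eo_interface_flux(a, a, 1, mod1) - batch_flux(a, mod1)),
              1e-15)
  }
  expect_equal(eo_interface_flux(0, 0, 1, mod1), 0)
  expect_equal(eo_interface_flux(0.8, 0.8, 1, mod1), 0)
  expect_error(eo_interface_flux(-0.1, 0.5, 1, mod1), "fractions")
  expect_error(eo_interface_flux(0.5, 1.2, 1, mod1), "fractions")
})

test_that("EO flux equals the Godunov value on the worked rarefaction-shock case", {
  # left 0.05, right 0.7: the minimum of r* f over [0.05, 0.7] sits at the
  # interior extremum alpha = 1/6
  f <- eo_interface_flux(0.05, 0.7, 1, mod1)
  expect_equal(f, -(1 / 6) * (5 / 6)^5, tolerance = 1e-12)
  expect_equal(f, -0.06698, tolerance = 1e-4)
  expect_equal(f, oracle_godunov_flux(0.05, 0.7, 1, 5, 0.8),
               tolerance = 1e-12)
})

test_that("EO flux matches its integral definition across random states and radii", {
  set.seed(101)
  for (i in 1:60) {
    al <- runif(1, 0, 0.85)
    ar <- runif(1, 0, 0.85)
    rf <- runif(1, 0.5, 1)
    expect_lt(abs(eo_interface_flux(al, ar, rf, mod1) -
                    oracle_eo_flux(al, ar, rf, 5, 0.8)), 1e-7)
  }
})

test_that("EO equals Godunov off transonic shocks and dominates it on them", {
  ac <- 1 / 6
  fac <- -(1 / 6) * (5 / 6)^5
  set.seed(101)
  for (i in 1:60) {
    al <- runif(1, 0, 0.85)
    ar <- runif(1, 0, 0.85)
    rf <- runif(1, 0.5, 1)
    feo <- eo_interface_flux(al, ar, rf, mod1)
    fgod <- oracle_godunov_flux(al, ar, rf, 5, 0.8)
    if (al > ac && ar < ac) {
      # shock straddling the flux minimum: EO is the more diffusive of the
      # two monotone fluxes, by exactly min(g(l), g(r)) - g(ac)
      gap <- min(rf * oracle_flux(al, 5, 0.8),
                 rf * oracle_flux(ar, 5, 0.8)) - rf * fac
      expect_lt(abs(feo - fgod - gap), 1e-10)
      expect_gte(feo, fgod - 1e-12)
      expect_lte(feo - fgod, rf * (-fac) + 1e-12)
    } else {
      expect_lt(abs(feo - fgod), 1e-10)
    }
  }
  # the canonical settling front (suspension below clear liquid): EO carries
  # a small upward numerical flux where Godunov is exactly zero
  expect_equal(eo_interface_flux(0.37, 0, 1, mod1),
               -0.37 * 0.63^5 - fac, tolerance = 1e-12)
  expect_equal(oracle_godunov_flux(0.37, 0, 1, 5, 0.8), 0)
})

test_that("flux scales with the settling velocity and the face radius", {
  mod3 <- settling_model(u_inf = 3, m_exponent = 5, alpha_max = 0.8)
  expect_equal(eo_interface_flux(0.05, 0.7, 1, mod3),
               3 * eo_interface_flux(0.05, 0.7, 1, mod1))
  expect_equal(eo_interface_flux(0.05, 0.7, 0.5, mod1),
               0.5 * eo_interface_flux(0.05, 0.7, 1, mod1))
})

test_that("stable timestep follows the CFL bound with max wave speed 1", {
  g <- solver_grid(cfl = 0.5, dr_star = 0.005)
  expect_equal(stable_timestep(g, mod1), 0.0025)
  g2 <- solver_grid(cfl = 0.25, dr_star = 0.005)
  expect_equal(stable_timestep(g2, mod1), 0.00125)
  # the dimensionless step does not depend on u_inf
  expect_equal(stable_timestep(g, settling_model(3.2e-6)), 0.0025)
  expect_error(stable_timestep(solver_grid(), mod1), "dr_star")
})

test_that("the full march agrees with a slow reference EO march", {
  set.seed(7)
  n <- 50
  alpha0 <- runif(n, 0, 0.8)
  dx <- 0.01
  r_faces <- 1 - seq_len(n - 1) * dx
  dt <- 0.5 * dx / 1
  n_steps <- 25L
  res <- prpspin:::kinwave_march(alpha0, dx, r_faces, 5, 0.8, 0.5,
                                 t_star_out = n_steps * dt)
  ref <- oracle_eo_march(alpha0, dx, r_faces, 5, 0.8, dt, n_steps)
  expect_equal(as.numeric(res$alpha[1, ]), ref, tolerance = 1e-6)
})

test_that("trivial initial states are fixed points", {
  pr <- centrifuge_protocol(1000, 120)
  f0 <- solve_sedimentation(0, volume = 9e-6, protocol = pr,
                            grid = solver_grid(n_cells = 40))
  expect_true(all(f0$alpha == 0))
  fmax <- solve_sedimentation(0.8, volume = 9e-6, protocol = pr,
                              grid = solver_grid(n_cells = 40))
  expect_true(all(abs(fmax$alpha - 0.8) < 1e-14))
})

test_that("solids are conserved and concentrations stay in bounds (flat tube)", {
  pr <- centrifuge_protocol(600, 600)
  f <- solve_sedimentation(0.45, volume = 9e-6, protocol = pr,
                           grid = solver_grid(n_cells = 120),
                           output_times = c(0, 150, 300, 600))
  mass <- rowSums(f$alpha)  # uniform cells: total solids up to a constant
  expect_true(all(abs(mass / mass[1] - 1) < 1e-6))
  expect_true(all(f$alpha >= 0))
  expect_true(all(f$alpha <= 0.8 + 1e-12))
})

test_that("solids are conserved and bounded on the conical tube (area-weighted)", {
  gc <- tube_geometry(bottom = "conical")
  pr <- centrifuge_protocol(600, 600)
  f <- solve_sedimentation(0.45, geometry = gc, volume = 9e-6, protocol = pr,
                           grid = solver_grid(n_cells = 120),
                           output_times = c(0, 150, 300, 600))
  A <- area_profile(gc, f$heights)
  mass <- as.numeric(f$alpha %*% A)
  expect_true(all(abs(mass / mass[1] - 1) < 1e-6))
  expect_true(all(f$alpha >= 0))
  expect_true(all(f$alpha <= 0.8 + 1e-12))
})

test_that("the numerical front tracks the exact Rankine-Hugoniot speed within one cell", {
  geom <- tube_geometry()
  mod <- settling_model(stokes_settling_velocity(rbc(), blood_plasma()))
  He <- 0.37
  L <- height_from_volume(geom, 9e-6)
  lambda <- L / geom$rotor_radius
  r_top <- 1 - lambda
  n <- 100
  for (t_star in c(0.05, 0.2)) {
    t_dim <- t_star * geom$rotor_radius / (300 * mod$u_inf)
    f <- solve_sedimentation(He, volume = 9e-6,
                             protocol = centrifuge_protocol(300, t_dim),
                             grid = solver_grid(n_cells = n), model = mod)
    ts <- f$t_star[length(f$t_star)]
    # frozen-state front: r*_front = r*_top exp((1 - alpha_o)^m t*)
    h_exact <- geom$rotor_radius * (1 - r_top * exp((1 - He)^5 * ts))
    h_num <- oracle_mid_front(f$alpha[1, ], f$heights, He / 2)
    expect_lt(abs(h_num - h_exact), L / n)
  }
  # with dilution of the suspension included (exact characteristics ODE),
  # the front still tracks within one cell at a later time
  t_star <- 0.5
  t_dim <- t_star * geom$rotor_radius / (300 * mod$u_inf)
  f <- solve_sedimentation(He, volume = 9e-6,
                           protocol = centrifuge_protocol(300, t_dim),
                           grid = solver_grid(n_cells = n), model = mod)
  ode <- oracle_front_ode(f$t_star[1], lambda, He)
  h_exact <- ode$x_front * geom$rotor_radius
  h_num <- oracle_mid_front(f$alpha[1, ], f$heights, ode$alpha_below / 2)
  expect_lt(abs(h_num - h_exact), L / n)
})

test_that("the suspension below the front dilutes as the characteristics ODE predicts", {
  geom <- tube_geometry()
  mod <- settling_model(stokes_settling_velocity(rbc(), blood_plasma()))
  t_dim <- 0.5 * geom$rotor_radius / (300 * mod$u_inf)
  f <- solve_sedimentation(0.37, volume = 9e-6,
                           protocol = centrifuge_protocol(300, t_dim),
                           grid = solver_grid(n_cells = 100), model = mod)
  ode <- oracle_front_ode(f$t_star[1], 0.5, 0.37)
  # probe the uniform region between the bed influence and the front
  mid <- f$alpha[1, 40:55]
  expect_true(all(abs(mid - ode$alpha_below) < 5e-3))
})

test_that("output sampling takes the last completed step before each requested time", {
  pr <- centrifuge_protocol(500, 300)
  f <- solve_sedimentation(0.4, volume = 9e-6, protocol = pr,
                           grid = solver_grid(n_cells = 40),
                           output_times = c(75, 150, 300))
  expect_true(all(f$times <= c(75, 150, 300) + 1e-9))
  dt_dim <- f$dt_star * (0.15 / (500 * f$model$u_inf))
  expect_true(all(c(75, 150, 300) - f$times < dt_dim + 1e-9))
  expect_equal(f$requested_times, c(75, 150, 300))
})

test_that("solver input validation catches bad initial data and horizons", {
  pr <- centrifuge_protocol(500, 300)
  expect_error(solve_sedimentation(1.0, volume = 9e-6, protocol = pr,
                                   grid = solver_grid(n_cells = 40)),
               "alpha_max")
  expect_error(solve_sedimentation(rep(0.4, 10), volume = 9e-6, protocol = pr,
                                   grid = solver_grid(n_cells = 40)),
               "length")
  expect_error(solve_sedimentation(0.4, volume = 9e-6, protocol = pr,
                                   grid = solver_grid(n_cells = 40),
                                   output_times = 301), "output_times")
  expect_error(solve_sedimentation(0.4, volume = 9e-6, protocol = pr,
                                   grid = solver_grid(n_cells = 40,
                                                      dr_star = 0.05)),
               "mixture column")
})

test_that("a three-zone structure develops in the demonstration configuration", {
  # alpha_o = 0.4 with a soft packing limit 0.65: clear liquid, retarded
  # settling zone and packed bed coexist mid-spin
  mod <- settling_model(stokes_settling_velocity(rbc(), blood_plasma()),
                        m_exponent = 5, alpha_max = 0.65)
  f <- solve_sedimentation(0.4, volume = 9e-6,
                           protocol = centrifuge_protocol(1000, 100),
                           grid = solver_grid(n_cells = 200), model = mod)
  ifc <- locate_interfaces(f)
  L <- f$column$fill_height
  expect_false(ifc$all_clear)
  expect_false(ifc$no_clear)
  expect_false(ifc$no_bed)
  expect_gt(ifc$I_sd, 0)
  expect_lt(ifc$I_ns, L)
  expect_lt(ifc$I_sd, ifc$I_ns)   # strictly: a settling zone persists
})

test_that("field export and print/plot interfaces work", {
  pr <- centrifuge_protocol(500, 120)
  f <- solve_sedimentation(0.4, volume = 9e-6, protocol = pr,
                           grid = solver_grid(n_cells = 40),
                           output_times = c(60, 120))
  df <- field_as_data_frame(f)
  expect_equal(nrow(df), 2 * 40)
  expect_named(df, c("time_s", "r_m", "height_above_bottom_m", "alpha"))
  expect_equal(df$height_above_bottom_m[1:40], f$heights)
  expect_output(print(f), "Concentration field")
  tmp <- tempfile(fileext = ".pdf")
  grDevices::pdf(tmp)
  expect_invisible(plot(f))
  grDevices::dev.off()
  unlink(tmp)
})
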