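frictionless_solve <- function(l = 0.03, outlet = "constant_pressure",
                               total_time = NULL, pulse = NULL, courant = 1) {
  ch <- culture_channel(l = l)
  if (is.null(pulse)) pulse <- impact_pulse(water, pmma_projectile())
  cf <- celerity_rect(water, ch)
  if (is.null(total_time)) total_time <- 0.95 * l / cf
  grid <- design_grid(cf, l = l, total_time = total_time, dz = l / 150,
                      courant = courant)
  solve_transient(water, ch, pulse, grid, outlet = outlet, friction = "none")
}

test_that("frictionless solver equals the analytic traveling wave", {
  f <- frictionless_solve()
  pulse <- f$pulse
  # half-open front convention: the jump is carried strictly behind the
  # characteristic t = z/cf (ambient exactly on it, matching the t = 0 IC)
  analytic <- outer(f$z, f$t, function(z, t) {
    el <- t - z / f$cf
    ifelse(el > 0, f$ambient + pulse$p_peak * exp(-pulse$lam * el), f$ambient)
  })
  err <- max(abs(f$p - analytic)) / pulse$p_peak
  expect_lt(err, 1e-3)
  # characteristic invariant behind the front: u = (p - ambient)/(rho cf)
  expect_equal(f$u, (f$p - f$ambient) / (water$rho0 * f$cf),
               tolerance = 1e-10)
})

test_that("initial condition and stability contract hold", {
  f <- small_solve()
  expect_true(all(f$p[, 1] == f$ambient))
  expect_true(all(f$u[, 1] == 0))
  # no spurious overshoot above inlet peak + ambient
  expect_lt(max(f$p), (f$ambient + f$pulse$p_peak) * 1.005)
  # Courant > 1 refused
  ch <- culture_channel(0.03)
  grid_bad <- design_grid(celerity_rect(water, ch), 0.03, 1e-5,
                          dz = 2e-4, courant = 1.05)
  expect_error(solve_transient(water, ch, f$pulse, grid_bad),
               "Courant")
})

test_that("arrival times follow the celerity and peaks do not grow with z", {
  f <- small_solve()
  for (fr in c(0.25, 0.5, 0.75)) {
    i <- which.min(abs(f$z - fr * f$grid$l))
    arr <- f$t[which(f$p[i, ] > f$ambient + 0.01 * f$pulse$p_peak)[1]]
    expect_lt(abs(arr - f$z[i] / f$cf), 1.5 * f$grid$dt)
  }
  pk <- apply(f$p[-nrow(f$p), ], 1, max)  # exclude pinned outlet node
  expect_true(all(diff(pk[pk > f$ambient + 0.5 * f$pulse$p_peak]) <= 1e-9))
})

test_that("boundary reflection coefficients: +1 closed, -1 constant-pressure", {
  pulse <- impact_pulse(water, pmma_projectile())
  # closed end: pressure doubling of the leading edge (whose discrete
  # amplitude is the pulse one step behind the characteristic)
  fc <- frictionless_solve(l = 0.015, outlet = "closed",
                           total_time = 1.6 * 0.015 / 1415)
  lead <- pulse_pressure(pulse, fc$grid$dt)
  end_peak <- max(fc$p[nrow(fc$p), ]) - fc$ambient
  expect_equal(end_peak / lead, 2, tolerance = 5e-3)
  # constant-pressure end: velocity doubling (pressure reflects with -1)
  fo <- frictionless_solve(l = 0.015, outlet = "constant_pressure",
                           total_time = 1.6 * 0.015 / 1415)
  end_u <- max(fo$u[nrow(fo$u), ])
  expect_equal(end_u / (lead / (water$rho0 * fo$cf)), 2, tolerance = 5e-3)
})

test_that("sub-unit Courant interpolation stays accurate and bounded", {
  f <- frictionless_solve(courant = 0.8)
  pulse <- f$pulse
  analytic <- outer(f$z, f$t, function(z, t) {
    el <- t - z / f$cf
    ifelse(el > 0, f$ambient + pulse$p_peak * exp(-pulse$lam * el), f$ambient)
  })
  # interpolation smears the front; peaks stay bounded and wave arrives on time
  expect_lt(max(f$p), (f$ambient + pulse$p_peak) * 1.005)
  i <- which.min(abs(f$z - 0.5 * f$grid$l))
  behind <- f$t > f$z[i] / f$cf + 20 * f$grid$dt
  expect_lt(max(abs(f$p[i, behind] - analytic[i, behind])) / pulse$p_peak,
            0.05)
})

test_that("viscous attenuation: zero without friction, monotone in viscosity", {
  f0 <- frictionless_solve(l = 0.06, total_time = 4.2e-5)
  expect_equal(peak_attenuation(f0, 0.015), 0, tolerance = 1e-12)
  att <- vapply(c(1e-3, 1e-2, 1e-1), function(mu) {
    fl <- fluid_spec(999.8, 1439, mu, 3.35e8, 7.15, 101325)
    ch <- culture_channel(0.06)
    pulse <- impact_pulse(fl, pmma_projectile())
    cf <- celerity_rect(fl, ch)
    grid <- design_grid(cf, 0.06, 4.2e-5, dz = 4e-4, courant = 1)
    peak_attenuation(solve_transient(fl, ch, pulse, grid,
                                     friction = "quasi_steady"), 0.015)
  }, numeric(1))
  expect_true(all(diff(att) > 0))
  expect_gt(att[1], 0)
})

test_that("unsteady friction closure runs and dissipates at least as much", {
  ch <- culture_channel(0.03)
  pulse <- impact_pulse(water, pmma_projectile())
  cf <- celerity_rect(water, ch)
  grid <- design_grid(cf, 0.03, 2.0e-5, dz = 2e-4, courant = 1)
  fq <- solve_transient(water, ch, pulse, grid, friction = "quasi_steady")
  fu <- solve_transient(water, ch, pulse, grid, friction = "unsteady")
  expect_lt(max(fu$p), (fu$ambient + pulse$p_peak) * 1.005)
  expect_gte(peak_attenuation(fu, 0.0075), peak_attenuation(fq, 0.0075))
})

test_that("monitor traces sample the field and carry the stress components", {
  f <- small_solve()
  tr <- monitor(f, c(0, 0.5, 0.75))
  # z = 0 trace equals the inlet pulse plus ambient (after the t = 0 IC)
  expect_equal(tr[[1]]$p[-1], f$ambient + pulse_pressure(f$pulse, f$t[-1]),
               tolerance = 1e-12)
  expect_identical(tr[[1]]$p[1], f$ambient)
  expect_identical(tr[[2]]$tau_x, 0)
  # shear phase-locked to compression: zero before front arrival
  i3 <- which.min(abs(f$z - 0.75 * f$grid$l))
  before <- f$t < f$z[i3] / f$cf
  expect_true(all(tr[[3]]$tau_z[before] == 0))
  expect_gt(max(tr[[3]]$tau_z), 0)
  expect_error(monitor(f, 1.5), "within the channel")
})

test_that("wave field exports to a long-format data frame", {
  f <- small_solve()
  df <- as.data.frame(f)
  expect_equal(nrow(df), length(f$z) * length(f$t))
  expect_named(df, c("z_m", "t_s", "p_Pa", "u_m_s"))
  expect_equal(df$p_Pa[df$t_s == 0], rep(f$ambient, length(f$z)))
})
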