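test_that("impedances match rho*c handbook arithmetic", {
  expect_equal(impedance(water), 999.8 * 1439)
  expect_equal(impedance(solid_material(1, 1, 1, 1)), 1)
  expect_equal(impedance(material_preset("steel")), 4.63e7, tolerance = 2e-3)
  expect_equal(impedance(material_preset("pmma")), 1180 * 2757)
})

test_that("matched amplitude: harmonic impedance mean, Joukowsky upper bound", {
  pr0 <- pmma_projectile(velocity = 0)
  expect_identical(matched_amplitude(water, pr0), 0)
  pr1 <- pmma_projectile(velocity = 1)
  expect_equal(matched_amplitude(water, pr1), 9.97556e5, tolerance = 1e-5)
  # rigid-projectile limit approaches the Joukowsky value Zf*up from below
  rigid <- projectile_spec(solid_material(7850e6, 5900e6, 1e9, 1e9),
                           length = 0.01, area = 9e-6, velocity = 1)
  expect_equal(matched_amplitude(water, rigid), impedance(water),
               tolerance = 1e-6)
  for (m in c("pmma", "steel", "glass")) {
    pr <- projectile_spec(material_preset(m), 0.01, 9e-6, velocity = 1)
    Zp <- impedance(material_preset(m))
    amp <- matched_amplitude(water, pr)
    expect_lt(amp, impedance(water))
    # relative gap to the Joukowsky bound equals Zf/(Zf+Zp)
    expect_equal(1 - amp / impedance(water),
                 impedance(water) / (impedance(water) + Zp),
                 tolerance = 1e-12)
  }
})

test_that("decay constant: frozen value, mass scaling, velocity independence", {
  pr <- pmma_projectile()
  lam <- decay_constant(water, pr)
  expect_equal(lam, 1.41104e5, tolerance = 1e-5)
  # doubling the length halves lambda at fixed section
  pr2 <- pmma_projectile(length = 0.02)
  expect_equal(decay_constant(water, pr2), lam / 2, tolerance = 1e-12)
  # independent of impact velocity
  expect_identical(decay_constant(water, pmma_projectile(velocity = 7)), lam)
})

test_that("source pulse evaluates the exponential exactly", {
  pulse <- impact_pulse(water, pmma_projectile())
  expect_identical(pulse_pressure(pulse, 0), pulse$p_peak)
  expect_equal(pulse_pressure(pulse, 1 / pulse$lam), pulse$p_peak / exp(1))
  expect_equal(pulse_pressure(pulse, 0, total = TRUE),
               pulse$p_peak + water$p0)
  expect_equal(predict(pulse, c(0, 1e-6)),
               pulse_pressure(pulse, c(0, 1e-6)))
  expect_error(pulse_pressure(pulse, -1e-9), "nonnegative")
  # positive, strictly decreasing, integrable to ~p_peak/lambda
  t <- seq(0, 5 / pulse$lam, length.out = 2001)
  v <- pulse_pressure(pulse, t)
  expect_true(all(v > 0) && all(diff(v) < 0))
  quad <- sum((v[-1] + v[-length(v)]) / 2 * diff(t))
  expect_equal(quad, pulse$p_peak / pulse$lam * (1 - exp(-5)),
               tolerance = 1e-4)
})

test_that("explicit projectile deceleration reproduces the closed form", {
  pr <- pmma_projectile()
  pulse <- impact_pulse(water, pr)
  t_end <- 5 / pulse$lam
  ode <- integrate_projectile_ode(water, pr, t_end, dt = t_end / 2000)
  # normalized decay shapes agree to well under 0.1%
  shape_ode <- ode$p / ode$p[1]
  shape_cls <- exp(-pulse$lam * ode$t)
  expect_lt(max(abs(shape_ode - shape_cls)), 1e-3 * 1)
  # momentum bookkeeping: impulse equals projectile momentum loss
  imp <- sum((ode$p[-1] + ode$p[-nrow(ode)]) / 2 * diff(ode$t)) * pr$area
  expect_equal(imp, pr$mass * (ode$u[1] - ode$u[nrow(ode)]),
               tolerance = 5e-3)
  # zero initial velocity gives identically zero pressure
  ode0 <- integrate_projectile_ode(water, pmma_projectile(velocity = 0),
                                   1e-5, 1e-7)
  expect_true(all(ode0$p == 0))
  expect_error(integrate_projectile_ode(water, pr, 1e-5, dt = 0), "positive")
})

test_that("pulse controls: amplitude scales with velocity, duration with length", {
  amps <- vapply(c(1, 2, 4), function(v)
    impact_pulse(water, pmma_projectile(velocity = v))$p_peak, numeric(1))
  expect_equal(amps / amps[1], c(1, 2, 4), tolerance = 1e-12)
  lam_v <- vapply(c(1, 2, 4), function(v)
    impact_pulse(water, pmma_projectile(velocity = v))$lam, numeric(1))
  expect_equal(lam_v, rep(lam_v[1], 3))
  # longer projectile: same amplitude, smaller lambda (slower decay)
  lams <- vapply(c(0.01, 0.02, 0.04), function(L)
    impact_pulse(water, pmma_projectile(length = L))$lam, numeric(1))
  expect_equal(lams[1] / lams, c(1, 2, 4), tolerance = 1e-12)
  amp_L <- vapply(c(0.01, 0.02, 0.04), function(L)
    impact_pulse(water, pmma_projectile(length = L))$p_peak, numeric(1))
  expect_equal(amp_L, rep(amp_L[1], 3))
})

test_that("projectile mass defaults to rho * L * A and validates", {
  pr <- pmma_projectile()
  expect_equal(pr$mass, 1180 * 0.01 * 9e-6)
  given <- projectile_spec(material_preset("steel"), 0.05, 1.14009e-3,
                           velocity = 18.5, mass = 0.67)
  expect_equal(given$mass, 0.67)
  expect_error(projectile_spec(material_preset("pmma"), 0.01, 9e-6,
                               velocity = -1), "nonnegative")
})
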