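glass <- material_preset("glass")

test_that("rectangular-duct compliance factor is well-posed and symmetric", {
  phi <- phi_thorley(0.003, 0.003, 0.003, glass)
  expect_true(is.finite(phi) && phi > 0)
  # symmetric under a <-> b by construction (a >= b enforced at the surface)
  expect_equal(phi_thorley(0.004, 0.002, 0.003, glass),
               phi_thorley(0.004, 0.002, 0.003, glass))
  expect_error(phi_thorley(0.001, 0.003, 0.003, glass), "geometry")
  expect_error(phi_thorley(0.003, 0.003, 0, glass), "geometry")
})

test_that("celerity: rigid limit, stiffness and thickness monotonicity", {
  ch <- culture_channel()
  # general form reduces to c0 for rigid walls
  expect_equal(celerity_general(water, 0), water$c0, tolerance = 1e-12)
  # stiff-walled culture channel propagates within 5% of c0
  cf <- celerity_rect(water, ch)
  expect_lt(cf, water$c0)
  expect_gt(cf, 0.95 * water$c0)
  # cf -> c0 as the wall stiffens (E, G scaled together)
  scales <- c(1, 10, 100, 1e4)
  cfs <- vapply(scales, function(s) {
    w <- solid_material(glass$rho_s, glass$c_s, glass$E * s, glass$G * s)
    celerity_rect(water, channel_spec(0.003, 0.003, 0.003, 0.06, w))
  }, numeric(1))
  expect_true(all(diff(cfs) > 0))
  expect_equal(cfs[4], water$c0, tolerance = 1e-4)
  # thicker wall -> smaller compliance -> larger cf
  es <- c(0.001, 0.002, 0.004, 0.008)
  cfe <- vapply(es, function(e)
    celerity_rect(water, channel_spec(0.003, 0.003, e, 0.06, glass)),
    numeric(1))
  expect_true(all(diff(cfe) > 0))
  # agreement between the general evaluator and the rectangular route
  phi <- phi_thorley(ch$a, ch$b, ch$e, ch$wall)
  expect_equal(celerity_general(water, phi / (ch$a * ch$b * ch$wall$E * ch$e^2)),
               cf)
})

test_that("corrected bulk modulus round-trips with the celerity", {
  expect_equal(corrected_bulk_modulus(water, water$c0), water$K)
  Kmod <- corrected_bulk_modulus(water, 1353.6)
  expect_equal(Kmod, 1.832e9, tolerance = 1e-3)
  expect_equal(sqrt(Kmod / water$rho0), 1353.6, tolerance = 1e-12)
  # Kmod/K = (cf/c0)^2 exactly
  cf <- celerity_rect(water, culture_channel())
  expect_equal(corrected_bulk_modulus(water, cf) / water$K,
               (cf / water$c0)^2, tolerance = 1e-12)
})

test_that("fluid loading flags the culture channel as rigid", {
  ch <- culture_channel()
  fl <- fluid_loading(water, ch)
  expect_lt(fl$beta, 0.1)
  expect_true(fl$rigid_ok)
  expect_equal(fl$R, ch$A / (ch$a + ch$b))
  # beta scales linearly with R at fixed wall and celerity
  cf <- 1400
  b1 <- fluid_loading(water, channel_spec(0.003, 0.003, 0.003, 0.06, glass), cf)
  b2 <- fluid_loading(water, channel_spec(0.006, 0.006, 0.003, 0.06, glass), cf)
  expect_equal(b2$beta / b1$beta, b2$R / b1$R, tolerance = 1e-12)
  # vanishing fluid density ratio -> rigid
  heavy <- solid_material(1e12, glass$c_s, glass$E, glass$G)
  expect_lt(fluid_loading(water,
                          channel_spec(0.003, 0.003, 0.003, 0.06, heavy))$beta,
            1e-8)
})

test_that("Knudsen continuum criterion", {
  kn <- knudsen(3e-3, 3e-10)
  expect_equal(kn$Kn, 1e-7)
  expect_true(kn$continuum_ok)
  expect_false(knudsen(1e-9, 1e-9)$continuum_ok)
  l <- c(1e-3, 1e-2, 1e-1)
  expect_true(all(diff(knudsen(l, 3e-10)$Kn) < 0))
  expect_error(knudsen(-1, 1e-10), "positive")
})

test_that("grid design reproduces the printed discretization arithmetic", {
  g <- design_grid(cf = 1439, l = 0.06, total_time = 4.2e-5,
                   dz = 1e-4, dt = 0.7e-7)
  expect_equal(g$courant, 1.0073, tolerance = 1e-4)
  expect_identical(g$nt, 600L)
  expect_identical(g$nz, 600L)
  # Courant target 1 gives dt = dz/cf exactly
  g1 <- design_grid(cf = 1439, l = 0.06, total_time = 4.2e-5, dz = 1e-4)
  expect_equal(g1$dt, 1e-4 / 1439, tolerance = 1e-15)
  expect_equal(g1$courant, 1, tolerance = 1e-12)
  expect_error(design_grid(-1, 0.06, 4.2e-5, 1e-4), "positive")
})

test_that("acoustics report aggregates criteria consistently", {
  rep <- acoustics_report(water, culture_channel())
  expect_equal(rep$Kmod, water$rho0 * rep$cf^2)
  expect_true(rep$rigid_ok && rep$continuum_ok)
  # flags re-derivable from the reported quantities
  expect_identical(rep$rigid_ok, rep$beta < 0.1)
  expect_identical(rep$continuum_ok, rep$Kn < 0.001)
  rigid <- acoustics_report(water, culture_channel(), rigid = TRUE)
  expect_identical(rigid$cf, water$c0)
})
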