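test_that("unperturbed sequence returns the equilibrium vector", {
  sys <- fix_three_pool()
  sch <- saturation_scheme(sat_flip_deg = 0, exc_flip_deg = 0)
  m <- steady_state_magnetization(sys, sch, 3.5, 0)
  expect_equal(m, equilibrium_vector(sys), tolerance = 1e-12)
})

test_that("closed form equals the iterated-cycle fixed point", {
  set.seed(42)
  for (i in 1:15) {
    cs <- fix_random_case()
    m_cf <- steady_state_magnetization(cs$system, cs$scheme, cs$offset_ppm,
                                       cs$w1)
    m_it <- steady_state_magnetization(cs$system, cs$scheme, cs$offset_ppm,
                                       cs$w1, method = "iterated",
                                       tol = 1e-10, max_cycles = 20000L)
    expect_equal(m_cf, m_it, tolerance = 1e-8)
  }
})

test_that("far off-resonance saturation has no effect on water", {
  sys <- fix_three_pool()
  sch <- saturation_scheme()
  m_far <- steady_state_magnetization(sys, sch, 1e6, cwep_amplitude(sch))
  m_off <- steady_state_magnetization(sys, sch, 1e6, 0)
  expect_equal(m_far[3], m_off[3], tolerance = 1e-6)
})

test_that("a single water pool gives a symmetric Z-spectrum", {
  sys <- pool_system(fix_water())
  sch <- saturation_scheme()
  offs <- c(-4, -2, -0.5, 0.5, 2, 4)
  z <- simulate_zspectrum(sys, sch, acq_schedule(c(offs, 800)))
  zp <- z$z[match(abs(offs[offs < 0]), z$offset_ppm)]
  zm <- z$z[match(offs[offs < 0], z$offset_ppm)]
  expect_equal(zp, zm, tolerance = 1e-12)
})

test_that("adding an exchanging solute deepens the spectrum at its shift", {
  sch <- saturation_scheme()
  sched <- acq_schedule(c(3.5, 800))
  z_w <- simulate_zspectrum(pool_system(fix_water()), sch, sched)
  z_s <- simulate_zspectrum(
    pool_system(fix_water(), pool("amide", 3.5, 1, 0.01, 0.005, 30)),
    sch, sched)
  expect_lt(z_s$z[1], z_w$z[1])
})

test_that("a pool with m0r = 0 is equivalent to removing it", {
  sch <- saturation_scheme()
  sched <- fix_schedule_small()
  sys0 <- pool_system(fix_water(),
                      pool("amide", 3.5, 1, 0.01, 0, 30),
                      pool("MT", -2.34, 1, 1e-5, 0.1, 23,
                           klass = "semisolid"))
  z0 <- simulate_zspectrum(sys0, sch, sched)
  z1 <- simulate_zspectrum(drop_pool(sys0, "amide"), sch, sched)
  expect_equal(z0$z, z1$z, tolerance = 1e-10)
})

test_that("water signal at 15 ppm decreases monotonically with PSR", {
  sch <- saturation_scheme()
  sched <- acq_schedule(c(15, 800), 540)
  zs <- vapply(c(0.05, 0.1, 0.15, 0.2, 0.25), function(m0r)
    simulate_zspectrum(fix_two_pool(psr = m0r), sch, sched)$z[1], numeric(1))
  expect_true(all(diff(zs) < 0))
})

test_that("compiled and reference spectrum engines agree", {
  sys <- make_pool_system("brain_7pool")
  sch <- saturation_scheme(sat_flip_deg = 180)
  sched <- fix_schedule_small(180)
  a <- cestmt:::.spectrum_raw(sys, sch, sched)
  b <- cestmt:::.spectrum_raw_r(sys, sch, sched)
  expect_equal(a, b, tolerance = 1e-10)
})

test_that("degenerate configurations raise informative errors", {
  sys <- pool_system(fix_water())
  expect_error(acq_schedule(numeric(0)), "non-empty")
  expect_error(acq_schedule(c(NA, 1)), "finite")
})
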