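test_that("time-stepped integration reproduces the continuous-wave limit", {
  # block pulse at 100% duty: the CWEP closed form is exact
  sys <- fix_two_pool(psr = 0.1, lineshape = "gaussian", shift = 0)
  sch <- saturation_scheme(n_pulses = 10, pulse_dur = 0.05, duty_cycle = 1,
                           pulse_shape = "block", sat_flip_deg = 300,
                           shot_interval = 0.875, t_s = 0.01)
  sched <- acq_schedule(c(-3, -1, 1, 3, 800), 300)
  z_cf <- simulate_zspectrum(sys, sch, sched)
  z_ts <- simulate_zspectrum_timestepped(sys, sch, sched, dt = 0.001)
  expect_equal(z_ts$z, z_cf$z, tolerance = 1e-6)
})

test_that("time-stepped solution is converged in the step size", {
  sys <- pool_system(fix_water(), pool("amide", 3.5, 1, 0.01, 0.005, 30))
  sch <- saturation_scheme(n_pulses = 5, shot_interval = 0.6, t_s = 0.01)
  sched <- acq_schedule(c(3.5, 800))
  z1 <- simulate_zspectrum_timestepped(sys, sch, sched,
                                       dt = sch$pulse_dur / 400, tol = 1e-10)
  z2 <- simulate_zspectrum_timestepped(sys, sch, sched,
                                       dt = sch$pulse_dur / 800, tol = 1e-10)
  expect_equal(z1$z, z2$z, tolerance = 1e-6)
  expect_error(simulate_zspectrum_timestepped(sys, sch, sched,
                                              dt = sch$pulse_dur / 10),
               "dt")
})

test_that("water-only saturation recovery matches the scalar closed form", {
  # with no RF the pre-excitation magnetization obeys the one-dimensional
  # saturation-recovery fixed point M = (1 - E) / (1 - E cos(alpha))
  t1 <- 1.4
  sys <- pool_system(fix_water(t1 = t1))
  for (alpha in c(10, 45, 90)) {
    sch <- saturation_scheme(sat_flip_deg = 0, exc_flip_deg = alpha)
    m <- steady_state_magnetization(sys, sch, 0, 0)
    E <- exp(-(sch$t_m + sch$t_s + sch$t_r) / t1)
    expect_equal(m[3], (1 - E) / (1 - E * cos(alpha * pi / 180)),
                 tolerance = 1e-6)
  }
})

test_that("shaped-pulse oracle stays within the CWEP error budget", {
  sys <- make_pool_system("bsa_agarose", c(bsa = 6, agarose = 0.65))
  sch <- saturation_scheme()  # fifty 20-ms gaussian pulses, 50% duty
  sched <- acq_schedule(c(seq(-5, 5, by = 2.5), 800))
  z_cf <- simulate_zspectrum(sys, sch, sched)
  z_ts <- simulate_zspectrum_timestepped(sys, sch, sched,
                                         dt = sch$pulse_dur / 100)
  expect_lt(max(abs(z_cf$z - z_ts$z)), 0.02)
})
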