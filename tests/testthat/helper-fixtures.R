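# shared fixtures: small pool systems, schemes and schedules kept deliberately
# small so individual tests stay fast

fix_water <- function(t1 = 1.05, t2 = 0.07) pool("water", 0, t1, t2, 1, 0)

fix_two_pool <- function(psr = 0.2, k = 23, t2m = 1e-5,
                         lineshape = "super_lorentzian", shift = -2.34) {
  pool_system(fix_water(),
              pool("MT", shift, 1, t2m, psr, k, klass = "semisolid",
                   lineshape = lineshape))
}

fix_three_pool <- function() {
  pool_system(fix_water(),
              pool("amide", 3.5, 1, 0.01, 0.0053, 30),
              pool("MT", -2.34, 1, 1e-5, 0.2, 23, klass = "semisolid"))
}

fix_scheme <- function(...) saturation_scheme(...)

# 13 CEST offsets + dual-power MT offsets + references
fix_schedule_small <- function(flip = 184) {
  acq_schedule(c(seq(-4.5, 4.5, by = 0.75), 7.5, 15, 30, 60, 100,
                 7.5, 15, 30, 60, 100, 800, 800),
               c(rep(flip, 13), rep(flip, 5), rep(540, 5), flip, 540))
}

# a random (but valid) pool system + scheme + point, for property tests
fix_random_case <- function() {
  n_mob <- sample(0:2, 1)
  n_semi <- sample(0:1, 1)
  pools <- list(fix_water(t1 = runif(1, 0.5, 3), t2 = runif(1, 0.03, 1)))
  for (j in seq_len(n_mob))
    pools <- c(pools, list(pool(paste0("s", j), runif(1, -4, 4),
                                t1 = runif(1, 0.5, 2),
                                t2 = 10^runif(1, -3, -1.5),
                                m0r = 10^runif(1, -4, -1.5),
                                k = 10^runif(1, 0.5, 3))))
  if (n_semi)
    pools <- c(pools, list(pool("MT", runif(1, -3, 0), 1,
                                10^runif(1, -5.3, -4.5),
                                m0r = runif(1, 0.01, 0.25),
                                k = runif(1, 5, 60), klass = "semisolid",
                                lineshape = sample(c("gaussian",
                                                     "super_lorentzian",
                                                     "lorentzian"), 1))))
  scheme <- saturation_scheme(
    n_pulses = sample(c(10L, 25L, 50L), 1), pulse_dur = 0.02,
    duty_cycle = runif(1, 0.4, 1),
    pulse_shape = sample(c("gaussian", "block"), 1),
    sat_flip_deg = runif(1, 90, 540), exc_flip_deg = runif(1, 0, 30),
    shot_interval = 3.5, t_s = 0.01)
  list(system = pool_system(pools), scheme = scheme,
       offset_ppm = runif(1, -6, 6),
       w1 = cwep_amplitude(scheme) * runif(1, 0.5, 1.2))
}
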