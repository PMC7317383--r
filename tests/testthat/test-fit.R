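test_that("noiseless two-pool data are recovered to optimizer precision", {
  sys <- fix_two_pool()
  sch <- saturation_scheme()
  sched <- fix_schedule_small()
  z <- simulate_zspectrum(sys, sch, sched)
  f <- cest_fit(z, sched, sch, sys, variant = "two_pool", n_starts = 1)
  truth <- c(water.t2 = 0.07, water.t1 = 1.05, MT.m0r = 0.2, MT.k = 23,
             MT.t2 = 1e-5)
  est <- coef(f)[names(truth)]
  expect_lt(max(abs(est - truth) / truth), 1e-3)
  expect_lt(f$rms, 1e-8)
  expect_true(f$convergence)
})

test_that("a vanishing prior sd pins the estimate at the prior mean", {
  sys <- fix_two_pool()
  sch <- saturation_scheme()
  sched <- fix_schedule_small()
  z <- simulate_zspectrum(sys, sch, sched)
  f <- cest_fit(z, sched, sch, sys, variant = "two_pool", n_starts = 1,
                priors = list("MT.k" = c(40, 1e-4)))
  expect_equal(unname(coef(f)["MT.k"]), 40, tolerance = 1e-3)
  f2 <- cest_fit(z, sched, sch, sys, variant = "two_pool", n_starts = 1,
                 priors = list("MT.k" = c(40, 0)))
  expect_identical(unname(coef(f2)["MT.k"]), 40)
  expect_equal(unname(f2$estimates$sd[f2$estimates$name == "MT.k"]), 0)
})

test_that("an injected B0 shift is recovered without disturbing the pools", {
  sys <- fix_two_pool()
  sch <- saturation_scheme()
  sched <- fix_schedule_small()
  z <- simulate_zspectrum(sys, sch, sched, b0_ppm = 0.08)
  f <- cest_fit(z, sched, sch, sys, variant = "two_pool", n_starts = 1)
  expect_lt(abs(f$b0_ppm - 0.08), 0.02)
  expect_equal(psr(f), 0.2, tolerance = 0.01)
})

test_that("fit contracts are enforced", {
  sys <- fix_two_pool()
  sch <- saturation_scheme()
  sched <- fix_schedule_small()
  expect_error(cest_fit(rep(0.9, 5), sched, sch, sys, variant = "two_pool"),
               "non-reference")
  z <- simulate_zspectrum(sys, sch, sched)
  expect_error(
    cest_fit(z, sched, sch, sys, variant = "two_pool", estimate_b0 = FALSE,
             priors = list("water.t2" = c(0.07, 0), "water.t1" = c(1.05, 0),
                           "MT.m0r" = c(0.2, 0), "MT.k" = c(23, 0),
                           "MT.t2" = c(1e-5, 0))),
    "degenerate")
  expect_error(
    cest_fit(z, sched, sch, pool_system(fix_water()), variant = "two_pool"),
    "semisolid")
  cest_only <- sched[abs(sched$offset_ppm) <= 5 | sched$is_ref, ]
  expect_error(fit_qmt_fix(z$z[abs(z$offset_ppm) <= 5], cest_only, sch, sys),
               "qMT")
})

test_that("qMT-Fix stage 1 is clean when CEST pools barely reach >5 ppm", {
  sys4 <- make_pool_system("bsa_agarose", c(bsa = 6, agarose = 0.65))
  sch <- saturation_scheme()
  sched <- fix_schedule_small()
  z <- simulate_zspectrum(sys4, sch, sched)
  fq <- fit_qmt_fix(z, sched, sch, make_pool_system("bsa_agarose"),
                    t1_obs = sys4$pools[[1]]$t1, n_starts = 1)
  expect_equal(psr(fq$stage1), 0.65 * 0.015, tolerance = 0.05)
  # stage 2 keeps the semisolid fixed at stage-1 values
  expect_equal(psr(fq), psr(fq$stage1), tolerance = 1e-12)
  expect_equal(fq$variant, "qmt_fix")
})

test_that("qMT-Fix on pure two-pool truth leaves CEST amplitudes at the floor", {
  sys2 <- make_pool_system("bsa_agarose", c(bsa = 0, agarose = 0.65))
  sch <- saturation_scheme()
  sched <- fix_schedule_small()
  z <- simulate_zspectrum(sys2, sch, sched)
  zn <- z$z + cestmt:::.seeded_rng(5L)$rnorm(length(z$z), 0, 0.002)
  fq <- fit_qmt_fix(zn, sched, sch, make_pool_system("bsa_agarose"),
                    t1_obs = sys2$pools[[1]]$t1, n_starts = 1,
                    noise_sd = 0.002)
  expect_lt(unname(coef(fq)["amide.m0r"]), 0.002)
  expect_lt(unname(coef(fq)["noe.m0r"]), 0.002)
})

test_that("the NOE+MT variant collapses the upfield pools into one", {
  sys4 <- make_pool_system("bsa_agarose", c(bsa = 6, agarose = 0.65))
  sch <- saturation_scheme()
  sched <- fix_schedule_small()
  z <- simulate_zspectrum(sys4, sch, sched)
  f <- cest_fit(z, sched, sch, make_pool_system("bsa_agarose"),
                variant = "noe_mt", n_starts = 1,
                t1_obs = sys4$pools[[1]]$t1)
  nm <- vapply(f$system$pools, `[[`, character(1), "name")
  expect_setequal(nm, c("water", "amide", "noe_mt"))
  expect_true(all(vapply(f$system$pools, `[[`, character(1), "klass") ==
                    "mobile"))
  expect_error(psr(f), "semisolid")
})

test_that("fit methods are coherent with the fitted object", {
  sys <- fix_two_pool()
  sch <- saturation_scheme()
  sched <- fix_schedule_small()
  z <- simulate_zspectrum(sys, sch, sched)
  f <- cest_fit(z, sched, sch, sys, variant = "two_pool", n_starts = 1)
  expect_equal(fitted(f) + residuals(f), f$z)
  expect_equal(nrow(predict(f)), length(f$z))
  sim <- simulate(f, nsim = 3, seed = 2)
  expect_equal(dim(sim), c(length(f$z), 3L))
  expect_false(identical(sim[, 1], sim[, 2]))
  V <- vcov(f)
  expect_true(all(diag(V) > 0))
  expect_output(print(f), "two_pool")
  expect_output(print(summary(f)), "PSR")
})

test_that("single-voxel image fitting reproduces the spectrum fit", {
  sys <- fix_two_pool()
  sch <- saturation_scheme()
  sched <- fix_schedule_small()
  z <- simulate_zspectrum(sys, sch, sched)
  arr <- array(z$z, dim = c(1, 1, length(z$z)))
  res <- fit_image(arr, sched, sch, sys, variant = "two_pool", n_starts = 1)
  f <- cest_fit(z, sched, sch, sys, variant = "two_pool", n_starts = 1)
  expect_equal(res$maps$psr[1, 1], psr(f))
  expect_equal(res$maps$MT.k[1, 1], unname(coef(f)["MT.k"]))
  expect_equal(res$failed, 0L)
  expect_error(fit_image(arr, sched, sch, sys,
                         mask = matrix(FALSE, 1, 1)), "empty")
  expect_error(fit_image(array(0.9, dim = c(1, 1, 3)), sched, sch, sys),
               "volumes")
})
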