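test_that("pool templates encode the intended study conditions", {
  s0 <- make_pool_system("bsa_agarose", c(bsa = 0, agarose = 0))
  m0r <- vapply(s0$pools, `[[`, numeric(1), "m0r")
  expect_equal(m0r[1], 1)
  expect_true(all(m0r[-1] == 0))

  sb <- make_pool_system("bsa_agarose", c(bsa = 6, agarose = 0.65))
  mt <- sb$pools[[which(vapply(sb$pools, `[[`, character(1), "klass") ==
                          "semisolid")]]
  expect_identical(mt$lineshape, "gaussian")

  s7 <- make_pool_system("brain_7pool")
  expect_length(s7$pools, 7L)
  mt7 <- s7$pools[[7L]]
  expect_identical(mt7$lineshape, "super_lorentzian")
  expect_equal(mt7$m0r, 0.20)

  s5 <- make_pool_system("brain_5pool_hydroxyl", c(bsa = 6, agarose = 0.65))
  hy <- s5$pools[[which(vapply(s5$pools, `[[`, character(1), "name") ==
                          "hydroxyl")]]
  expect_equal(hy$k, 2000)
  expect_error(make_pool_system("bsa_agarose", c(bsa = -1, agarose = 0)),
               ">= 0")
})

test_that("the BSA series has strictly increasing amide fractions", {
  lay <- phantom_layout()
  amide <- vapply(seq_len(nrow(lay$conc)), function(t)
    make_pool_system("bsa_agarose",
                     c(bsa = lay$conc$bsa[t],
                       agarose = lay$conc$agarose[t]))$pools[[2]]$m0r,
    numeric(1))
  expect_true(all(diff(amide) > 0))
})

test_that("field maps honour their bounds and are reproducible", {
  f0 <- generate_field_maps(c(12, 12), 0, 0, seed = 1)
  expect_true(all(f0$b0_ppm == 0))
  expect_true(all(f0$b1_scale == 1))
  f <- generate_field_maps(c(12, 12), 0.15, 0.1, seed = 7)
  expect_lte(max(abs(f$b0_ppm)), 0.15 + 1e-12)
  expect_equal(mean(f$b1_scale), 1, tolerance = 1e-12)
  f2 <- generate_field_maps(c(12, 12), 0.15, 0.1, seed = 7)
  expect_identical(f, f2)
  f3 <- generate_field_maps(c(12, 12), 0.15, 0.1, seed = 8)
  expect_false(identical(f$b0_ppm, f3$b0_ppm))
  # smoothness: adjacent differences below a generous polynomial bound
  h <- 2 / 11
  bound <- 0.15 * 7 * h
  expect_lt(max(abs(diff(f$b0_ppm))), bound)
  expect_lt(max(abs(t(diff(t(f$b0_ppm))))), bound)
})

test_that("noiseless phantom voxels equal their tube's analytic spectrum", {
  lay <- phantom_layout(shape = c(8, 8),
                        conc = data.frame(bsa = c(0, 9),
                                          agarose = c(0.65, 0.65)),
                        radius = 1)
  sch <- saturation_scheme()
  sched <- fix_schedule_small()
  ph <- generate_phantom_image(lay, sch, sched, noise_sd = 0, seed = 3)
  for (t in 1:2) {
    vox <- which(ph$labels == t, arr.ind = TRUE)[1, ]
    z_ref <- simulate_zspectrum(ph$systems[[t]], sch, sched)$z
    expect_equal(ph$data[vox[1], vox[2], ], z_ref)
  }
  expect_true(all(ph$data[ph$labels == 0 & row(ph$labels) > 0][1] == 0))
})

test_that("phantom generation is deterministic in the seed", {
  lay <- phantom_layout(shape = c(8, 8),
                        conc = data.frame(bsa = 3, agarose = 0.5),
                        radius = 1)
  sch <- saturation_scheme()
  sched <- fix_schedule_small()
  a <- generate_phantom_image(lay, sch, sched, noise_sd = 0.01, seed = 5)
  b <- generate_phantom_image(lay, sch, sched, noise_sd = 0.01, seed = 5)
  expect_identical(a$data, b$data)
  c2 <- generate_phantom_image(lay, sch, sched, noise_sd = 0.01, seed = 6)
  expect_false(identical(a$data, c2$data))
})

test_that("overlapping tubes are rejected", {
  expect_error(generate_phantom_image(
    phantom_layout(shape = c(8, 8),
                   conc = data.frame(bsa = c(1, 2), agarose = c(0, 0)),
                   radius = 4),
    saturation_scheme(), fix_schedule_small(), noise_sd = 0),
    "overlap")
})
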