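test_that("water-only relaxation matrix is the bare Bloch diagonal", {
  sys <- pool_system(fix_water(t1 = 2, t2 = 0.5))
  R <- relaxation_matrix(sys)
  expect_equal(dim(R), c(3L, 3L))
  expect_equal(unname(diag(R)), c(-2, -2, -0.5))
  expect_true(all(R[upper.tri(R)] == 0) && all(R[lower.tri(R)] == 0))
})

test_that("three-pool relaxation matrix has the water-centric row structure", {
  kSF <- 30; m0S <- 0.005; kMF <- 23; m0M <- 0.2
  sys <- pool_system(fix_water(),
                     pool("amide", 3.5, 1, 0.01, m0S, kSF),
                     pool("MT", -2.34, 1, 1e-5, m0M, kMF,
                          klass = "semisolid"))
  R <- relaxation_matrix(sys)
  expect_equal(dim(R), c(7L, 7L))
  kFS <- kSF * m0S; kFM <- kMF * m0M
  r1f <- 1 / 1.05
  expect_equal(R[3, ], c(0, 0, -r1f - kFS - kFM, 0, 0, kSF, kMF))
  expect_equal(R[1, 1], -1 / 0.07 - kFS)   # semisolid has no transverse term
  expect_equal(R[6, 6], -1 - kSF)
  expect_equal(R[7, 7], -1 - kMF)
  expect_equal(R[7, 3], kFM)
})

test_that("detailed balance: R_L applied to M0 leaves pure relaxation", {
  sys <- fix_three_pool()
  R <- relaxation_matrix(sys)
  v <- R %*% equilibrium_vector(sys)
  r1 <- vapply(sys$pools, function(p) p$m0r / p$t1, numeric(1))
  expect_equal(unname(v[c(3, 6, 7)]), -r1)
  expect_equal(unname(v[c(1, 2, 4, 5)]), rep(0, 4))
})

test_that("exchange alone conserves total z magnetization", {
  # emulate R1 = R2 = 0 with extremely slow relaxation
  sys <- pool_system(pool("water", 0, 1e9, 1e9, 1, 0),
                     pool("amide", 3.5, 1e9, 1e9, 0.01, 50),
                     pool("MT", 0, 1e9, 1e9, 0.15, 20, klass = "semisolid"))
  R <- relaxation_matrix(sys)
  zrows <- c(3, 6, 7)
  expect_equal(unname(colSums(R[zrows, zrows])), rep(0, 3),
               tolerance = 1e-7)
})

test_that("saturation matrix carries precession, B1 coupling and ppm scaling", {
  sys <- fix_three_pool()
  W0 <- saturation_matrix(sys, 3.5, 0)
  expect_equal(W0[7, 7], 0)                      # no RF, no semisolid term
  expect_equal(W0[4, 5], 0)                      # on-resonance amide
  expect_equal(W0[1, 2], 2 * pi * 446.95, tolerance = 1e-10) # 3.5 ppm, 127.7 MHz
  w1 <- 150
  W <- saturation_matrix(sys, 3.5, w1)
  expect_equal(W[2, 3], -w1); expect_equal(W[3, 2], w1)
  expect_equal(W[1, 2], W0[1, 2])                # precession unchanged by B1
  expect_lt(W[7, 7], 0)
  # ppm -> Hz conversion is linear in the scanner frequency
  sys2 <- sys; sys2$center_freq_mhz <- 2 * sys$center_freq_mhz
  expect_equal(saturation_matrix(sys2, 3.5, 0)[1, 2], 2 * W0[1, 2])
  expect_error(saturation_matrix(sys, 0, -1), "w1")
})

test_that("pool and pool-system invariants are enforced", {
  expect_error(pool("x", 0, t1 = -1), "t1")
  expect_error(pool("x", 0, m0r = -0.1), "m0r")
  expect_error(pool("x", 0, k = -5), "exchange")
  expect_error(pool_system(pool("notwater", 1, 1, 0.1, 1, 0)), "water")
  expect_error(pool_system(fix_water(), fix_water()), "duplicate|one water")
})
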