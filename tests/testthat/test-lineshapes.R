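test_that("on-resonance peak values match the closed forms", {
  t2 <- 1e-5
  expect_equal(lineshape_value("lorentzian", 0, t2), t2 / pi)
  expect_equal(lineshape_value("gaussian", 0, t2), t2 / sqrt(2 * pi))
})

test_that("super-Lorentzian agrees with a finer independent quadrature", {
  # oracle: adaptive-resolution Gauss-Legendre with 10x the nodes
  sl_oracle <- function(delta_hz, t2, n = 5120) {
    gl <- pracma::gaussLegendre(n, 0, pi / 2)
    den <- 3 * cos(gl$x)^2 - 1
    u <- 2 * pi * delta_hz * t2
    sum(gl$w * sin(gl$x) * sqrt(2 / pi) * (t2 / abs(den)) *
          exp(-2 * (u / den)^2))
  }
  for (d in c(1500, 5000, 10000, 50000)) {
    v <- lineshape_value("super_lorentzian", d, 1e-5)
    expect_equal(v, sl_oracle(d, 1e-5), tolerance = 1e-6)
  }
})

test_that("lineshapes are normalized over angular frequency and symmetric", {
  for (kind in c("lorentzian", "gaussian", "super_lorentzian")) {
    t2 <- 1e-5
    d <- seq(-20 / t2, 20 / t2, length.out = 200001)
    g <- lineshape_value(kind, d, t2)
    integral <- sum(g) * (d[2] - d[1]) * 2 * pi
    # the super-Lorentzian near-resonance interpolation replaces the
    # (integrable) on-resonance divergence by a finite cap, removing ~2%
    # of the total mass at T2 = 10 us; the analytic forms are exact
    tol <- if (kind == "super_lorentzian") 0.025 else 0.01
    expect_equal(integral, 1, tolerance = tol)
    # symmetry on a coarse probe set
    probe <- c(10, 640, 1500, 1e4, 1e5)
    expect_equal(lineshape_value(kind, probe, t2),
                 lineshape_value(kind, -probe, t2))
    expect_true(all(g >= 0))
  }
})

test_that("super-Lorentzian near-resonance interpolation is capped and tame", {
  t2 <- 1e-5
  inband <- lineshape_value("super_lorentzian", seq(0, 999, by = 111), t2)
  cap <- lineshape_value("super_lorentzian", 0, t2)
  expect_true(all(inband <= cap + 1e-16))
  # continuous across the cutoff
  expect_equal(lineshape_value("super_lorentzian", 999.9, t2),
               lineshape_value("super_lorentzian", 1000.1, t2),
               tolerance = 1e-3)
  # decays to zero far off resonance
  expect_lt(lineshape_value("super_lorentzian", 5e6, t2), 1e-12)
})

test_that("RF absorption rate is pi * w1^2 * g with the expected limits", {
  expect_identical(rf_absorption_rate(0, 500, 1e-5, "gaussian"), 0)
  r1 <- rf_absorption_rate(100, 1234, 1e-5, "super_lorentzian")
  r2 <- rf_absorption_rate(200, 1234, 1e-5, "super_lorentzian")
  expect_equal(r2 / r1, 4)
  w1 <- 2 * pi * 500
  expect_equal(rf_absorption_rate(w1, 0, 1e-5, "lorentzian"), w1^2 * 1e-5)
})

test_that("parameter-domain errors are raised", {
  expect_error(lineshape_value("lorentzian", 0, -1), "positive")
  expect_error(lineshape_value("lorentzian", Inf, 1e-5), "finite")
  expect_error(rf_absorption_rate(-1, 0, 1e-5), "non-negative")
})
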