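# Absorption lineshapes for the semisolid pool and the RF saturation rate they
# induce. All lineshapes g(Delta, T2) are absorption densities in seconds,
# normalized so that the integral over angular frequency (2*pi*Delta) is 1.

.cestmt_env <- new.env(parent = emptyenv())

#' Gyromagnetic ratio of the proton
#'
#' `gamma_hz` is gamma/2pi in Hz/T; `gamma_rad` is gamma in rad/s/T.
#' @name gamma
#' @keywords internal
NULL
.gamma_hz <- 42.577478518e6
.gamma_rad <- 2 * pi * 42.577478518e6

.lineshape_kinds <- c("lorentzian", "gaussian", "super_lorentzian")

# 512-point Gauss-Legendre rule on [0, pi/2], cached
.gl_theta <- function(n = 512L) {
  key <- paste0("gl", n)
  if (is.null(.cestmt_env[[key]])) {
    .cestmt_env[[key]] <- pracma::gaussLegendre(n, 0, pi / 2)
  }
  .cestmt_env[[key]]
}

# raw super-Lorentzian integral (no on-resonance handling), vectorized in delta
.sl_raw <- function(delta_hz, t2) {
  gl <- .gl_theta()
  cth2 <- cos(gl$x)^2
  denom <- 3 * cth2 - 1          # vanishes at the magic angle
  w <- gl$w * sin(gl$x)
  u <- 2 * pi * delta_hz * t2
  vapply(u, function(ui) {
    sum(w * sqrt(2 / pi) * (t2 / abs(denom)) * exp(-2 * (ui / denom)^2))
  }, numeric(1))
}

#' Absorption lineshape of a semisolid pool
#'
#' Computes the absorption lineshape g(Delta, T2) used to model RF saturation
#' of semisolid (macromolecular) protons. Three standard shapes are supported:
#' Lorentzian, Gaussian and super-Lorentzian (the orientation-averaged shape
#' used for semisolid pools in tissue). All are normalized so that the
#' integral of g over angular frequency equals one.
#'
#' The super-Lorentzian diverges on resonance; for `|delta_hz| < sl_cutoff_hz`
#' (default 1 kHz, the common quantitative-MT convention) the value is replaced
#' by a cubic polynomial interpolation anchored at samples in
#' `[sl_cutoff_hz, 1.5 * sl_cutoff_hz]`, capped at its zero-offset
#' extrapolation.
#'
#' @param kind One of `"lorentzian"`, `"gaussian"`, `"super_lorentzian"`.
#' @param delta_hz Frequency offset from the pool resonance, in Hz (vector ok).
#' @param t2 Transverse relaxation time of the pool, in seconds (`> 0`).
#' @param sl_cutoff_hz Near-resonance cutoff for the super-Lorentzian, Hz.
#' @return Absorption density in seconds, same length as `delta_hz`.
#' @examples
#' lineshape_value("lorentzian", 0, 1e-5)   # T2/pi
#' lineshape_value("gaussian", 0, 1e-5)     # T2/sqrt(2*pi)
#' @export
lineshape_value <- function(kind, delta_hz, t2,
                            sl_cutoff_hz = getOption("cestmt.sl_cutoff_hz", 1000)) {
  kind <- match.arg(kind, .lineshape_kinds)
  if (!is.numeric(t2) || length(t2) != 1L || !is.finite(t2) || t2 <= 0)
    stop("'t2' must be a single positive finite number")
  if (any(!is.finite(delta_hz)))
    stop("'delta_hz' must be finite")
  u <- 2 * pi * delta_hz * t2
  switch(kind,
    lorentzian = (t2 / pi) / (1 + u^2),
    gaussian = (t2 / sqrt(2 * pi)) * exp(-u^2 / 2),
    super_lorentzian = {
      out <- numeric(length(delta_hz))
      far <- abs(delta_hz) >= sl_cutoff_hz
      if (any(far)) out[far] <- .sl_raw(delta_hz[far], t2)
      if (any(!far)) {
        # cubic through four anchors in [cutoff, 1.5*cutoff]
        xa <- sl_cutoff_hz * c(1, 7 / 6, 8 / 6, 1.5)
        ya <- .sl_raw(xa, t2)
        cf <- solve(outer(xa, 0:3, `^`), ya)
        cap <- cf[1]  # extrapolated value at Delta = 0
        v <- drop(outer(abs(delta_hz[!far]), 0:3, `^`) %*% cf)
        out[!far] <- pmin(pmax(v, 0), cap)
      }
      out
    })
}

#' RF saturation rate of a semisolid pool
#'
#' The mean saturation rate `pi * omega1^2 * g(Delta, T2)` (in 1/s) experienced
#' by a semisolid pool under RF irradiation of amplitude `w1` (rad/s) at offset
#' `delta_hz` from its resonance.
#'
#' @param w1 RF amplitude omega1 = gamma*B1 in rad/s (`>= 0`).
#' @param delta_hz Offset from the pool resonance, Hz.
#' @param t2 Pool transverse relaxation time, s.
#' @param kind Lineshape kind, see [lineshape_value()].
#' @param ... Passed to [lineshape_value()].
#' @return Saturation rate in 1/s.
#' @export
rf_absorption_rate <- function(w1, delta_hz, t2, kind = "super_lorentzian", ...) {
  if (any(w1 < 0)) stop("'w1' must be non-negative")
  pi * w1^2 * lineshape_value(kind, delta_hz, t2, ...)
}
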