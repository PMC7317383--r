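# Pulsed saturation scheme and its continuous-wave-equivalent (CWEP)
# reduction. A shot is: saturation train (t_m) -> spoil -> free precession
# (t_s) -> on-resonance excitation (flip alpha; the excitation interval t_p is
# treated as instantaneous, its duration folded into t_r) -> readout/recovery
# free precession (t_r) -> spoil -> next shot.

#' Describe a pulsed CEST/MT saturation scheme
#'
#' @param n_pulses Number of saturation pulses per shot.
#' @param pulse_dur Duration of one saturation pulse, s.
#' @param duty_cycle Pulse duty cycle in (0, 1]; the pulse period is
#'   `pulse_dur / duty_cycle`.
#' @param pulse_shape `"gaussian"` (truncated at +/- 3 sigma, sigma = dur/6)
#'   or `"block"`.
#' @param sat_flip_deg Nominal per-pulse flip angle, degrees.
#' @param exc_flip_deg Excitation flip angle alpha, degrees.
#' @param shot_interval Shot-to-shot interval, s.
#' @param t_s Spoil/free-precession interval after saturation, s.
#' @param t_p Excitation pulse duration, s (folded into `t_r`).
#' @param t_r Readout + recovery interval, s; defaults to
#'   `shot_interval - t_m - t_s - t_p`.
#' @return A `saturation_scheme` object with the saturation duration `t_m =
#'   n_pulses * pulse_dur / duty_cycle` and all interval durations.
#' @examples
#' saturation_scheme()  # the fifty 20-ms pulse, 50% duty, 2.375-s shot default
#' @export
saturation_scheme <- function(n_pulses = 50L, pulse_dur = 0.020,
                              duty_cycle = 0.5,
                              pulse_shape = c("gaussian", "block"),
                              sat_flip_deg = 184, exc_flip_deg = 7,
                              shot_interval = 2.375, t_s = 0.010, t_p = 0,
                              t_r = NULL) {
  pulse_shape <- match.arg(pulse_shape)
  if (pulse_dur <= 0) stop("'pulse_dur' must be > 0")
  if (duty_cycle <= 0 || duty_cycle > 1) stop("'duty_cycle' must be in (0, 1]")
  t_m <- n_pulses * pulse_dur / duty_cycle
  if (is.null(t_r)) t_r <- shot_interval - t_m - t_s - t_p
  if (abs(t_m + t_s + t_p + t_r - shot_interval) > 1e-9)
    stop("t_m + t_s + t_p + t_r must equal shot_interval")
  if (any(c(t_m, t_s, t_p, t_r) < 0)) stop("all interval durations must be >= 0")
  structure(list(n_pulses = as.integer(n_pulses), pulse_dur = pulse_dur,
                 duty_cycle = duty_cycle, pulse_shape = pulse_shape,
                 sat_flip_deg = sat_flip_deg, exc_flip_deg = exc_flip_deg,
                 shot_interval = shot_interval, t_m = t_m, t_s = t_s,
                 t_p = t_p, t_r = t_r + t_p),
            class = "saturation_scheme")
}

#' @export
print.saturation_scheme <- function(x, ...) {
  cat(sprintf(
    "Saturation scheme: %d x %.0f-ms %s pulses, duty %.0f%%, flip %.0f deg\n",
    x$n_pulses, 1000 * x$pulse_dur, x$pulse_shape, 100 * x$duty_cycle,
    x$sat_flip_deg))
  cat(sprintf("  t_m = %.3f s, t_s = %.3f s, t_r = %.3f s, shot = %.3f s, alpha = %.0f deg\n",
              x$t_m, x$t_s, x$t_r, x$shot_interval, x$exc_flip_deg))
  invisible(x)
}

# analytic shape integrals over one pulse: s(t) in [0,1], returns
# list(int_s, int_s2) of integral s dt and integral s^2 dt
.pulse_shape_integrals <- function(shape, tau) {
  if (shape == "block") {
    list(int_s = tau, int_s2 = tau)
  } else { # gaussian, sigma = tau/6, truncated +/- 3 sigma
    sg <- tau / 6
    int_s <- sg * sqrt(2 * pi) * (stats::pnorm(3) - stats::pnorm(-3))
    int_s2 <- sg * sqrt(pi) * pracma::erf(3)
    list(int_s = int_s, int_s2 = int_s2)
  }
}

#' Continuous-wave-equivalent pulse amplitude
#'
#' Reduces a shaped saturation pulse train to the constant RF amplitude with
#' the same mean-square amplitude (average power) over the full pulse-train
#' period, gaps included. For a block pulse at 100% duty this equals the
#' nominal amplitude. Setting `mode = "amplitude"` matches the mean amplitude
#' instead.
#'
#' @param scheme A [saturation_scheme()].
#' @param sat_flip_deg Per-pulse flip angle, degrees (defaults to the
#'   scheme's).
#' @param mode `"power"` (RMS, default) or `"amplitude"` (mean).
#' @return omega1 in rad/s (`w1`), with the equivalent B1 in tesla as
#'   attribute `"b1_tesla"`.
#' @export
cwep_amplitude <- function(scheme, sat_flip_deg = scheme$sat_flip_deg,
                           mode = c("power", "amplitude")) {
  mode <- match.arg(mode)
  tau <- scheme$pulse_dur
  ints <- .pulse_shape_integrals(scheme$pulse_shape, tau)
  flip_rad <- sat_flip_deg * pi / 180
  w1_peak <- flip_rad / ints$int_s      # gamma * integral B1 dt = flip
  period <- tau / scheme$duty_cycle
  w1 <- if (mode == "power") {
    w1_peak * sqrt(ints$int_s2 / period)
  } else {
    w1_peak * ints$int_s / period
  }
  attr(w1, "b1_tesla") <- w1 / .gamma_rad
  w1
}

# sample the shaped pulse omega1(t) at midpoints of n steps over the pulse
.pulse_w1_samples <- function(scheme, sat_flip_deg, n) {
  tau <- scheme$pulse_dur
  tt <- (seq_len(n) - 0.5) * tau / n
  s <- if (scheme$pulse_shape == "block") rep(1, n)
       else exp(-(tt - tau / 2)^2 / (2 * (tau / 6)^2))
  ints <- .pulse_shape_integrals(scheme$pulse_shape, tau)
  (sat_flip_deg * pi / 180) / ints$int_s * s
}
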