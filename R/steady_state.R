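# Periodic steady state of the pulsed CEST/MT sequence under the CWEP
# approximation, and Z-spectrum simulation. One shot, starting immediately
# before the excitation pulse, is
#   excitation C -> free precession t_r -> spoil -> saturation t_m (R_L + W)
#   -> spoil -> free precession t_s
# and the reported magnetization is the fixed point of this affine cycle map.

# affine maps M -> A %*% M + c, composed right-to-left
.aff_compose <- function(f, g) list(A = f$A %*% g$A, c = drop(f$A %*% g$c) + f$c)
.aff_apply <- function(f, m) drop(f$A %*% m) + f$c
.aff_diag <- function(d) list(A = diag(d), c = numeric(length(d)))
.aff_free <- function(E, m0) list(A = E, c = drop(m0 - E %*% m0))

# per-parameter-set pieces of the cycle that do not depend on the offset
.cycle_parts <- function(system, scheme) {
  RL <- relaxation_matrix(system)
  m0 <- equilibrium_vector(system)
  Er <- .expm_t(RL, scheme$t_r)
  Es <- .expm_t(RL, scheme$t_s)
  list(RL = RL, m0 = m0,
       exc = .aff_diag(.excitation_diag(system, scheme$exc_flip_deg)),
       spoil = .aff_diag(.spoil_diag(system)),
       fr = .aff_free(Er, m0), fs = .aff_free(Es, m0))
}

# saturation interval affine for one (offset, w1)
.sat_affine <- function(parts, system, scheme, offset_ppm, w1) {
  X <- parts$RL + saturation_matrix(system, offset_ppm, w1)
  mss <- tryCatch(solve(X, drop(parts$RL %*% parts$m0)),
                  error = function(cond)
                    stop("degenerate saturation parameters: (R_L + W) is singular"))
  Em <- .expm_t(X, scheme$t_m)
  list(A = Em, c = drop(mss - Em %*% mss))
}

.cycle_affine <- function(parts, sat) {
  f <- parts$exc
  for (step in list(parts$fr, parts$spoil, sat, parts$spoil, parts$fs))
    f <- .aff_compose(step, f)
  f
}

#' Steady-state magnetization before excitation
#'
#' Solves the periodic steady state of the pulsed sequence for a single
#' (offset, amplitude) point, either in closed form (solving the linear
#' fixed-point equation of the cycle map) or by iterating the cycle from
#' equilibrium until convergence (the verification oracle).
#'
#' @param system A [pool_system()].
#' @param scheme A [saturation_scheme()].
#' @param offset_ppm RF offset relative to water, ppm.
#' @param w1 CWEP saturation amplitude, rad/s.
#' @param method `"closed_form"` or `"iterated"`.
#' @param tol,max_cycles Convergence control for `"iterated"`.
#' @return State vector immediately before the excitation pulse.
#' @export
steady_state_magnetization <- function(system, scheme, offset_ppm, w1,
                                       method = c("closed_form", "iterated"),
                                       tol = 1e-10, max_cycles = 10000L) {
  method <- match.arg(method)
  parts <- .cycle_parts(system, scheme)
  sat <- .sat_affine(parts, system, scheme, offset_ppm, w1)
  f <- .cycle_affine(parts, sat)
  if (method == "closed_form") {
    I <- diag(nrow(f$A))
    m <- tryCatch(solve(I - f$A, f$c), error = function(cond)
      stop("non-convergent sequence configuration: (I - cycle propagator) is singular"))
    return(m)
  }
  m <- parts$m0
  for (i in seq_len(max_cycles)) {
    m_new <- .aff_apply(f, m)
    if (max(abs(m_new - m)) <= tol * max(1, max(abs(m_new)))) return(m_new)
    m <- m_new
  }
  warning("cycle iteration did not converge within ", max_cycles, " cycles")
  m
}

# water-z steady state for every row of a schedule; returns raw (unnormalized)
# values. w1_by_flip caches the CWEP amplitude per distinct flip angle.
.raw_water_signal <- function(system, scheme, schedule, b0_ppm = 0,
                              b1_scale = 1) {
  parts <- .cycle_parts(system, scheme)
  I <- diag(length(parts$m0))
  zi_w <- .z_index(system)[1L]
  flips <- schedule$sat_flip_deg
  w1s <- vapply(sort(unique(flips)), function(fl)
    cwep_amplitude(scheme, fl) * b1_scale, numeric(1))
  names(w1s) <- as.character(sort(unique(flips)))
  vapply(seq_len(nrow(schedule)), function(i) {
    sat <- .sat_affine(parts, system, scheme,
                       schedule$offset_ppm[i] + b0_ppm,
                       w1s[[as.character(flips[i])]])
    f <- .cycle_affine(parts, sat)
    solve(I - f$A, f$c)[zi_w]
  }, numeric(1))
}

#' Simulate a Z-spectrum (closed-form CWEP model)
#'
#' Computes the normalized water signal for every non-reference point of the
#' schedule: the water z magnetization immediately before excitation, divided
#' by the value at the reference (800 ppm) point acquired with the same
#' saturation power.
#'
#' @param system A [pool_system()].
#' @param scheme A [saturation_scheme()].
#' @param schedule An [acq_schedule()].
#' @param b0_ppm B0 field offset added to every schedule offset, ppm.
#' @param b1_scale Relative B1 scale applied to the nominal amplitude.
#' @return A `zspectrum` data frame with columns `offset_ppm`,
#'   `sat_flip_deg`, `z`; reference signals are kept in attribute `"s0"`.
#' @export
simulate_zspectrum <- function(system, scheme, schedule, b0_ppm = 0,
                               b1_scale = 1) {
  raw <- .spectrum_raw(system, scheme, schedule, b0_ppm, b1_scale)
  .normalize_spectrum(schedule, raw)
}

.normalize_spectrum <- function(schedule, raw) {
  ref <- schedule$is_ref
  if (!any(ref)) stop("schedule has no reference (S0) point")
  s0 <- tapply(raw[ref], schedule$sat_flip_deg[ref], mean)
  z <- numeric(sum(!ref))
  sub <- schedule[!ref, , drop = FALSE]
  for (fl in unique(sub$sat_flip_deg)) {
    key <- as.character(fl)
    s0_fl <- if (key %in% names(s0)) s0[[key]] else mean(unlist(s0))
    z[sub$sat_flip_deg == fl] <- raw[!ref][sub$sat_flip_deg == fl] / s0_fl
  }
  out <- data.frame(offset_ppm = sub$offset_ppm,
                    sat_flip_deg = sub$sat_flip_deg, z = z)
  attr(out, "s0") <- s0
  class(out) <- c("zspectrum", "data.frame")
  out
}

#' @export
plot.zspectrum <- function(x, add = FALSE, col = 1, pch = 16, ...) {
  cest <- abs(x$offset_ppm) <= 6
  if (!add) {
    plot(x$offset_ppm[cest], x$z[cest], xlim = rev(range(x$offset_ppm[cest])),
         ylim = c(0, 1), xlab = "offset (ppm)", ylab = "Z", col = col,
         pch = pch, ...)
  } else {
    graphics::points(x$offset_ppm[cest], x$z[cest], col = col, pch = pch, ...)
  }
  invisible(x)
}

#' Simulate a Z-spectrum with the time-stepped Bloch-McConnell oracle
#'
#' Integrates the coupled differential equations with the shaped pulse train
#' sampled piecewise-constant at step `dt`, iterating shots from equilibrium
#' until the periodic steady state is reached (successive-shot change below
#' `tol`). Serves as the verification oracle for the closed-form CWEP model.
#'
#' @inheritParams simulate_zspectrum
#' @param dt Integration step within a saturation pulse, s (must be at most
#'   `pulse_dur / 50`).
#' @param tol Successive-shot convergence tolerance.
#' @param max_shots Shot cap; non-convergence raises an error reporting the
#'   residual.
#' @return A `zspectrum` data frame; attribute `"shots"` records the number
#'   of shots needed per point.
#' @export
simulate_zspectrum_timestepped <- function(system, scheme, schedule,
                                           b0_ppm = 0, b1_scale = 1,
                                           dt = scheme$pulse_dur / 100,
                                           tol = 1e-8, max_shots = 5000L) {
  if (dt > scheme$pulse_dur / 50 + 1e-12)
    stop("'dt' must be at most pulse_dur / 50")
  parts <- .cycle_parts(system, scheme)
  zi_w <- .z_index(system)[1L]
  nsub <- as.integer(ceiling(scheme$pulse_dur / dt))
  gap <- scheme$pulse_dur * (1 / scheme$duty_cycle - 1)
  flips <- schedule$sat_flip_deg
  raw <- numeric(nrow(schedule))
  shots_used <- integer(nrow(schedule))
  for (i in seq_len(nrow(schedule))) {
    w1t <- .pulse_w1_samples(scheme, flips[i], nsub) * b1_scale
    off <- schedule$offset_ppm[i] + b0_ppm
    # affine over one pulse period (shaped pulse then gap)
    per <- list(A = diag(length(parts$m0)), c = numeric(length(parts$m0)))
    h <- scheme$pulse_dur / nsub
    for (w1k in w1t) {
      X <- parts$RL + saturation_matrix(system, off, w1k)
      Ek <- .expm_t(X, h)
      mss <- solve(X, drop(parts$RL %*% parts$m0))
      per <- .aff_compose(list(A = Ek, c = drop(mss - Ek %*% mss)), per)
    }
    if (gap > 0) {
      Eg <- .expm_t(parts$RL, gap)
      per <- .aff_compose(.aff_free(Eg, parts$m0), per)
    }
    sat <- list(A = diag(length(parts$m0)), c = numeric(length(parts$m0)))
    for (k in seq_len(scheme$n_pulses)) sat <- .aff_compose(per, sat)
    f <- .cycle_affine(parts, sat)
    m <- parts$m0
    converged <- FALSE
    for (s in seq_len(max_shots)) {
      m_new <- .aff_apply(f, m)
      if (max(abs(m_new - m)) <= tol) { converged <- TRUE; m <- m_new; break }
      m <- m_new
    }
    if (!converged)
      stop(sprintf(
        "time-stepped simulation did not reach steady state within %d shots (residual %.3g)",
        max_shots, max(abs(.aff_apply(f, m) - m))))
    shots_used[i] <- s
    raw[i] <- m[zi_w]
  }
  out <- .normalize_spectrum(schedule, raw)
  attr(out, "shots") <- shots_used
  out
}
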