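# MTR*: the model-derived CEST effect size. The fitted concentration and
# exchange rate of a pool are inserted into an idealized two-pool simulation
# (water + that pool, fixed "ideal" relaxation values) and compared with an
# idealized one-pool water spectrum at the pool's resonance offset.

.mtrstar_ideal <- list(
  water = list(t1 = 1.0, t2 = 0.140),
  amide = list(t1 = 1.0, t2 = 0.010),
  noe = list(t1 = 1.0, t2 = 0.005))

#' Model-derived CEST effect size (MTR*)
#'
#' Simulates an idealized two-pool Z-spectrum (water plus the target pool,
#' using the supplied concentration and exchange rate but fixed idealized
#' relaxation values: water T1 = 1.0 s, T2 = 140 ms; amide T1 = 1 s,
#' T2 = 10 ms; NOE T1 = 1 s, T2 = 5 ms) and an idealized one-pool water
#' spectrum under the same saturation scheme, and returns their difference at
#' the pool resonance, normalized by the unsaturated signal.
#'
#' @param m0r Fitted relative concentration of the pool.
#' @param k Fitted exchange rate to water, 1/s.
#' @param shift_ppm Pool resonance offset, ppm (+3.5 amide, -3.5 NOE).
#' @param scheme A [saturation_scheme()]; its `sat_flip_deg` sets the power.
#' @param ideal `"amide"` or `"noe"` relaxation preset, or a list
#'   `list(t1 =, t2 =)` for the solute pool.
#' @param center_freq_mhz Scanner frequency, MHz.
#' @param percent Return percent (default) rather than fraction.
#' @return MTR* in percent (or fraction).
#' @export
mtr_star <- function(m0r, k, shift_ppm, scheme,
                     ideal = if (shift_ppm < 0) "noe" else "amide",
                     center_freq_mhz = 127.7, percent = TRUE) {
  if (!is.finite(m0r) || !is.finite(k)) stop("fitted parameters must be finite")
  if (is.character(ideal)) ideal <- .mtrstar_ideal[[match.arg(ideal, c("amide", "noe"))]]
  wat <- .mtrstar_ideal$water
  sched <- acq_schedule(c(shift_ppm, 800), scheme$sat_flip_deg)
  one <- pool_system(pool("water", 0, wat$t1, wat$t2, 1, 0),
                     center_freq_mhz = center_freq_mhz)
  two <- pool_system(pool("water", 0, wat$t1, wat$t2, 1, 0),
                     pool("solute", shift_ppm, ideal$t1, ideal$t2, m0r, k),
                     center_freq_mhz = center_freq_mhz)
  d <- simulate_zspectrum(one, scheme, sched)$z -
    simulate_zspectrum(two, scheme, sched)$z
  if (percent) 100 * d else d
}
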