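# The package's computational experiments: the seven-pool/three-pool
# underfitting simulation and the bootstrap CEST-offset-removal analysis of
# qMT parameter bias.

#' Seven-pool underfitting bias experiment
#'
#' Simulates a Z-spectrum from a detailed multi-pool truth (by default the
#' packaged seven-pool white-matter-like system) under the simulation
#' schedule (36 offsets between +/- 5 ppm at one power, MT offsets at
#' 7.5-100 ppm at two powers), then fits a reduced three-pool model (water,
#' amide, semisolid) and reports the fitted pool size ratio and amide MTR*
#' against their true values.
#'
#' @param truth A [pool_system()] truth; default the seven-pool template.
#' @param scheme A [saturation_scheme()]; default fifty 20-ms Gaussian
#'   pulses, 50% duty, 180 deg saturation flip, 7 deg excitation.
#' @param schedule An [acq_schedule()]; default [schedule_simulation()].
#' @param fit_template Reduced model template; default water + amide +
#'   semisolid taken from `truth`.
#' @param seed Fit start-jitter seed.
#' @param n_starts Optimization starts.
#' @return A `bias_report` list: `true`, `fitted` (named vectors including
#'   `psr` as a fraction and `amide_mtrstar` in percent), `bias`
#'   (fitted - true, absolute and relative), and the `fit`.
#' @export
run_seven_pool_bias <- function(truth = make_pool_system("brain_7pool"),
                                scheme = saturation_scheme(sat_flip_deg = 180,
                                                           exc_flip_deg = 7),
                                schedule = schedule_simulation(),
                                fit_template = NULL, seed = 1L,
                                n_starts = 3L) {
  z <- simulate_zspectrum(truth, scheme, schedule)
  nm <- .pool_names(truth)
  klass <- vapply(truth$pools, `[[`, character(1), "klass")
  if (is.null(fit_template)) {
    keep <- nm %in% c(nm[1L], "amide") | klass == "semisolid"
    fit_template <- pool_system(truth$pools[keep],
                                center_freq_mhz = truth$center_freq_mhz)
  }
  fit <- cest_fit(z, schedule, scheme, fit_template, variant = "cest_mt",
                  t1_obs = truth$pools[[1L]]$t1, seed = seed,
                  n_starts = n_starts)
  am <- truth$pools[[which(nm == "amide")]]
  mt <- truth$pools[[which(klass == "semisolid")[1L]]]
  cest_flip <- schedule$sat_flip_deg[!schedule$is_ref &
                                       abs(schedule$offset_ppm) <= 5][1L]
  mtr_scheme <- scheme; mtr_scheme$sat_flip_deg <- cest_flip
  true_v <- c(psr = mt$m0r,
              amide_mtrstar = mtr_star(am$m0r, am$k, am$shift_ppm, mtr_scheme,
                                       center_freq_mhz = truth$center_freq_mhz))
  fit_v <- c(psr = psr(fit),
             amide_mtrstar = fit_mtr_star(fit, "amide"))
  structure(list(true = true_v, fitted = fit_v,
                 bias = fit_v - true_v,
                 rel_bias = (fit_v - true_v) / true_v,
                 fit = fit, z = z),
            class = "bias_report")
}

#' @export
print.bias_report <- function(x, ...) {
  cat("Underfitting bias report\n")
  tab <- data.frame(true = x$true, fitted = x$fitted, bias = x$bias,
                    rel_bias_pct = 100 * x$rel_bias)
  print(tab, digits = 4)
  invisible(x)
}

#' Bootstrap CEST-offset-removal analysis
#'
#' Repeatedly fits a two-pool (water + semisolid) model to CEST+MT data
#' while removing `n_remove_per_iter` pseudo-random CEST offsets at a time
#' (nested subsets; MT offsets are always retained), producing one posterior
#' estimate per CEST-offset count, plus a qMT-only fit. The B0 posterior of
#' the full-data fit is used as the B0 prior for all reduced fits.
#'
#' @param z A `zspectrum` (or numeric vector) of the full schedule.
#' @param schedule The full [acq_schedule()].
#' @param scheme A [saturation_scheme()].
#' @param system Two-pool template (water + semisolid); extra pools are
#'   dropped automatically.
#' @param n_remove_per_iter Offsets removed per iteration.
#' @param iterations Number of removal iterations.
#' @param seed Seed for the pseudo-random removal (recorded in the output).
#' @param t1_obs,b1_scale,n_starts,noise_sd Passed to [cest_fit()].
#' @param boundary_ppm CEST/qMT boundary, ppm.
#' @return List with one element per subset (named by CEST-offset count,
#'   plus `"qmt_only"`): each has `n_cest`, `psr`, `k_mf`, `t2_m`, `b0_ppm`,
#'   `sd` (named), and the `fit`; attribute `"seed"` records the seed.
#' @export
bootstrap_offset_removal <- function(z, schedule, scheme, system,
                                     n_remove_per_iter = 10L,
                                     iterations = 5L, seed = 1L,
                                     t1_obs = NULL, b1_scale = 1,
                                     n_starts = 2L, boundary_ppm = 5,
                                     noise_sd = NULL) {
  zvec <- if (is.data.frame(z)) z$z else as.numeric(z)
  part <- schedule_partition(schedule, boundary_ppm)
  cest_rows <- which(part$cest)
  if (!length(cest_rows)) stop("no CEST offsets in the schedule")
  if (!any(part$qmt)) stop("no qMT offsets in the schedule")
  nonref <- which(!schedule$is_ref)
  rs <- .seeded_rng(seed)

  fit_rows <- function(rows_keep, b0_prior, start = NULL) {
    rows <- sort(unique(c(rows_keep, which(part$qmt), which(part$ref))))
    sch <- schedule[rows, , drop = FALSE]
    zz <- zvec[match(setdiff(rows, which(part$ref)), nonref)]
    cest_fit(zz, sch, scheme, system, variant = "two_pool", t1_obs = t1_obs,
             b1_scale = b1_scale, b0_prior = b0_prior, n_starts = n_starts,
             seed = seed, noise_sd = noise_sd, start = start)
  }
  # full-data fit provides the B0 image prior for the reduced fits
  full <- fit_rows(cest_rows, c(0, 0.1))
  b0_sd <- full$estimates$sd[full$estimates$name == "b0"]
  b0_prior <- c(full$b0_ppm,
                max(ifelse(length(b0_sd) && is.finite(b0_sd), b0_sd, 0.01),
                    0.005))
  # warm-start the reduced fits at the full-data mode (the B0 coordinate is
  # re-standardized against its new prior, whose mean is the full-data mode)
  warm <- full$phi
  b0pos <- which(full$par_table$name[full$par_table$free] == "b0")
  if (length(b0pos)) warm[b0pos] <- 0
  out <- list()
  keep <- cest_rows
  counts <- integer(0)
  for (it in seq_len(iterations)) {
    if (it > 1L) {
      drop_n <- min(n_remove_per_iter, length(keep) - 1L)
      keep <- sort(rs$sample(keep, length(keep) - drop_n))
    }
    fit <- if (it == 1L) full else fit_rows(keep, b0_prior, start = warm)
    cf <- stats::coef(fit)
    mt_name <- .pool_names(fit$system)[2L]
    sds <- stats::setNames(fit$estimates$sd, fit$estimates$name)
    out[[as.character(length(keep))]] <- list(
      n_cest = length(keep), psr = psr(fit),
      k_mf = unname(cf[paste0(mt_name, ".k")]),
      t2_m = unname(cf[paste0(mt_name, ".t2")]),
      b0_ppm = fit$b0_ppm, sd = sds,
      cest_offsets = schedule$offset_ppm[keep], fit = fit)
    counts <- c(counts, length(keep))
  }
  qfit <- fit_rows(integer(0), b0_prior, start = warm)
  cf <- stats::coef(qfit)
  mt_name <- .pool_names(qfit$system)[2L]
  out[["qmt_only"]] <- list(
    n_cest = 0L, psr = psr(qfit),
    k_mf = unname(cf[paste0(mt_name, ".k")]),
    t2_m = unname(cf[paste0(mt_name, ".t2")]),
    b0_ppm = qfit$b0_ppm,
    sd = stats::setNames(qfit$estimates$sd, qfit$estimates$name),
    cest_offsets = numeric(0), fit = qfit)
  attr(out, "seed") <- seed
  attr(out, "subset_sizes") <- counts
  out
}
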