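# Voxel-wise Bayesian (MAP) estimation of pool parameters from Z-spectra.
# The posterior is a Gaussian likelihood on the normalized signal times
# log-normal priors on positive pool parameters (concentration, exchange
# rate, T2, water T1) and a normal prior on the B0 shift. Optimization is in
# prior-standardized coordinates with multiple jittered starts; posterior
# standard deviations come from a Laplace approximation at the mode.

.default_prior_decades <- c(m0r = 1, k = 1, t2 = 0.5, t1 = 0.05)

# one row per potentially-free parameter; transform is log for all pool
# parameters, identity for b0 (ppm)
.build_par_table <- function(system, t1_obs = NULL, estimate_b0 = TRUE,
                             b0_prior = c(0, 0.1), priors = NULL,
                             fixed = NULL) {
  rows <- list()
  addp <- function(name, pool_idx, field, mean, sd_dec) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, pool = pool_idx, field = field, log = TRUE,
      mu = log(mean), s = sd_dec * log(10), value0 = mean)
  }
  for (j in seq_along(system$pools)) {
    p <- system$pools[[j]]
    if (j == 1L) {
      t1w <- if (!is.null(t1_obs)) t1_obs else p$t1
      addp("water.t2", 1L, "t2", p$t2, .default_prior_decades[["t2"]])
      addp("water.t1", 1L, "t1", t1w, .default_prior_decades[["t1"]])
    } else {
      addp(paste0(p$name, ".m0r"), j, "m0r", max(p$m0r, 1e-4),
           .default_prior_decades[["m0r"]])
      addp(paste0(p$name, ".k"), j, "k", max(p$k, 1), .default_prior_decades[["k"]])
      addp(paste0(p$name, ".t2"), j, "t2", p$t2, .default_prior_decades[["t2"]])
    }
  }
  tab <- do.call(rbind, rows)
  if (estimate_b0)
    tab <- rbind(tab, data.frame(name = "b0", pool = NA_integer_,
                                 field = "b0", log = FALSE,
                                 mu = b0_prior[1], s = b0_prior[2],
                                 value0 = b0_prior[1]))
  tab$free <- TRUE
  if (!is.null(priors)) {
    for (nm in names(priors)) {
      i <- match(nm, tab$name)
      if (is.na(i)) stop("prior override for unknown parameter '", nm, "'")
      pr <- priors[[nm]]
      mean_i <- pr[[1]]; sd_i <- pr[[2]]
      if (tab$log[i]) {
        tab$mu[i] <- log(mean_i); tab$s[i] <- sd_i * log(10)
      } else {
        tab$mu[i] <- mean_i; tab$s[i] <- sd_i
      }
      tab$value0[i] <- mean_i
      if (sd_i == 0) tab$free[i] <- FALSE
    }
  }
  if (!is.null(fixed)) {
    bad <- setdiff(fixed, tab$name)
    if (length(bad)) stop("unknown fixed parameter(s): ",
                          paste(bad, collapse = ", "))
    tab$free[tab$name %in% fixed] <- FALSE
  }
  if (!any(tab$free)) stop("degenerate configuration: no free parameters")
  tab
}

# natural parameter values for standardized coordinates phi (free params only)
.par_values <- function(tab, phi) {
  th <- tab$mu
  th[tab$free] <- tab$mu[tab$free] + tab$s[tab$free] * phi
  ifelse(tab$log, exp(th), th)
}

.apply_pars <- function(system, tab, values) {
  b0 <- 0
  for (i in seq_len(nrow(tab))) {
    if (tab$field[i] == "b0") { b0 <- values[i]; next }
    system$pools[[tab$pool[i]]][[tab$field[i]]] <- values[i]
  }
  list(system = system, b0 = b0)
}

# variant-specific reduction of the pool template
.variant_system <- function(system, variant) {
  nm <- .pool_names(system)
  klass <- vapply(system$pools, `[[`, character(1), "klass")
  switch(variant,
    cest_mt = system,
    two_pool = {
      if (!any(klass == "semisolid"))
        stop("two_pool variant requires a semisolid pool in the template")
      pool_system(system$pools[klass == "semisolid" | seq_along(nm) == 1L],
                  center_freq_mhz = system$center_freq_mhz)
    },
    noe_mt = {
      keep <- seq_along(nm) == 1L |
        (klass == "mobile" & vapply(system$pools, `[[`, numeric(1), "shift_ppm") > 0)
      comb_m0r <- sum(vapply(system$pools[!keep], `[[`, numeric(1), "m0r"))
      pool_system(c(system$pools[keep],
                    list(pool("noe_mt", -3.5, 1.0, 0.005,
                              max(comb_m0r, 0.01), 20))),
                  center_freq_mhz = system$center_freq_mhz)
    },
    stop("unknown variant '", variant, "'"))
}

#' Fit a multi-pool CEST/MT model to a Z-spectrum
#'
#' Maximum-a-posteriori estimation of pool parameters (per non-water pool:
#' relative concentration `m0r`, exchange rate `k`, `t2`; for water: `t2` and
#' `t1` with the T1 prior centred on the observed T1) plus an optional global
#' B0 shift, from a single normalized Z-spectrum. Posterior standard
#' deviations are obtained from a Laplace approximation at the mode.
#'
#' Variants: `"cest_mt"` fits the full template; `"two_pool"` fits water +
#' semisolid only; `"noe_mt"` replaces the NOE and semisolid pools by a
#' single mobile exchanging pool at -3.5 ppm (Lorentzian, no semisolid
#' lineshape); `"qmt_fix"` delegates to [fit_qmt_fix()].
#'
#' @param z A `zspectrum` data frame from [simulate_zspectrum()], or a
#'   numeric vector of normalized signals matching the non-reference rows of
#'   `schedule`.
#' @param schedule An [acq_schedule()] describing `z`.
#' @param scheme A [saturation_scheme()].
#' @param system A [pool_system()] template; its values are the prior means.
#' @param variant Analysis variant, see Details.
#' @param t1_obs Observed water T1 (s) used as the water T1 prior mean.
#' @param b1_scale Relative B1 transmit scale for this voxel.
#' @param estimate_b0 Estimate a global B0 shift (ppm).
#' @param b0_prior `c(mean, sd)` of the B0 prior, ppm.
#' @param priors Named list of prior overrides, each `c(mean, sd)` with sd in
#'   decades for log-domain parameters (sd 0 fixes the parameter).
#' @param fixed Character vector of parameter names to fix at their prior
#'   mean (e.g. `"MT.m0r"`).
#' @param noise_sd Gaussian noise sd of the normalized signal; `NULL`
#'   estimates it from the fit residual in a second pass.
#' @param n_starts Number of optimization starts (first at the prior mean,
#'   others jittered).
#' @param seed Seed for the start jitter.
#' @param maxit Iteration cap per start.
#' @param factr L-BFGS-B relative convergence tolerance (in units of machine
#'   epsilon).
#' @param start Optional start vector in prior-standardized coordinates (one
#'   value per free parameter; 0 is the prior mean) -- used to warm-start
#'   from a previous fit of the same model.
#' @param hessian Compute Laplace posterior sds at the mode (disable to
#'   save time when only point estimates are needed).
#' @return A `cest_fit` object; see [coef.cest_fit()], [summary.cest_fit()],
#'   [psr()], [fit_mtr_star()].
#' @export
cest_fit <- function(z, schedule, scheme, system,
                     variant = c("cest_mt", "two_pool", "noe_mt", "qmt_fix"),
                     t1_obs = NULL, b1_scale = 1, estimate_b0 = TRUE,
                     b0_prior = c(0, 0.1), priors = NULL, fixed = NULL,
                     noise_sd = NULL, n_starts = 3L, seed = 1L,
                     maxit = 400L, factr = 5e8, start = NULL,
                     hessian = TRUE) {
  variant <- match.arg(variant)
  if (variant == "qmt_fix")
    return(fit_qmt_fix(z, schedule, scheme, system, t1_obs = t1_obs,
                       b1_scale = b1_scale, estimate_b0 = estimate_b0,
                       b0_prior = b0_prior, priors = priors,
                       noise_sd = noise_sd, n_starts = n_starts, seed = seed,
                       maxit = maxit))
  zvec <- if (is.data.frame(z)) z$z else as.numeric(z)
  nonref <- !schedule$is_ref
  if (length(zvec) != sum(nonref))
    stop("z has ", length(zvec), " points but the schedule has ",
         sum(nonref), " non-reference rows")
  model_sys <- .variant_system(system, variant)
  tab <- .build_par_table(model_sys, t1_obs, estimate_b0, b0_prior, priors,
                          fixed)
  nfree <- sum(tab$free)
  if (sum(nonref) < nfree)
    warning("fewer data points (", sum(nonref), ") than free parameters (",
            nfree, ")")

  ctx <- .spectrum_context(model_sys, scheme, schedule, b1_scale)
  model_z <- function(values) {
    ap <- .apply_pars(model_sys, tab, values)
    .spectrum_eval(ctx, ap$system, ap$b0)
  }
  make_obj <- function(sigma) function(phi) {
    zh <- tryCatch(model_z(.par_values(tab, phi)), error = function(cond) NULL)
    if (is.null(zh) || any(!is.finite(zh))) return(1e10)
    0.5 * sum(((zvec - zh) / sigma)^2) + 0.5 * sum(phi^2)
  }
  run_starts <- function(obj, starts) {
    best <- NULL
    for (s0 in starts) {
      fit <- tryCatch(
        stats::optim(s0, obj, method = "L-BFGS-B", lower = -10, upper = 10,
                     control = list(maxit = maxit, factr = factr,
                                    pgtol = 1e-4,
                                    ndeps = rep(1e-5, length(s0)))),
        error = function(cond) NULL)
      if (!is.null(fit) && (is.null(best) || fit$value < best$value))
        best <- fit
    }
    if (is.null(best)) stop("all optimization starts failed")
    best
  }
  rs <- .seeded_rng(seed)
  starts <- c(list(if (is.null(start)) rep(0, nfree) else {
                if (length(start) != nfree)
                  stop("'start' must have one value per free parameter")
                start
              }),
              lapply(seq_len(max(0L, n_starts - 1L)), function(i)
                rs$rnorm(nfree, 0, 0.5)))
  # continuation: optimize under a softened noise model first, then refine at
  # the target noise level from that mode -- avoids likelihood-dominated local
  # traps when the model is (deliberately or not) misspecified
  sigma <- if (is.null(noise_sd)) 0.01 else noise_sd
  sigma0 <- max(sigma, 0.01)
  best <- run_starts(make_obj(sigma0), starts)
  if (sigma < sigma0)
    best <- run_starts(make_obj(sigma), list(best$par))
  if (is.null(noise_sd)) {
    zh <- model_z(.par_values(tab, best$par))
    sigma <- max(sqrt(mean((zvec - zh)^2)), 2e-4)
    best <- run_starts(make_obj(sigma), list(best$par))
  }
  phi <- best$par
  values <- .par_values(tab, phi)
  zh <- model_z(values)
  rms <- sqrt(mean((zvec - zh)^2))
  # Laplace sds at the mode
  H <- if (hessian)
    tryCatch(stats::optimHess(phi, make_obj(sigma),
                              control = list(ndeps = rep(1e-4, nfree))),
             error = function(cond) NULL)
  else NULL
  sd_phi <- rep(NA_real_, nfree)
  cov_phi <- NULL
  if (!is.null(H)) {
    cov_phi <- tryCatch(solve(H), error = function(cond) NULL)
    if (!is.null(cov_phi) && all(diag(cov_phi) > 0))
      sd_phi <- sqrt(diag(cov_phi))
  }
  est <- data.frame(name = tab$name, value = values, sd = NA_real_,
                    prior_mean = tab$value0,
                    free = tab$free, stringsAsFactors = FALSE)
  sd_theta <- tab$s[tab$free] * sd_phi
  est$sd[tab$free] <- ifelse(tab$log[tab$free],
                             values[tab$free] * sd_theta, sd_theta)
  est$sd[!tab$free] <- 0
  ap <- .apply_pars(model_sys, tab, values)
  structure(list(
    estimates = est, system = ap$system, template = model_sys,
    b0_ppm = ap$b0, sigma = sigma, rms = rms, value = best$value,
    convergence = best$convergence %in% c(0L, 52L) &&
      (!hessian || !anyNA(sd_phi)),
    counts = best$counts, cov_phi = cov_phi, par_table = tab, phi = phi,
    z = zvec, schedule = schedule, scheme = scheme, b1_scale = b1_scale,
    variant = variant, call = match.call()),
    class = "cest_fit")
}

#' Two-stage qMT-Fix analysis
#'
#' Stage 1 fits a two-pool (water + semisolid) model using only the
#' `|offset| > 5 ppm` (qMT) points; stage 2 fixes the water and semisolid
#' parameters at their stage-1 estimates and fits the CEST pools on the full
#' schedule.
#'
#' @inheritParams cest_fit
#' @param boundary_ppm CEST/qMT boundary, ppm.
#' @return A `cest_fit` (stage 2) with the stage-1 fit in `$stage1`.
#' @export
fit_qmt_fix <- function(z, schedule, scheme, system, t1_obs = NULL,
                        b1_scale = 1, estimate_b0 = TRUE, b0_prior = c(0, 0.1),
                        priors = NULL, noise_sd = NULL, n_starts = 3L,
                        seed = 1L, maxit = 300L, boundary_ppm = 5) {
  part <- schedule_partition(schedule, boundary_ppm)
  if (!any(part$qmt)) stop("no qMT points (|offset| > ", boundary_ppm,
                           " ppm) in the schedule")
  zvec <- if (is.data.frame(z)) z$z else as.numeric(z)
  keep <- part$qmt[!schedule$is_ref] # indices within non-reference rows
  sch1 <- schedule[part$qmt | part$ref, , drop = FALSE]
  s1 <- cest_fit(zvec[keep], sch1, scheme, system, variant = "two_pool",
                 t1_obs = t1_obs, b1_scale = b1_scale,
                 estimate_b0 = estimate_b0, b0_prior = b0_prior,
                 noise_sd = noise_sd, n_starts = n_starts, seed = seed,
                 maxit = maxit)
  # fix water + semisolid at stage-1 posterior means
  klass <- vapply(system$pools, `[[`, character(1), "klass")
  mt_name <- .pool_names(system)[klass == "semisolid"][1L]
  c1 <- stats::coef(s1)
  fix_priors <- list(
    "water.t2" = c(unname(c1["water.t2"]), 0),
    "water.t1" = c(unname(c1["water.t1"]), 0))
  for (f in c("m0r", "k", "t2")) {
    s1name <- paste0(mt_name, ".", f)
    fix_priors[[s1name]] <- c(unname(c1[s1name]), 0)
  }
  if (estimate_b0) b0_prior <- c(s1$b0_ppm, max(s1$estimates$sd[
    s1$estimates$name == "b0"], 0.01))
  s2 <- cest_fit(zvec, schedule, scheme, system, variant = "cest_mt",
                 t1_obs = t1_obs, b1_scale = b1_scale,
                 estimate_b0 = estimate_b0, b0_prior = b0_prior,
                 priors = utils::modifyList(
                   if (is.null(priors)) list() else priors, fix_priors),
                 noise_sd = noise_sd, n_starts = n_starts, seed = seed,
                 maxit = maxit)
  s2$stage1 <- s1
  s2$variant <- "qmt_fix"
  s2
}
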