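# Standard modelling methods for cest_fit objects.

#' @export
print.cest_fit <- function(x, ...) {
  cat(sprintf("Multi-pool CEST/MT fit (variant '%s', %d points, %d free parameters)\n",
              x$variant, length(x$z), sum(x$par_table$free)))
  cat(sprintf("  residual RMS %.4g, noise sd %.4g, B0 shift %.4f ppm%s\n",
              x$rms, x$sigma, x$b0_ppm,
              if (x$convergence) "" else "  [NOT CONVERGED]"))
  print(utils::head(summary(x)$table, 25), digits = 4, row.names = FALSE)
  invisible(x)
}

#' Summarize a cest_fit
#'
#' @param object A `cest_fit`.
#' @param ... Unused.
#' @return A `summary.cest_fit` with the posterior mean/sd table, the pool
#'   size ratio of any semisolid pool, residual RMS and B0 shift.
#' @export
summary.cest_fit <- function(object, ...) {
  tabout <- data.frame(parameter = object$estimates$name,
                       mean = object$estimates$value,
                       sd = object$estimates$sd,
                       prior_mean = object$estimates$prior_mean,
                       fitted = object$estimates$free)
  klass <- vapply(object$system$pools, `[[`, character(1), "klass")
  psr_val <- if (any(klass == "semisolid"))
    object$system$pools[[which(klass == "semisolid")[1L]]]$m0r else NA_real_
  structure(list(table = tabout, psr = psr_val, rms = object$rms,
                 sigma = object$sigma, b0_ppm = object$b0_ppm,
                 convergence = object$convergence, variant = object$variant),
            class = "summary.cest_fit")
}

#' @export
print.summary.cest_fit <- function(x, ...) {
  cat(sprintf("CEST/MT fit summary (variant '%s')\n", x$variant))
  print(x$table, digits = 4, row.names = FALSE)
  if (!is.na(x$psr)) cat(sprintf("PSR: %.2f%%\n", 100 * x$psr))
  cat(sprintf("Residual RMS %.4g; B0 %.4f ppm; %s\n", x$rms, x$b0_ppm,
              if (x$convergence) "converged" else "not converged"))
  invisible(x)
}

#' @export
coef.cest_fit <- function(object, ...) {
  stats::setNames(object$estimates$value, object$estimates$name)
}

#' @export
vcov.cest_fit <- function(object, ...) {
  tab <- object$par_table
  if (is.null(object$cov_phi)) return(NULL)
  values <- object$estimates$value[tab$free]
  d <- tab$s[tab$free] * ifelse(tab$log[tab$free], values, 1)
  V <- diag(d) %*% object$cov_phi %*% diag(d)
  dimnames(V) <- list(tab$name[tab$free], tab$name[tab$free])
  V
}

#' @export
fitted.cest_fit <- function(object, ...) {
  simulate_zspectrum(object$system, object$scheme, object$schedule,
                     b0_ppm = object$b0_ppm, b1_scale = object$b1_scale)$z
}

#' @export
residuals.cest_fit <- function(object, ...) object$z - fitted(object)

#' Predict the fitted Z-spectrum, optionally on a new schedule
#'
#' @param object A `cest_fit`.
#' @param schedule Optional [acq_schedule()]; defaults to the fitted one.
#' @param ... Unused.
#' @return A `zspectrum` data frame.
#' @export
predict.cest_fit <- function(object, schedule = object$schedule, ...) {
  simulate_zspectrum(object$system, object$scheme, schedule,
                     b0_ppm = object$b0_ppm, b1_scale = object$b1_scale)
}

#' Simulate noisy replicate spectra from a fitted model
#'
#' @param object A `cest_fit`.
#' @param nsim Number of replicates.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return Matrix with one column per replicate.
#' @export
simulate.cest_fit <- function(object, nsim = 1, seed = NULL, ...) {
  zh <- fitted(object)
  rs <- .seeded_rng(if (is.null(seed)) 1L else seed)
  matrix(rep(zh, nsim) + rs$rnorm(length(zh) * nsim, 0, object$sigma),
         ncol = nsim)
}

#' @export
plot.cest_fit <- function(x, ...) {
  o <- order(x$schedule$offset_ppm[!x$schedule$is_ref])
  cest <- abs(x$schedule$offset_ppm[!x$schedule$is_ref][o]) <= 6
  off <- x$schedule$offset_ppm[!x$schedule$is_ref][o][cest]
  plot(off, x$z[o][cest], xlim = rev(range(off)), ylim = c(0, 1),
       xlab = "offset (ppm)", ylab = "Z", pch = 16, ...)
  graphics::lines(off, fitted(x)[o][cest], col = 2, lwd = 2)
  graphics::legend("bottomright", c("data", "fit"), pch = c(16, NA),
                   lty = c(NA, 1), col = c(1, 2), bty = "n")
  invisible(x)
}

#' Pool size ratio of a fit
#'
#' The fitted semisolid-to-water pool size ratio (PSR), i.e. the relative
#' equilibrium magnetization of the semisolid pool.
#'
#' @param fit A `cest_fit`.
#' @param percent Return percent (default fraction).
#' @return PSR as a fraction (or percent).
#' @export
psr <- function(fit, percent = FALSE) {
  klass <- vapply(fit$system$pools, `[[`, character(1), "klass")
  if (!any(klass == "semisolid")) stop("fit has no semisolid pool")
  v <- fit$system$pools[[which(klass == "semisolid")[1L]]]$m0r
  if (percent) 100 * v else v
}

#' MTR* of a fitted CEST pool
#'
#' Inserts the fitted concentration and exchange rate of a pool into the
#' idealized two-pool simulation of [mtr_star()].
#'
#' @param fit A `cest_fit`.
#' @param pool Pool name (e.g. `"amide"`, `"noe"`).
#' @param ... Passed to [mtr_star()].
#' @return MTR* in percent.
#' @export
fit_mtr_star <- function(fit, pool = "amide", ...) {
  nm <- .pool_names(fit$system)
  if (!pool %in% nm) stop("no pool named '", pool, "' in the fit")
  p <- fit$system$pools[[which(nm == pool)]]
  mtr_star(p$m0r, p$k, p$shift_ppm, fit$scheme,
           center_freq_mhz = fit$system$center_freq_mhz, ...)
}
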