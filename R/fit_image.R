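# Voxel-wise fitting over an image stack.

#' Fit a pool model voxel-wise over a Z-spectrum image stack
#'
#' Runs [cest_fit()] in every masked voxel of a 3D (x, y, spectral) or 4D
#' (x, y, z, spectral) stack of normalized signals, taking the per-voxel
#' water T1 prior from `t1_map` and the per-voxel B1 scale from `b1_map`.
#'
#' @param data Array whose last dimension indexes the non-reference schedule
#'   points, in schedule order.
#' @param schedule An [acq_schedule()].
#' @param scheme A [saturation_scheme()].
#' @param system A [pool_system()] template.
#' @param mask Logical array matching the spatial grid; default: voxels with
#'   any non-zero signal.
#' @param t1_map,b1_map Optional per-voxel water T1 (s) / relative B1 maps.
#' @param b0_map Optional per-voxel B0 prior mean map (ppm).
#' @param ... Passed to [cest_fit()] (variant, priors, seeds, ...).
#' @return List: `maps` (named list of posterior-mean arrays, one per free
#'   parameter plus `psr`, `rms`), `sd_maps`, `mask`, and `failed` (voxel
#'   count where the fit errored).
#' @export
fit_image <- function(data, schedule, scheme, system, mask = NULL,
                      t1_map = NULL, b1_map = NULL, b0_map = NULL, ...) {
  dd <- dim(data)
  nspec <- dd[length(dd)]
  spatial <- dd[-length(dd)]
  if (nspec != sum(!schedule$is_ref))
    stop("stack has ", nspec, " volumes but the schedule has ",
         sum(!schedule$is_ref), " non-reference rows")
  dm <- matrix(data, prod(spatial), nspec)
  if (is.null(mask)) mask <- array(rowSums(abs(dm)) > 0, dim = spatial)
  if (!all(dim(mask) == spatial)) stop("mask grid does not match data")
  vox <- which(as.logical(mask))
  if (!length(vox)) stop("mask is empty")
  chk <- function(m, nm) {
    if (!is.null(m) && !all(dim(m) == spatial))
      stop(nm, " grid does not match data")
    m
  }
  t1_map <- chk(t1_map, "t1_map"); b1_map <- chk(b1_map, "b1_map")
  b0_map <- chk(b0_map, "b0_map")

  maps <- sd_maps <- NULL
  failed <- 0L
  store <- function(arrlist, i, vals) {
    for (nm in names(vals)) arrlist[[nm]][i] <- vals[[nm]]
    arrlist
  }
  for (i in vox) {
    args <- list(z = dm[i, ], schedule = schedule, scheme = scheme,
                 system = system, ...)
    if (!is.null(t1_map)) args$t1_obs <- t1_map[i]
    if (!is.null(b1_map)) args$b1_scale <- b1_map[i]
    if (!is.null(b0_map)) args$b0_prior <- c(b0_map[i], 0.1)
    fit <- tryCatch(do.call(cest_fit, args), error = function(cond) NULL)
    if (is.null(fit)) { failed <- failed + 1L; next }
    est <- stats::setNames(fit$estimates$value, fit$estimates$name)
    sds <- stats::setNames(fit$estimates$sd, fit$estimates$name)
    klass <- vapply(fit$system$pools, `[[`, character(1), "klass")
    extra <- c(rms = fit$rms,
               psr = if (any(klass == "semisolid")) psr(fit) else NA_real_)
    if (is.null(maps)) {
      mk <- function() array(NA_real_, dim = spatial)
      maps <- stats::setNames(lapply(seq_along(c(est, extra)), function(j) mk()),
                              names(c(est, extra)))
      sd_maps <- stats::setNames(lapply(seq_along(est), function(j) mk()),
                                 names(est))
    }
    maps <- store(maps, i, as.list(c(est, extra)))
    sd_maps <- store(sd_maps, i, as.list(sds))
  }
  list(maps = maps, sd_maps = sd_maps, mask = mask, failed = failed)
}
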