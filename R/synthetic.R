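# Synthetic pool systems and digital phantoms. The templates encode the two
# study conditions the package is designed around: a BSA/agarose tube phantom
# series (amide + NOE scale with BSA, a Gaussian-lineshape semisolid pool
# scales with agarose) and a white-matter-like seven-pool brain spectrum
# (water, amide, creatine/guanidinium, three relayed-NOE pools, and a
# super-Lorentzian semisolid pool with a 20% pool size ratio).

# literature-style white-matter values; the amide fraction is calibrated so
# that the idealized-model MTR* of the true amide parameters is 11.0% under
# the simulation scheme (180 deg saturation flip)
.brain_7pool_params <- list(
  water    = list(shift = 0,     t1 = 1.05, t2 = 0.070, m0r = 1,       k = 0),
  amide    = list(shift = 3.5,   t1 = 1.0,  t2 = 0.010, m0r = 0.00530, k = 30),
  creatine = list(shift = 2.0,   t1 = 1.0,  t2 = 0.010, m0r = 0.0010,  k = 1000),
  noe1     = list(shift = -1.75, t1 = 1.0,  t2 = 0.005, m0r = 0.0030,  k = 16),
  noe2     = list(shift = -2.5,  t1 = 1.0,  t2 = 0.005, m0r = 0.0040,  k = 16),
  noe3     = list(shift = -3.5,  t1 = 1.0,  t2 = 0.005, m0r = 0.0080,  k = 16),
  MT       = list(shift = -2.34, t1 = 1.0,  t2 = 1.0e-5, m0r = 0.20,   k = 23))

# linear concentration -> parameter calibration for the tube phantoms
# (synthetic convention: the paper reports no calibration, only monotone
# association; 9% w/v BSA maps to an amide fraction comparable to the brain
# template's)
.conc_map <- list(
  amide_per_bsa = 6e-4,    # m0r per % w/v BSA
  noe_per_bsa = 1.2e-3,
  hydroxyl_per_bsa = 8e-4,
  mt_per_agar = 0.015,     # m0r per % w/v agarose
  r1_base = 0.33, r1_per_bsa = 0.02, r1_per_agar = 0.05,   # 1/s
  r2_base = 0.5, r2_per_bsa = 0.25, r2_per_agar = 5.0)     # 1/s

#' Pool-system templates for the packaged study conditions
#'
#' * `"bsa_agarose"`: water + amide (+3.5 ppm) + relayed NOE (-3.5 ppm) +
#'   Gaussian-lineshape semisolid pool, with pool fractions and relaxation
#'   scaled linearly with the BSA / agarose concentrations (% w/v).
#' * `"brain_7pool"`: the white-matter-like seven-pool spectrum (water,
#'   amide, creatine, three relayed-NOE pools, super-Lorentzian semisolid
#'   with PSR = 20%).
#' * `"brain_5pool_hydroxyl"`: the tube-phantom four-pool system plus a
#'   fast-exchanging hydroxyl pool (+1.0 ppm, 2000 1/s).
#'
#' @param template Template name.
#' @param conc For the phantom templates, `c(bsa = , agarose = )` in % w/v.
#' @param center_freq_mhz Scanner frequency, MHz.
#' @return A [pool_system()].
#' @export
make_pool_system <- function(template = c("bsa_agarose", "brain_7pool",
                                          "brain_5pool_hydroxyl"),
                             conc = c(bsa = 6, agarose = 0.65),
                             center_freq_mhz = 127.7) {
  template <- match.arg(template)
  if (template == "brain_7pool") {
    pl <- lapply(names(.brain_7pool_params), function(nm) {
      p <- .brain_7pool_params[[nm]]
      pool(nm, p$shift, p$t1, p$t2, p$m0r, p$k,
           klass = if (nm == "MT") "semisolid" else "mobile",
           lineshape = "super_lorentzian")
    })
    return(pool_system(pl, center_freq_mhz = center_freq_mhz))
  }
  bsa <- unname(conc[["bsa"]]); agar <- unname(conc[["agarose"]])
  if (bsa < 0 || agar < 0) stop("concentrations must be >= 0")
  cm <- .conc_map
  t1f <- 1 / (cm$r1_base + cm$r1_per_bsa * bsa + cm$r1_per_agar * agar)
  t2f <- 1 / (cm$r2_base + cm$r2_per_bsa * bsa + cm$r2_per_agar * agar)
  pl <- list(
    pool("water", 0, t1f, t2f, 1, 0),
    pool("amide", 3.5, 1.0, 0.010, cm$amide_per_bsa * bsa, 30),
    pool("noe", -3.5, 1.0, 0.005, cm$noe_per_bsa * bsa, 16))
  if (template == "brain_5pool_hydroxyl")
    pl <- c(pl, list(pool("hydroxyl", 1.0, 1.0, 0.010,
                          cm$hydroxyl_per_bsa * bsa, 2000)))
  pl <- c(pl, list(pool("MT", 0, 1.0, 1.2e-5, cm$mt_per_agar * agar, 40,
                        klass = "semisolid", lineshape = "gaussian")))
  pool_system(pl, center_freq_mhz = center_freq_mhz)
}

#' Tube phantom layout
#'
#' @param shape Image grid `c(nx, ny)`.
#' @param conc Data frame with one row per tube and columns `bsa`,
#'   `agarose` (% w/v); defaults to the variable-BSA series (BSA 0, 1.8,
#'   3.6, 6, 7.2, 9% w/v, agarose 0.65% except 0.78% for the 6% tube).
#' @param radius Tube radius in voxels.
#' @return A `phantom_layout` with tube centers, radii and concentrations.
#' @export
phantom_layout <- function(shape = c(24L, 24L),
                           conc = data.frame(
                             bsa = c(0, 1.8, 3.6, 6, 7.2, 9),
                             agarose = c(0.65, 0.65, 0.65, 0.78, 0.65, 0.65)),
                           radius = max(1, floor(min(shape) / 10))) {
  if (any(conc < 0)) stop("concentrations must be >= 0")
  n <- nrow(conc)
  ncol_t <- ceiling(sqrt(n)); nrow_t <- ceiling(n / ncol_t)
  cx <- round(shape[1] * (2 * (((seq_len(n) - 1) %% ncol_t) + 1) - 1) /
                (2 * ncol_t))
  cy <- round(shape[2] * (2 * (((seq_len(n) - 1) %/% ncol_t) + 1) - 1) /
                (2 * nrow_t))
  structure(list(shape = as.integer(shape),
                 centers = cbind(cx, cy), radius = radius, conc = conc),
            class = "phantom_layout")
}

# integer label image: 0 background, tube index elsewhere
.layout_labels <- function(layout) {
  lab <- matrix(0L, layout$shape[1], layout$shape[2])
  for (t in seq_len(nrow(layout$conc))) {
    cx <- layout$centers[t, 1]; cy <- layout$centers[t, 2]
    for (i in max(1, cx - layout$radius):min(layout$shape[1], cx + layout$radius))
      for (j in max(1, cy - layout$radius):min(layout$shape[2], cy + layout$radius))
        if ((i - cx)^2 + (j - cy)^2 <= layout$radius^2) {
          if (lab[i, j] != 0L) stop("tubes overlap")
          lab[i, j] <- t
        }
  }
  lab
}

#' Smooth synthetic B0 / B1 field maps
#'
#' Low-order 2D polynomial fields with random coefficients: the B0 map is
#' bounded by `+/- b0_amplitude_ppm`, the B1 map is a relative transmit
#' scale with mean 1 bounded within `b1_range`.
#'
#' @param shape `c(nx, ny)`.
#' @param b0_amplitude_ppm Maximum B0 offset amplitude, ppm.
#' @param b1_range Half-width of the B1 scale variation (e.g. 0.1 for
#'   roughly 0.9-1.1).
#' @param seed Integer seed (deterministic output).
#' @return List with matrices `b0_ppm` and `b1_scale`.
#' @export
generate_field_maps <- function(shape = c(24L, 24L), b0_amplitude_ppm = 0.1,
                                b1_range = 0.1, seed = 1L) {
  if (b0_amplitude_ppm < 0 || b1_range < 0) stop("amplitudes must be >= 0")
  rs <- .seeded_rng(seed)
  x <- seq(-1, 1, length.out = shape[1])
  y <- seq(-1, 1, length.out = shape[2])
  basis <- function(cf) outer(x, y, function(u, v)
    cf[1] * u + cf[2] * v + cf[3] * u * v + cf[4] * (u^2 - 0.5) +
      cf[5] * (v^2 - 0.5))
  poly_field <- function(amp) {
    f <- basis(rs$runif(5, -1, 1))
    if (max(abs(f)) > 0) f <- f / max(abs(f)) * amp
    f
  }
  b0 <- poly_field(b0_amplitude_ppm)
  b1 <- poly_field(b1_range)
  list(b0_ppm = b0, b1_scale = 1 + b1 - mean(b1))
}

# private RNG stream so synthetic generators do not disturb the global seed
.seeded_rng <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    s
  })
  with_state <- function(f) function(...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    out <- f(...)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    out
  }
  list(runif = with_state(stats::runif), rnorm = with_state(stats::rnorm),
       sample = with_state(base::sample))
}

#' Generate a noisy digital tube-phantom acquisition
#'
#' Simulates the Z-spectrum stack of a tube phantom: per voxel, the
#' steady-state spectrum of the tube's pool system under the local B0 shift
#' and B1 scale, plus additive Gaussian noise on the normalized signal.
#' Background voxels are zero. Deterministic given `seed`.
#'
#' @param layout A [phantom_layout()].
#' @param scheme A [saturation_scheme()].
#' @param schedule An [acq_schedule()].
#' @param noise_sd Gaussian noise standard deviation, normalized-signal units.
#' @param b0_amplitude_ppm,b1_range Field inhomogeneity amplitudes (0 for
#'   homogeneous fields).
#' @param template Pool template, `"bsa_agarose"` or
#'   `"brain_5pool_hydroxyl"`.
#' @param seed Integer seed.
#' @return List: `data` (nx x ny x n_points array of normalized signals,
#'   schedule order, reference points excluded), `truth` (per-tube true
#'   parameter table), `labels` (tube label image), `t1_map`, `b1_map`,
#'   `b0_map`, `schedule`, `scheme`.
#' @export
generate_phantom_image <- function(layout = phantom_layout(),
                                   scheme = saturation_scheme(),
                                   schedule = schedule_invivo(),
                                   noise_sd = 0.005,
                                   b0_amplitude_ppm = 0, b1_range = 0,
                                   template = "bsa_agarose", seed = 1L) {
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  labels <- .layout_labels(layout)
  fields <- generate_field_maps(layout$shape, b0_amplitude_ppm, b1_range,
                                seed = seed + 1L)
  systems <- lapply(seq_len(nrow(layout$conc)), function(t)
    make_pool_system(template, c(bsa = layout$conc$bsa[t],
                                 agarose = layout$conc$agarose[t])))
  npt <- sum(!schedule$is_ref)
  data <- array(0, dim = c(layout$shape[1], layout$shape[2], npt))
  t1_map <- matrix(0, layout$shape[1], layout$shape[2])
  homogeneous <- b0_amplitude_ppm == 0 && b1_range == 0
  cache <- lapply(systems, function(s)
    if (homogeneous) simulate_zspectrum(s, scheme, schedule)$z else NULL)
  rs <- .seeded_rng(seed)
  for (i in seq_len(layout$shape[1])) for (j in seq_len(layout$shape[2])) {
    t <- labels[i, j]
    if (t == 0L) next
    z <- if (homogeneous) cache[[t]] else
      simulate_zspectrum(systems[[t]], scheme, schedule,
                         b0_ppm = fields$b0_ppm[i, j],
                         b1_scale = fields$b1_scale[i, j])$z
    if (noise_sd > 0) z <- z + rs$rnorm(npt, 0, noise_sd)
    data[i, j, ] <- z
    t1_map[i, j] <- systems[[t]]$pools[[1L]]$t1
  }
  truth <- do.call(rbind, lapply(seq_along(systems), function(t) {
    s <- systems[[t]]
    nm <- .pool_names(s)
    data.frame(tube = t, bsa = layout$conc$bsa[t],
               agarose = layout$conc$agarose[t],
               amide_m0r = if ("amide" %in% nm) s$pools[[which(nm == "amide")]]$m0r else 0,
               noe_m0r = if ("noe" %in% nm) s$pools[[which(nm == "noe")]]$m0r else 0,
               psr = s$pools[[which(nm == "MT")]]$m0r,
               t1f = s$pools[[1L]]$t1)
  }))
  list(data = data, truth = truth, labels = labels, t1_map = t1_map,
       b1_map = fields$b1_scale, b0_map = fields$b0_ppm,
       schedule = schedule, scheme = scheme, systems = systems)
}
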