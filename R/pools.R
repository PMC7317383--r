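# Pool and pool-system containers. A pool system is water plus any number of
# mobile solute pools (x, y, z magnetization components) and semisolid pools
# (z only, with an absorption lineshape), with water-centric exchange.

#' Define an exchanging proton pool
#'
#' @param name Pool label (e.g. `"water"`, `"amide"`).
#' @param shift_ppm Chemical shift relative to water, ppm; positive downfield
#'   (amide +3.5, relayed NOE -3.5).
#' @param t1,t2 Longitudinal / transverse relaxation times, s.
#' @param m0r Equilibrium magnetization relative to water (water is 1).
#' @param k Exchange rate from this pool to water, 1/s (k_SF for solutes,
#'   k_MF for the semisolid pool). The reverse rate follows from detailed
#'   balance, `k_FS = k * m0r`.
#' @param klass `"mobile"` or `"semisolid"`.
#' @param lineshape Absorption lineshape of a semisolid pool (ignored for
#'   mobile pools); see [lineshape_value()].
#' @return A `cest_pool` list.
#' @export
pool <- function(name, shift_ppm = 0, t1 = 1, t2 = 0.1, m0r = 0, k = 0,
                 klass = c("mobile", "semisolid"),
                 lineshape = "super_lorentzian") {
  klass <- match.arg(klass)
  if (m0r < 0) stop("pool '", name, "': m0r must be >= 0")
  if (t1 <= 0 || t2 <= 0) stop("pool '", name, "': t1 and t2 must be > 0")
  if (k < 0) stop("pool '", name, "': exchange rate must be >= 0")
  if (klass == "semisolid") lineshape <- match.arg(lineshape, .lineshape_kinds)
  structure(list(name = name, shift_ppm = shift_ppm, t1 = t1, t2 = t2,
                 m0r = m0r, k = k, klass = klass,
                 lineshape = if (klass == "semisolid") lineshape else NA_character_),
            class = "cest_pool")
}

#' Assemble a multi-pool exchange system
#'
#' Water must be the first pool and have `shift_ppm = 0`, `m0r = 1`, `k = 0`.
#' Exchange topology is water-centric: every non-water pool exchanges with
#' water only.
#'
#' @param ... `cest_pool` objects (water first), or a single list of them.
#' @param center_freq_mhz Scanner proton frequency in MHz, used for the
#'   ppm-to-Hz conversion (127.7 at 3 T).
#' @return A `pool_system` object.
#' @export
pool_system <- function(..., center_freq_mhz = 127.7) {
  pools <- list(...)
  if (length(pools) == 1L && !inherits(pools[[1L]], "cest_pool"))
    pools <- pools[[1L]]
  if (!length(pools)) stop("at least one pool (water) is required")
  if (!all(vapply(pools, inherits, logical(1), "cest_pool")))
    stop("all arguments must be cest_pool objects")
  w <- pools[[1L]]
  if (w$klass != "mobile" || w$shift_ppm != 0 || w$m0r != 1 || w$k != 0)
    stop("the first pool must be water: mobile, shift_ppm = 0, m0r = 1, k = 0")
  nm <- vapply(pools, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate pool names: ",
                              paste(nm[duplicated(nm)], collapse = ", "))
  if (sum(nm == nm[1L]) != 1L || any(nm[-1L] == nm[1L]))
    stop("exactly one water pool is allowed")
  structure(list(pools = pools, center_freq_mhz = center_freq_mhz),
            class = "pool_system")
}

#' @export
print.pool_system <- function(x, ...) {
  cat(sprintf("Pool system: %d pools, %.1f MHz\n", length(x$pools),
              x$center_freq_mhz))
  df <- do.call(rbind, lapply(x$pools, function(p)
    data.frame(name = p$name, class = p$klass, shift_ppm = p$shift_ppm,
               t1_s = p$t1, t2_s = p$t2, m0r = p$m0r, k_to_water = p$k,
               lineshape = ifelse(is.na(p$lineshape), "", p$lineshape))))
  print(df, row.names = FALSE, digits = 4)
  invisible(x)
}

.pool_names <- function(system) vapply(system$pools, `[[`, character(1), "name")
.is_mobile <- function(system) vapply(system$pools, `[[`, character(1), "klass") == "mobile"

# state-vector dimension: 3 per mobile pool, 1 per semisolid pool
.state_dim <- function(system) {
  mob <- .is_mobile(system)
  3L * sum(mob) + sum(!mob)
}

# z-row index of each pool in the state vector (mobile pools listed first
# in system order keep their (x,y,z) triples; semisolid pools follow)
.z_index <- function(system) {
  mob <- .is_mobile(system)
  idx <- integer(length(mob))
  mi <- cumsum(mob); si <- cumsum(!mob); nmob <- sum(mob)
  idx[mob] <- 3L * mi[mob]
  idx[!mob] <- 3L * nmob + si[!mob]
  idx
}

# first index of the (x,y,z) triple of mobile pool i (system order)
.xyz_index <- function(system) {
  mob <- .is_mobile(system)
  mi <- cumsum(mob)
  ifelse(mob, 3L * (mi - 1L) + 1L, NA_integer_)
}

#' Drop or zero a pool from a system
#'
#' @param system A `pool_system`.
#' @param name Pool name to remove.
#' @return The reduced `pool_system`.
#' @export
drop_pool <- function(system, name) {
  keep <- .pool_names(system) != name
  if (all(keep)) stop("no pool named '", name, "'")
  pool_system(system$pools[keep], center_freq_mhz = system$center_freq_mhz)
}

#' Equilibrium magnetization vector
#'
#' Zeros in transverse components, `m0r` in each z component (water = 1).
#' @param system A `pool_system`.
#' @return Numeric state vector.
#' @export
equilibrium_vector <- function(system) {
  m0 <- numeric(.state_dim(system))
  m0[.z_index(system)] <- vapply(system$pools, `[[`, numeric(1), "m0r")
  m0
}
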