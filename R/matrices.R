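# System matrices of the N-pool model: relaxation/exchange matrix R_L,
# saturation matrix W(offset, B1), excitation and spoiling diagonals, and a
# matrix-exponential helper. State ordering: (x, y, z) triples for mobile
# pools in system order, then one z component per semisolid pool.

#' Relaxation and exchange matrix
#'
#' The homogeneous part R_L of the coupled Bloch-McConnell system. Water's
#' z diagonal is `-R1F - sum(k_F->s)` over all non-water pools; each solute
#' z (and x, y) diagonal is `-R1S - k_SF` (`-R2S - k_SF`); the semisolid
#' diagonal is `-R1M - k_MF`. Off-diagonal terms couple every pool with water
#' only, with `k_FS = k_SF * m0r` (detailed balance).
#'
#' @param system A [pool_system()].
#' @return Square matrix of the state-vector dimension, with the
#'   inhomogeneous relaxation vector (R1 * m0r in z rows) as attribute `"b"`.
#' @export
relaxation_matrix <- function(system) {
  pools <- system$pools
  n <- .state_dim(system)
  zi <- .z_index(system)
  xi <- .xyz_index(system)
  R <- matrix(0, n, n)
  w <- pools[[1L]]
  # forward rates water -> pool
  kf <- vapply(pools, function(p) p$k * p$m0r, numeric(1)); kf[1L] <- 0
  mob <- .is_mobile(system)
  # water block
  r2f <- 1 / w$t2; r1f <- 1 / w$t1
  kf_mob <- sum(kf[-1L][mob[-1L]])
  R[xi[1L], xi[1L]] <- R[xi[1L] + 1L, xi[1L] + 1L] <- -r2f - kf_mob
  R[zi[1L], zi[1L]] <- -r1f - sum(kf)
  for (j in seq_along(pools)[-1L]) {
    p <- pools[[j]]
    if (p$klass == "mobile") {
      for (d in 0:1) { # x, y
        i <- xi[j] + d; iw <- xi[1L] + d
        R[i, i] <- -1 / p$t2 - p$k
        R[iw, i] <- p$k
        R[i, iw] <- kf[j]
      }
    }
    # z rows
    R[zi[j], zi[j]] <- -1 / p$t1 - p$k
    R[zi[1L], zi[j]] <- p$k
    R[zi[j], zi[1L]] <- kf[j]
  }
  b <- numeric(n)
  b[zi] <- vapply(pools, function(p) p$m0r / p$t1, numeric(1))
  attr(R, "b") <- b
  R
}

#' Saturation matrix W for one (offset, amplitude) point
#'
#' For each mobile pool a 2*pi*Delta precession block (Delta = offset minus
#' the pool shift, converted to Hz via the scanner frequency) with the
#' +/- omega1 coupling between y and z; for each semisolid pool the scalar RF
#' absorption rate `pi * omega1^2 * g(Delta, T2)` negated on the diagonal.
#'
#' @param system A [pool_system()].
#' @param offset_ppm RF offset relative to water, ppm.
#' @param w1 CWEP amplitude omega1, rad/s.
#' @return Square matrix of the state-vector dimension.
#' @export
saturation_matrix <- function(system, offset_ppm, w1) {
  if (w1 < 0) stop("'w1' must be >= 0")
  pools <- system$pools
  n <- .state_dim(system)
  zi <- .z_index(system)
  xi <- .xyz_index(system)
  f0 <- system$center_freq_mhz
  W <- matrix(0, n, n)
  for (j in seq_along(pools)) {
    p <- pools[[j]]
    d_hz <- (offset_ppm - p$shift_ppm) * f0
    if (p$klass == "mobile") {
      u <- 2 * pi * d_hz
      ix <- xi[j]
      W[ix, ix + 1L] <- u
      W[ix + 1L, ix] <- -u
      W[ix + 1L, ix + 2L] <- -w1
      W[ix + 2L, ix + 1L] <- w1
    } else {
      W[zi[j], zi[j]] <- -rf_absorption_rate(w1, d_hz, p$t2, p$lineshape)
    }
  }
  W
}

# excitation diagonal: sin(alpha) on transverse, cos(alpha) on all z
.excitation_diag <- function(system, alpha_deg) {
  a <- alpha_deg * pi / 180
  d <- rep(cos(a), .state_dim(system))
  xi <- .xyz_index(system)
  for (i in xi[!is.na(xi)]) d[c(i, i + 1L)] <- sin(a)
  d
}

# spoiler diagonal: zero transverse, keep z
.spoil_diag <- function(system) {
  d <- rep(1, .state_dim(system))
  xi <- .xyz_index(system)
  for (i in xi[!is.na(xi)]) d[c(i, i + 1L)] <- 0
  d
}

# matrix exponential expm(A * t); eigendecomposition with a
# scaling-and-squaring fallback for ill-conditioned eigenvector bases
.expm_t <- function(A, t) .expm_fast(A, t)
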