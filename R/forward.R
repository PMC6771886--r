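#' Construct a z-spectrum object
#'
#' @param offsets Saturation offsets, ppm.
#' @param signal Normalized signal (dimensionless, 1 = unsaturated).
#' @param s0 Absolute unsaturated signal used for normalization.
#' @return An object of class `"zspectrum"`.
#' @export
zspectrum <- function(offsets, signal, s0) {
  if (length(offsets) != length(signal))
    stop("offsets and signal must have the same length")
  # Mz can transiently nutate below zero under strong saturation, so the
  # physical range is [-1, 1] (normalized); steady protocols stay in [0, 1]
  if (any(!is.finite(signal)) || any(signal < -1 - 1e-6))
    stop("signal values must be finite and >= -1")
  structure(list(offsets = as.numeric(offsets), signal = as.numeric(signal),
                 s0 = s0), class = "zspectrum")
}

#' @export
print.zspectrum <- function(x, ...) {
  cat(sprintf("<zspectrum> %d offsets, s0=%g, min signal %.4f at %g ppm\n",
              length(x$offsets), x$s0, min(x$signal),
              x$offsets[which.min(x$signal)]))
  invisible(x)
}

#' Assemble the Bloch-McConnell generator for one saturation offset
#'
#' Builds the linear system `dM/dt = A M + b` for the stacked
#' `(Mx, My, Mz)` components of all pools (water first) under CW
#' saturation. Exchange terms enforce detailed balance: each solute pool
#' exchanges with water at its `kex`, and the reverse water-to-pool rate is
#' `kex * m0_pool / m0_water`. Saturation couples My and Mz with strength
#' `gamma * B1`; off-resonance terms rotate Mx/My at
#' `2 * pi * larmor * (offset - dw - b0_shift)` rad/s.
#'
#' This is a plain-R reference construction; the z-spectrum simulator
#' builds the same system in compiled code.
#'
#' @param pools List of [pool()] objects, water first.
#' @param b1 CW saturation amplitude, microtesla.
#' @param offset Saturation offset, ppm.
#' @param b0_shift Water resonance shift, ppm.
#' @param larmor Larmor frequency, MHz.
#' @return A list with square matrix `A` (dimension `3 * n_pools`) and
#'   constant vector `b`.
#' @examples
#' g <- assemble_generator(default_tissue_pools(), b1 = 0.55, offset = 3.5)
#' dim(g$A)
#' @export
assemble_generator <- function(pools, b1, offset, b0_shift = 0,
                               larmor = 127.74) {
  pm <- pool_matrix(pools)
  if (b1 < 0) stop("b1 must be >= 0")
  n <- nrow(pm)
  w1 <- 267.5221874 * b1
  A <- matrix(0, 3 * n, 3 * n)
  b <- numeric(3 * n)
  m0w <- pm[1, "m0"]
  c_water <- if (n > 1) sum(pm[-1, "kex"] * pm[-1, "m0"]) / m0w else 0
  for (i in seq_len(n)) {
    m0 <- pm[i, "m0"]; r1 <- 1 / pm[i, "t1"]; r2 <- 1 / pm[i, "t2"]
    theta <- 2 * pi * larmor * (offset - pm[i, "dw"] - b0_shift)
    closs <- if (i == 1) c_water else pm[i, "kex"]
    x <- 3 * (i - 1) + 1; y <- x + 1; z <- x + 2
    A[x, x] <- -(r2 + closs); A[x, y] <- theta
    A[y, x] <- -theta; A[y, y] <- -(r2 + closs); A[y, z] <- w1
    A[z, y] <- -w1; A[z, z] <- -(r1 + closs)
    b[z] <- r1 * m0
    if (i > 1) {
      k_sw <- pm[i, "kex"]; k_ws <- k_sw * m0 / m0w
      for (cc in 0:2) {
        A[1 + cc, x + cc] <- A[1 + cc, x + cc] + k_sw
        A[x + cc, 1 + cc] <- A[x + cc, 1 + cc] + k_ws
      }
    }
  }
  list(A = A, b = b)
}

#' Simulate a CEST z-spectrum
#'
#' Propagates the multi-pool Bloch-McConnell system from thermal
#' equilibrium over the saturation duration at every offset of the
#' protocol, using the exact matrix-exponential solution of the linear ODE
#' `M(t) = expm(A t) (M(0) + A^-1 b) - A^-1 b`. The returned signal is the
#' water-pool longitudinal magnetization normalized by the water `m0`.
#'
#' @param pools List of [pool()] objects, water first.
#' @param protocol A [saturation_protocol()].
#' @param b0_shift Water resonance shift for this voxel, ppm.
#' @return A [zspectrum()].
#' @examples
#' z <- simulate_zspectrum(default_tissue_pools(), default_protocol())
#' range(z$signal)
#' @export
simulate_zspectrum <- function(pools, protocol, b0_shift = 0) {
  stopifnot(inherits(protocol, "cest_protocol"))
  pm <- pool_matrix(pools)
  mz <- .bm_zspectrum_cpp(pm, protocol$b1, protocol$offsets, b0_shift,
                          protocol$larmor, protocol$t_sat)
  s0 <- pm[1, "m0"]
  zspectrum(protocol$offsets, as.numeric(mz) / s0, s0)
}

# Absolute (unnormalized) water Mz spectrum; internal fast path used by the
# mixture model and the fitting objective (no class construction).
sim_mz_abs <- function(pm, protocol, b0_shift) {
  as.numeric(.bm_zspectrum_cpp(pm, protocol$b1, protocol$offsets, b0_shift,
                               protocol$larmor, protocol$t_sat))
}
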