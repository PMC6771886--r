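#' Define a magnetization pool
#'
#' A pool is one exchanging magnetization compartment in the
#' Bloch-McConnell system: bulk water, amide protons, the semisolid
#' (magnetization-transfer) compartment, or the nuclear Overhauser (NOE)
#' compartment. The first pool of any system must be water.
#'
#' @param name Pool label, e.g. `"water"`, `"amide"`, `"mt"`, `"noe"`.
#' @param m0 Equilibrium magnetization. For water this sets the absolute
#'   signal scale; for solute pools it is the concentration relative to the
#'   water pool (dimensionless).
#' @param kex Pool-to-water exchange rate in s^-1. Ignored for water
#'   (exchange rates are attached to the solute side; the reverse
#'   water-to-pool rate follows from detailed balance as
#'   `kex * m0_pool / m0_water`).
#' @param t1,t2 Longitudinal and transverse relaxation times in seconds.
#' @param dw Chemical shift relative to water, in ppm. Positive is
#'   downfield of water (amide at +3.5 ppm, NOE at negative ppm).
#' @return An object of class `"cest_pool"`.
#' @examples
#' pool("amide", m0 = 0.001, kex = 30, t1 = 1, t2 = 0.02, dw = 3.5)
#' @export
pool <- function(name, m0, kex = 0, t1, t2, dw = 0) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(m0) || m0 < 0) stop("pool '", name, "': m0 must be >= 0")
  if (!is.finite(kex) || kex < 0) stop("pool '", name, "': kex must be >= 0")
  if (!is.finite(t1) || t1 <= 0) stop("pool '", name, "': t1 must be > 0")
  if (!is.finite(t2) || t2 <= 0) stop("pool '", name, "': t2 must be > 0")
  if (t2 > t1) stop("pool '", name, "': t2 must not exceed t1")
  structure(list(name = name, m0 = m0, kex = kex, t1 = t1, t2 = t2, dw = dw),
            class = "cest_pool")
}

#' @export
print.cest_pool <- function(x, ...) {
  cat(sprintf("<pool %s> m0=%g kex=%g s^-1 t1=%g s t2=%g s dw=%g ppm\n",
              x$name, x$m0, x$kex, x$t1, x$t2, x$dw))
  invisible(x)
}

# Convert a list of pools to the n x 5 numeric matrix used by the compiled
# simulator (columns m0, kex, t1, t2, dw; water first).
pool_matrix <- function(pools) {
  stopifnot(length(pools) >= 1L)
  if (!all(vapply(pools, inherits, logical(1), "cest_pool")))
    stop("'pools' must be a list of cest_pool objects")
  if (pools[[1L]]$dw != 0)
    stop("the first pool must be water (chemical shift 0 ppm); got dw = ",
         pools[[1L]]$dw, " ppm")
  m <- t(vapply(pools, function(p) c(p$m0, p$kex, p$t1, p$t2, p$dw),
                numeric(5)))
  dimnames(m) <- list(vapply(pools, `[[`, character(1), "name"),
                      c("m0", "kex", "t1", "t2", "dw"))
  m
}

#' Default tissue and CSF pool parameters
#'
#' `default_tissue_pools()` returns the 4-pool description of brain tissue
#' used throughout the package: bulk water, amide protons resonating at
#' +3.5 ppm, a symmetric semisolid (MT) compartment at 0 ppm, and an NOE
#' compartment at -3.5 ppm. `default_csf_pool()` returns the single free
#' water pool used for cerebrospinal fluid. Values are literature-based
#' 3 T defaults and are fully editable; the CSF `m0` given here is a
#' placeholder that is always re-expressed relative to the tissue water
#' scale via [constrain_csf_m0()] before use.
#'
#' @return A list of [pool()] objects (`default_tissue_pools`) or a single
#'   [pool()] (`default_csf_pool`).
#' @examples
#' default_tissue_pools()
#' @export
default_tissue_pools <- function() {
  list(
    pool("water", m0 = 1.0,   kex = 0,  t1 = 1.3,  t2 = 0.07,  dw = 0),
    pool("amide", m0 = 1e-3,  kex = 30, t1 = 1.0,  t2 = 0.02,  dw = 3.5),
    pool("mt",    m0 = 0.08,  kex = 25, t1 = 1.0,  t2 = 1e-5,  dw = 0),
    pool("noe",   m0 = 5e-3,  kex = 15, t1 = 1.0,  t2 = 1e-3,  dw = -3.5)
  )
}

#' @rdname default_tissue_pools
#' @export
default_csf_pool <- function() {
  pool("csf", m0 = 0.53, kex = 0, t1 = 4.3, t2 = 2.0, dw = 0)
}
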