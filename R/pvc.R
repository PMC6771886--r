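#' Two-compartment (tissue + CSF) CEST model
#'
#' Bundles the 4-pool tissue description, the 1-pool CSF description, and
#' the proportionality constant that ties the CSF equilibrium
#' magnetization to the tissue water scale. The CSF pool concentration is
#' never a free quantity: it is always re-derived as
#' `ratio * tissue water m0` via [constrain_csf_m0()] (without this
#' constraint a mixture fit collapses onto the tissue compartment alone).
#'
#' @param tissue_pools List of 4 [pool()] objects (water, amide, MT, NOE).
#' @param csf_pool A single [pool()] with `dw = 0`; its `m0` is ignored and
#'   replaced by the constrained value.
#' @param csf_tissue_ratio Ratio of CSF `m0` to tissue water `m0`
#'   (a proton-density ratio modulated by T1). Default 0.53.
#' @return An object of class `"compartment_model"`.
#' @examples
#' compartment_model()
#' @export
compartment_model <- function(tissue_pools = default_tissue_pools(),
                              csf_pool = default_csf_pool(),
                              csf_tissue_ratio = 0.53) {
  stopifnot(inherits(csf_pool, "cest_pool"))
  if (csf_pool$dw != 0) stop("the CSF pool must resonate at 0 ppm")
  if (!is.finite(csf_tissue_ratio) || csf_tissue_ratio <= 0)
    stop("csf_tissue_ratio must be > 0")
  pool_matrix(tissue_pools)  # validates water-first ordering
  csf_pool$m0 <- constrain_csf_m0(tissue_pools[[1L]]$m0, csf_tissue_ratio)
  structure(list(tissue_pools = tissue_pools, csf_pool = csf_pool,
                 csf_tissue_ratio = csf_tissue_ratio),
            class = "compartment_model")
}

#' Constrain the CSF equilibrium magnetization to the tissue water scale
#'
#' @param tissue_water_m0 Absolute tissue water equilibrium signal.
#' @param ratio CSF-to-tissue proportionality constant.
#' @return The CSF pool `m0` on the same absolute scale.
#' @examples
#' constrain_csf_m0(1.0, 0.53)
#' @export
constrain_csf_m0 <- function(tissue_water_m0, ratio) {
  if (!is.finite(tissue_water_m0) || tissue_water_m0 <= 0)
    stop("tissue_water_m0 must be > 0")
  if (!is.finite(ratio) || ratio <= 0) stop("ratio must be > 0")
  ratio * tissue_water_m0
}

#' Partial-volume-corrected mixture z-spectrum
#'
#' Computes the spectrum of a voxel containing a tissue fraction `pve` and
#' a CSF fraction `1 - pve` as the tissue-weighted sum
#' `Stotal(w) = (1 - pve) * SCSF(w) + pve * Stissue(w)`. Both component
#' spectra are simulated with [simulate_zspectrum()] machinery under the
#' same `b0_shift`, expressed as absolute magnetizations, and normalized by
#' the combined unsaturated signal
#' `s0 = (1 - pve) * m0_CSF + pve * m0_tissue`, so the weighted-sum
#' identity holds exactly for the returned normalized components.
#'
#' @param model A [compartment_model()].
#' @param pve Tissue partial-volume fraction in `[0, 1]`.
#' @param protocol A [saturation_protocol()].
#' @param b0_shift Water resonance shift shared by both compartments, ppm.
#' @return A [zspectrum()] with attribute `"components"`: a list holding
#'   the normalized `csf` and `tissue` component spectra and the `pve`.
#' @examples
#' z <- pvc_spectrum(compartment_model(), pve = 0.6, default_protocol())
#' comp <- attr(z, "components")
#' max(abs(z$signal - (0.4 * comp$csf + 0.6 * comp$tissue)))  # 0
#' @export
pvc_spectrum <- function(model, pve, protocol, b0_shift = 0) {
  stopifnot(inherits(model, "compartment_model"))
  if (!is.finite(pve) || pve < 0 || pve > 1)
    stop("pve must be a fraction in [0, 1]; got ", pve)
  pm_t <- pool_matrix(model$tissue_pools)
  pm_c <- pool_matrix(list(model$csf_pool))
  mz_t <- sim_mz_abs(pm_t, protocol, b0_shift)
  mz_c <- sim_mz_abs(pm_c, protocol, b0_shift)
  s0 <- (1 - pve) * pm_c[1, "m0"] + pve * pm_t[1, "m0"]
  s_csf <- mz_c / s0
  s_tis <- mz_t / s0
  z <- zspectrum(protocol$offsets, (1 - pve) * s_csf + pve * s_tis, s0)
  attr(z, "components") <- list(csf = s_csf, tissue = s_tis, pve = pve)
  z
}

#' Estimate the CSF-to-tissue concentration ratio from unsaturated images
#'
#' Fits the per-voxel unsaturated signal as a linear combination of the
#' tissue and CSF partial-volume fractions,
#' `S0_v = a * tissue_pve_v + c * csf_pve_v`, by least squares over the
#' masked voxels, and returns the ratio `c / a` with a voxel-bootstrap
#' standard deviation. The ratio is a proton-density ratio modulated by T1
#' and is the constant consumed by [constrain_csf_m0()].
#'
#' @param s0_volume Numeric array of unsaturated signal.
#' @param tissue_pve_map,csf_pve_map Arrays of fractions on the same grid.
#' @param mask Logical array selecting voxels to use (typically voxels with
#'   `tissue + csf PVE` close to 1). Default: all voxels.
#' @param n_boot Bootstrap replicates for the standard deviation.
#' @param seed Optional integer seed for the bootstrap.
#' @return A list with `ratio`, `sd`, `n_voxels`.
#' @export
estimate_csf_tissue_ratio <- function(s0_volume, tissue_pve_map, csf_pve_map,
                                      mask = NULL, n_boot = 200, seed = NULL) {
  dims <- dim(s0_volume)
  if (!identical(dims, dim(tissue_pve_map)) ||
      !identical(dims, dim(csf_pve_map)))
    stop("s0_volume, tissue_pve_map and csf_pve_map must share one grid")
  if (is.null(mask)) mask <- array(TRUE, dim = dims)
  if (!identical(dim(mask), dims)) stop("mask must share the data grid")
  s0 <- as.numeric(s0_volume[mask])
  pt <- as.numeric(tissue_pve_map[mask])
  pc <- as.numeric(csf_pve_map[mask])
  ok <- is.finite(s0) & is.finite(pt) & is.finite(pc)
  s0 <- s0[ok]; pt <- pt[ok]; pc <- pc[ok]
  if (length(s0) < 10L)
    stop("ratio unidentifiable: fewer than 10 usable voxels in mask")
  if (all(pc <= 0))
    stop("ratio unidentifiable: no CSF-containing voxels in mask")
  fit <- lm(s0 ~ 0 + pt + pc)
  a <- coef(fit)[["pt"]]; cc <- coef(fit)[["pc"]]
  if (!is.finite(a) || a <= 0)
    stop("ratio unidentifiable: tissue coefficient not positive")
  if (!is.null(seed)) set.seed(seed)
  n <- length(s0)
  boot <- vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(n, n, replace = TRUE)
    cf <- coef(lm(s0[idx] ~ 0 + pt[idx] + pc[idx]))
    cf[[2L]] / cf[[1L]]
  }, numeric(1))
  list(ratio = cc / a, sd = sd(boot, na.rm = TRUE), n_voxels = n)
}
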