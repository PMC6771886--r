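#' Specify a synthetic CEST phantom
#'
#' A phantom specification fixes everything needed to generate a synthetic
#' CEST dataset with known ground truth: the voxel grid, the tissue
#' partial-volume map (CSF fraction is its complement), an optional lesion
#' with reduced amide concentration plus its mirrored contralateral ROI, a
#' smooth per-voxel B0 offset field, the noise level, the saturation
#' protocol, and the true compartment parameters.
#'
#' @param tissue_pve 3D array of tissue fractions in `[0, 1]`.
#' @param lesion_mask,contra_mask Logical arrays on the same grid (may be
#'   all-`FALSE`). Lesion voxels must have tissue PVE >= 0.5.
#' @param amide_reduction Multiplier in `(0, 1]` applied to the amide `m0`
#'   inside the lesion (e.g. 0.7 for a 30% reduction).
#' @param b0_field 3D array of per-voxel water shifts, ppm (default all 0).
#' @param noise_sd Gaussian noise standard deviation as a fraction of the
#'   voxel's unsaturated signal.
#' @param protocol A [saturation_protocol()].
#' @param compartments A [compartment_model()] giving the true tissue and
#'   CSF parameters.
#' @param seed Integer seed for the noise.
#' @return An object of class `"phantom_spec"`.
#' @seealso [default_stroke_spec()], [pve_ramp_spec()], [generate_phantom()]
#' @export
phantom_spec <- function(tissue_pve, lesion_mask = NULL, contra_mask = NULL,
                         amide_reduction = 0.7, b0_field = NULL,
                         noise_sd = 0.01, protocol = default_protocol(),
                         compartments = compartment_model(), seed = 42L) {
  dims <- dim(tissue_pve)
  if (length(dims) != 3L) stop("tissue_pve must be a 3D array")
  if (any(tissue_pve < 0 | tissue_pve > 1))
    stop("tissue_pve values must lie in [0, 1]")
  if (is.null(lesion_mask)) lesion_mask <- array(FALSE, dims)
  if (is.null(contra_mask)) contra_mask <- array(FALSE, dims)
  if (is.null(b0_field)) b0_field <- array(0, dims)
  stopifnot(identical(dim(lesion_mask), dims),
            identical(dim(contra_mask), dims),
            identical(dim(b0_field), dims))
  if (amide_reduction <= 0 || amide_reduction > 1)
    stop("amide_reduction must be in (0, 1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (any(lesion_mask & tissue_pve < 0.5))
    stop("spec error: lesion voxels must lie in tissue (PVE >= 0.5)")
  structure(list(dims = dims, tissue_pve = tissue_pve,
                 lesion_mask = lesion_mask, contra_mask = contra_mask,
                 amide_reduction = amide_reduction, b0_field = b0_field,
                 noise_sd = noise_sd, protocol = protocol,
                 compartments = compartments, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Canonical phantom geometries
#'
#' `default_stroke_spec()` is the digital stroke phantom used for
#' end-to-end validation: a 16 x 16 x 1 slab with a pure-CSF band
#' (columns 1-2), a mixed tissue-CSF boundary (columns 3-5, tissue PVE
#' 0.25 / 0.60 / 0.80), pure tissue elsewhere, a 3 x 3 ischemic core with
#' the amide concentration reduced by 30%, a mirrored contralateral ROI in
#' clean tissue, a smooth polynomial B0 field of approximately
#' +-0.04 ppm, and 1% Gaussian noise.
#'
#' `pve_ramp_spec()` is the dilution test bed: constant tissue parameters
#' while the tissue fraction ramps across columns (default 0.5 to 1.0 in
#' steps of 0.05), no lesion, no B0 offset, and zero noise by default.
#'
#' @param seed Noise seed.
#' @param noise_sd Noise level (fraction of the unsaturated signal).
#' @param amide_reduction Lesion amide multiplier.
#' @param pve_levels Tissue fractions of the ramp columns.
#' @param n_rows Rows (voxels per ramp level).
#' @return A [phantom_spec()].
#' @export
default_stroke_spec <- function(seed = 42L, noise_sd = 0.01,
                                amide_reduction = 0.7) {
  nx <- 16L; ny <- 16L
  pve <- array(1, c(nx, ny, 1L))
  pve[, 1:2, 1] <- 0
  pve[, 3, 1] <- 0.25
  pve[, 4, 1] <- 0.60
  pve[, 5, 1] <- 0.80
  lesion <- array(FALSE, c(nx, ny, 1L)); lesion[5:7, 8:10, 1] <- TRUE
  contra <- array(FALSE, c(nx, ny, 1L)); contra[10:12, 8:10, 1] <- TRUE
  xn <- (seq_len(nx) - 1) / (nx - 1) - 0.5
  yn <- (seq_len(ny) - 1) / (ny - 1) - 0.5
  b0 <- array(0.05 * outer(xn, yn^2, function(a, b) a + b - 0.125),
              c(nx, ny, 1L))
  phantom_spec(pve, lesion, contra, amide_reduction = amide_reduction,
               b0_field = b0, noise_sd = noise_sd, seed = seed)
}

#' @rdname default_stroke_spec
#' @export
pve_ramp_spec <- function(pve_levels = seq(0.5, 1, by = 0.05), n_rows = 2L,
                          noise_sd = 0, seed = 1L) {
  nx <- as.integer(n_rows); ny <- length(pve_levels)
  pve <- array(rep(pve_levels, each = nx), c(nx, ny, 1L))
  phantom_spec(pve, noise_sd = noise_sd, seed = seed)
}

#' Add seeded Gaussian noise in the signal domain
#'
#' @param data Numeric array.
#' @param sd Noise standard deviation: a scalar or an array of the same
#'   shape as `data`.
#' @param seed Optional integer seed; the same seed reproduces the same
#'   noise exactly.
#' @return `data` plus independent Gaussian noise, same shape.
#' @export
add_noise <- function(data, sd, seed = NULL) {
  if (any(sd < 0)) stop("sd must be >= 0")
  if (!(length(sd) == 1L || identical(dim(sd), dim(data)) ||
        length(sd) == length(data)))
    stop("sd must be scalar or match the shape of data")
  if (all(sd == 0)) return(data)
  if (!is.null(seed)) set.seed(seed)
  data + array(rnorm(length(data)), dim = dim(data)) * sd
}

#' Generate a synthetic CEST dataset with ground truth
#'
#' Builds, voxel by voxel, the two-compartment mixture spectrum
#' (via [pvc_spectrum()]) at the voxel's true tissue fraction, region
#' parameters (lesion voxels get the reduced amide concentration) and B0
#' offset, scales it to absolute signal by the voxel's combined
#' unsaturated signal, and adds seeded Gaussian noise proportional to that
#' signal. The unsaturated `s0_volume` is returned noise-free.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `"phantom_dataset"`: `data_4d`
#'   `[x, y, z, offset]` in absolute signal units, `s0_volume`,
#'   `tissue_pve`, `csf_pve` (its complement), `roi` (list `core`,
#'   `contralateral`), `truth` (per-voxel data frame with `pve`, `b0`,
#'   `amide_m0`, `region`), plus the `spec` and `protocol`.
#' @examples
#' ds <- generate_phantom(pve_ramp_spec(c(0.5, 1), n_rows = 1))
#' dim(ds$data_4d)
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- spec$dims
  protocol <- spec$protocol
  n_off <- length(protocol$offsets)
  cm <- spec$compartments
  amide_i <- which(vapply(cm$tissue_pools, `[[`, character(1), "name") ==
                     "amide")
  if (length(amide_i) != 1L)
    stop("compartments must contain exactly one amide pool")
  cm_lesion <- cm
  cm_lesion$tissue_pools[[amide_i]]$m0 <-
    cm$tissue_pools[[amide_i]]$m0 * spec$amide_reduction

  data_4d <- array(NA_real_, c(dims, n_off))
  s0_vol <- array(NA_real_, dims)
  truth <- vector("list", prod(dims))
  vi <- 0L
  for (k in seq_len(dims[3L])) for (j in seq_len(dims[2L]))
    for (i in seq_len(dims[1L])) {
      vi <- vi + 1L
      p <- spec$tissue_pve[i, j, k]
      b0 <- spec$b0_field[i, j, k]
      lesion <- spec$lesion_mask[i, j, k]
      model <- if (lesion) cm_lesion else cm
      z <- pvc_spectrum(model, p, protocol, b0)
      data_4d[i, j, k, ] <- z$signal * z$s0
      s0_vol[i, j, k] <- z$s0
      region <- if (lesion) "core"
        else if (spec$contra_mask[i, j, k]) "contralateral"
        else if (p == 0) "csf" else if (p < 1) "boundary" else "tissue"
      truth[[vi]] <- data.frame(
        x = i, y = j, z = k, pve = p, csf_pve = 1 - p, b0 = b0,
        amide_m0 = model$tissue_pools[[amide_i]]$m0 * (p > 0),
        region = region)
    }
  if (spec$noise_sd > 0) {
    sd4d <- array(rep(as.vector(s0_vol), n_off), c(dims, n_off)) *
      spec$noise_sd
    data_4d <- add_noise(data_4d, sd4d, seed = spec$seed)
    data_4d[data_4d < 0] <- 0
  }
  structure(list(data_4d = data_4d, s0_volume = s0_vol,
                 tissue_pve = spec$tissue_pve,
                 csf_pve = 1 - spec$tissue_pve,
                 roi = list(core = spec$lesion_mask,
                            contralateral = spec$contra_mask),
                 truth = do.call(rbind, truth), spec = spec,
                 protocol = protocol),
            class = "phantom_dataset")
}

#' @export
print.phantom_dataset <- function(x, ...) {
  cat(sprintf(
    "<phantom_dataset> %s grid, %d offsets, noise sd %g, %d core voxels\n",
    paste(dim(x$s0_volume), collapse = "x"), dim(x$data_4d)[4L],
    x$spec$noise_sd, sum(x$roi$core)))
  invisible(x)
}
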