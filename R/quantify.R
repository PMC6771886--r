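#' Model-based APTR* from a fitted voxel
#'
#' Computes the model-based amide proton transfer ratio: the difference
#' between the fitted spectrum without the amide pool (`Sw`, water + MT +
#' NOE) and with it (`Sw+a`, all four pools), evaluated at the amide
#' resonance (+3.5 ppm) and normalized by the fitted water-compartment
#' unsaturated signal `S0`. For a PVC fit only the tissue compartment's
#' spectra enter, so the measure is undiluted by CSF; at a tissue fraction
#' of 1 the two definitions coincide.
#'
#' By default the spectra are evaluated in the B0-corrected frame (the
#' fitted water shift is removed, so evaluation is exactly at the amide
#' resonance); `frame = "nominal"` instead evaluates at the raw +3.5 ppm
#' acquisition offset with the fitted shift applied.
#'
#' @param fit A [fit_voxel()] result with `model_tag` `"four_pool"` or
#'   `"pvc"` (a `csf_only` fit carries no amide pool and is an error).
#' @param protocol The [saturation_protocol()] (B1, duration, Larmor
#'   frequency are used; evaluation is at +3.5 ppm regardless of the
#'   sampled offsets).
#' @param frame `"b0_corrected"` (default) or `"nominal"`.
#' @return APTR*, dimensionless. If the fit did not converge the value is
#'   still computed and carries attribute `flagged = TRUE`.
#' @export
aptr_star <- function(fit, protocol, frame = c("b0_corrected", "nominal")) {
  stopifnot(inherits(fit, "voxel_fit"), inherits(protocol, "cest_protocol"))
  frame <- match.arg(frame)
  if (fit$model_tag == "csf_only")
    stop("no-APT error: a csf_only fit has no amide pool; APTR* is ",
         "undefined for voxels with tissue PVE < 0.5")
  if (isTRUE(fit$flagged)) stop("cannot quantify a flagged (skipped) voxel")
  pools <- fit$pools
  amide <- which(vapply(pools, `[[`, character(1), "name") == "amide")
  if (length(amide) != 1L) stop("fit does not contain exactly one amide pool")

  b0 <- if (frame == "b0_corrected") 0 else fit$b0_shift
  eval_proto <- saturation_protocol(protocol$b1, protocol$t_sat,
                                    offsets = 3.5, larmor = protocol$larmor,
                                    reference_offset =
                                      protocol$reference_offset)
  s0 <- pools[[1L]]$m0
  swa <- sim_mz_abs(pool_matrix(pools), eval_proto, b0)
  sw <- sim_mz_abs(pool_matrix(pools[-amide]), eval_proto, b0)
  out <- (sw - swa) / s0
  if (!fit$converged) attr(out, "flagged") <- TRUE
  out
}

#' APTR* map from an image fit
#'
#' Applies [aptr_star()] to every APTR*-eligible voxel of a
#' [fit_image()] result (voxels fitted with a tissue model; `csf_only`
#' and flagged voxels stay `NA` and are excluded from the eligibility
#' mask).
#'
#' @param image_fit A `"cest_fit_image"` object.
#' @param frame Passed to [aptr_star()]; defaults to the frame recorded in
#'   the fit options.
#' @return A list of class `"aptr_map"` with `values` (3D array, `NA` where
#'   ineligible), `eligible_mask`, and `model_tag`.
#' @export
aptr_star_image <- function(image_fit, frame = NULL) {
  stopifnot(inherits(image_fit, "cest_fit_image"))
  if (is.null(frame)) frame <- image_fit$options$aptr_frame
  vdim <- dim(image_fit$eligible)
  vals <- array(NA_real_, dim = vdim)
  idx <- image_fit$voxels
  for (v in seq_len(nrow(idx))) {
    f <- image_fit$fits[[v]]
    if (is.null(f) || !f$model_tag %in% c("four_pool", "pvc") ||
        isTRUE(f$flagged)) next
    vals[idx[v, 1L], idx[v, 2L], idx[v, 3L]] <-
      as.numeric(aptr_star(f, image_fit$protocol, frame))
  }
  structure(list(values = vals, eligible_mask = image_fit$eligible,
                 model_tag = image_fit$model_tag),
            class = "aptr_map")
}

#' @export
print.aptr_map <- function(x, ...) {
  v <- x$values[x$eligible_mask]
  cat(sprintf("<aptr_map %s> %d eligible voxels, mean APTR* = %.4g\n",
              x$model_tag, sum(x$eligible_mask), mean(v, na.rm = TRUE)))
  invisible(x)
}

#' Analysis masks from a tissue PVE map
#'
#' Builds the three analysis masks used throughout: the whole-slice mask
#' (tissue PVE 0.50-1.00), the low-PVE mask (the bottom half of that
#' range, 0.50-0.75) and the high-PVE mask (the top half, 0.75-1.00).
#' The shared 0.75 boundary is assigned to the high mask so that low and
#' high partition the whole-slice mask. Voxels below 0.50 belong to no
#' mask.
#'
#' @param tissue_pve_map Array of tissue fractions in `[0, 1]`.
#' @return A list of class `"mask_set"` with logical arrays `whole_slice`,
#'   `low_pve`, `high_pve`.
#' @examples
#' m <- make_pve_masks(array(c(0.3, 0.6, 0.75, 0.9), c(4, 1, 1)))
#' sapply(m, sum)
#' @export
make_pve_masks <- function(tissue_pve_map) {
  p <- tissue_pve_map
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("tissue PVE values must lie in [0, 1]")
  whole <- !is.na(p) & p >= 0.50 & p <= 1.00
  low <- whole & p < 0.75
  high <- whole & p >= 0.75
  structure(list(whole_slice = whole, low_pve = low, high_pve = high),
            class = "mask_set")
}
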