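#' Coefficient of variation
#'
#' Sample standard deviation divided by the mean, in percent. The sample
#' (n - 1) divisor is used throughout the package.
#'
#' @param values Numeric vector with at least 2 elements.
#' @return CoV in percent.
#' @examples
#' coefficient_of_variation(c(8, 12))  # 28.28
#' @export
coefficient_of_variation <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("CoV needs at least 2 values")
  if (any(!is.finite(values))) stop("CoV input must be finite")
  m <- mean(values)
  if (m == 0) stop("CoV undefined: mean is zero")
  100 * sd(values) / m
}

#' Repeatability as a coefficient of variation
#'
#' Summarizes repeatability of an ROI-mean measure either between time
#' points or between subjects.
#'
#' `mode = "timepoints"`: for each subject, the CoV of its per-timepoint
#' ROI means is computed; the per-subject CoVs are then aggregated by
#' unweighted mean, reported together with their SD (the "mean CoV (SD)"
#' convention). `mode = "subjects"`: the CoV across per-subject means
#' (subjects with several timepoints contribute their mean over
#' timepoints).
#'
#' @param means Data frame with columns `subject`, `timepoint`, `value`
#'   (one ROI-mean per subject/timepoint).
#' @param mode `"timepoints"` or `"subjects"`.
#' @return For `"timepoints"`, a list with `mean_cov` and `sd_cov`
#'   (percent); for `"subjects"`, a single CoV in percent.
#' @examples
#' d <- data.frame(subject = rep(1:2, each = 3), timepoint = rep(1:3, 2),
#'                 value = c(10, 10, 10, 8, 12, 10))
#' repeatability(d, "timepoints")  # mean 10, sd 14.14
#' @export
repeatability <- function(means, mode = c("timepoints", "subjects")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(means),
            all(c("subject", "timepoint", "value") %in% names(means)))
  if (mode == "timepoints") {
    split_by_subject <- split(means$value, means$subject)
    if (any(lengths(split_by_subject) < 2L))
      stop("insufficient replication: every subject needs >= 2 timepoints")
    covs <- vapply(split_by_subject, coefficient_of_variation, numeric(1))
    list(mean_cov = mean(covs),
         sd_cov = if (length(covs) > 1L) sd(covs) else NA_real_,
         per_subject = covs)
  } else {
    subj_means <- vapply(split(means$value, means$subject), mean, numeric(1))
    if (length(subj_means) < 2L)
      stop("insufficient replication: need >= 2 subjects")
    coefficient_of_variation(subj_means)
  }
}

#' Spatial variability within an ROI
#'
#' The CoV of voxel values within one ROI, a measure of the ROI's spatial
#' heterogeneity.
#'
#' @param values Voxel values of the ROI (>= 2 voxels).
#' @return CoV in percent.
#' @export
spatial_variability <- function(values) coefficient_of_variation(values)

#' Contrast-to-noise ratio of a lesion ROI
#'
#' `CNR = (mean(core) - mean(contra)) / sd(contra)`: the ischemic-core
#' contrast relative to contralateral tissue, normalized by the
#' contralateral standard deviation. A core with reduced APT signal gives
#' a negative CNR.
#'
#' @param core,contra Numeric vectors of APTR* values in the ischemic-core
#'   and mirrored contralateral ROIs.
#' @return Dimensionless CNR.
#' @examples
#' contrast_to_noise(c(7, 8, 9), c(8, 10, 12))  # -1
#' @export
contrast_to_noise <- function(core, contra) {
  if (length(core) < 1L || length(contra) < 2L)
    stop("core must be non-empty and contra needs >= 2 values")
  if (any(!is.finite(core)) || any(!is.finite(contra)))
    stop("CNR input must be finite")
  s <- sd(contra)
  if (s == 0) stop("CNR undefined: contralateral sd is zero")
  (mean(core) - mean(contra)) / s
}

#' APTR* variability across CSF-fraction bins
#'
#' Bins voxels into 10 equally spaced CSF partial-volume ranges from 0% to
#' 50% (`[0, 0.05), [0.05, 0.10), ..., [0.45, 0.50]`), computes the mean
#' APTR* per bin, and returns the CoV of the bin means. A measure that is
#' insensitive to CSF content (the goal of partial-volume correction)
#' yields a low across-bin CoV.
#'
#' @param aptr_values Array or vector of APTR* values.
#' @param csf_pve Array or vector of CSF fractions, same shape.
#' @param mask Optional logical selection of voxels to include.
#' @return A list with `bin_means` (length 10, `NA` for empty bins),
#'   `bin_counts`, and `cov` (percent, over non-empty bins).
#' @export
csf_fraction_profile <- function(aptr_values, csf_pve, mask = NULL) {
  a <- as.numeric(aptr_values)
  p <- as.numeric(csf_pve)
  if (length(a) != length(p))
    stop("aptr_values and csf_pve must share one grid")
  keep <- if (is.null(mask)) rep(TRUE, length(a)) else as.logical(mask)
  keep <- keep & is.finite(a) & is.finite(p) & p >= 0 & p <= 0.5
  a <- a[keep]; p <- p[keep]
  if (length(a) == 0L) stop("no voxels fall in the CSF PVE range [0, 0.5]")
  # small epsilon so fractions computed as complements (e.g. 1 - 0.95)
  # land in their nominal bin despite floating-point representation
  bin <- pmin(floor(p / 0.05 + 1e-9), 9) + 1L
  bin_means <- vapply(1:10, function(b)
    if (any(bin == b)) mean(a[bin == b]) else NA_real_, numeric(1))
  bin_counts <- tabulate(bin, nbins = 10L)
  filled <- bin_means[!is.na(bin_means)]
  if (length(filled) < 2L)
    stop("fewer than 2 non-empty CSF bins; profile CoV undefined")
  list(bin_means = bin_means, bin_counts = bin_counts,
       cov = coefficient_of_variation(filled))
}

#' Tidy ROI statistics table
#'
#' Convenience assembly of the package's robustness statistics into the
#' tidy long format `subject, timepoint, roi, mask_band, model, statistic,
#' value`, suitable for export and for external group testing.
#'
#' @param aptr An `"aptr_map"` (or plain array of APTR* values).
#' @param rois Named list of logical arrays (e.g. `core`,
#'   `contralateral`), each combined with the PVE-band masks.
#' @param masks A [make_pve_masks()] result.
#' @param model Label recorded in the `model` column.
#' @param subject,timepoint Identifiers recorded per row.
#' @return A data frame in long format with ROI means and spatial CoVs.
#' @export
roi_stats_table <- function(aptr, rois, masks, model = "pvc",
                            subject = 1L, timepoint = 1L) {
  vals <- if (inherits(aptr, "aptr_map")) aptr$values else aptr
  bands <- list(whole = masks$whole_slice, low_pve = masks$low_pve,
                high_pve = masks$high_pve)
  out <- list()
  for (rn in names(rois)) for (bn in names(bands)) {
    sel <- rois[[rn]] & bands[[bn]] & is.finite(vals)
    if (sum(sel) < 2L) next
    v <- vals[sel]
    out[[length(out) + 1L]] <- data.frame(
      subject = subject, timepoint = timepoint, roi = rn, mask_band = bn,
      model = model,
      statistic = c("mean", "spatial_cov", "n_voxels"),
      value = c(mean(v), spatial_variability(v), length(v)))
  }
  do.call(rbind, out)
}
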