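#' Read and write saturation-offset lists
#'
#' Offsets files are plain text, one ppm value per line, in acquisition
#' order: line i corresponds to the i-th volume of the 4D data. Blank
#' lines and `#` comments are ignored on read.
#'
#' @param path File path.
#' @return `read_offsets`: numeric vector of offsets in ppm.
#' @export
read_offsets <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  offs <- suppressWarnings(as.numeric(lines))
  if (any(is.na(offs)))
    stop("offsets file '", path, "' contains non-numeric lines")
  offs
}

#' @rdname read_offsets
#' @param offsets Numeric vector to write.
#' @export
write_offsets <- function(offsets, path) {
  writeLines(sprintf("%.15g", offsets), path)
  invisible(path)
}

parse_kv_file <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("cannot parse line(s) in '", path, "': ",
                     paste(lines[bad], collapse = "; "))
  vals <- trimws(vapply(kv, `[[`, character(1), 2L))
  setNames(as.list(vals), trimws(vapply(kv, `[[`, character(1), 1L)))
}

#' Read or write a saturation protocol configuration
#'
#' Protocol files are plain-text `key = value` pairs with keys `b1_uT`,
#' `t_sat_s`, `larmor_MHz` and optionally `reference_offset_ppm`; the
#' offset list lives in a separate offsets file (see [read_offsets()]).
#'
#' @param path Path of the config file.
#' @param offsets Offsets (ppm) to attach to the protocol.
#' @return A [saturation_protocol()].
#' @export
read_protocol <- function(path, offsets) {
  kv <- parse_kv_file(path)
  need <- c("b1_uT", "t_sat_s", "larmor_MHz")
  if (!all(need %in% names(kv)))
    stop("protocol file must define: ", paste(need, collapse = ", "))
  saturation_protocol(
    b1 = as.numeric(kv$b1_uT), t_sat = as.numeric(kv$t_sat_s),
    offsets = offsets, larmor = as.numeric(kv$larmor_MHz),
    reference_offset = if (!is.null(kv$reference_offset_ppm))
      as.numeric(kv$reference_offset_ppm) else 300)
}

#' @rdname read_protocol
#' @param protocol A [saturation_protocol()] to write.
#' @export
write_protocol <- function(protocol, path) {
  writeLines(c(
    sprintf("b1_uT = %.10g", protocol$b1),
    sprintf("t_sat_s = %.10g", protocol$t_sat),
    sprintf("larmor_MHz = %.10g", protocol$larmor),
    sprintf("reference_offset_ppm = %.10g", protocol$reference_offset)),
    path)
  invisible(path)
}

#' Read or write a prior registry
#'
#' Priors are stored as plain CSV with the columns of [default_priors()].
#'
#' @param path CSV path.
#' @return `read_priors`: the registry data frame.
#' @export
read_priors <- function(path) {
  reg <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("pool", "param", "transform", "mean", "sd", "lower", "upper",
            "frozen")
  if (!all(need %in% names(reg)))
    stop("priors file must have columns: ", paste(need, collapse = ", "))
  reg$frozen <- as.logical(reg$frozen)
  reg
}

#' @rdname read_priors
#' @param priors Registry data frame to write.
#' @export
write_priors <- function(priors, path) {
  write.csv(priors, path, row.names = FALSE)
  invisible(path)
}

nifti_affine <- function(img) unclass(RNifti::xform(img))

#' Load and grid-check a CEST dataset
#'
#' Reads the 4D CEST data, the offsets list, and any auxiliary volumes
#' (unsaturated reference, tissue/CSF PVE maps, ROI masks), verifying that
#' the 4th-dimension length equals the number of offsets and that every
#' volume shares the data grid and affine (within `1e-3`). Non-finite
#' voxels in the data raise a warning and are removed from the validity
#' mask.
#'
#' @param data_path Path to the 4D NIfTI CEST data.
#' @param offsets_path Path to the plain-text offsets file.
#' @param protocol_path Optional protocol config ([read_protocol()]); when
#'   `NULL` the default B1/duration/field are assumed.
#' @param s0_path,tissue_pve_path,csf_pve_path Optional volume paths.
#' @param mask_paths Optional named character vector of ROI mask paths.
#' @return A list of class `"cest_bundle"`: `data_4d`, `offsets`,
#'   `protocol`, `affine`, `valid_mask`, plus any of `s0`, `tissue_pve`,
#'   `csf_pve`, `masks` that were supplied.
#' @export
load_bundle <- function(data_path, offsets_path, protocol_path = NULL,
                        s0_path = NULL, tissue_pve_path = NULL,
                        csf_pve_path = NULL, mask_paths = NULL) {
  img <- RNifti::readNifti(data_path)
  data_4d <- unclass(img)[, , , , drop = FALSE]
  if (length(dim(data_4d)) != 4L)
    stop("'", data_path, "' is not 4D (dims: ",
         paste(dim(img), collapse = "x"), ")")
  offsets <- read_offsets(offsets_path)
  if (length(offsets) != dim(data_4d)[4L])
    stop("offset-count mismatch: ", length(offsets), " offsets but ",
         dim(data_4d)[4L], " volumes in '", data_path, "'")
  protocol <- if (is.null(protocol_path)) {
    p <- default_protocol(); p$offsets <- offsets; p
  } else read_protocol(protocol_path, offsets)
  aff <- nifti_affine(img)
  vdim <- dim(data_4d)[1:3]

  read_aux <- function(path, what) {
    if (is.null(path)) return(NULL)
    a <- RNifti::readNifti(path)
    adim <- dim(a)
    if (is.null(adim)) adim <- length(a)
    adim <- c(adim, 1L, 1L)[1:3]   # NIfTI drops trailing singleton dims
    if (!identical(as.integer(adim), as.integer(vdim)))
      stop("grid mismatch for ", what, ": data is ",
           paste(vdim, collapse = "x"), " but '", path, "' is ",
           paste(adim, collapse = "x"))
    if (max(abs(nifti_affine(a) - aff)) > 1e-3)
      stop("affine mismatch beyond 1e-3 for ", what, " ('", path, "')")
    array(as.numeric(a), dim = vdim)
  }
  bundle <- list(data_4d = data_4d, offsets = offsets, protocol = protocol,
                 affine = aff,
                 s0 = read_aux(s0_path, "unsaturated reference"),
                 tissue_pve = read_aux(tissue_pve_path, "tissue PVE map"),
                 csf_pve = read_aux(csf_pve_path, "CSF PVE map"))
  if (!is.null(mask_paths))
    bundle$masks <- lapply(setNames(as.list(mask_paths), names(mask_paths)),
                           function(p) read_aux(p, "ROI mask") > 0.5)
  valid <- array(TRUE, dim = vdim)
  bad <- apply(!is.finite(data_4d), c(1, 2, 3), any)
  if (any(bad)) {
    warning(sum(bad), " voxel(s) contain non-finite data; masked out")
    valid[bad] <- FALSE
  }
  bundle$valid_mask <- valid
  structure(bundle, class = "cest_bundle")
}

hash_config <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(deparse(x), collapse = "\n"), f)
  unname(tools::md5sum(f))
}

#' Write parameter maps as NIfTI volumes with a manifest
#'
#' Writes each map as a float32 NIfTI file named `<name>.nii.gz` and a
#' `manifest.json` listing every written file together with provenance
#' (model tag, configuration hash, seed).
#'
#' @param maps Named list of 3D numeric or logical arrays.
#' @param out_dir Output directory (created if needed).
#' @param reference Optional NIfTI image or path whose affine/header is
#'   used as template.
#' @param info Named list recorded in the manifest (e.g. `model`, `seed`,
#'   `config` -- the config is hashed, not embedded).
#' @return Invisibly, the manifest path.
#' @export
write_maps <- function(maps, out_dir, reference = NULL, info = list()) {
  stopifnot(is.list(maps), length(names(maps)) == length(maps))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (nm in names(maps)) {
    m <- maps[[nm]]
    if (is.logical(m)) m <- array(as.numeric(m), dim = dim(m))
    path <- file.path(out_dir, paste0(nm, ".nii.gz"))
    if (!is.null(reference)) {
      img <- RNifti::asNifti(m, reference = reference)
      RNifti::writeNifti(img, path, datatype = "float")
    } else {
      RNifti::writeNifti(m, path, datatype = "float")
    }
    files <- c(files, basename(path))
  }
  manifest <- list(
    files = files,
    model = if (!is.null(info$model)) info$model else NA,
    seed = if (!is.null(info$seed)) info$seed else NA,
    config_hash = if (!is.null(info$config)) hash_config(info$config)
                  else NA,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  invisible(mpath)
}

#' Write a phantom dataset to disk
#'
#' Writes the synthetic 4D data, unsaturated reference, PVE maps and ROI
#' masks as NIfTI, the offsets and protocol as plain text, the per-voxel
#' ground truth as CSV, and a manifest -- a directory immediately
#' consumable by [load_bundle()] and the `fit` command line.
#'
#' @param dataset A [generate_phantom()] result.
#' @param out_dir Output directory.
#' @return Invisibly, `out_dir`.
#' @export
write_phantom <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "phantom_dataset"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  RNifti::writeNifti(dataset$data_4d, file.path(out_dir, "cest.nii.gz"),
                     datatype = "float")
  write_maps(list(s0 = dataset$s0_volume,
                  tissue_pve = dataset$tissue_pve,
                  csf_pve = dataset$csf_pve,
                  core_mask = dataset$roi$core,
                  contra_mask = dataset$roi$contralateral),
             out_dir,
             info = list(model = "phantom", seed = dataset$spec$seed,
                         config = dataset$spec[c("dims", "amide_reduction",
                                                 "noise_sd", "seed")]))
  write_offsets(dataset$protocol$offsets, file.path(out_dir, "offsets.txt"))
  write_protocol(dataset$protocol, file.path(out_dir, "protocol.cfg"))
  write.csv(dataset$truth, file.path(out_dir, "truth.csv"),
            row.names = FALSE)
  invisible(out_dir)
}
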