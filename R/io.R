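# TIFF I/O. The installed tiff backend stores samples reliably only in
# [0, 1], so float imagery is linearly rescaled on write and the offset and
# scale are carried in a JSON sidecar next to the file; frame stacks are
# written as 16-bit camera counts over a fixed ADU ceiling.

sidecar_path <- function(path) paste0(path, ".json")

#' Write a float image as 32-bit TIFF with a JSON sidecar
#'
#' @param x Numeric matrix.
#' @param path Output TIFF path; `<path>.json` records offset and scale.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(x, path) {
  stopifnot(is.matrix(x))
  offset <- min(x)
  scale <- max(x) - offset
  if (scale <= 0) scale <- 1
  tiff::writeTIFF((x - offset) / scale, path, bits.per.sample = 32L,
                  compression = "deflate", reduce = FALSE)
  jsonlite::write_json(list(offset = offset, scale = scale,
                            nrow = nrow(x), ncol = ncol(x)),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a 32-bit TIFF written by [write_image_tiff()]
#' @param path TIFF path.
#' @return Numeric matrix.
#' @export
read_image_tiff <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path))
  y <- tiff::readTIFF(path)
  if (length(dim(y)) > 2) y <- y[, , 1]
  y * meta$scale + meta$offset
}

#' Write a frame stack as multi-page 16-bit TIFF
#'
#' @param frames List of matrices in camera ADU.
#' @param path Output TIFF path.
#' @param max_adu Full-scale ADU value mapped to the 16-bit ceiling.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(frames, path, max_adu = 65535) {
  stopifnot(is.list(frames), length(frames) >= 1)
  norm <- lapply(frames, function(f) pmin(pmax(f / max_adu, 0), 1))
  tiff::writeTIFF(norm, path, bits.per.sample = 16L, compression = "deflate")
  jsonlite::write_json(list(max_adu = max_adu, n_frames = length(frames)),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF stack written by [write_stack_tiff()]
#' @param path TIFF path.
#' @return List of matrices in camera ADU.
#' @export
read_stack_tiff <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path))
  y <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(y)) y <- list(y)
  lapply(y, function(f) f * meta$max_adu)
}

#' Write a simulated dataset to a directory
#'
#' Serialises a [simulate_fov()] dataset: single-frame TIFFs for the
#' interferogram, fluorescence channels, their backgrounds and a
#' bright-field placeholder; multi-frame TIFFs for the radioluminescence
#' and dark stacks; the ground-truth phantom table as CSV; and a JSON
#' manifest with the optics/acquisition configuration and seed.
#'
#' @param ds An `rc_dataset` from [simulate_fov()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "rc_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(dir, f)
  write_image_tiff(ds$qpm$sample, fp("interferogram.tif"))
  write_image_tiff(ds$qpm$background, fp("interferogram_bg.tif"))
  write_image_tiff(ds$gfp$image, fp("gfp.tif"))
  write_image_tiff(ds$gfp$background, fp("gfp_bg.tif"))
  write_image_tiff(ds$rfp$image, fp("rfp.tif"))
  write_image_tiff(ds$rfp$background, fp("rfp_bg.tif"))
  write_image_tiff(ds$brightfield, fp("brightfield.tif"))
  write_stack_tiff(ds$rlm$frames, fp("rlm_stack.tif"))
  write_stack_tiff(ds$rlm$dark, fp("rlm_dark.tif"))
  truth <- as.data.frame(ds$phantoms)
  utils::write.csv(truth, fp("truth.csv"), row.names = FALSE)
  manifest <- list(
    seed = ds$seed,
    n_cells = nrow(ds$phantoms),
    optics = unclass(ds$optics),
    acq = unclass(ds$acq),
    noise = ds$noise,
    generator = paste0("radiocell ",
                       as.character(utils::packageVersion("radiocell")))
  )
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset()]
#' @param dir Dataset directory.
#' @return An `rc_dataset` (without the ground-truth event ledger, which is
#'   not serialised).
#' @export
read_dataset <- function(dir) {
  fp <- function(f) file.path(dir, f)
  manifest <- jsonlite::read_json(fp("manifest.json"))
  optics <- optics_config(
    pixel_pitch_um = manifest$optics$pixel_pitch_um,
    sensor_px = manifest$optics$sensor_px,
    wavelength_um = manifest$optics$wavelength_um,
    carrier_freq_cyc_per_um = unlist(manifest$optics$carrier_freq_cyc_per_um),
    rlm_binning = manifest$optics$rlm_binning,
    psf_fwhm_um = manifest$optics$psf_fwhm_um)
  acq <- acq_config(
    n_frames = manifest$acq$n_frames,
    exposure_s = manifest$acq$exposure_s,
    dead_time_fraction = manifest$acq$dead_time_fraction,
    start_offset_min = manifest$acq$start_offset_min,
    half_life_min = manifest$acq$half_life_min,
    n_dark_frames = manifest$acq$n_dark_frames)
  phantoms <- utils::read.csv(fp("truth.csv"), stringsAsFactors = FALSE)
  phantoms$cycle_phase <- factor(phantoms$cycle_phase,
                                 levels = cycle_phases())
  structure(list(
    phantoms = phantoms,
    qpm = list(sample = read_image_tiff(fp("interferogram.tif")),
               background = read_image_tiff(fp("interferogram_bg.tif")),
               phase_truth = NULL),
    gfp = list(image = read_image_tiff(fp("gfp.tif")),
               background = read_image_tiff(fp("gfp_bg.tif"))),
    rfp = list(image = read_image_tiff(fp("rfp.tif")),
               background = read_image_tiff(fp("rfp_bg.tif"))),
    brightfield = read_image_tiff(fp("brightfield.tif")),
    rlm = structure(list(frames = read_stack_tiff(fp("rlm_stack.tif")),
                         dark = read_stack_tiff(fp("rlm_dark.tif")),
                         events = NULL, optics = optics, acq = acq),
                    class = "rlm_stack"),
    optics = optics, acq = acq,
    noise = manifest$noise,
    seed = manifest$seed
  ), class = "rc_dataset")
}
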