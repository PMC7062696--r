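#' Normalise a fluorescence channel against its background image
#'
#' Divides the raw channel image by its (smoothed) empty-field background to
#' compensate for nonuniform excitation light, subtracts the average count
#' of an empty region, and zeroes all pixels below a noise threshold. The
#' empty region is taken as the pixels below the `empty_quantile` quantile
#' of the normalised image (cells occupy a small area fraction); the noise
#' threshold is `noise_k` empty-region standard deviations.
#'
#' @param image,background Numeric matrices of identical shape.
#' @param smooth_sigma_px Gaussian sigma (pixels) used to smooth the
#'   background before division; the smoothed background must remain
#'   strictly positive.
#' @param empty_quantile Quantile defining the empty region.
#' @param noise_k Threshold in units of empty-region standard deviation.
#' @return An object of class `fucci_channel` with `image` (normalised,
#'   offset-subtracted, thresholded), `normalized` (before subtraction),
#'   `empty_mean`, `empty_sd`, `threshold`.
#' @export
normalize_channel <- function(image, background, smooth_sigma_px = 8,
                              empty_quantile = 0.95, noise_k = 3) {
  if (!is.matrix(image) || !is.matrix(background) ||
      !all(dim(image) == dim(background)))
    stop("image and background must be matrices of identical shape")
  bg <- background
  if (smooth_sigma_px > 0) {
    # cap the kernel so it fits small images (brush is ~6 sigma wide)
    sig <- min(smooth_sigma_px, (min(dim(background)) - 1) / 8)
    if (sig > 0)
      bg <- as.matrix(EBImage::gblur(background, sigma = sig))
  }
  if (any(bg <= 0))
    stop("background is not strictly positive after smoothing")
  norm <- image / bg
  empty <- norm <= stats::quantile(norm, empty_quantile)
  empty_mean <- mean(norm[empty])
  empty_sd <- stats::sd(norm[empty])
  out <- norm - empty_mean
  thr <- noise_k * empty_sd
  out[out < thr] <- 0
  structure(list(image = out, normalized = norm, empty_mean = empty_mean,
                 empty_sd = empty_sd, threshold = thr),
            class = "fucci_channel")
}

#' Summed fluorescence per cell
#'
#' Sums the normalised, thresholded channel intensity over each cell mask.
#'
#' @param channel A [normalize_channel()] result (or a plain matrix).
#' @param cells A [segment_cells()] result (uses each cell's undilated
#'   mask).
#' @return Numeric vector of per-cell sums, named by cell label.
#' @export
fluorescence_sums <- function(channel, cells) {
  img <- if (inherits(channel, "fucci_channel")) channel$image else channel
  vapply(cells, function(cl) {
    bb <- cl$bbox
    sum(img[bb[1]:bb[2], bb[3]:bb[4]][cl$mask])
  }, numeric(1))
}

#' Classify cell-cycle phase from FUCCI expression
#'
#' Applies the FUCCI rules to per-cell summed intensities: cells expressing
#' only the red reporter (Cdt1) are in G1; only green (geminin) in S/G2/M;
#' both in G1/S; neither in M/G1. "Expressing" means the channel sum
#' exceeds its threshold. The four rules are exhaustive and mutually
#' exclusive, and the labelling is monotone in each sum.
#'
#' @param green_sum,red_sum Nonnegative per-cell summed intensities
#'   (vectorised).
#' @param green_thresh,red_thresh Expression thresholds (>= 0).
#' @return Factor with levels [cycle_phases()].
#' @export
classify_phase <- function(green_sum, red_sum, green_thresh = 0,
                           red_thresh = 0) {
  stopifnot(green_thresh >= 0, red_thresh >= 0,
            length(green_sum) == length(red_sum))
  g <- green_sum > green_thresh
  r <- red_sum > red_thresh
  out <- ifelse(r & !g, "G1",
         ifelse(g & !r, "S_G2_M",
         ifelse(g & r, "G1_S", "M_G1")))
  factor(out, levels = cycle_phases())
}

#' Apply explicit manual phase overrides
#'
#' Mirrors the manual verification step of the reference protocol: a named
#' set of corrections (cell label -> phase) replaces the automatic
#' assignment, and every override is recorded - never silent.
#'
#' @param phases Factor of automatic assignments.
#' @param labels Cell labels aligned with `phases`.
#' @param overrides Named character vector (names = cell labels as
#'   character, values = phase names), or `NULL`.
#' @return A list with `phase` (factor) and `overridden` (logical vector).
#' @export
apply_phase_overrides <- function(phases, labels, overrides = NULL) {
  overridden <- rep(FALSE, length(phases))
  if (!is.null(overrides) && length(overrides)) {
    if (!all(overrides %in% cycle_phases()))
      stop("override phases must be one of: ",
           paste(cycle_phases(), collapse = ", "))
    idx <- match(names(overrides), as.character(labels))
    if (anyNA(idx)) stop("override refers to unknown cell label(s): ",
                         paste(names(overrides)[is.na(idx)], collapse = ", "))
    phases[idx] <- overrides
    overridden[idx] <- TRUE
  }
  list(phase = phases, overridden = overridden)
}
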