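# Sobel gradient magnitude > 0 on a padded local binary mask; returns the
# contour pixels of the mask
sobel_boundary <- function(mask) {
  m <- nrow(mask); n <- ncol(mask)
  pm <- matrix(0, m + 2L, n + 2L)
  pm[2:(m + 1L), 2:(n + 1L)] <- mask
  sh <- function(dr, dc) pm[(2L + dr):(m + 1L + dr), (2L + dc):(n + 1L + dc)]
  gx <- -sh(-1, -1) + sh(-1, 1) - 2 * sh(0, -1) + 2 * sh(0, 1) -
    sh(1, -1) + sh(1, 1)
  gy <- -sh(-1, -1) - 2 * sh(-1, 0) - sh(-1, 1) +
    sh(1, -1) + 2 * sh(1, 0) + sh(1, 1)
  (gx^2 + gy^2 > 0) & mask
}

#' Segment cells from a background-levelled phase image
#'
#' Thresholds the phase image into a binary mask, labels its connected
#' components, keeps components of at least `min_area_um2`, attaches the
#' Sobel contour of each binary mask, and (by default) excludes cells
#' touching the field-of-view border, whose radioluminescence counts would
#' be truncated. Labels are assigned in reading order of the component
#' centroids, so segmentation is deterministic across reruns.
#'
#' @param phase A [phase_image()].
#' @param phase_thresh Phase threshold in radians.
#' @param min_area_um2 Minimum component area, square micrometres.
#' @param exclude_border Drop components touching the image border.
#' @return An object of class `cell_set`: a list with `cells` (one entry
#'   per kept cell: `label`, `bbox`, `mask`, `boundary`, `centroid_um`,
#'   `area_um2`, `merged`, `dilated_bbox`, `dilated_mask`), `labels` (full
#'   integer label matrix), `pixel_pitch_um`, `dim`.
#' @export
segment_cells <- function(phase, phase_thresh = 0.1, min_area_um2 = 50,
                          exclude_border = TRUE) {
  stopifnot(inherits(phase, "phase_image"))
  v <- phase$values
  pitch <- phase$pixel_pitch_um
  mask <- v > phase_thresh
  out <- list(cells = list(), labels = matrix(0L, nrow(v), ncol(v)),
              pixel_pitch_um = pitch, dim = dim(v))
  class(out) <- "cell_set"
  if (!any(mask)) return(out)
  lab <- matrix(as.integer(EBImage::bwlabel(mask)), nrow(v), ncol(v))
  n0 <- max(lab)
  min_px <- min_area_um2 / pitch^2
  keep <- list()
  for (l in seq_len(n0)) {
    pix <- which(lab == l)
    if (length(pix) < min_px) next
    rc <- arrayInd(pix, dim(v))
    on_border <- any(rc[, 1] == 1L | rc[, 1] == nrow(v) |
                     rc[, 2] == 1L | rc[, 2] == ncol(v))
    if (exclude_border && on_border) next
    keep[[length(keep) + 1L]] <- list(old = l, rc = rc)
  }
  if (!length(keep)) return(out)
  cy <- vapply(keep, function(k) mean(k$rc[, 1]), numeric(1))
  cx <- vapply(keep, function(k) mean(k$rc[, 2]), numeric(1))
  ord <- order(round(cy / 8), cx)  # reading order, row bands of ~8 px
  keep <- keep[ord]
  labels <- matrix(0L, nrow(v), ncol(v))
  cells <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    rc <- keep[[i]]$rc
    labels[rc] <- i
    bb <- c(min(rc[, 1]), max(rc[, 1]), min(rc[, 2]), max(rc[, 2]))
    lm <- matrix(FALSE, bb[2] - bb[1] + 1L, bb[4] - bb[3] + 1L)
    lm[cbind(rc[, 1] - bb[1] + 1L, rc[, 2] - bb[3] + 1L)] <- TRUE
    cells[[i]] <- list(label = i, bbox = bb, mask = lm,
                       boundary = sobel_boundary(lm),
                       centroid_um = c(x = (mean(rc[, 2]) - 1) * pitch,
                                       y = (mean(rc[, 1]) - 1) * pitch),
                       area_um2 = nrow(rc) * pitch^2,
                       merged = FALSE,
                       dilated_bbox = NULL, dilated_mask = NULL)
  }
  out$cells <- cells
  out$labels <- labels
  out
}

#' @export
print.cell_set <- function(x, ...) {
  nm <- sum(vapply(x$cells, `[[`, logical(1), "merged"))
  cat("Cell set: ", length(x$cells), " cells (", nm, " flagged merged) on ",
      x$dim[1], "x", x$dim[2], " px @ ", x$pixel_pitch_um, " um/px\n",
      sep = "")
  invisible(x)
}

#' Dilate cell boundaries and flag merged cells
#'
#' Dilates every cell mask by a disc of radius `sigma_um` (one PSF sigma,
#' 12.5 um by default), extending each boundary to capture events detected
#' outside the cell footprint. Cells whose dilated masks intersect are all
#' flagged as merged (the flag is symmetric) and are excluded from count
#' integration downstream, since their counts would cross-contaminate. For
#' convex cells this intersection rule is equivalent to an edge gap below
#' 2 sigma.
#'
#' @param cellset A [segment_cells()] result.
#' @param sigma_um Dilation radius in micrometres.
#' @return The updated `cell_set` with `dilated_mask`/`dilated_bbox` and
#'   `merged` flags filled in.
#' @export
dilate_and_flag <- function(cellset, sigma_um = 12.5) {
  stopifnot(inherits(cellset, "cell_set"), sigma_um > 0)
  if (!length(cellset$cells)) return(cellset)
  pitch <- cellset$pixel_pitch_um
  r_px <- max(1L, round(sigma_um / pitch))
  brush <- EBImage::makeBrush(2L * r_px + 1L, shape = "disc")
  un <- cellset$labels > 0L
  dil <- EBImage::dilate(un * 1, brush) > 0
  dlab <- matrix(as.integer(EBImage::bwlabel(dil)), nrow(dil), ncol(dil))
  # which dilated component holds each cell, and how many cells per comp
  comp <- vapply(cellset$cells, function(cl) {
    rc <- which(cl$mask, arr.ind = TRUE)[1, , drop = FALSE]
    dlab[cl$bbox[1] + rc[1] - 1L, cl$bbox[3] + rc[2] - 1L]
  }, integer(1))
  tab <- table(comp)
  for (i in seq_along(cellset$cells)) {
    ci <- comp[i]
    cellset$cells[[i]]$merged <- tab[[as.character(ci)]] > 1L
    pix <- which(dlab == ci)
    rc <- arrayInd(pix, dim(dlab))
    bb <- c(min(rc[, 1]), max(rc[, 1]), min(rc[, 2]), max(rc[, 2]))
    dm <- matrix(FALSE, bb[2] - bb[1] + 1L, bb[4] - bb[3] + 1L)
    dm[cbind(rc[, 1] - bb[1] + 1L, rc[, 2] - bb[3] + 1L)] <- TRUE
    cellset$cells[[i]]$dilated_bbox <- bb
    cellset$cells[[i]]$dilated_mask <- dm
  }
  attr(cellset, "dilation_sigma_um") <- sigma_um
  cellset
}

#' Integrate radioluminescence counts inside a dilated cell boundary
#'
#' Sums the counts grid over the cell's dilated mask downsampled to the
#' binned resolution - a binned pixel is inside when its centre falls in
#' the dilated mask (both grids share their physical origin at the
#' top-left pixel centre, so binned pixel (i, j) is probed at full-
#' resolution pixel (binning x i, binning x j)) - divides by the live time
#' and multiplies by the decay correction factor.
#'
#' @param cell One entry of a dilated `cell_set` (must not be merged).
#' @param counts A [accumulate_events()] counts image.
#' @param binning Integer ratio between the phase and counts grids.
#' @param decay_factor Decay correction multiplier; defaults to the one
#'   recorded in `counts`.
#' @param full_dim Dimensions of the full-resolution grid (for the
#'   registration check).
#' @return Decay-corrected counts per minute (nonnegative scalar).
#' @export
integrate_counts <- function(cell, counts, binning = 8L,
                             decay_factor = counts$decay_factor,
                             full_dim = NULL) {
  stopifnot(inherits(counts, "counts_image"))
  if (isTRUE(cell$merged))
    stop("cell is flagged merged; counts would be cross-contaminated")
  if (is.null(cell$dilated_mask))
    stop("cell has no dilated mask; run dilate_and_flag() first")
  if (!is.null(full_dim) &&
      !all(dim(counts$grid) * binning == full_dim))
    stop("phase and counts grids are not registered")
  bb <- cell$dilated_bbox
  # binned pixels whose centre (full-res pixel binning*i, 0-based) lies in
  # the dilated bbox
  i0 <- ceiling((bb[1] - 1L) / binning); i1 <- floor((bb[2] - 1L) / binning)
  j0 <- ceiling((bb[3] - 1L) / binning); j1 <- floor((bb[4] - 1L) / binning)
  i1 <- min(i1, nrow(counts$grid) - 1L); j1 <- min(j1, ncol(counts$grid) - 1L)
  tot <- 0L
  if (i0 <= i1 && j0 <= j1) {
    ii <- i0:i1; jj <- j0:j1
    inmask <- cell$dilated_mask[cbind(rep(ii * binning + 1L - bb[1] + 1L,
                                          length(jj)),
                                      rep(jj * binning + 1L - bb[3] + 1L,
                                          each = length(ii)))]
    sub <- counts$grid[ii + 1L, jj + 1L, drop = FALSE]
    tot <- sum(sub[matrix(inmask, length(ii), length(jj))])
  }
  tot / counts$live_time_min * decay_factor
}

#' Assemble the per-cell measurement table
#'
#' Joins the three modality outputs for one field of view: segments cells
#' from the phase image, computes each cell's dry mass, sums the normalised
#' fluorescence channels and classifies the cycle phase (with optional
#' explicit manual overrides), dilates boundaries and discards merged
#' cells, and integrates decay-corrected radioluminescence counts.
#'
#' @param phase A [phase_image()] (background-levelled).
#' @param green,red [normalize_channel()] results for the GFP and RFP
#'   channels.
#' @param counts A [accumulate_events()] counts image.
#' @param binning Ratio between phase and counts grid resolutions.
#' @param dilation_sigma_um Boundary dilation radius (one PSF sigma).
#' @param phase_thresh,min_area_um2 Segmentation settings.
#' @param dm_params A [dry_mass_params()].
#' @param decay_factor Decay correction multiplier.
#' @param overrides Optional named character vector of manual phase
#'   overrides (label -> phase).
#' @param green_thresh,red_thresh Optional scalar expression thresholds for
#'   the channel sums; by default each cell's threshold is `3 x` the
#'   channel's empty-region pixel standard deviation `x sqrt(cell area in
#'   pixels)` (the summed-noise scale).
#' @return A data.frame of class `cell_table` with one row per retained
#'   (non-merged) cell: `label`, `x_um`, `y_um`, `area_um2`, `dry_mass_pg`,
#'   `green_sum`, `red_sum`, `cycle_phase`, `counts_per_min`, `merged`,
#'   `overridden`. Discarded cells are recorded in `attr(, "discarded")`.
#' @export
build_cell_table <- function(phase, green, red, counts, binning = 8L,
                             dilation_sigma_um = 12.5,
                             phase_thresh = 0.1, min_area_um2 = 50,
                             dm_params = dry_mass_params(),
                             decay_factor = counts$decay_factor,
                             overrides = NULL,
                             green_thresh = NULL, red_thresh = NULL) {
  stopifnot(inherits(phase, "phase_image"))
  gi <- if (inherits(green, "fucci_channel")) green$image else green
  ri <- if (inherits(red, "fucci_channel")) red$image else red
  if (!all(dim(gi) == dim(phase$values)) ||
      !all(dim(ri) == dim(phase$values)))
    stop("modality geometries do not match")
  if (!all(dim(counts$grid) * binning == dim(phase$values)))
    stop("modality geometries do not match")

  cs <- segment_cells(phase, phase_thresh, min_area_um2)
  cs <- dilate_and_flag(cs, dilation_sigma_um)
  n <- length(cs$cells)
  if (n == 0L) {
    out <- data.frame(label = integer(), x_um = numeric(), y_um = numeric(),
                      area_um2 = numeric(), dry_mass_pg = numeric(),
                      green_sum = numeric(), red_sum = numeric(),
                      cycle_phase = factor(character(),
                                           levels = cycle_phases()),
                      counts_per_min = numeric(), merged = logical(),
                      overridden = logical())
    class(out) <- c("cell_table", "data.frame")
    attr(out, "discarded") <- data.frame(label = integer(),
                                         reason = character())
    return(out)
  }

  gsum <- fluorescence_sums(green, cs$cells)
  rsum <- fluorescence_sums(red, cs$cells)
  area_px <- vapply(cs$cells, function(cl) sum(cl$mask), numeric(1))
  gsd <- if (inherits(green, "fucci_channel")) green$empty_sd else 0
  rsd <- if (inherits(red, "fucci_channel")) red$empty_sd else 0
  gth <- if (is.null(green_thresh)) 3 * gsd * sqrt(area_px) + 1e-6 else
    rep(green_thresh, n)
  rth <- if (is.null(red_thresh)) 3 * rsd * sqrt(area_px) + 1e-6 else
    rep(red_thresh, n)
  phs <- classify_phase(gsum, rsum, gth, rth)
  ov <- apply_phase_overrides(phs, seq_len(n), overrides)

  mass <- vapply(cs$cells, function(cl) {
    sub <- phase$values[cl$bbox[1]:cl$bbox[2], cl$bbox[3]:cl$bbox[4],
                        drop = FALSE]
    pm <- phase_image(sub, phase$pixel_pitch_um)
    dry_mass(pm, cl$mask, dm_params)
  }, numeric(1))

  merged <- vapply(cs$cells, `[[`, logical(1), "merged")
  cpm <- rep(NA_real_, n)
  for (i in which(!merged))
    cpm[i] <- integrate_counts(cs$cells[[i]], counts, binning, decay_factor,
                               full_dim = dim(phase$values))

  tab <- data.frame(
    label = seq_len(n),
    x_um = vapply(cs$cells, function(cl) cl$centroid_um[["x"]], numeric(1)),
    y_um = vapply(cs$cells, function(cl) cl$centroid_um[["y"]], numeric(1)),
    area_um2 = vapply(cs$cells, `[[`, numeric(1), "area_um2"),
    dry_mass_pg = mass,
    green_sum = as.numeric(gsum),
    red_sum = as.numeric(rsum),
    cycle_phase = ov$phase,
    counts_per_min = cpm,
    merged = merged,
    overridden = ov$overridden
  )
  out <- tab[!merged, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cell_table", "data.frame")
  attr(out, "discarded") <- data.frame(
    label = tab$label[merged],
    reason = rep("merged_by_dilation", sum(merged)))
  attr(out, "cell_set") <- cs
  out
}
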