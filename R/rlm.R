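#' Radioactive decay correction factor
#'
#' Multiplicative correction 2^(elapsed / half-life) referring measured
#' counts back to the tracer calibration time (half-life 110 min for
#' fluorine-18).
#'
#' @param elapsed_min Minutes elapsed since calibration (>= 0).
#' @param half_life_min Isotope half-life, minutes.
#' @return The decay correction multiplier (>= 1).
#' @examples
#' decay_correction_factor(0)    # 1
#' decay_correction_factor(110)  # 2
#' @export
decay_correction_factor <- function(elapsed_min, half_life_min = 110) {
  if (any(elapsed_min < 0)) stop("elapsed time must be nonnegative")
  stopifnot(half_life_min > 0)
  2^(elapsed_min / half_life_min)
}

#' Dark-field correction of a frame stack
#'
#' Subtracts the per-pixel temporal mean of the dark stack from every frame
#' and clips negative values to zero.
#'
#' @param stack List of frame matrices (or an `rlm_stack`, whose own dark
#'   frames are then used unless `dark` is given).
#' @param dark List of dark-frame matrices.
#' @return List of corrected frame matrices.
#' @export
dark_correct <- function(stack, dark = NULL) {
  if (inherits(stack, "rlm_stack")) {
    if (is.null(dark)) dark <- stack$dark
    stack <- stack$frames
  }
  stopifnot(is.list(stack), is.list(dark), length(dark) >= 1)
  if (!all(dim(stack[[1]]) == dim(dark[[1]])))
    stop("stack and dark stack geometries differ")
  dark_mean <- Reduce(`+`, dark) / length(dark)
  lapply(stack, function(f) {
    if (!all(dim(f) == dim(dark_mean)))
      stop("stack and dark stack geometries differ")
    pmax(f - dark_mean, 0)
  })
}

# 3x3 (8-neighbour) grayscale dilation
dilate3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  mm <- matrix(-Inf, nr + 2L, nc + 2L)
  mm[2:(nr + 1L), 2:(nc + 1L)] <- m
  out <- m
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    out <- pmax(out, mm[(2L + dr):(nr + 1L + dr), (2L + dc):(nc + 1L + dc)])
  }
  out
}

# grayscale morphological reconstruction of `marker` under `maskimg`
# (iterative; patches are small so convergence is quick)
grey_reconstruct <- function(marker, maskimg) {
  rec <- pmin(marker, maskimg)
  repeat {
    nxt <- pmin(dilate3(rec), maskimg)
    if (all(nxt == rec)) return(rec)
    rec <- nxt
  }
}

# h-maxima domains of a patch: connected plateaus of the regional maxima of
# reconstruct(patch - h, patch); each domain is a peak of prominence >= h
h_maxima_domains <- function(patch, h) {
  rec <- grey_reconstruct(pmax(patch - h, 0), patch)
  regmax <- (rec >= dilate3(rec)) & (patch > 0)
  if (!any(regmax)) return(matrix(0L, nrow(patch), ncol(patch)))
  lab <- EBImage::bwlabel(regmax)
  matrix(as.integer(lab), nrow(patch), ncol(patch))
}

# fraction of a track's spectral energy beyond the k-space radius `radius`
# expressed on a grid of width frame_n; computed on a power-of-two patch
# holding the above-threshold track profile (patch-size invariant by
# Parseval up to discretisation)
track_sharpness <- function(vals, rc, frame_n, radius) {
  if (sum(vals) <= 0) return(0)
  ext <- max(diff(range(rc[, 1])), diff(range(rc[, 2]))) + 1
  p <- 2^ceiling(log2(max(16, 2 * ext)))
  patch <- matrix(0, p, p)
  r0 <- min(rc[, 1]); c0 <- min(rc[, 2])
  off <- floor((p - ext) / 2)
  patch[cbind(rc[, 1] - r0 + 1L + off, rc[, 2] - c0 + 1L + off)] <- vals
  e <- Mod(stats::fft(patch))^2
  e[1, 1] <- 0
  k <- ifelse(seq_len(p) - 1 > p / 2, seq_len(p) - 1 - p, seq_len(p) - 1)
  d2 <- outer(k^2, k^2, `+`)
  cutoff <- radius * p / frame_n
  tot <- sum(e)
  if (tot <= 0) return(0)
  sum(e[d2 > cutoff^2]) / tot
}

#' Detect scintillation events in a single frame
#'
#' ORBIT-style single-frame event detection: the dark-corrected frame is
#' binarised at `binary_threshold`; shallow maxima are suppressed with an
#' h-maxima step of height `h_value` (a connected component containing two
#' or more peaks of prominence at least `h_value` is split between them);
#' each resulting component yields one event with its intensity-weighted
#' centre of gravity, maximum Feret extent (binned pixels) and spectral
#' sharpness score. Events are classified `long` when the extent exceeds
#' `max_length_px`, `diffuse` when the high-frequency energy fraction falls
#' below the sharpness cutoff (deep-crystal gamma glows), `sensor_hit` for
#' single-pixel saturated impulses, and `short` otherwise.
#'
#' @param frame Dark-corrected frame matrix at binned resolution.
#' @param params An [orbit_params()].
#' @param frame_index Frame number recorded with each event.
#' @param pitch_um Binned pixel pitch (micrometres) for the `x_um`/`y_um`
#'   columns.
#' @return A data.frame with one row per event: `frame_index`, `x_px`,
#'   `y_px` (0-based binned-pixel centroid), `x_um`, `y_um`, `length_px`,
#'   `n_px`, `peak_intensity`, `sharpness`, `klass`.
#' @export
detect_events <- function(frame, params = orbit_params(), frame_index = 0L,
                          pitch_um = 5) {
  stopifnot(is.matrix(frame))
  empty <- data.frame(frame_index = integer(), x_px = numeric(),
                      y_px = numeric(), x_um = numeric(), y_um = numeric(),
                      length_px = numeric(), n_px = integer(),
                      peak_intensity = numeric(), sharpness = numeric(),
                      klass = character(), stringsAsFactors = FALSE)
  if (max(frame) < params$binary_threshold) return(empty)
  mask <- frame >= params$binary_threshold
  lab <- matrix(as.integer(EBImage::bwlabel(mask)), nrow(frame), ncol(frame))
  nlab <- max(lab)
  if (nlab == 0L) return(empty)
  nr <- nrow(frame)
  rows <- vector("list", nlab)
  mkrow <- function(src) {
    # one event from a set of pixel coordinates (rows of arrayInd)
    w <- frame[src]
    cy <- sum(w * (src[, 1] - 1)) / sum(w)
    cx <- sum(w * (src[, 2] - 1)) / sum(w)
    len <- if (nrow(src) == 1L) 1 else max(stats::dist(src)) + 1
    peak <- max(w)
    kl <- NA_character_
    sh <- NA_real_
    if (nrow(src) == 1L && peak >= params$sensor_hit_min_intensity) {
      kl <- "sensor_hit"
    } else if (len > params$max_length_px) {
      kl <- "long"
    } else {
      sh <- track_sharpness(pmax(w - params$binary_threshold, 0), src,
                            nr, params$sharpness)
      kl <- if (sh < params$sharpness_min_fraction) "diffuse" else "short"
    }
    data.frame(frame_index = frame_index, x_px = cx, y_px = cy,
               x_um = cx * pitch_um, y_um = cy * pitch_um,
               length_px = len, n_px = nrow(src), peak_intensity = peak,
               sharpness = sh, klass = kl, stringsAsFactors = FALSE)
  }
  for (l in seq_len(nlab)) {
    pix <- which(lab == l)
    rc <- arrayInd(pix, dim(frame))
    # a track longer than the cutoff is a single (rejected) event; the
    # h-maxima split below applies only to compact components, so noise
    # ripple along a streak cannot shatter it into spurious short events
    len_comp <- if (nrow(rc) == 1L) 1 else max(stats::dist(rc)) + 1
    if (len_comp > params$max_length_px) {
      rows[[l]] <- mkrow(rc)
      next
    }
    r0 <- max(1L, min(rc[, 1]) - 2L); r1 <- min(nr, max(rc[, 1]) + 2L)
    c0 <- max(1L, min(rc[, 2]) - 2L); c1 <- min(ncol(frame), max(rc[, 2]) + 2L)
    patch <- frame[r0:r1, c0:c1, drop = FALSE]
    incomp <- lab[r0:r1, c0:c1, drop = FALSE] == l
    dom <- h_maxima_domains(patch * incomp, params$h_value)
    ndom <- max(dom)
    if (ndom >= 2L) {
      prc <- cbind(rc[, 1] - r0 + 1L, rc[, 2] - c0 + 1L)
      cen <- t(vapply(seq_len(ndom), function(d) {
        colMeans(which(dom == d, arr.ind = TRUE))
      }, numeric(2)))
      d2 <- outer(prc[, 1], cen[, 1], `-`)^2 + outer(prc[, 2], cen[, 2], `-`)^2
      part <- max.col(-d2)
      rows[[l]] <- do.call(rbind, lapply(seq_len(ndom), function(pidx)
        mkrow(rc[part == pidx, , drop = FALSE])))
    } else {
      rows[[l]] <- mkrow(rc)
    }
  }
  do.call(rbind, rows)
}

#' Detect events across a whole stack
#'
#' Applies [detect_events()] to every frame of a dark-corrected stack.
#'
#' @param stack List of dark-corrected frame matrices.
#' @param params An [orbit_params()].
#' @param pitch_um Binned pixel pitch, micrometres.
#' @return Combined event data.frame (`frame_index` is 1-based).
#' @export
detect_stack <- function(stack, params = orbit_params(), pitch_um = 5) {
  out <- vector("list", length(stack))
  for (f in seq_along(stack)) {
    ev <- detect_events(stack[[f]], params, frame_index = f,
                        pitch_um = pitch_um)
    if (nrow(ev)) out[[f]] <- ev
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(detect_events(matrix(0, 2, 2), params))
  do.call(rbind, out)
}

#' Accumulate accepted events into a counts image
#'
#' Increments a counter at each accepted event's nearest binned pixel
#' (round half away from zero; coordinates are 0-based pixel-centre).
#' Long tracks, diffuse glows and direct sensor hits are discarded; only
#' the classes in `accept` (default `short`) are counted. The grid total
#' equals the accepted-event count exactly.
#'
#' @param events Event data.frame from [detect_stack()].
#' @param dims Length-2 grid dimensions (rows, cols) at binned resolution.
#' @param live_time_min Live acquisition time in minutes
#'   (frames x exposure / 60).
#' @param decay_factor Decay correction multiplier recorded with the image.
#' @param accept Character vector of accepted classes.
#' @return An object of class `counts_image` with `grid` (integer matrix),
#'   `live_time_min`, `decay_factor`, `accepted_classes`, `n_accepted`.
#' @export
accumulate_events <- function(events, dims, live_time_min,
                              decay_factor = 1, accept = "short") {
  stopifnot(length(dims) == 2, live_time_min > 0, decay_factor >= 1)
  grid <- matrix(0L, dims[1], dims[2])
  keep <- events[events$klass %in% accept, , drop = FALSE]
  if (nrow(keep)) {
    iy <- pmin(pmax(floor(keep$y_px + 0.5), 0), dims[1] - 1L) + 1L
    ix <- pmin(pmax(floor(keep$x_px + 0.5), 0), dims[2] - 1L) + 1L
    for (r in seq_along(ix)) grid[iy[r], ix[r]] <- grid[iy[r], ix[r]] + 1L
  }
  structure(list(grid = grid, live_time_min = live_time_min,
                 decay_factor = decay_factor, accepted_classes = accept,
                 n_accepted = nrow(keep)),
            class = "counts_image")
}

#' @export
print.counts_image <- function(x, ...) {
  cat("Counts image ", nrow(x$grid), "x", ncol(x$grid), ": ",
      sum(x$grid), " accepted events over ", round(x$live_time_min, 2),
      " live minutes (decay factor ", round(x$decay_factor, 4), ")\n",
      sep = "")
  invisible(x)
}
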