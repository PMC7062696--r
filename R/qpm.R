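#' Phase image container
#'
#' A 2-D map of optical phase in radians together with its pixel pitch.
#' After background compensation the cell-free region is centred at zero.
#'
#' @param values Numeric matrix of phase values (radians); rows index y,
#'   columns index x.
#' @param pixel_pitch_um Pixel pitch in micrometres.
#' @return An object of class `phase_image`.
#' @export
phase_image <- function(values, pixel_pitch_um) {
  stopifnot(is.matrix(values), pixel_pitch_um > 0)
  if (!all(is.finite(values))) stop("phase values must be finite")
  structure(list(values = values, pixel_pitch_um = pixel_pitch_um),
            class = "phase_image")
}

#' @export
print.phase_image <- function(x, ...) {
  cat("Phase image ", nrow(x$values), "x", ncol(x$values), " px @ ",
      x$pixel_pitch_um, " um/px; range [",
      round(min(x$values), 3), ", ", round(max(x$values), 3), "] rad\n",
      sep = "")
  invisible(x)
}

# wrap to (-pi, pi]
wrap_pi <- function(x) x - 2 * pi * round(x / (2 * pi))

# Solve the discrete Poisson equation with Neumann boundaries by even
# (mirror) extension and FFT diagonalisation; solution defined up to an
# additive constant (fixed by zeroing the DC mode).
solve_poisson_neumann <- function(rho) {
  m <- nrow(rho); n <- ncol(rho)
  e <- rbind(cbind(rho, rho[, n:1, drop = FALSE]),
             cbind(rho[m:1, , drop = FALSE], rho[m:1, n:1, drop = FALSE]))
  f <- stats::fft(e)
  wi <- 2 * cos(2 * pi * (seq_len(2 * m) - 1) / (2 * m))
  wj <- 2 * cos(2 * pi * (seq_len(2 * n) - 1) / (2 * n))
  denom <- outer(wi, wj, `+`) - 4
  denom[1, 1] <- 1
  f <- f / denom
  f[1, 1] <- 0
  phi <- Re(stats::fft(f, inverse = TRUE)) / (4 * m * n)
  phi[seq_len(m), seq_len(n), drop = FALSE]
}

#' Two-dimensional least-squares phase unwrapping
#'
#' Unwraps a wrapped phase map by integrating its wrapped gradients in the
#' least-squares sense (Poisson solve with Neumann boundaries via a mirrored
#' FFT). Exact for consistent (residue-free) gradient fields, which is the
#' regime of compact smooth cells; the result is offset so that it agrees
#' with the wrapped input modulo 2 pi in the median.
#'
#' @param psi Numeric matrix of wrapped phase values (radians).
#' @return Numeric matrix of continuous phase, same shape.
#' @export
unwrap_phase <- function(psi) {
  stopifnot(is.matrix(psi))
  m <- nrow(psi); n <- ncol(psi)
  dx <- matrix(0, m, n); dy <- matrix(0, m, n)
  dx[, -n] <- wrap_pi(psi[, -1, drop = FALSE] - psi[, -n, drop = FALSE])
  dy[-m, ] <- wrap_pi(psi[-1, , drop = FALSE] - psi[-m, , drop = FALSE])
  rho <- dx; rho[, -1] <- rho[, -1] - dx[, -n, drop = FALSE]
  rho2 <- dy; rho2[-1, ] <- rho2[-1, ] - dy[-m, , drop = FALSE]
  phi <- solve_poisson_neumann(rho + rho2)
  phi + stats::median(wrap_pi(psi - phi))
}

# least-squares 2nd-order polynomial surface fit on selected pixels,
# evaluated over the whole image
fit_poly2_surface <- function(img, use, stride = 1L) {
  m <- nrow(img); n <- ncol(img)
  ri <- seq(1L, m, by = stride); ci <- seq(1L, n, by = stride)
  y <- matrix((ri - 1) / (m - 1) - 0.5, length(ri), length(ci))
  x <- matrix((ci - 1) / (n - 1) - 0.5, length(ri), length(ci), byrow = TRUE)
  z <- img[ri, ci, drop = FALSE]
  u <- use[ri, ci, drop = FALSE]
  X <- cbind(1, x[u], y[u], x[u]^2, x[u] * y[u], y[u]^2)
  beta <- stats::lm.fit(X, z[u])$coefficients
  beta[!is.finite(beta)] <- 0
  yy <- (row(img) - 1) / (m - 1) - 0.5
  xx <- (col(img) - 1) / (n - 1) - 0.5
  beta[1] + beta[2] * xx + beta[3] * yy + beta[4] * xx^2 +
    beta[5] * xx * yy + beta[6] * yy^2
}

#' Retrieve the phase map from an off-axis interferogram
#'
#' Demodulates an off-axis interferogram against its empty-field background:
#' the 2-D spectrum's carrier sideband is located (auto-detected on the
#' background spectrum unless `carrier_hint` is given), extracted with a
#' circular window of radius equal to half the carrier magnitude, shifted to
#' baseband and inverse transformed for both images; the per-pixel phase is
#' the argument of the sample field times the conjugate background field,
#' unwrapped in two dimensions, and finally levelled by subtracting a
#' second-order polynomial surface fitted on cell-free pixels (robustly
#' auto-selected unless `cellfree_mask` is supplied) so the background is
#' centred at zero.
#'
#' @param interferogram,background Numeric matrices of identical shape.
#' @param pixel_pitch_um Pixel pitch in micrometres.
#' @param carrier_hint Optional length-2 carrier frequency (cycles/um, x
#'   then y) used instead of auto-detection.
#' @param cellfree_mask Optional logical matrix marking cell-free pixels for
#'   the background surface fit.
#' @param contrast_min Minimum ratio of carrier-peak magnitude to the median
#'   spectral magnitude; below it the fringe contrast is declared too low.
#' @return A [phase_image()].
#' @export
retrieve_phase <- function(interferogram, background,
                           pixel_pitch_um = 0.625,
                           carrier_hint = NULL,
                           cellfree_mask = NULL,
                           contrast_min = 5) {
  if (!is.matrix(interferogram) || !is.matrix(background) ||
      !all(dim(interferogram) == dim(background)))
    stop("interferogram and background must be matrices of identical shape")
  m <- nrow(interferogram); n <- ncol(interferogram)
  fs <- stats::fft(interferogram)
  fb <- stats::fft(background)
  mag <- Mod(fb)

  # centred frequency offsets per axis (rows = y, cols = x)
  ky <- ifelse(seq_len(m) - 1 > m / 2, seq_len(m) - 1 - m, seq_len(m) - 1)
  kx <- ifelse(seq_len(n) - 1 > n / 2, seq_len(n) - 1 - n, seq_len(n) - 1)
  if (is.null(carrier_hint)) {
    dc_excl <- max(3, round(0.02 * min(m, n)))
    d2 <- outer(ky^2, kx^2, `+`)
    cand <- mag
    cand[d2 <= dc_excl^2] <- 0
    cand[, kx < 0] <- 0      # restrict to one half-plane for determinism
    pk <- arrayInd(which.max(cand), dim(cand))
    if (cand[pk] < contrast_min * stats::median(mag))
      stop("carrier peak indistinguishable from DC: fringe contrast too low")
  } else {
    tx <- carrier_hint[1] * n * pixel_pitch_um
    ty <- carrier_hint[2] * m * pixel_pitch_um
    pk <- cbind(which.min(abs(ky - round(ty))),
                which.min(abs(kx - round(tx))))
  }
  cy <- ky[pk[1]]; cx <- kx[pk[2]]
  cdist <- sqrt(cx^2 + cy^2)
  wr <- floor(cdist / 2)
  if (wr < 2) stop("carrier peak indistinguishable from DC: fringe contrast too low")

  # circular window, raised-cosine tapered over its outer 30% to limit
  # ringing from the hard spectral cut
  d <- sqrt(outer((ky - cy)^2, (kx - cx)^2, `+`))
  win <- matrix(0, m, n)
  win[d <= 0.7 * wr] <- 1
  tap <- d > 0.7 * wr & d <= wr
  win[tap] <- 0.5 * (1 + cos(pi * (d[tap] - 0.7 * wr) / (0.3 * wr)))
  use_win <- win > 0
  demod <- function(f) {
    f <- f * win
    f <- f[c(pk[1]:m, seq_len(pk[1] - 1L)), c(pk[2]:n, seq_len(pk[2] - 1L)),
           drop = FALSE]
    stats::fft(f, inverse = TRUE) / (m * n)
  }
  s <- demod(fs)
  b <- demod(fb)
  psi <- Arg(s * Conj(b))
  phi <- unwrap_phase(psi)

  # background levelling: robust 2nd-order surface on cell-free pixels
  stride <- max(1L, floor(min(m, n) / 256))
  if (is.null(cellfree_mask)) {
    use <- matrix(TRUE, m, n)
    for (it in 1:2) {
      surf <- fit_poly2_surface(phi, use, stride)
      res <- phi - surf
      s0 <- stats::mad(res[use], center = 0)
      use <- abs(res) <= 3 * max(s0, 1e-6)
    }
  } else {
    stopifnot(all(dim(cellfree_mask) == dim(phi)))
    use <- cellfree_mask
    surf <- fit_poly2_surface(phi, use, stride)
    res <- phi - surf
  }
  out <- phi - surf
  out <- out - stats::median(out[use])
  phase_image(out, pixel_pitch_um)
}

#' Cell dry mass from a phase image
#'
#' Computes the dry mass m = lambda / (2 pi alpha) * sum(Phi) * A_px over a
#' binary cell mask, where `lambda` is the wavelength (um), `alpha` the
#' specific refraction increment (um^3/pg) and A_px the pixel area (um^2);
#' the result is in picograms. The integral is a plain Riemann sum over the
#' mask pixels.
#'
#' @param phase A [phase_image()].
#' @param mask Logical matrix congruent with the phase map.
#' @param params A [dry_mass_params()].
#' @return Dry mass in picograms.
#' @examples
#' p <- phase_image(matrix(1, 16, 16), 0.625)  # 1 rad over 100 um^2
#' dry_mass(p, matrix(TRUE, 16, 16))           # 55.97 pg
#' @export
dry_mass <- function(phase, mask, params = dry_mass_params()) {
  stopifnot(inherits(phase, "phase_image"))
  if (!is.logical(mask) || !all(dim(mask) == dim(phase$values)))
    stop("mask must be a logical matrix congruent with the phase image")
  if (!any(mask)) stop("empty mask")
  v <- phase$values[mask]
  if (any(!is.finite(v))) stop("non-finite phase under mask")
  params$wavelength_um / (2 * pi * params$alpha_um3_per_pg) *
    sum(v) * phase$pixel_pitch_um^2
}
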