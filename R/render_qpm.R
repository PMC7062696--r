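# Smooth radial bump used as the cell's phase footprint: a truncated cosine
# cap, Phi(r) = Phi0 * cos(pi r / (2 R)) for r <= R. Its area integral is
# Phi0 * R^2 * (4 - 8/pi), which the renderer inverts to set Phi0 from the
# target dry mass.
cap_integral_const <- function() 4 - 8 / pi

# peak phase (radians) of a cosine-cap cell with the given dry mass/radius
cap_peak_phase <- function(mass_pg, radius_um, params = dry_mass_params()) {
  mass_pg * (2 * pi * params$alpha_um3_per_pg / params$wavelength_um) /
    (radius_um^2 * cap_integral_const())
}

# add per-cell cosine caps (scaled by `amplitude`) onto a map; map pixel k
# (0-based) sits at k * pitch micrometres
add_caps <- function(map, x_um, y_um, radius_um, amplitude, pitch_um) {
  n <- ncol(map); m <- nrow(map)
  for (i in seq_along(x_um)) {
    r_px <- radius_um[i] / pitch_um
    cx <- x_um[i] / pitch_um; cy <- y_um[i] / pitch_um
    c0 <- max(1L, floor(cx - r_px) + 1L); c1 <- min(n, ceiling(cx + r_px) + 1L)
    r0 <- max(1L, floor(cy - r_px) + 1L); r1 <- min(m, ceiling(cy + r_px) + 1L)
    if (c0 > c1 || r0 > r1) next
    xs <- (seq(c0, c1) - 1) - cx
    ys <- (seq(r0, r1) - 1) - cy
    d <- sqrt(outer(ys^2, xs^2, `+`)) / r_px
    patch <- amplitude[i] * cos(pi * d / 2)
    patch[d > 1] <- 0
    map[r0:r1, c0:c1] <- map[r0:r1, c0:c1] + patch
  }
  map
}

#' Ground-truth phase map of a phantom population
#'
#' Renders each phantom as a truncated cosine cap whose peak phase is set by
#' inverting the dry-mass relation, so the per-cell phase integral matches
#' the phantom's `dry_mass_pg` exactly.
#'
#' @param phantoms A [make_phantom_population()] data.frame (or any
#'   data.frame with `x_um`, `y_um`, `radius_um`, `dry_mass_pg`).
#' @param optics An [optics_config()].
#' @param params A [dry_mass_params()].
#' @return A [phase_image()] at full sensor resolution.
#' @export
phantom_phase_map <- function(phantoms, optics = optics_config(),
                              params = dry_mass_params()) {
  map <- matrix(0, optics$sensor_px, optics$sensor_px)
  if (nrow(phantoms) > 0) {
    amp <- cap_peak_phase(phantoms$dry_mass_pg, phantoms$radius_um, params)
    map <- add_caps(map, phantoms$x_um, phantoms$y_um, phantoms$radius_um,
                    amp, optics$pixel_pitch_um)
  }
  phase_image(map, optics$pixel_pitch_um)
}

#' Render an off-axis interferogram of a phantom population
#'
#' Produces a carrier-fringe interferogram pair following the intensity
#' model I = A + B cos(2 pi f . x + Phi(x, y)): the background image carries
#' pure straight fringes (Phi = 0) and the sample image carries fringes
#' distorted by the population's phase map. A warning is issued when the
#' rendered phase gradient exceeds `grad_warn_rad_per_px` per pixel (the
#' image is still rendered, but unwrapping may not be safe).
#'
#' @param phantoms Phantom population; cells must lie inside the FOV.
#' @param optics An [optics_config()] (supplies the carrier frequency, which
#'   must be below Nyquist).
#' @param noise_sd Additive Gaussian noise level (normalised intensity
#'   units); 0 gives a noiseless pair.
#' @param amplitude,modulation Fringe offset A and modulation depth B.
#' @param grad_warn_rad_per_px Unwrapping-safe bound on the per-pixel phase
#'   step.
#' @param dm_params A [dry_mass_params()].
#' @return A list with `sample`, `background` (matrices in `[0, 1]`-ish
#'   normalised intensity) and `phase_truth` (the rendered [phase_image()]).
#' @export
render_interferogram <- function(phantoms, optics = optics_config(),
                                 noise_sd = 0.01,
                                 amplitude = 0.5, modulation = 0.45,
                                 grad_warn_rad_per_px = 2.5,
                                 dm_params = dry_mass_params()) {
  np <- optics$sensor_px
  if (nrow(phantoms) > 0) {
    if (any(phantoms$x_um < 0 | phantoms$x_um > optics$fov_um |
            phantoms$y_um < 0 | phantoms$y_um > optics$fov_um))
      stop("phantoms must lie inside the field of view")
    peak <- cap_peak_phase(phantoms$dry_mass_pg, phantoms$radius_um, dm_params)
    max_step <- max(peak * (pi / 2) / (phantoms$radius_um / optics$pixel_pitch_um))
    if (max_step > grad_warn_rad_per_px)
      warning("rendered phase gradient ", round(max_step, 2),
              " rad/px exceeds the unwrapping-safe bound")
  }
  phi <- phantom_phase_map(phantoms, optics, dm_params)
  x_um <- (seq_len(np) - 1) * optics$pixel_pitch_um
  carrier <- 2 * pi * (outer(rep(1, np), x_um * optics$carrier_freq_cyc_per_um[1]) +
                       outer(x_um * optics$carrier_freq_cyc_per_um[2], rep(1, np)))
  sample <- amplitude + modulation * cos(carrier + phi$values)
  background <- amplitude + modulation * cos(carrier)
  if (noise_sd > 0) {
    sample <- sample + stats::rnorm(length(sample), 0, noise_sd)
    background <- background + stats::rnorm(length(background), 0, noise_sd)
  }
  list(sample = sample, background = background, phase_truth = phi)
}
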