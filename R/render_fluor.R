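#' Smooth nonuniform excitation field
#'
#' A strictly positive, slowly varying gain map emulating nonuniform
#' excitation light (vignetting plus an off-centre hot spot), used by the
#' fluorescence renderer and compensated for by [normalize_channel()].
#'
#' @param optics An [optics_config()].
#' @param strength Peak relative deviation from unit gain.
#' @return A strictly positive matrix.
#' @export
default_excitation_field <- function(optics = optics_config(),
                                     strength = 0.3) {
  np <- optics$sensor_px
  u <- (seq_len(np) - 1) / (np - 1)
  gx <- exp(-(u - 0.35)^2 / (2 * 0.35^2))
  gy <- exp(-(u - 0.6)^2 / (2 * 0.4^2))
  1 + strength * outer(gy, gx)
}

#' Render a FUCCI fluorescence channel
#'
#' Produces an image/background pair under the model
#' image = excitation_field x (cell footprint + offset) + noise and
#' background = excitation_field x offset + noise. Each cell's footprint is
#' its cosine-cap profile scaled by the phantom's channel level (`gfp_level`
#' or `rfp_level`), so per-phase expression is honoured exactly at zero
#' noise: G1 cells show no GFP signal, S/G2/M cells no RFP signal, G1/S
#' cells both, M/G1 cells neither.
#'
#' @param phantoms Phantom population.
#' @param channel `"GFP"` or `"RFP"`.
#' @param optics An [optics_config()].
#' @param excitation_field Strictly positive gain matrix; default
#'   [default_excitation_field()].
#' @param offset Uniform fluorescence offset (medium autofluorescence).
#' @param noise_sd Additive Gaussian noise level.
#' @return A list with `image` and `background` matrices.
#' @export
render_fluorescence <- function(phantoms, channel = c("GFP", "RFP"),
                                optics = optics_config(),
                                excitation_field = NULL,
                                offset = 0.05, noise_sd = 0.005) {
  channel <- match.arg(channel)
  np <- optics$sensor_px
  if (is.null(excitation_field))
    excitation_field <- default_excitation_field(optics)
  if (!all(dim(excitation_field) == c(np, np)))
    stop("excitation_field must match the sensor dimensions")
  if (any(excitation_field <= 0))
    stop("excitation_field must be strictly positive")
  level <- if (channel == "GFP") phantoms$gfp_level else phantoms$rfp_level
  fp <- matrix(0, np, np)
  if (nrow(phantoms) > 0 && any(level > 0)) {
    keep <- level > 0
    fp <- add_caps(fp, phantoms$x_um[keep], phantoms$y_um[keep],
                   phantoms$radius_um[keep], level[keep],
                   optics$pixel_pitch_um)
  }
  image <- excitation_field * (fp + offset)
  background <- excitation_field * offset
  if (noise_sd > 0) {
    image <- image + stats::rnorm(length(image), 0, noise_sd)
    background <- background + stats::rnorm(length(background), 0, noise_sd)
  }
  list(image = image, background = background)
}
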