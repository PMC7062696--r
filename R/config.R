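#' Optical configuration of the multimodal microscope
#'
#' Geometry and optics constants shared by all imaging modalities. Defaults
#' reproduce the published instrument: a 1024 x 1024 EMCCD at 0.625 um per
#' pixel (640 um field of view), a 633 nm He-Ne laser for the off-axis
#' interferometer, 8 x 8 camera binning for radioluminescence (5 um per binned
#' pixel), and a ~30 um FWHM scintillator point-spread function
#' (sigma = FWHM / (2 sqrt(2 ln 2)) = 12.74 um; the conventional rounded
#' sigma of 12.5 um is used for boundary dilation, see [dilate_and_flag()]).
#'
#' @param pixel_pitch_um Full-resolution pixel pitch in micrometres.
#' @param sensor_px Sensor side length in pixels (square sensor).
#' @param wavelength_um Laser wavelength in micrometres.
#' @param carrier_freq_cyc_per_um Length-2 numeric, spatial carrier frequency
#'   of the off-axis interferogram in cycles per micrometre (x, y).
#' @param rlm_binning Integer camera binning factor for radioluminescence.
#' @param psf_fwhm_um Full width at half maximum of the radioluminescence
#'   point-spread function, micrometres.
#' @return An object of class `optics_config`.
#' @examples
#' oc <- optics_config()
#' oc$fov_um            # 640
#' oc$rlm_pitch_um      # 5
#' @export
optics_config <- function(pixel_pitch_um = 0.625,
                          sensor_px = 1024L,
                          wavelength_um = 0.633,
                          carrier_freq_cyc_per_um = c(0.4, 0.25),
                          rlm_binning = 8L,
                          psf_fwhm_um = 30) {
  stopifnot(pixel_pitch_um > 0, wavelength_um > 0, psf_fwhm_um > 0)
  sensor_px <- as.integer(sensor_px)
  rlm_binning <- as.integer(rlm_binning)
  if (sensor_px < rlm_binning || sensor_px %% rlm_binning != 0L)
    stop("sensor_px must be divisible by rlm_binning")
  fnorm <- sqrt(sum(carrier_freq_cyc_per_um^2))
  if (fnorm >= 1 / (2 * pixel_pitch_um))
    stop("carrier frequency must be below the Nyquist limit 1/(2*pixel_pitch_um)")
  out <- list(
    pixel_pitch_um = pixel_pitch_um,
    sensor_px = sensor_px,
    wavelength_um = wavelength_um,
    carrier_freq_cyc_per_um = carrier_freq_cyc_per_um,
    rlm_binning = rlm_binning,
    psf_fwhm_um = psf_fwhm_um,
    psf_sigma_um = psf_fwhm_um / (2 * sqrt(2 * log(2))),
    fov_um = sensor_px * pixel_pitch_um,
    rlm_pitch_um = rlm_binning * pixel_pitch_um,
    rlm_px = sensor_px %/% rlm_binning
  )
  class(out) <- "optics_config"
  out
}

#' @export
print.optics_config <- function(x, ...) {
  cat("Optics: ", x$sensor_px, "x", x$sensor_px, " px @ ", x$pixel_pitch_um,
      " um/px (FOV ", x$fov_um, " um); lambda = ", x$wavelength_um * 1e3,
      " nm; RLM ", x$rlm_binning, "x", x$rlm_binning, " binning -> ",
      x$rlm_pitch_um, " um/px; PSF sigma ", round(x$psf_sigma_um, 2),
      " um\n", sep = "")
  invisible(x)
}

#' Radioluminescence acquisition configuration
#'
#' Frame-stack acquisition settings. Defaults follow the published protocol:
#' 20,000 frames of 20 ms exposure recorded continuously with roughly 32%
#' camera dead time, a fluorine-18 half-life of 110 min, and an acquisition
#' starting 90 min after the tracer calibration time. Dead time is modelled
#' as readout gaps between frames: it stretches the wall-clock duration (and
#' hence the isotope decay across the stack) but not the live exposure.
#'
#' @param n_frames Number of radioluminescence frames.
#' @param exposure_s Exposure per frame, seconds.
#' @param dead_time_fraction Fraction of wall-clock time lost to readout,
#'   in `[0, 1)`.
#' @param start_offset_min Minutes elapsed between tracer calibration and the
#'   acquisition start (frame 0); used for decay correction.
#' @param half_life_min Isotope half-life in minutes (110 for fluorine-18).
#' @param n_dark_frames Number of dark frames recorded for dark-field
#'   correction.
#' @return An object of class `acq_config` with derived fields
#'   `live_time_s`, `live_time_min` and `wall_time_s`.
#' @export
acq_config <- function(n_frames = 20000L,
                       exposure_s = 0.020,
                       dead_time_fraction = 0.32,
                       start_offset_min = 90,
                       half_life_min = 110,
                       n_dark_frames = 200L) {
  n_frames <- as.integer(n_frames)
  stopifnot(n_frames >= 1L, exposure_s > 0,
            dead_time_fraction >= 0, dead_time_fraction < 1,
            start_offset_min >= 0, half_life_min > 0, n_dark_frames >= 1L)
  live <- n_frames * exposure_s
  out <- list(
    n_frames = n_frames,
    exposure_s = exposure_s,
    dead_time_fraction = dead_time_fraction,
    start_offset_min = start_offset_min,
    half_life_min = half_life_min,
    n_dark_frames = as.integer(n_dark_frames),
    live_time_s = live,
    live_time_min = live / 60,
    wall_time_s = live / (1 - dead_time_fraction)
  )
  class(out) <- "acq_config"
  out
}

#' @export
print.acq_config <- function(x, ...) {
  cat("Acquisition: ", x$n_frames, " frames x ", x$exposure_s * 1e3,
      " ms (live ", round(x$live_time_min, 2), " min, wall ",
      round(x$wall_time_s / 60, 2), " min, ",
      round(100 * x$dead_time_fraction), "% dead time); T1/2 = ",
      x$half_life_min, " min; start +", x$start_offset_min,
      " min after calibration\n", sep = "")
  invisible(x)
}

#' ORBIT-style track-detection parameters
#'
#' Parameters of the scintillation-event detector, matching the published
#' reconstruction settings: binary threshold 700 ADU, h-value 100 ADU,
#' sharpness cutoff at k-space distance 20, and a maximum accepted track
#' length of 10 binned pixels (50 um at 5 um per binned pixel).
#'
#' `sharpness_min_fraction` is this package's realisation of the sharpness
#' filter: a detected component is classified `diffuse` when less than that
#' fraction of its (above-threshold) spectral energy lies beyond k-space
#' radius `sharpness` on the native frame grid. `sensor_hit_min_intensity`
#' flags single-pixel saturated impulses (gamma rays striking the sensor
#' directly).
#'
#' @param binary_threshold Binarisation intensity threshold (ADU, after dark
#'   correction).
#' @param h_value Minimum peak prominence (h-maxima height), ADU.
#' @param sharpness K-space radius (frequency-plane pixels on the native
#'   frame grid) separating focused from diffuse tracks.
#' @param max_length_px Maximum accepted track extent, binned pixels.
#' @param sharpness_min_fraction Minimum high-frequency energy fraction for
#'   a focused (non-diffuse) track.
#' @param sensor_hit_min_intensity Minimum intensity for a single-pixel
#'   component to be classified as a direct sensor hit.
#' @return An object of class `orbit_params`.
#' @export
orbit_params <- function(binary_threshold = 700,
                         h_value = 100,
                         sharpness = 20,
                         max_length_px = 10,
                         sharpness_min_fraction = 0.2,
                         sensor_hit_min_intensity = 10000) {
  stopifnot(binary_threshold > 0, h_value > 0, sharpness > 0,
            max_length_px > 0, sharpness_min_fraction >= 0,
            sensor_hit_min_intensity > 0)
  out <- list(binary_threshold = binary_threshold,
              h_value = h_value,
              sharpness = sharpness,
              max_length_px = max_length_px,
              sharpness_min_fraction = sharpness_min_fraction,
              sensor_hit_min_intensity = sensor_hit_min_intensity)
  class(out) <- "orbit_params"
  out
}

#' Dry-mass conversion parameters
#'
#' Constants of the phase-to-mass relation
#' m = lambda / (2 pi alpha) * integral of Phi(x, y) dx dy,
#' with the wavelength in micrometres and the specific refraction increment
#' alpha = 0.18 mL/g = 0.18 um^3/pg, so that the integral of a phase map
#' (radians) over area (um^2) yields picograms directly.
#'
#' @param wavelength_um Laser wavelength, micrometres.
#' @param alpha_um3_per_pg Specific refraction increment, um^3 per pg.
#' @return An object of class `dry_mass_params`.
#' @export
dry_mass_params <- function(wavelength_um = 0.633, alpha_um3_per_pg = 0.18) {
  stopifnot(wavelength_um > 0, alpha_um3_per_pg > 0)
  structure(list(wavelength_um = wavelength_um,
                 alpha_um3_per_pg = alpha_um3_per_pg),
            class = "dry_mass_params")
}

#' Reference per-phase calibration table
#'
#' Published-style per-phase medians and interquartile ranges for HeLa-FUCCI
#' dry mass (pg) and decay-corrected FDG counts per minute, used to calibrate
#' the synthetic phantom population. The derived `uptake_cpm_per_pg` column
#' is the per-phase median counts/min divided by the median dry mass; the
#' S/G2/M-to-G1 ratio of the counts medians (87/44) encodes the roughly
#' twofold higher uptake of cycling cells.
#'
#' @return A data.frame with one row per cycle phase (G1, G1_S, S_G2_M) plus
#'   an `all` row, columns `mass_median`, `mass_q1`, `mass_q3`,
#'   `counts_median`, `counts_q1`, `counts_q3`, `uptake_cpm_per_pg`.
#' @export
phase_calibration <- function() {
  d <- data.frame(
    phase = c("all", "G1", "G1_S", "S_G2_M"),
    mass_median = c(604, 422, 612, 628),
    mass_q1 = c(494, 396, 530, 544),
    mass_q3 = c(669, 450, 631, 732),
    counts_median = c(67, 44, 64, 87),
    counts_q1 = c(54, 37, 48, 65),
    counts_q3 = c(88, 50, 77, 95),
    stringsAsFactors = FALSE
  )
  d$uptake_cpm_per_pg <- d$counts_median / d$mass_median
  d
}

#' Cell-cycle phase levels
#'
#' Order of the FUCCI cycle-phase factor used throughout the package.
#' @return Character vector of the four phase labels.
#' @export
cycle_phases <- function() c("G1", "G1_S", "S_G2_M", "M_G1")
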