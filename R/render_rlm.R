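#' Radioluminescence simulation parameters
#'
#' Shape and intensity knobs of the simulated ionisation-track classes.
#' The reference data describe three morphologies - short compact tracks
#' (positrons travelling perpendicular to the imaging plane), long shallow-
#' angle streaks, and diffuse deep-crystal gamma glows - but give no
#' quantitative track-shape model; these defaults are stated assumptions
#' chosen so that the published detector settings separate the classes
#' cleanly, and are documented as simulator knobs, not measured facts.
#'
#' All lengths are in binned pixels, intensities in camera ADU.
#'
#' @param class_prob Named class proportions (short, long, diffuse).
#' @param short_sigma_px Range of the short-track Gaussian spot sigma.
#' @param short_amp_meanlog,short_amp_sdlog,short_amp_min Log-normal peak
#'   amplitude of short tracks, floored at `short_amp_min`.
#' @param long_length_px Range of long-track lengths (all above the 10 px
#'   acceptance cutoff by construction).
#' @param long_sigma_px,long_step_px,long_step_amp Cross-track sigma,
#'   rendering step and per-step amplitude of streaks.
#' @param diffuse_sigma_px,diffuse_amp Ranges of the diffuse-glow sigma and
#'   peak amplitude.
#' @param baseline_adu,fixed_pattern_sd_adu,read_noise_adu EMCCD baseline
#'   offset, per-pixel fixed-pattern sigma (drawn once per acquisition and
#'   shared by the dark stack, so dark correction removes it) and additive
#'   read-noise sigma.
#' @param sensor_hit_rate_per_frame Expected direct sensor hits per frame
#'   (single-pixel saturated impulses).
#' @param sensor_hit_amp Amplitude of a sensor hit.
#' @return An object of class `rlm_sim_params`.
#' @export
rlm_sim_params <- function(class_prob = c(short = 0.75, long = 0.15,
                                          diffuse = 0.10),
                           short_sigma_px = c(0.6, 1.0),
                           short_amp_meanlog = log(2500),
                           short_amp_sdlog = 0.25,
                           short_amp_min = 1200,
                           long_length_px = c(12, 18),
                           long_sigma_px = 0.7,
                           long_step_px = 0.5,
                           long_step_amp = 600,
                           diffuse_sigma_px = c(3.5, 4.5),
                           diffuse_amp = c(1000, 1300),
                           baseline_adu = 100,
                           fixed_pattern_sd_adu = 20,
                           read_noise_adu = 30,
                           sensor_hit_rate_per_frame = 0,
                           sensor_hit_amp = 20000) {
  stopifnot(all(class_prob >= 0), sum(class_prob) > 0,
            all(c("short", "long", "diffuse") %in% names(class_prob)))
  structure(list(class_prob = class_prob / sum(class_prob),
                 short_sigma_px = short_sigma_px,
                 short_amp_meanlog = short_amp_meanlog,
                 short_amp_sdlog = short_amp_sdlog,
                 short_amp_min = short_amp_min,
                 long_length_px = long_length_px,
                 long_sigma_px = long_sigma_px,
                 long_step_px = long_step_px,
                 long_step_amp = long_step_amp,
                 diffuse_sigma_px = diffuse_sigma_px,
                 diffuse_amp = diffuse_amp,
                 baseline_adu = baseline_adu,
                 fixed_pattern_sd_adu = fixed_pattern_sd_adu,
                 read_noise_adu = read_noise_adu,
                 sensor_hit_rate_per_frame = sensor_hit_rate_per_frame,
                 sensor_hit_amp = sensor_hit_amp),
            class = "rlm_sim_params")
}

# add an isotropic Gaussian spot to a frame; x/y are 0-based pixel coords
add_spot <- function(frame, x, y, sigma, amp) {
  n <- ncol(frame); m <- nrow(frame)
  r <- ceiling(3 * sigma + 1)
  c0 <- max(1L, floor(x - r) + 1L); c1 <- min(n, ceiling(x + r) + 1L)
  r0 <- max(1L, floor(y - r) + 1L); r1 <- min(m, ceiling(y + r) + 1L)
  if (c0 > c1 || r0 > r1) return(frame)
  xs <- (seq(c0, c1) - 1) - x
  ys <- (seq(r0, r1) - 1) - y
  patch <- amp * exp(-outer(ys^2, xs^2, `+`) / (2 * sigma^2))
  frame[r0:r1, c0:c1] <- frame[r0:r1, c0:c1] + patch
  frame
}

#' Simulate a radioluminescence frame stack
#'
#' Generates the frame stack of a radioluminescence acquisition directly at
#' the binned resolution, plus a matching dark stack. Per frame, each cell
#' emits `Poisson(activity x exposure x decay(t))` detectable ionisation
#' events, where the decay factor follows the isotope half-life over the
#' wall-clock frame time (dead time stretches the wall clock, not the live
#' exposure). Each event is drawn from the configured class mix: short
#' tracks are compact spots centred `Normal(cell centre, PSF sigma)`; long
#' tracks are streaks longer than the acceptance cutoff starting at the
#' cell; diffuse tracks are broad low-sharpness blobs at uniform random
#' positions (gamma interactions). Frames carry an EMCCD baseline plus
#' Gaussian read noise; the dark stack carries noise only.
#'
#' @param phantoms Phantom population (uses `x_um`, `y_um`, `activity_eps`).
#' @param optics An [optics_config()].
#' @param acq An [acq_config()].
#' @param sim An [rlm_sim_params()].
#' @return A list of class `rlm_stack` with `frames` (list of matrices),
#'   `dark` (list of matrices), `events` (ground-truth ledger: one row per
#'   rendered event with frame index, 0-based binned-pixel position, class
#'   and amplitude), `optics`, `acq`, `sim`.
#' @export
simulate_rlm_stack <- function(phantoms, optics = optics_config(),
                               acq = acq_config(), sim = rlm_sim_params()) {
  stopifnot(inherits(acq, "acq_config"))
  if (acq$n_frames < 1) stop("zero frames requested")
  if (nrow(phantoms) > 0 && any(!is.finite(phantoms$activity_eps)))
    stop("phantom activities must be finite")
  np <- optics$rlm_px
  pitch <- optics$rlm_pitch_um
  psf_sigma_px <- optics$psf_sigma_um / pitch

  dt_wall_min <- acq$exposure_s / (1 - acq$dead_time_fraction) / 60
  decay_t <- 2^(-(seq_len(acq$n_frames) - 1) * dt_wall_min / acq$half_life_min)

  # Poisson event draws per cell and frame
  ev <- list()
  classes <- names(sim$class_prob)
  for (i in seq_len(nrow(phantoms))) {
    lam <- phantoms$activity_eps[i] * acq$exposure_s * decay_t
    k <- stats::rpois(acq$n_frames, lam)
    tot <- sum(k)
    if (tot == 0) next
    ev[[length(ev) + 1L]] <- data.frame(
      cell = phantoms$id[i],
      frame = rep.int(seq_len(acq$n_frames), k),
      klass = sample(classes, tot, replace = TRUE, prob = sim$class_prob),
      cx = phantoms$x_um[i] / pitch,
      cy = phantoms$y_um[i] / pitch,
      stringsAsFactors = FALSE
    )
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(cell = integer(), frame = integer(), klass = character(),
               cx = numeric(), cy = numeric(), stringsAsFactors = FALSE)

  ne <- nrow(events)
  events$x_px <- events$y_px <- events$amp <- events$sigma_px <-
    events$length_px <- events$angle <- numeric(ne)
  is_s <- events$klass == "short"
  is_l <- events$klass == "long"
  is_d <- events$klass == "diffuse"
  if (any(is_s)) {
    n <- sum(is_s)
    events$x_px[is_s] <- events$cx[is_s] + stats::rnorm(n, 0, psf_sigma_px)
    events$y_px[is_s] <- events$cy[is_s] + stats::rnorm(n, 0, psf_sigma_px)
    events$sigma_px[is_s] <- stats::runif(n, sim$short_sigma_px[1],
                                          sim$short_sigma_px[2])
    events$amp[is_s] <- pmax(sim$short_amp_min,
                             stats::rlnorm(n, sim$short_amp_meanlog,
                                           sim$short_amp_sdlog))
    events$length_px[is_s] <- 0
  }
  if (any(is_l)) {
    n <- sum(is_l)
    events$x_px[is_l] <- events$cx[is_l] + stats::rnorm(n, 0, psf_sigma_px)
    events$y_px[is_l] <- events$cy[is_l] + stats::rnorm(n, 0, psf_sigma_px)
    events$length_px[is_l] <- stats::runif(n, sim$long_length_px[1],
                                           sim$long_length_px[2])
    events$angle[is_l] <- stats::runif(n, 0, 2 * pi)
    events$amp[is_l] <- sim$long_step_amp
    events$sigma_px[is_l] <- sim$long_sigma_px
  }
  if (any(is_d)) {
    n <- sum(is_d)
    events$x_px[is_d] <- stats::runif(n, 0, np - 1)
    events$y_px[is_d] <- stats::runif(n, 0, np - 1)
    events$sigma_px[is_d] <- stats::runif(n, sim$diffuse_sigma_px[1],
                                          sim$diffuse_sigma_px[2])
    events$amp[is_d] <- stats::runif(n, sim$diffuse_amp[1], sim$diffuse_amp[2])
    events$length_px[is_d] <- 0
  }

  # direct sensor hits (not tied to cells)
  if (sim$sensor_hit_rate_per_frame > 0) {
    kh <- stats::rpois(acq$n_frames, sim$sensor_hit_rate_per_frame)
    nh <- sum(kh)
    if (nh > 0) {
      hit <- data.frame(cell = NA_integer_,
                        frame = rep.int(seq_len(acq$n_frames), kh),
                        klass = "sensor_hit", cx = NA_real_, cy = NA_real_,
                        x_px = sample.int(np, nh, replace = TRUE) - 1,
                        y_px = sample.int(np, nh, replace = TRUE) - 1,
                        amp = sim$sensor_hit_amp, sigma_px = 0,
                        length_px = 0, angle = 0, stringsAsFactors = FALSE)
      events <- rbind(events, hit)
    }
  }

  # render frames: fixed pattern (baseline + per-pixel offsets, shared
  # with the dark stack) + read noise + events
  pattern <- sim$baseline_adu +
    matrix(stats::rnorm(np * np, 0, sim$fixed_pattern_sd_adu), np, np)
  frames <- vector("list", acq$n_frames)
  for (f in seq_len(acq$n_frames))
    frames[[f]] <- pattern + matrix(stats::rnorm(np * np, 0,
                                                 sim$read_noise_adu), np, np)
  if (ne > 0 || nrow(events) > 0) {
    for (r in seq_len(nrow(events))) {
      f <- events$frame[r]
      kl <- events$klass[r]
      if (kl == "long") {
        steps <- seq(0, events$length_px[r], by = sim$long_step_px)
        steps <- steps - events$length_px[r] / 2
        xs <- events$x_px[r] + steps * cos(events$angle[r])
        ys <- events$y_px[r] + steps * sin(events$angle[r])
        for (s in seq_along(xs))
          frames[[f]] <- add_spot(frames[[f]], xs[s], ys[s],
                                  events$sigma_px[r], events$amp[r])
      } else if (kl == "sensor_hit") {
        ix <- round(events$x_px[r]) + 1L; iy <- round(events$y_px[r]) + 1L
        frames[[f]][iy, ix] <- frames[[f]][iy, ix] + events$amp[r]
      } else {
        frames[[f]] <- add_spot(frames[[f]], events$x_px[r], events$y_px[r],
                                events$sigma_px[r], events$amp[r])
      }
    }
  }

  dark <- vector("list", acq$n_dark_frames)
  for (f in seq_len(acq$n_dark_frames))
    dark[[f]] <- pattern + matrix(stats::rnorm(np * np, 0,
                                               sim$read_noise_adu), np, np)

  structure(list(frames = frames, dark = dark, events = events,
                 optics = optics, acq = acq, sim = sim),
            class = "rlm_stack")
}

#' @export
print.rlm_stack <- function(x, ...) {
  cat("RLM stack: ", length(x$frames), " frames (",
      nrow(x$events), " rendered events: ",
      paste(names(table(x$events$klass)), table(x$events$klass),
            sep = "=", collapse = ", "),
      "), ", length(x$dark), " dark frames\n", sep = "")
  invisible(x)
}
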