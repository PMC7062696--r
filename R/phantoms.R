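#' Phantom population distribution settings
#'
#' Distribution parameters of the synthetic HeLa-FUCCI phantom population.
#' Per-phase dry-mass medians and log-scale spreads default to the reference
#' calibration table ([phase_calibration()]); per-phase FDG uptake is
#' parameterised as decay-corrected counts per minute per picogram of dry
#' mass, so that counts are proportional to mass within a phase with
#' log-normal cell-to-cell scatter (`uptake_sdlog`). Cell radius scales as
#' the cube root of dry mass around `radius_ref_um` at the reference mass.
#'
#' @param phase_prob Named probabilities of the four cycle phases. The M_G1
#'   phase is retained in the state space but has default probability 0 (no
#'   such cells were observed in the reference data set; freshly divided
#'   cells cluster and are not imaged).
#' @param mass_median_pg,mass_sdlog Named per-phase log-normal dry-mass
#'   medians (pg) and log-sd.
#' @param uptake_median_cpm_per_pg Named per-phase median uptake.
#' @param uptake_sdlog Log-sd of the per-cell uptake multiplier.
#' @param radius_ref_um Cell radius at the reference mass `mass_ref_pg`.
#' @param mass_ref_pg Reference dry mass for the radius scaling.
#' @param radius_sdlog Log-sd of the radius jitter.
#' @param fluor_meanlog,fluor_sdlog Log-normal parameters of the expressed
#'   fluorescence level (normalised camera units).
#' @param dilation_sigma_um Boundary-dilation radius used downstream;
#'   enters the analytic capture fraction used to convert target counts to
#'   phantom activity.
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(phase_prob = c(G1 = 0.27, G1_S = 0.19,
                                          S_G2_M = 0.54, M_G1 = 0),
                           mass_median_pg = NULL,
                           mass_sdlog = NULL,
                           uptake_median_cpm_per_pg = NULL,
                           uptake_sdlog = 0.30,
                           radius_ref_um = 11,
                           mass_ref_pg = 604,
                           radius_sdlog = 0.05,
                           fluor_meanlog = log(0.5),
                           fluor_sdlog = 0.3,
                           dilation_sigma_um = 12.5) {
  cal <- phase_calibration()
  cal <- cal[match(c("G1", "G1_S", "S_G2_M"), cal$phase), ]
  if (is.null(mass_median_pg)) {
    mass_median_pg <- c(cal$mass_median, cal$mass_median[1])
    names(mass_median_pg) <- cycle_phases()
  }
  if (is.null(mass_sdlog)) {
    mass_sdlog <- c(log(cal$mass_q3 / cal$mass_q1) / (2 * stats::qnorm(0.75)),
                    0.10)
    names(mass_sdlog) <- cycle_phases()
  }
  if (is.null(uptake_median_cpm_per_pg)) {
    uptake_median_cpm_per_pg <- c(cal$uptake_cpm_per_pg,
                                  cal$uptake_cpm_per_pg[1])
    names(uptake_median_cpm_per_pg) <- cycle_phases()
  }
  ph <- cycle_phases()
  stopifnot(all(ph %in% names(phase_prob)),
            all(ph %in% names(mass_median_pg)),
            all(ph %in% names(mass_sdlog)),
            all(ph %in% names(uptake_median_cpm_per_pg)))
  if (any(phase_prob < 0) || sum(phase_prob) <= 0)
    stop("phase_prob must be nonnegative with positive sum")
  if (any(mass_median_pg <= 0))
    stop("dry-mass medians must be strictly positive")
  if (any(uptake_median_cpm_per_pg < 0))
    stop("uptake medians must be nonnegative")
  structure(list(phase_prob = phase_prob[ph] / sum(phase_prob),
                 mass_median_pg = mass_median_pg[ph],
                 mass_sdlog = mass_sdlog[ph],
                 uptake_median_cpm_per_pg = uptake_median_cpm_per_pg[ph],
                 uptake_sdlog = uptake_sdlog,
                 radius_ref_um = radius_ref_um,
                 mass_ref_pg = mass_ref_pg,
                 radius_sdlog = radius_sdlog,
                 fluor_meanlog = fluor_meanlog,
                 fluor_sdlog = fluor_sdlog,
                 dilation_sigma_um = dilation_sigma_um),
            class = "phantom_params")
}

# Mean decay factor 2^(-t/T) averaged over frame start times of the stack,
# with dead time stretching the wall clock between frames.
mean_stack_decay <- function(acq) {
  dt_wall_min <- acq$exposure_s / (1 - acq$dead_time_fraction) / 60
  t <- (seq_len(acq$n_frames) - 1) * dt_wall_min
  mean(2^(-t / acq$half_life_min))
}

# Fraction of a centred 2-D Gaussian (sigma = PSF sigma) falling inside a
# disc of radius r + sigma_d (the dilated boundary of a cell of radius r).
capture_fraction <- function(radius_um, psf_sigma_um, dilation_sigma_um) {
  r <- radius_um + dilation_sigma_um
  1 - exp(-r^2 / (2 * psf_sigma_um^2))
}

#' Generate a ground-truth phantom population
#'
#' Draws `n_cells` cell phantoms with cycle phase, dry mass, radius,
#' phase-consistent FUCCI fluorescence levels, target decay-corrected
#' counts/min (uptake x mass), and the detectable ionisation-event rate
#' (`activity_eps`, events per second at acquisition start) that makes the
#' expected measured counts/min equal the target after track-class losses,
#' point-spread capture, within-stack decay and decay correction. Cells are
#' placed by dart throwing with a minimum separation that keeps the dilated
#' boundaries disjoint (so the default population yields no merged cells)
#' and a border margin that keeps dilated masks inside the field of view.
#'
#' @param n_cells Number of phantoms (>= 1).
#' @param seed Integer seed; fixed seed gives a bit-identical population.
#' @param params A [phantom_params()] object.
#' @param optics An [optics_config()].
#' @param acq An [acq_config()]; together with `rlm_sim` it converts target
#'   counts/min into event rates.
#' @param rlm_sim An [rlm_sim_params()]; its short-track fraction enters the
#'   activity calibration.
#' @param min_separation_um Minimum centre-to-centre distance; default keeps
#'   dilated masks disjoint with a 5 um margin.
#' @param border_margin_um Minimum distance of a centre from the FOV edge;
#'   default radius + dilation sigma + 5 um.
#' @return A data.frame of class `phantom_population` with one row per cell:
#'   `id`, `x_um`, `y_um`, `radius_um`, `dry_mass_pg`, `cycle_phase`,
#'   `gfp_level`, `rfp_level`, `uptake_cpm_per_pg`, `expected_cpm`,
#'   `activity_eps`.
#' @export
make_phantom_population <- function(n_cells,
                                    seed = 1L,
                                    params = phantom_params(),
                                    optics = optics_config(),
                                    acq = acq_config(),
                                    rlm_sim = rlm_sim_params(),
                                    min_separation_um = NULL,
                                    border_margin_um = NULL) {
  if (!is.numeric(n_cells) || length(n_cells) != 1L || n_cells < 1)
    stop("n_cells must be a positive integer")
  n_cells <- as.integer(n_cells)
  stopifnot(inherits(params, "phantom_params"))
  set.seed(as.integer(seed))

  ph <- cycle_phases()
  phase <- sample(ph, n_cells, replace = TRUE, prob = params$phase_prob)
  mass <- stats::rlnorm(n_cells,
                        meanlog = log(params$mass_median_pg[phase]),
                        sdlog = params$mass_sdlog[phase])
  if (any(mass <= 0)) stop("mass distribution produced nonpositive mass")
  radius <- params$radius_ref_um * (mass / params$mass_ref_pg)^(1 / 3) *
    stats::rlnorm(n_cells, 0, params$radius_sdlog)

  uptake <- params$uptake_median_cpm_per_pg[phase] *
    stats::rlnorm(n_cells, 0, params$uptake_sdlog)
  expected_cpm <- uptake * mass

  # phase-consistent FUCCI expression
  lvl <- function(k) stats::rlnorm(k, params$fluor_meanlog, params$fluor_sdlog)
  gfp <- ifelse(phase %in% c("S_G2_M", "G1_S"), lvl(n_cells), 0)
  rfp <- ifelse(phase %in% c("G1", "G1_S"), lvl(n_cells), 0)

  # activity calibration: expected measured (decay-corrected) cpm equals the
  # target uptake x mass
  dcf <- decay_correction_factor(acq$start_offset_min, acq$half_life_min)
  msd <- mean_stack_decay(acq)
  capt <- capture_fraction(radius, optics$psf_sigma_um,
                           params$dilation_sigma_um)
  short_frac <- rlm_sim$class_prob[["short"]]
  if (short_frac <= 0) {
    activity <- rep(0, n_cells)
  } else {
    activity <- expected_cpm / (60 * short_frac * capt * msd * dcf)
  }

  if (is.null(border_margin_um)) border_margin_um <- radius +
      params$dilation_sigma_um + 5
  pos <- place_phantoms(n_cells, radius, optics$fov_um,
                        min_separation_um, border_margin_um,
                        params$dilation_sigma_um)

  out <- data.frame(
    id = seq_len(n_cells),
    x_um = pos$x, y_um = pos$y,
    radius_um = radius,
    dry_mass_pg = mass,
    cycle_phase = factor(phase, levels = ph),
    gfp_level = gfp, rfp_level = rfp,
    uptake_cpm_per_pg = as.numeric(uptake),
    expected_cpm = as.numeric(expected_cpm),
    activity_eps = as.numeric(activity),
    stringsAsFactors = FALSE
  )
  attr(out, "seed") <- as.integer(seed)
  attr(out, "params") <- params
  class(out) <- c("phantom_population", "data.frame")
  out
}

# Dart-throwing placement with pairwise minimum separation.
place_phantoms <- function(n, radius, fov_um, min_sep, margin, sigma_d) {
  if (length(margin) == 1L) margin <- rep(margin, n)
  x <- y <- numeric(n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (trial in seq_len(5000L)) {
      xi <- stats::runif(1, margin[i], fov_um - margin[i])
      yi <- stats::runif(1, margin[i], fov_um - margin[i])
      if (i == 1L) { ok <- TRUE }
      else {
        j <- seq_len(i - 1L)
        sep <- if (is.null(min_sep))
          radius[i] + radius[j] + 2 * sigma_d + 5 else min_sep
        ok <- all((xi - x[j])^2 + (yi - y[j])^2 >= sep^2)
      }
      if (ok) { x[i] <- xi; y[i] <- yi; break }
    }
    if (!ok) stop("could not place phantoms with the requested separation; ",
                  "reduce n_cells or the separation")
  }
  list(x = x, y = y)
}

#' @export
print.phantom_population <- function(x, ...) {
  cat("Phantom population: ", nrow(x), " cells (seed ",
      attr(x, "seed"), ")\n", sep = "")
  print(table(x$cycle_phase))
  cat("dry mass median ", round(stats::median(x$dry_mass_pg), 1),
      " pg; target counts/min median ",
      round(stats::median(x$expected_cpm), 1), "\n", sep = "")
  invisible(x)
}
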