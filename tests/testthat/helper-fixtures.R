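# shared fixtures: all synthetic, built in code at test time

tiny_optics <- function(sensor_px = 256L)
  optics_config(sensor_px = sensor_px)

# one hand-built phantom row (bypasses the population sampler)
one_phantom <- function(x_um = 80, y_um = 76, radius_um = 12,
                        dry_mass_pg = 190, phase = "G1",
                        gfp = 0, rfp = 0.5, activity = 0) {
  data.frame(id = 1L, x_um = x_um, y_um = y_um, radius_um = radius_um,
             dry_mass_pg = dry_mass_pg,
             cycle_phase = factor(phase, levels = cycle_phases()),
             gfp_level = gfp, rfp_level = rfp,
             uptake_cpm_per_pg = 0.1, expected_cpm = 0.1 * dry_mass_pg,
             activity_eps = activity, stringsAsFactors = FALSE)
}

# greedy per-frame matching of detected to true events within a radius
match_events <- function(detected, truth, max_dist_px = 2) {
  tp <- 0L
  for (f in unique(detected$frame_index)) {
    d <- detected[detected$frame_index == f, , drop = FALSE]
    t <- truth[truth$frame == f, , drop = FALSE]
    for (i in seq_len(nrow(d))) {
      if (!nrow(t)) break
      d2 <- (t$x_px - d$x_px[i])^2 + (t$y_px - d$y_px[i])^2
      j <- which.min(d2)
      if (d2[j] <= max_dist_px^2) {
        tp <- tp + 1L
        t <- t[-j, , drop = FALSE]
      }
    }
  }
  tp
}

# small noiseless multimodal dataset on a reduced sensor (fast e2e fixture)
small_dataset <- function(n_cells = 5, seed = 3, n_frames = 300,
                          exposure_s = 0.2, noiseless = FALSE,
                          sensor_px = 512L) {
  simulate_fov(
    n_cells, seed = seed, optics = tiny_optics(sensor_px),
    acq = acq_config(n_frames = n_frames, exposure_s = exposure_s,
                     n_dark_frames = 50),
    interferogram_noise_sd = if (noiseless) 0 else 0.01,
    fluor_noise_sd = if (noiseless) 0 else 0.005,
    rlm_sim = if (noiseless)
      rlm_sim_params(fixed_pattern_sd_adu = 0, read_noise_adu = 1e-6)
    else rlm_sim_params()
  )
}
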