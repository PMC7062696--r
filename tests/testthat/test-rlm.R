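# deterministic event renderers used as test oracles (independent of the
# package's own simulator internals)
gauss_frame <- function(np, x, y, sigma, amp) {
  g <- seq_len(np) - 1
  amp * exp(-outer((g - y)^2, (g - x)^2, `+`) / (2 * sigma^2))
}
streak_frame <- function(np, x0, y0, length_px, angle, sigma, step_amp) {
  f <- matrix(0, np, np)
  for (s in seq(0, length_px, by = 0.5))
    f <- f + gauss_frame(np, x0 + s * cos(angle), y0 + s * sin(angle),
                         sigma, step_amp)
  f
}

test_that("decay correction follows 2^(dt / half-life)", {
  expect_identical(decay_correction_factor(0), 1)
  expect_identical(decay_correction_factor(110), 2)
  expect_equal(decay_correction_factor(55), sqrt(2), tolerance = 1e-12)
  expect_equal(round(decay_correction_factor(55), 5), 1.41421)
  expect_error(decay_correction_factor(-1), "nonnegative")
})

test_that("dark correction subtracts the temporal dark mean and clips", {
  dark <- list(matrix(4, 8, 8), matrix(6, 8, 8))   # mean 5
  stack <- list(matrix(5, 8, 8), matrix(5 + 3, 8, 8))
  out <- dark_correct(stack, dark)
  expect_equal(out[[1]], matrix(0, 8, 8))
  expect_equal(out[[2]], matrix(3, 8, 8))
  expect_error(dark_correct(list(matrix(0, 4, 4)), dark), "geometries")
})

test_that("dark correction raises event-region SNR on simulated frames", {
  ph <- one_phantom(x_um = 320, y_um = 320, activity = 40)
  acq <- acq_config(n_frames = 40, exposure_s = 0.2, n_dark_frames = 60)
  set.seed(8)
  st <- simulate_rlm_stack(ph, optics_config(), acq,
                           rlm_sim_params(class_prob = c(short = 1, long = 0,
                                                         diffuse = 0)))
  cor <- dark_correct(st)
  snr <- function(frames) {
    m <- Reduce(`+`, frames) / length(frames)
    ev <- m[60:68, 60:68]          # cell neighbourhood (centre 64, 64)
    bg <- m[1:30, 1:30]
    (mean(ev) - mean(bg)) / sd(bg)
  }
  expect_gt(snr(cor), snr(st$frames))
})

test_that("an empty frame yields no events", {
  expect_equal(nrow(detect_events(matrix(0, 128, 128))), 0)
})

test_that("a compact blob is localised at its intensity centroid", {
  np <- 128
  f <- gauss_frame(np, x = 40.3, y = 70.6, sigma = 0.9, amp = 2000)
  ev <- detect_events(f, orbit_params())
  expect_equal(nrow(ev), 1)
  expect_equal(ev$klass, "short")
  # oracle: exhaustive intensity-weighted mean over the rendered blob
  g <- seq_len(np) - 1
  ox <- sum(f %*% g) / sum(f)
  oy <- sum(g %*% f) / sum(f)
  expect_lt(abs(ev$x_px - ox), 0.5)
  expect_lt(abs(ev$y_px - oy), 0.5)
})

test_that("track morphology separates long, diffuse and sensor hits", {
  np <- 128
  # 12-px streak -> long
  f <- streak_frame(np, 50, 50, 12, 0.4, sigma = 0.7, step_amp = 600)
  ev <- detect_events(f, orbit_params())
  expect_equal(nrow(ev), 1)
  expect_equal(ev$klass, "long")
  expect_gt(ev$length_px, 10)
  # broad low-sharpness glow -> diffuse
  fd <- gauss_frame(np, 80, 30, sigma = 4, amp = 1200)
  evd <- detect_events(fd, orbit_params())
  expect_equal(evd$klass, "diffuse")
  # single saturated pixel -> sensor hit
  fs <- matrix(0, np, np); fs[20, 90] <- 30000
  evs <- detect_events(fs, orbit_params())
  expect_equal(evs$klass, "sensor_hit")
})

test_that("two overlapping prominent peaks are split by the h-maxima step", {
  np <- 128
  f <- gauss_frame(np, 60, 60, 0.9, 2400) + gauss_frame(np, 63.5, 60, 0.9, 2400)
  ev <- detect_events(f, orbit_params())
  expect_equal(nrow(ev), 2)
  expect_true(all(ev$klass == "short"))
})

test_that("detection is covariant under intensity rescaling", {
  np <- 128
  f <- gauss_frame(np, 40.3, 70.6, 0.9, 2000) +
    gauss_frame(np, 90, 20, 4, 1200)
  p1 <- orbit_params()
  ev1 <- detect_events(f, p1)
  cc <- 3.7
  p2 <- orbit_params(binary_threshold = cc * p1$binary_threshold,
                     h_value = cc * p1$h_value,
                     sensor_hit_min_intensity =
                       cc * p1$sensor_hit_min_intensity)
  ev2 <- detect_events(cc * f, p2)
  expect_equal(ev1[c("x_px", "y_px", "length_px", "n_px", "klass")],
               ev2[c("x_px", "y_px", "length_px", "n_px", "klass")])
  expect_equal(ev2$peak_intensity, cc * ev1$peak_intensity)
})

test_that("counts accumulation conserves accepted events", {
  ev <- data.frame(frame_index = 1, x_px = c(10.2, 10.4, 9.8, 50),
                   y_px = c(20.1, 19.9, 20.3, 60),
                   length_px = 2, n_px = 4, peak_intensity = 1000,
                   sharpness = 0.5,
                   klass = c("short", "short", "short", "long"))
  ci <- accumulate_events(ev, dims = c(128, 128), live_time_min = 400 / 60)
  expect_equal(sum(ci$grid), 3)              # long event discarded
  expect_equal(ci$grid[21, 11], 3L)          # nearest binned pixel (0-based 20, 10)
  empty <- accumulate_events(ev[0, ], c(128, 128), 1)
  expect_equal(sum(empty$grid), 0)
})

test_that("a long-track-only stack yields zero accepted counts", {
  ph <- one_phantom(x_um = 320, y_um = 320, activity = 30)
  acq <- acq_config(n_frames = 30, exposure_s = 0.2, n_dark_frames = 20)
  set.seed(12)
  st <- simulate_rlm_stack(ph, optics_config(), acq,
                           rlm_sim_params(class_prob = c(short = 0, long = 1,
                                                         diffuse = 0)))
  expect_gt(nrow(st$events), 0)
  ev <- detect_stack(dark_correct(st), orbit_params())
  ci <- accumulate_events(ev, c(128, 128), acq$live_time_min)
  expect_equal(sum(ci$grid), 0)
})

test_that("zero-activity stacks are statistically identical to darks", {
  ph <- one_phantom(activity = 0)
  acq <- acq_config(n_frames = 30, exposure_s = 0.2, n_dark_frames = 30)
  set.seed(4)
  st <- simulate_rlm_stack(ph, optics_config(), acq)
  expect_equal(nrow(st$events), 0)
  mf <- sapply(st$frames, mean); md <- sapply(st$dark, mean)
  expect_lt(abs(mean(mf) - mean(md)), 1)     # both ~ baseline 100
  expect_equal(nrow(detect_stack(dark_correct(st), orbit_params())), 0)
})

test_that("rendered event budget matches the analytic decay integral", {
  # expectation: activity x exposure x sum(decay_t); Poisson spread around it
  ph <- one_phantom(x_um = 320, y_um = 320, activity = 50)
  acq <- acq_config(n_frames = 500, exposure_s = 0.2, n_dark_frames = 2,
                    dead_time_fraction = 0.32, half_life_min = 110)
  set.seed(19)
  st <- simulate_rlm_stack(ph, optics_config(), acq,
                           rlm_sim_params(class_prob = c(short = 1, long = 0,
                                                         diffuse = 0)))
  dt_wall <- acq$exposure_s / (1 - acq$dead_time_fraction) / 60
  expected <- 50 * acq$exposure_s *
    sum(2^(-(0:(acq$n_frames - 1)) * dt_wall / 110))
  expect_lt(abs(nrow(st$events) - expected), 4 * sqrt(expected))
})

test_that("counts-centroid localisation sharpens as events accumulate", {
  # RMS distance of the counts centroid from the true centre shrinks
  # roughly like sigma_psf / sqrt(N)
  set.seed(99)
  sigma <- 2.5
  rms_err <- function(n_events, reps = 40) {
    e <- replicate(reps, {
      x <- rnorm(n_events, 64, sigma); y <- rnorm(n_events, 64, sigma)
      ev <- data.frame(frame_index = 1, x_px = x, y_px = y, length_px = 1,
                       n_px = 1, peak_intensity = 1000, sharpness = 1,
                       klass = "short")
      ci <- accumulate_events(ev, c(128, 128), 1)
      w <- which(ci$grid > 0, arr.ind = TRUE)
      cx <- sum((w[, 2] - 1) * ci$grid[w]) / sum(ci$grid[w])
      cy <- sum((w[, 1] - 1) * ci$grid[w]) / sum(ci$grid[w])
      sqrt((cx - 64)^2 + (cy - 64)^2)
    })
    sqrt(mean(e^2))
  }
  e25 <- rms_err(25); e400 <- rms_err(400)
  expect_lt(e400, e25 / 2)                       # ~1/4 expected
  expect_lt(abs(e400 / (sigma * sqrt(2) / 20) - 1), 0.6)
})
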