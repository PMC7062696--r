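# the dry-mass prefactor lambda/(2 pi alpha) for the defaults, checked by
# independent scalar arithmetic: 0.633 / (2 * pi * 0.18) = 0.5597
test_that("dry mass of a uniform phase patch matches direct evaluation", {
  p <- phase_image(matrix(0, 16, 16), 0.625)
  m <- matrix(TRUE, 16, 16)
  expect_equal(dry_mass(p, m), 0)
  # 1 rad over exactly 100 um^2 (16x16 px at 0.625 um -> 10x10 um)
  p1 <- phase_image(matrix(1, 16, 16), 0.625)
  expect_equal(dry_mass(p1, m), 0.633 / (2 * pi * 0.18) * 100,
               tolerance = 1e-10)
  expect_equal(round(dry_mass(p1, m), 2), 55.97)
})

test_that("dry mass is linear, additive over disjoint masks, and shift
           invariant", {
  set.seed(1)
  v <- matrix(abs(rnorm(32 * 32)), 32, 32)
  p <- phase_image(v, 0.625)
  full <- matrix(TRUE, 32, 32)
  expect_equal(dry_mass(phase_image(3.7 * v, 0.625), full),
               3.7 * dry_mass(p, full))
  a <- matrix(FALSE, 32, 32); a[1:16, ] <- TRUE
  b <- !a
  expect_equal(dry_mass(p, a) + dry_mass(p, b), dry_mass(p, full))
  # whole-pixel translation of cell + mask leaves the mass unchanged
  v2 <- matrix(0, 32, 32); v2[5:12, 5:12] <- 2
  m2 <- v2 > 0
  v3 <- matrix(0, 32, 32); v3[15:22, 11:18] <- 2
  m3 <- v3 > 0
  expect_equal(dry_mass(phase_image(v2, 0.625), m2),
               dry_mass(phase_image(v3, 0.625), m3))
})

test_that("dry mass input contracts are enforced", {
  p <- phase_image(matrix(1, 8, 8), 0.625)
  expect_error(dry_mass(p, matrix(FALSE, 8, 8)), "empty mask")
  expect_error(dry_mass(p, matrix(TRUE, 4, 4)), "congruent")
  v <- matrix(1, 8, 8)
  p2 <- phase_image(v, 0.625)
  p2$values[3, 3] <- NaN
  expect_error(dry_mass(p2, matrix(TRUE, 8, 8)), "finite")
})

test_that("demodulating a background against itself gives zero phase", {
  oc <- tiny_optics()
  ig <- render_interferogram(one_phantom()[0, ], oc, noise_sd = 0)
  pr <- retrieve_phase(ig$background, ig$background, oc$pixel_pitch_um)
  expect_lt(max(abs(pr$values)), 0.05)
})

test_that("a known smooth phase bump is recovered within 0.02 rad", {
  oc <- tiny_optics()
  np <- oc$sensor_px
  x_um <- (seq_len(np) - 1) * oc$pixel_pitch_um
  r2 <- outer((x_um - 75)^2, (x_um - 85)^2, `+`)
  phi0 <- 1.8 * exp(-r2 / (2 * 8^2))  # sigma 8 um, peak 1.8 rad
  carrier <- 2 * pi * (outer(rep(1, np),
                             x_um * oc$carrier_freq_cyc_per_um[1]) +
                       outer(x_um * oc$carrier_freq_cyc_per_um[2],
                             rep(1, np)))
  sample <- 0.5 + 0.45 * cos(carrier + phi0)
  background <- 0.5 + 0.45 * cos(carrier)
  pr <- retrieve_phase(sample, background, oc$pixel_pitch_um)
  inside <- phi0 > 0.05
  expect_lt(max(abs(pr$values - phi0)[inside]), 0.02)
})

test_that("an 8-rad peak unwraps without 2-pi discontinuities", {
  oc <- tiny_optics()
  np <- oc$sensor_px
  x_um <- (seq_len(np) - 1) * oc$pixel_pitch_um
  r2 <- outer((x_um - 75)^2, (x_um - 85)^2, `+`)
  phi0 <- 8 * exp(-r2 / (2 * 10^2))
  carrier <- 2 * pi * (outer(rep(1, np),
                             x_um * oc$carrier_freq_cyc_per_um[1]) +
                       outer(x_um * oc$carrier_freq_cyc_per_um[2],
                             rep(1, np)))
  pr <- retrieve_phase(0.5 + 0.45 * cos(carrier + phi0),
                       0.5 + 0.45 * cos(carrier),
                       oc$pixel_pitch_um)
  v <- pr$values
  expect_lt(max(abs(diff(v))), pi)        # columns
  expect_lt(max(abs(diff(t(v)))), pi)     # rows
  expect_gt(max(v), 7.5)                  # genuinely unwrapped, not clipped
})

test_that("degenerate interferograms are rejected", {
  expect_error(retrieve_phase(matrix(0, 8, 8), matrix(0, 16, 16)),
               "identical shape")
  flat <- matrix(0.5, 64, 64)
  expect_error(retrieve_phase(flat, flat), "contrast")
})

test_that("cosine-cap rendering inverts the mass relation exactly", {
  oc <- tiny_optics()
  ph <- one_phantom(dry_mass_pg = 604, radius_um = 11)
  tm <- phantom_phase_map(ph, oc)
  m <- dry_mass(tm, tm$values > 0)
  expect_lt(abs(m / 604 - 1), 0.005)  # Riemann discretisation only
})

test_that("noiseless interferogram round trip recovers dry mass within 2%", {
  oc <- tiny_optics()
  ph <- one_phantom(dry_mass_pg = 604, radius_um = 11)
  ig <- render_interferogram(ph, oc, noise_sd = 0)
  pr <- retrieve_phase(ig$sample, ig$background, oc$pixel_pitch_um)
  cs <- segment_cells(pr)
  expect_length(cs$cells, 1)
  cl <- cs$cells[[1]]
  sub <- phase_image(pr$values[cl$bbox[1]:cl$bbox[2],
                               cl$bbox[3]:cl$bbox[4]], oc$pixel_pitch_um)
  expect_lt(abs(dry_mass(sub, cl$mask) / 604 - 1), 0.02)
})

test_that("steep phase gradients trigger the unwrapping-safety warning", {
  oc <- tiny_optics()
  ph <- one_phantom(dry_mass_pg = 1500, radius_um = 7)
  expect_warning(render_interferogram(ph, oc, noise_sd = 0),
                 "unwrapping-safe")
})
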