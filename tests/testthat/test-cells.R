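test_that("segmentation handles flat images and separates cells", {
  flat <- phase_image(matrix(0, 64, 64), 0.625)
  expect_length(segment_cells(flat)$cells, 0)

  oc <- tiny_optics()
  ph <- rbind(one_phantom(x_um = 50, y_um = 50),
              one_phantom(x_um = 115, y_um = 110))
  ph$id <- 1:2
  tm <- phantom_phase_map(ph, oc)
  cs1 <- segment_cells(tm)
  cs2 <- segment_cells(tm)
  expect_length(cs1$cells, 2)
  expect_identical(cs1$labels, cs2$labels)   # deterministic labelling
  # mask area close to the phantom footprint
  a <- cs1$cells[[1]]$area_um2
  expect_lt(abs(a / (pi * 12^2) - 1), 0.10)
  # border-touching components are excluded
  phb <- one_phantom(x_um = 2, y_um = 50)
  expect_length(segment_cells(phantom_phase_map(phb, oc))$cells, 0)
})

test_that("merge flagging matches the 2-sigma edge-gap oracle", {
  oc <- tiny_optics()
  sigma <- 12.5
  set.seed(42)
  checked <- 0L
  for (i in 1:50) {
    r <- runif(2, 8, 10)
    gap <- runif(1, 10, 40)
    # centres along a random direction, separated by r1 + r2 + gap
    th <- runif(1, 0, 2 * pi)
    d <- sum(r) + gap
    c1 <- c(80 - d / 2 * cos(th), 80 - d / 2 * sin(th))
    c2 <- c(80 + d / 2 * cos(th), 80 + d / 2 * sin(th))
    ph <- rbind(one_phantom(x_um = c1[1], y_um = c1[2], radius_um = r[1]),
                one_phantom(x_um = c2[1], y_um = c2[2], radius_um = r[2]))
    ph$id <- 1:2
    cs <- segment_cells(phantom_phase_map(ph, oc))
    if (length(cs$cells) != 2) next
    cs <- dilate_and_flag(cs, sigma)
    flags <- vapply(cs$cells, `[[`, logical(1), "merged")
    expect_equal(flags[1], flags[2])        # symmetry, always
    # effective mask radii (threshold trims the cap rim slightly)
    reff <- sqrt(vapply(cs$cells, `[[`, numeric(1), "area_um2") / pi)
    gap_eff <- d - sum(reff)
    if (abs(gap_eff - 2 * sigma) < 2) next  # skip pixel-quantised boundary
    checked <- checked + 1L
    expect_equal(unique(flags), gap_eff < 2 * sigma,
                 info = sprintf("gap %.1f um", gap_eff))
  }
  expect_gt(checked, 35)
})

test_that("dilated masks contain the original masks", {
  oc <- tiny_optics()
  cs <- dilate_and_flag(segment_cells(phantom_phase_map(one_phantom(), oc)))
  cl <- cs$cells[[1]]
  expect_false(cl$merged)
  inner <- which(cl$mask, arr.ind = TRUE)
  inner[, 1] <- inner[, 1] + cl$bbox[1] - cl$dilated_bbox[1]
  inner[, 2] <- inner[, 2] + cl$bbox[3] - cl$dilated_bbox[3]
  expect_true(all(cl$dilated_mask[inner]))
})

test_that("count integration applies live time and decay exactly", {
  oc <- tiny_optics()
  ph <- one_phantom(x_um = 80, y_um = 80)
  cs <- dilate_and_flag(segment_cells(phantom_phase_map(ph, oc)))
  cl <- cs$cells[[1]]
  dims <- c(oc$rlm_px, oc$rlm_px)
  k <- 7
  ev <- data.frame(frame_index = 1, x_px = rep(80 / 5, k),
                   y_px = rep(80 / 5, k), length_px = 1, n_px = 1,
                   peak_intensity = 1000, sharpness = 1, klass = "short")
  ci <- accumulate_events(ev, dims, live_time_min = 400 / 60)
  expect_equal(integrate_counts(cl, ci, binning = 8, decay_factor = 1),
               k / (400 / 60))
  expect_equal(integrate_counts(cl, ci, binning = 8, decay_factor = 2),
               2 * k / (400 / 60))
  # zero counts image
  ci0 <- accumulate_events(ev[0, ], dims, 400 / 60)
  expect_equal(integrate_counts(cl, ci0, binning = 8, decay_factor = 1), 0)
  # events outside the dilated mask are not attributed to the cell
  evfar <- ev; evfar$x_px <- 2; evfar$y_px <- 2
  cifar <- accumulate_events(evfar, dims, 400 / 60)
  expect_equal(integrate_counts(cl, cifar, 8, 1), 0)
  # contract violations
  clm <- cl; clm$merged <- TRUE
  expect_error(integrate_counts(clm, ci, 8, 1), "merged")
  expect_error(integrate_counts(cl, ci, 8, 1, full_dim = c(999, 999)),
               "registered")
})

test_that("cells merged by dilation are discarded from the table", {
  oc <- tiny_optics()
  ph <- rbind(one_phantom(x_um = 65, y_um = 80),
              one_phantom(x_um = 95, y_um = 80))   # 30 um apart: gap << 2 sigma
  ph$id <- 1:2
  tm <- phantom_phase_map(ph, oc)
  dims <- c(oc$rlm_px, oc$rlm_px)
  ci <- accumulate_events(data.frame(), dims, 1)
  zero <- matrix(0, oc$sensor_px, oc$sensor_px)
  tab <- build_cell_table(tm, zero, zero, ci, binning = 8)
  expect_equal(nrow(tab), 0)
  expect_equal(nrow(attr(tab, "discarded")), 2)
  expect_equal(attr(tab, "discarded")$reason,
               rep("merged_by_dilation", 2))
})

test_that("an isolated cell produces one fully populated record", {
  ds <- small_dataset(n_cells = 1, seed = 9, n_frames = 80,
                      noiseless = TRUE)
  res <- process_dataset(ds)
  tab <- res$cell_table
  expect_equal(nrow(tab), 1)
  expect_false(tab$merged)
  expect_gt(tab$dry_mass_pg, 0)
  expect_gte(tab$counts_per_min, 0)
  expect_false(is.na(tab$cycle_phase))
})
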