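#' Simulate one complete multimodal field of view
#'
#' Generates a seeded, ground-truth-annotated multimodal dataset: a phantom
#' population, the off-axis interferogram pair, both FUCCI fluorescence
#' channel pairs, a bright-field placeholder, and the radioluminescence
#' frame and dark stacks. A fixed seed yields a bit-identical dataset.
#'
#' The default acquisition profile keeps the reference protocol's 400 s of
#' live exposure but groups it as 2,000 frames of 200 ms rather than
#' 20,000 frames of 20 ms, which leaves the accepted-count statistics per
#' cell unchanged while keeping a full simulated study tractable on a
#' desktop; pass `acq = acq_config()` for the full-scale frame budget.
#'
#' @param n_cells Number of phantom cells.
#' @param seed Integer seed for the whole dataset.
#' @param optics An [optics_config()].
#' @param acq An [acq_config()].
#' @param params A [phantom_params()].
#' @param rlm_sim An [rlm_sim_params()].
#' @param interferogram_noise_sd,fluor_noise_sd Additive noise levels for
#'   the optical modalities (0 = noiseless).
#' @param out_dir Optional directory; when given the dataset is also
#'   written with [write_dataset()].
#' @return An object of class `rc_dataset`.
#' @export
simulate_fov <- function(n_cells = 26L, seed = 1L,
                         optics = optics_config(),
                         acq = acq_config(n_frames = 2000L,
                                          exposure_s = 0.2),
                         params = phantom_params(),
                         rlm_sim = rlm_sim_params(),
                         interferogram_noise_sd = 0.01,
                         fluor_noise_sd = 0.005,
                         out_dir = NULL) {
  phantoms <- make_phantom_population(n_cells, seed = seed, params = params,
                                      optics = optics, acq = acq,
                                      rlm_sim = rlm_sim)
  qpm <- render_interferogram(phantoms, optics,
                              noise_sd = interferogram_noise_sd)
  gfp <- render_fluorescence(phantoms, "GFP", optics,
                             noise_sd = fluor_noise_sd)
  rfp <- render_fluorescence(phantoms, "RFP", optics,
                             noise_sd = fluor_noise_sd)
  bf <- 0.5 - 0.1 * tanh(qpm$phase_truth$values)  # inspection-only placeholder
  rlm <- simulate_rlm_stack(phantoms, optics, acq, rlm_sim)
  ds <- structure(list(phantoms = phantoms, qpm = qpm, gfp = gfp, rfp = rfp,
                       brightfield = bf, rlm = rlm, optics = optics,
                       acq = acq,
                       noise = list(interferogram_sd = interferogram_noise_sd,
                                    fluor_sd = fluor_noise_sd),
                       seed = as.integer(seed)),
                  class = "rc_dataset")
  if (!is.null(out_dir)) write_dataset(ds, out_dir)
  ds
}

#' @export
print.rc_dataset <- function(x, ...) {
  cat("Multimodal dataset (seed ", x$seed, "): ", nrow(x$phantoms),
      " phantoms, ", length(x$rlm$frames), " RLM frames\n", sep = "")
  invisible(x)
}

#' Process a multimodal dataset into a per-cell table
#'
#' Runs the full measurement pipeline on one field of view: interferogram
#' demodulation and background levelling, fluorescence normalisation,
#' dark correction, event detection, track filtering and accumulation of
#' the counts image, phase-based segmentation with PSF dilation and
#' merged-cell discarding, per-cell dry mass, cycle-phase classification
#' and decay-corrected count integration. Processing is deterministic:
#' identical inputs and configuration give byte-identical outputs.
#'
#' @param ds An `rc_dataset` from [simulate_fov()], or a dataset directory
#'   written by [write_dataset()].
#' @param orbit An [orbit_params()].
#' @param dilation_sigma_um Boundary-dilation radius, micrometres.
#' @param phase_thresh,min_area_um2 Segmentation settings.
#' @param overrides Optional named manual phase overrides (label -> phase).
#' @param out_dir Optional output directory: writes `cells.csv`, the label
#'   image, the counts image + sidecar, and `process_manifest.json` with
#'   configuration, per-stage record counts and output file hashes.
#' @return An object of class `rc_result`: list with `cell_table`,
#'   `events`, `counts`, `phase`, `manifest`.
#' @export
process_dataset <- function(ds, orbit = orbit_params(),
                            dilation_sigma_um = 12.5,
                            phase_thresh = 0.1, min_area_um2 = 50,
                            overrides = NULL, out_dir = NULL) {
  if (is.character(ds)) ds <- read_dataset(ds)
  stopifnot(inherits(ds, "rc_dataset"))
  optics <- ds$optics; acq <- ds$acq

  phase <- retrieve_phase(ds$qpm$sample, ds$qpm$background,
                          pixel_pitch_um = optics$pixel_pitch_um,
                          carrier_hint = optics$carrier_freq_cyc_per_um)
  green <- normalize_channel(ds$gfp$image, ds$gfp$background)
  red <- normalize_channel(ds$rfp$image, ds$rfp$background)

  corrected <- dark_correct(ds$rlm$frames, ds$rlm$dark)
  events <- detect_stack(corrected, orbit, pitch_um = optics$rlm_pitch_um)
  dcf <- decay_correction_factor(acq$start_offset_min, acq$half_life_min)
  counts <- accumulate_events(events,
                              dims = c(optics$rlm_px, optics$rlm_px),
                              live_time_min = acq$live_time_min,
                              decay_factor = dcf)

  tab <- build_cell_table(phase, green, red, counts,
                          binning = optics$rlm_binning,
                          dilation_sigma_um = dilation_sigma_um,
                          phase_thresh = phase_thresh,
                          min_area_um2 = min_area_um2,
                          decay_factor = dcf, overrides = overrides)

  manifest <- list(
    software = paste0("radiocell ",
                      as.character(utils::packageVersion("radiocell"))),
    seed = ds$seed,
    config = list(orbit = unclass(orbit),
                  dilation_sigma_um = dilation_sigma_um,
                  phase_thresh = phase_thresh,
                  min_area_um2 = min_area_um2,
                  decay_factor = dcf,
                  optics = unclass(optics), acq = unclass(acq)),
    stages = list(
      n_frames = length(ds$rlm$frames),
      events_by_class = as.list(table(events$klass)),
      events_accepted = counts$n_accepted,
      cells_found = nrow(tab) + nrow(attr(tab, "discarded")),
      cells_discarded_merged = nrow(attr(tab, "discarded")),
      cells_reported = nrow(tab)
    )
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    csv <- file.path(out_dir, "cells.csv")
    utils::write.csv(format_cell_table(tab), csv, row.names = FALSE)
    cimg <- file.path(out_dir, "counts.tif")
    write_image_tiff(counts$grid + 0, cimg)
    jsonlite::write_json(list(live_time_min = counts$live_time_min,
                              decay_factor = counts$decay_factor,
                              params = unclass(orbit)),
                         file.path(out_dir, "counts_meta.json"),
                         auto_unbox = TRUE, digits = NA)
    limg <- file.path(out_dir, "labels.tif")
    cs <- attr(tab, "cell_set")
    tiff::writeTIFF(cs$labels / 65535, limg, bits.per.sample = 16L,
                    compression = "deflate")
    outs <- c(csv, cimg, limg)
    manifest$outputs <- as.list(tools::md5sum(outs))
    jsonlite::write_json(manifest,
                         file.path(out_dir, "process_manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(list(cell_table = tab, events = events, counts = counts,
                 phase = phase, manifest = manifest),
            class = "rc_result")
}

# fixed-precision serialisation so reruns are byte-identical
format_cell_table <- function(tab) {
  out <- as.data.frame(tab)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) sprintf("%.6f", x))
  out
}

#' @export
print.rc_result <- function(x, ...) {
  st <- x$manifest$stages
  cat("Pipeline result: ", st$cells_reported, " cells reported (",
      st$cells_discarded_merged, " merged-discarded); ",
      st$events_accepted, " accepted events\n", sep = "")
  invisible(x)
}

#' Statistical report and figures for a cell table
#'
#' Reproduces the study-level analyses on a per-cell table: median/IQR
#' summaries of dry mass, counts/min and mass-normalised counts per cycle
#' phase; two-tailed Mann-Whitney tests and one-way ANOVA across phases;
#' the S/G2/M-versus-G1 percent increase of median uptake; and Huber IRLS
#' regressions of counts/min on dry mass and of mass-normalised counts on
#' dry mass. With fewer than 3 cells the regression is skipped with a
#' warning and only the summaries are returned. When `out_dir` is given,
#' a JSON report and publication-style figures (scatter with robust fit
#' and 95% confidence band, mass-normalised scatter, per-phase box plots)
#' are written.
#'
#' @param cell_table A [build_cell_table()] data.frame (needs
#'   `dry_mass_pg`, `counts_per_min`, `cycle_phase`).
#' @param out_dir Optional output directory for `report.json` and figures.
#' @return A list of class `rc_report` with `summaries`, `tests`,
#'   `regression`, `regression_normalized`, `n_cells`.
#' @export
run_report <- function(cell_table, out_dir = NULL) {
  n <- nrow(cell_table)
  mass <- cell_table$dry_mass_pg
  cpm <- cell_table$counts_per_min
  phase <- droplevels(cell_table$cycle_phase)
  norm_cpm <- cpm / mass

  summaries <- list(
    dry_mass_all = summarize_groups(mass),
    counts_all = summarize_groups(cpm),
    dry_mass_by_phase = summarize_groups(mass, phase),
    counts_by_phase = summarize_groups(cpm, phase),
    normalized_by_phase = summarize_groups(norm_cpm, phase)
  )

  tests <- list()
  cb <- summaries$counts_by_phase
  if (all(c("G1", "S_G2_M") %in% levels(phase))) {
    g1c <- cpm[phase == "G1"]; sc <- cpm[phase == "S_G2_M"]
    g1m <- mass[phase == "G1"]; sm <- mass[phase == "S_G2_M"]
    tests$mw_counts_sg2m_vs_g1 <- mann_whitney_two_tailed(sc, g1c)
    tests$mw_mass_sg2m_vs_g1 <- mann_whitney_two_tailed(sm, g1m)
    tests$uptake_increase_pct <-
      100 * (stats::median(sc) - stats::median(g1c)) / stats::median(g1c)
    tests$counts_median_ratio_sg2m_g1 <-
      stats::median(sc) / stats::median(g1c)
  }
  big <- names(table(phase))[table(phase) >= 2]
  if (length(big) >= 2) {
    sel <- phase %in% big
    tests$anova_counts <- anova_oneway(cpm[sel], phase[sel])
    tests$anova_mass <- anova_oneway(mass[sel], phase[sel])
    tests$anova_normalized <- anova_oneway(norm_cpm[sel], phase[sel])
  }

  regression <- regression_norm <- NULL
  if (n >= 3 && stats::sd(mass) > 0) {
    regression <- huber_irls(mass, cpm)
    regression_norm <- huber_irls(mass, norm_cpm)
  } else {
    warning("fewer than 3 usable cells: regression skipped")
  }

  rep <- structure(list(summaries = summaries, tests = tests,
                        regression = regression,
                        regression_normalized = regression_norm,
                        n_cells = n),
                   class = "rc_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report_to_list(rep),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(regression)) {
      plot_scatter_fit(mass, cpm, regression,
                       xlab = "dry mass (pg)", ylab = "counts/min",
                       file.path(out_dir, "counts_vs_mass.png"))
      plot_scatter_fit(mass, norm_cpm, regression_norm,
                       xlab = "dry mass (pg)",
                       ylab = "counts/min per pg",
                       file.path(out_dir, "normalized_vs_mass.png"))
    }
    plot_phase_boxes(mass, cpm, norm_cpm, phase,
                     file.path(out_dir, "phase_boxplots.png"))
  }
  rep
}

report_to_list <- function(rep) {
  reg <- function(f) if (is.null(f)) NULL else
    list(slope = unname(f$coefficients["slope"]),
         intercept = unname(f$coefficients["intercept"]),
         adjusted_r_squared = f$adj_r_squared,
         adjusted_r_squared_ols = f$adj_r_squared_ols,
         p_value_slope = f$p_value_slope, n = f$n,
         converged = f$converged, n_irls_iterations = f$iterations)
  list(n_cells = rep$n_cells,
       summaries = lapply(rep$summaries, function(s) {
         attr(s, "quartile_type") <- NULL
         s
       }),
       quartile_rule = "type-7 linear interpolation",
       tests = rapply(rep$tests, unclass, how = "replace"),
       regression = reg(rep$regression),
       regression_normalized = reg(rep$regression_normalized))
}

plot_scatter_fit <- function(x, y, fit, xlab, ylab, path) {
  grDevices::png(path, width = 900, height = 700, res = 130)
  on.exit(grDevices::dev.off())
  graphics::plot(x, y, pch = 19, col = "steelblue4", xlab = xlab,
                 ylab = ylab)
  xs <- seq(min(x), max(x), length.out = 100)
  pred <- fit$coefficients[1] + fit$coefficients[2] * xs
  sepred <- sqrt(fit$vcov[1, 1] + 2 * xs * fit$vcov[1, 2] +
                   xs^2 * fit$vcov[2, 2])
  tq <- stats::qt(0.975, df = fit$n - 2)
  graphics::polygon(c(xs, rev(xs)),
                    c(pred - tq * sepred, rev(pred + tq * sepred)),
                    col = grDevices::adjustcolor("grey60", 0.4),
                    border = NA)
  graphics::lines(xs, pred, col = "red3", lwd = 2)
  graphics::points(x, y, pch = 19, col = "steelblue4")
  invisible(path)
}

plot_phase_boxes <- function(mass, cpm, norm_cpm, phase, path) {
  grDevices::png(path, width = 1300, height = 500, res = 130)
  on.exit(grDevices::dev.off())
  op <- graphics::par(mfrow = c(1, 3))
  on.exit(graphics::par(op), add = TRUE)
  graphics::boxplot(mass ~ phase, range = 0, ylab = "dry mass (pg)",
                    xlab = "")
  graphics::boxplot(cpm ~ phase, range = 0, ylab = "counts/min", xlab = "")
  graphics::boxplot(norm_cpm ~ phase, range = 0,
                    ylab = "counts/min per pg", xlab = "")
  invisible(path)
}

#' @export
print.rc_report <- function(x, ...) {
  cat("Report over ", x$n_cells, " cells\n", sep = "")
  cat("  dry mass median ",
      round(x$summaries$dry_mass_all$median, 1), " pg [",
      round(x$summaries$dry_mass_all$q1, 1), "-",
      round(x$summaries$dry_mass_all$q3, 1), "]\n", sep = "")
  cat("  counts/min median ",
      round(x$summaries$counts_all$median, 1), " [",
      round(x$summaries$counts_all$q1, 1), "-",
      round(x$summaries$counts_all$q3, 1), "]\n", sep = "")
  if (!is.null(x$tests$uptake_increase_pct))
    cat("  S/G2/M vs G1 uptake increase ",
        round(x$tests$uptake_increase_pct, 1), "%\n", sep = "")
  if (!is.null(x$regression))
    cat("  counts ~ mass: slope ",
        signif(x$regression$coefficients["slope"], 3),
        ", adjusted R^2 ", round(x$regression$adj_r_squared, 3),
        ", p ", format.pval(x$regression$p_value_slope), "\n", sep = "")
  invisible(x)
}

#' Concatenate per-cell tables from several experiments
#'
#' Pools cell tables from separate fields of view or experiments into one
#' table with an experiment identifier and globally unique labels.
#'
#' @param ... `cell_table` data.frames (or a single list of them).
#' @param ids Optional experiment identifiers (default sequential).
#' @return A pooled `cell_table`.
#' @export
aggregate_tables <- function(..., ids = NULL) {
  tabs <- list(...)
  if (length(tabs) == 1L && is.list(tabs[[1]]) &&
      !inherits(tabs[[1]], "data.frame")) tabs <- tabs[[1]]
  if (is.null(ids)) ids <- seq_along(tabs)
  out <- do.call(rbind, lapply(seq_along(tabs), function(i) {
    t <- as.data.frame(tabs[[i]])
    t$experiment <- ids[i]
    t
  }))
  out$label <- seq_len(nrow(out))
  class(out) <- c("cell_table", "data.frame")
  out
}
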