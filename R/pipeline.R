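#' Run the full monitoring pipeline on a synthetic scenario
#'
#' Convenience wrapper for replicate studies: simulates the image, fiber
#' and process series of a scenario, registers the frames, computes the
#' per-layer similarity series, derives carbon rate and permeability, and
#' applies the onset detector to the four online indicators (sensor-fiber
#' transmission, blue-layer correlation, permeability, feed-channel
#' pressure drop).
#'
#' Defaults adapt the pixel-dimensioned settings to the scenario's frame
#' size: the template is a centered square of about 1/8 frame height, the
#' crop margins scale from the full-frame `(127, 175)`, and baselines span
#' 24 h of samples per series.
#'
#' @param config a [scenario_config()].
#' @param roi optional [template_roi()]; default a centered square.
#' @param margins optional crop margins; default scales `(127, 175)` with
#'   frame height.
#' @param start_h conditioning cutoff before which indicator baselines are
#'   not trusted.
#' @param k,persistence onset-detector settings, see [detect_onset()].
#' @param sensor_interval_h sampling interval of the fiber and process
#'   records (images follow the scenario's `frame_interval_h`).
#' @return List of class `monitoring_report`: `onsets` (named numeric:
#'   `pof`, `blue`, `permeability`, `fcp`; `NA` where not detected),
#'   `similarity`, `pof`, `derived`, `offsets`, `reports` (the
#'   [detect_onset()] reports).
#' @export
monitor_scenario <- function(config, roi = NULL, margins = NULL,
                             start_h = 96, k = 3, persistence = 5L,
                             sensor_interval_h = 1) {
  cfg <- validate_scenario(config)
  H <- cfg$frame_height; W <- cfg$frame_width
  scale <- H / 2064
  if (is.null(margins))
    margins <- pmax(c(8L, 8L), as.integer(round(c(127, 175) * scale)))
  if (is.null(roi)) {
    side <- max(16L, as.integer(round(H / 8)))
    roi <- template_roi(row0 = (H - side) %/% 2L, col0 = (W - side) %/% 2L,
                        height = side, width = side)
  }

  sim <- simulate_image_series(cfg)
  reg <- register_series(sim$frames, reference_index = 1L, roi = roi,
                         margins = margins)
  simil <- similarity_series(reg)
  pof <- simulate_pof_series(cfg, interval_h = sensor_interval_h)
  proc <- simulate_process_series(cfg, interval_h = sensor_interval_h)
  der <- derive_series(proc)

  bw_img <- max(5L, round(24 / cfg$frame_interval_h))
  bw_sen <- max(5L, round(24 / sensor_interval_h))
  reports <- list(
    pof = detect_onset(pof$time_h, pof$sensor, "decrease",
                       baseline_window = bw_sen, k = k,
                       persistence = persistence, start_h = start_h,
                       signal = "POF transmission"),
    blue = detect_onset(simil$time_h, simil$r_blue, "decrease",
                        baseline_window = bw_img, k = k,
                        persistence = persistence, start_h = start_h,
                        signal = "blue-layer correlation"),
    permeability = detect_onset(der$time_h, der$permeability, "decrease",
                                baseline_window = bw_sen, k = k,
                                persistence = persistence, start_h = start_h,
                                signal = "permeability"),
    fcp = detect_onset(der$time_h, der$fcp, "increase",
                       baseline_window = bw_sen, k = k,
                       persistence = persistence, start_h = start_h,
                       signal = "feed-channel pressure drop"))
  onsets <- vapply(reports, function(r) r$onset_time_h, numeric(1))
  structure(list(onsets = onsets, similarity = simil, pof = pof,
                 derived = der, offsets = reg$offsets, reports = reports,
                 planted_offsets = sim$planted_offsets,
                 coverage = sim$coverage, config = cfg),
            class = "monitoring_report")
}

#' @export
print.monitoring_report <- function(x, ...) {
  cat("Biofouling monitoring report\n")
  for (nm in names(x$onsets)) {
    o <- x$onsets[[nm]]
    cat(sprintf("  %-14s %s\n", nm,
                if (is.na(o)) "no onset" else sprintf("onset at %g h", o)))
  }
  fin <- x$similarity[nrow(x$similarity), ]
  cat(sprintf("  final layer correlations: R %.4f, G %.4f, B %.4f\n",
              fin$r_red, fin$r_green, fin$r_blue))
  invisible(x)
}
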