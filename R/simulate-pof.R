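#' Simulate polymer-optical-fiber transmission series
#'
#' Generates the normalized light transmission of a decladded sensor fiber
#' and an intact reference fiber over the scenario. The trace combines
#' (i) an asymptotic conditioning decay from water uptake and mechanical
#' stress, `(1 - amplitude) + amplitude * exp(-t / tau_h)`;
#' (ii) a multiplicative 24 h modulation from the daily temperature cycle;
#' and, for the sensor fiber only, (iii) exponential attenuation by biofilm
#' coverage, `exp(-fouling_k * coverage)`, with coverage capped at the
#' `plateau` value at which the sensing zone is fully overgrown and the
#' signal saturates. Cleaning-in-place events remove the configured fraction
#' of accumulated biomass, so the trace recovers stepwise. Both traces are
#' normalized to 1 at time zero (before measurement noise).
#'
#' The biofilm coverage driving the attenuation is the same patch set that
#' darkens the image series: both are drawn from the scenario's root seed.
#'
#' @param config a [scenario_config()].
#' @param interval_h sampling interval in hours (defaults to the scenario's
#'   frame interval).
#' @return A data frame of class `transmission_series` with columns
#'   `time_h`, `sensor`, `reference`, plus attributes `coverage_frac`
#'   (latent coverage per sample) and `config`.
#' @export
simulate_pof_series <- function(config, interval_h = config$frame_interval_h) {
  cfg <- validate_scenario(config)
  pp <- cfg$pof_params
  J <- cfg$jitter_max
  Hc <- cfg$frame_height + 2L * J
  Wc <- cfg$frame_width + 2L * J
  patches <- sample_patches(cfg, Hc, Wc)
  set.seed(cfg$seed + 1L)   # noise stream distinct from the patch draw

  t <- seq(0, cfg$duration_h, by = interval_h)
  cov <- vapply(t, function(ti)
    coverage_fraction_scalar(cfg, patches, Hc, Wc, ti), numeric(1))
  cov_capped <- pmin(cov, pp$plateau)

  conditioning <- (1 - pp$amplitude) + pp$amplitude * exp(-t / pp$tau_h)
  diurnal <- 1 + pp$diurnal * sin(2 * pi * t / 24)
  sensor <- conditioning * diurnal * exp(-pp$fouling_k * cov_capped)
  reference <- conditioning * diurnal
  if (pp$noise_sd > 0) {
    sensor <- sensor + stats::rnorm(length(t), sd = pp$noise_sd)
    reference <- reference + stats::rnorm(length(t), sd = pp$noise_sd)
  }
  out <- data.frame(time_h = t, sensor = sensor, reference = reference)
  attr(out, "coverage_frac") <- cov
  attr(out, "config") <- cfg
  class(out) <- c("transmission_series", "data.frame")
  out
}

#' @export
plot.transmission_series <- function(x, ...) {
  graphics::matplot(x$time_h, cbind(x$sensor, x$reference), type = "l",
                    lty = 1, col = c("firebrick", "grey40"),
                    xlab = "time [h]", ylab = "normalized transmission", ...)
  graphics::legend("bottomleft", legend = c("sensor fiber", "reference fiber"),
                   col = c("firebrick", "grey40"), lty = 1, bty = "n")
  invisible(x)
}
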