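#' Scenario configuration for the synthetic biofouling experiment
#'
#' Builds and validates the full parameterization of a simulated
#' accelerated-biofouling run on a reverse-osmosis flat module: the imaging
#' geometry and cadence, camera jitter, biofilm nucleation and growth, the
#' channel-specific colour attenuation that turns the white membrane brown,
#' illumination drift, cleaning-in-place (CIP) events, the
#' polymer-optical-fiber (POF) transmission model, and the process-data
#' templates (TOC mass balance, permeability, feed-channel pressure drop).
#'
#' All stochastic draws of every simulator derive from the single `seed`, so
#' an identical configuration reproduces identical output.
#'
#' @param seed integer root seed for all randomness.
#' @param duration_h experiment duration in hours.
#' @param frame_interval_h imaging interval in hours (photographs of the
#'   membrane surface are taken at regular intervals; 1 h by default).
#' @param frame_height,frame_width frame dimensions in pixels. Defaults
#'   match a 6.4 MP industrial camera (2064 x 3088).
#' @param jitter_max maximum absolute camera translation per axis, pixels.
#' @param onset_h time at which biofouling starts (nutrient dosing), hours.
#' @param nucleation_rate expected biofilm patches nucleating per hour
#'   after onset.
#' @param patch_growth_rate patch radius growth, pixels per hour.
#' @param channel_attenuation named numeric triple `c(r=, g=, b=)`:
#'   fractional intensity loss per unit biofilm coverage for the red, green
#'   and blue layers. A biofilm absorbs blue light most and red least, so
#'   the values must be ordered b >= g >= r.
#' @param illumination_drift fractional lamp-intensity drift per 100 h
#'   (applied multiplicatively and uniformly over the frame).
#' @param noise_sd pixel noise standard deviation, 8-bit intensity units.
#' @param cip_events list of `list(time_h=, efficacy=)` cleaning events;
#'   each event removes the given fraction of accumulated biofilm.
#' @param pof_params list with elements `amplitude` (conditioning decay
#'   amplitude as a fraction of the initial transmission), `tau_h`
#'   (conditioning time constant, hours), `diurnal` (relative amplitude of
#'   the 24 h temperature-cycle modulation), `fouling_k` (transmission
#'   attenuation per unit coverage), `plateau` (coverage at which the fiber
#'   surface is effectively overgrown and the signal saturates), `noise_sd`
#'   (relative measurement noise).
#' @param process_params list with elements `toc_feed` (baseline feed TOC,
#'   mg/L), `flow_feed` and `flow_ret` (feed and retentate flow, L/h),
#'   `area_m2` (membrane area), `tmp_net` (net transmembrane pressure,
#'   bar), `perm_baseline` (clean-membrane permeability, L/(m^2 h bar)),
#'   `fcp_baseline` (baseline feed-channel pressure drop, mbar),
#'   `detach_h` (time the carbon balance flips from attachment to
#'   detachment), `perm_rise_frac` (relative permeability rise after the
#'   feed change, from the pH-dependent surface-charge effect),
#'   `perm_decline_h` (permeability decline onset), `perm_decline_rate`
#'   (relative decline per hour), `fcp_onset_h` (FCP increase onset),
#'   `fcp_rate` (mbar/h), `carbon_amp` (peak carbon-rate magnitude, mg/h),
#'   `toc_noise`, `perm_noise`, `fcp_noise` (measurement noise sd).
#'
#' @return An object of class `scenario_config` (a validated list).
#' @seealso [simulate_image_series()], [simulate_pof_series()],
#'   [simulate_process_series()], [scaled_scenario()]
#' @export
#' @examples
#' cfg <- scenario_config(seed = 1, frame_height = 128, frame_width = 192,
#'                        duration_h = 48, onset_h = 24)
#' cfg
scenario_config <- function(seed = 1L,
                            duration_h = 360,
                            frame_interval_h = 1,
                            frame_height = 2064L,
                            frame_width = 3088L,
                            jitter_max = 20L,
                            onset_h = 120,
                            nucleation_rate = 0.6,
                            patch_growth_rate = 2,
                            channel_attenuation = c(r = 0.15, g = 0.35, b = 0.60),
                            illumination_drift = 0.02,
                            noise_sd = 2,
                            cip_events = list(),
                            pof_params = list(),
                            process_params = list()) {
  pof_default <- list(amplitude = 0.2, tau_h = 24, diurnal = 0.01,
                      fouling_k = 2.5, plateau = 0.9, noise_sd = 0.002)
  proc_default <- list(toc_feed = 1.0, flow_feed = 11.5, flow_ret = 10.5,
                       area_m2 = 0.01, tmp_net = 10,
                       perm_baseline = 10, fcp_baseline = 100,
                       detach_h = 160,
                       perm_rise_frac = 0.03, perm_decline_h = 220,
                       perm_decline_rate = 0.008,
                       fcp_onset_h = 240, fcp_rate = 0.8,
                       carbon_amp = 1.5,
                       toc_noise = 0.01, perm_noise = 0.01, fcp_noise = 0.5)
  pof_params <- utils::modifyList(pof_default, pof_params)
  process_params <- utils::modifyList(proc_default, process_params)

  cfg <- list(seed = as.integer(seed),
              duration_h = duration_h,
              frame_interval_h = frame_interval_h,
              frame_height = as.integer(frame_height),
              frame_width = as.integer(frame_width),
              jitter_max = as.integer(jitter_max),
              onset_h = onset_h,
              nucleation_rate = nucleation_rate,
              patch_growth_rate = patch_growth_rate,
              channel_attenuation = channel_attenuation,
              illumination_drift = illumination_drift,
              noise_sd = noise_sd,
              cip_events = cip_events,
              pof_params = pof_params,
              process_params = process_params)
  class(cfg) <- "scenario_config"
  validate_scenario(cfg)
}

validate_scenario <- function(cfg) {
  stop_cfg <- function(...) stop("invalid scenario configuration: ", ...,
                                 call. = FALSE)
  if (length(cfg$seed) != 1L || is.na(cfg$seed))
    stop_cfg("seed must be a single integer")
  if (!is.finite(cfg$frame_interval_h) || cfg$frame_interval_h <= 0)
    stop_cfg("frame_interval_h must be > 0")
  if (cfg$duration_h < cfg$frame_interval_h)
    stop_cfg("duration_h must be at least one frame interval")
  if (cfg$frame_height <= 0L || cfg$frame_width <= 0L)
    stop_cfg("frame dimensions must be positive")
  if (cfg$jitter_max < 0L)
    stop_cfg("jitter_max must be >= 0")
  att <- cfg$channel_attenuation
  if (length(att) != 3L || any(!is.finite(att)) || any(att < 0))
    stop_cfg("channel_attenuation must be three finite non-negative values")
  if (is.null(names(att)) || !identical(names(att), c("r", "g", "b")))
    names(att) <- c("r", "g", "b")
  if (!(att[["b"]] >= att[["g"]] && att[["g"]] >= att[["r"]]))
    stop_cfg("channel_attenuation must be ordered b >= g >= r ",
             "(biofilm absorbs blue most, red least)")
  cfg$channel_attenuation <- att
  for (ev in cfg$cip_events) {
    if (is.null(ev$time_h) || is.null(ev$efficacy))
      stop_cfg("each CIP event needs time_h and efficacy")
    if (ev$efficacy < 0 || ev$efficacy > 1)
      stop_cfg("CIP efficacy must lie in [0, 1]")
  }
  if (cfg$pof_params$tau_h <= 0)
    stop_cfg("POF conditioning time constant tau_h must be positive")
  if (cfg$pof_params$plateau <= 0 || cfg$pof_params$plateau > 1)
    stop_cfg("POF plateau coverage must lie in (0, 1]")
  if (cfg$noise_sd < 0) stop_cfg("noise_sd must be >= 0")
  cfg
}

#' Rescale a scenario to a smaller frame size
#'
#' Produces the same study conditions at a lower imaging resolution: pixel
#' dimensioned parameters (jitter, patch growth) are scaled with the frame so
#' the simulated membrane, its spacer mesh and the biofilm coverage dynamics
#' are resolution-invariant. Useful for replicate studies where full 6.4 MP
#' frames would be wasteful.
#'
#' @param scale linear scale factor relative to the full 2064 x 3088 frame
#'   (e.g. 0.25 gives 516 x 772).
#' @param ... further arguments passed to [scenario_config()].
#' @return A `scenario_config`.
#' @export
scaled_scenario <- function(scale = 0.25, ...) {
  args <- list(...)
  defaults <- list(frame_height = as.integer(round(2064 * scale)),
                   frame_width = as.integer(round(3088 * scale)),
                   jitter_max = max(1L, as.integer(round(20 * scale))),
                   patch_growth_rate = 2 * scale)
  do.call(scenario_config, utils::modifyList(defaults, args))
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Synthetic biofouling scenario\n")
  cat(sprintf("  frames: %d x %d px every %g h for %g h (seed %d)\n",
              x$frame_height, x$frame_width, x$frame_interval_h,
              x$duration_h, x$seed))
  cat(sprintf("  fouling onset at %g h; nucleation %.3g patches/h, growth %.3g px/h\n",
              x$onset_h, x$nucleation_rate, x$patch_growth_rate))
  cat(sprintf("  attenuation per coverage (R,G,B): %.2f, %.2f, %.2f\n",
              x$channel_attenuation[["r"]], x$channel_attenuation[["g"]],
              x$channel_attenuation[["b"]]))
  if (length(x$cip_events))
    cat(sprintf("  CIP events: %s\n",
                paste(vapply(x$cip_events, function(e)
                  sprintf("%g h (efficacy %.2f)", e$time_h, e$efficacy), ""),
                  collapse = ", ")))
  invisible(x)
}

## Frame timestamps for a scenario.
scenario_times <- function(cfg) {
  seq(0, cfg$duration_h, by = cfg$frame_interval_h)
}

## Cumulative CIP survival factor applied to biofilm accumulated before t:
## each event at time_h <= t multiplies existing biomass by (1 - efficacy).
cip_factor_at <- function(cfg, t) {
  f <- 1
  for (ev in cfg$cip_events) if (ev$time_h <= t) f <- f * (1 - ev$efficacy)
  f
}
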