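#' Simulate process-data records for a biofouling scenario
#'
#' Generates the online and offline process observables of the simulated
#' run: feed and retentate TOC, flow rates, permeate flow, net
#' transmembrane pressure and feed-channel pressure drop (FCP), built so
#' that the derived indicators show the canonical two-phase biofouling
#' signature:
#' \itemize{
#'   \item the organic-carbon mass balance is zero before onset, turns
#'     negative while organisms attach and accumulate inside the module,
#'     and flips to positive exactly once (at `detach_h`) when biomass
#'     starts detaching;
#'   \item permeability first rises slightly after the feed change (a
#'     pH-driven membrane surface-charge effect) and declines from
#'     `perm_decline_h` onward as the biofilm adds hydraulic resistance;
#'   \item the FCP stays flat and increases only from `fcp_onset_h`, the
#'     last indicator to respond, as the biofilm constricts the spacer
#'     channel.
#' }
#' Fouling-driven features (carbon imbalance, permeability decline, FCP
#' rise) are suppressed when the scenario nucleates no biofilm, so a null
#' scenario yields flat, noisy records.
#'
#' @param config a [scenario_config()].
#' @param interval_h sampling interval in hours (defaults to the scenario's
#'   frame interval).
#' @return A data frame of class `process_series` with columns `time_h`,
#'   `toc_feed`, `toc_ret` (mg/L), `vdot_feed`, `vdot_ret`, `vdot_p` (L/h),
#'   `tmp_net` (bar), `membrane_area` (m^2), `fcp` (mbar). Ground-truth
#'   phase boundaries are attached as attribute `truth` (list with
#'   `onset_h`, `carbon_sign_change_h`, `perm_decline_h`, `fcp_onset_h`).
#' @export
simulate_process_series <- function(config, interval_h = config$frame_interval_h) {
  cfg <- validate_scenario(config)
  pr <- cfg$process_params
  fouling <- cfg$nucleation_rate > 0 && cfg$onset_h < cfg$duration_h
  set.seed(cfg$seed + 2L)

  t <- seq(0, cfg$duration_h, by = interval_h)
  n <- length(t)

  ## organic-carbon mass-balance template [mg/h]
  carbon_true <- numeric(n)
  if (fouling) {
    attach <- t > cfg$onset_h & t <= pr$detach_h
    carbon_true[attach] <- -pr$carbon_amp *
      sin(pi * (t[attach] - cfg$onset_h) / (pr$detach_h - cfg$onset_h))
    detach <- t > pr$detach_h
    carbon_true[detach] <- pr$carbon_amp *
      (1 - exp(-(t[detach] - pr$detach_h) / 24))
  }

  toc_feed <- pr$toc_feed + stats::rnorm(n, sd = pr$toc_noise)
  toc_ret <- (pr$toc_feed * pr$flow_feed + carbon_true) / pr$flow_ret +
    stats::rnorm(n, sd = pr$toc_noise)

  ## permeability template [L/(m^2 h bar)]
  perm_true <- rep(pr$perm_baseline, n)
  after <- t > cfg$onset_h
  perm_true[after] <- pr$perm_baseline *
    (1 + pr$perm_rise_frac * (1 - exp(-(t[after] - cfg$onset_h) / 24)))
  if (fouling) {
    dec <- t > pr$perm_decline_h
    perm_true[dec] <- perm_true[dec] *
      exp(-pr$perm_decline_rate * (t[dec] - pr$perm_decline_h))
  }
  perm_obs <- perm_true * (1 + stats::rnorm(n, sd = pr$perm_noise))
  vdot_p <- perm_obs * pr$area_m2 * pr$tmp_net

  ## feed-channel pressure drop [mbar]
  fcp <- pr$fcp_baseline + stats::rnorm(n, sd = pr$fcp_noise)
  if (fouling) {
    up <- t > pr$fcp_onset_h
    fcp[up] <- fcp[up] + pr$fcp_rate * (t[up] - pr$fcp_onset_h)
  }

  out <- data.frame(time_h = t,
                    toc_feed = toc_feed, toc_ret = toc_ret,
                    vdot_feed = pr$flow_feed, vdot_ret = pr$flow_ret,
                    vdot_p = vdot_p,
                    tmp_net = pr$tmp_net, membrane_area = pr$area_m2,
                    fcp = fcp)
  attr(out, "truth") <- list(
    onset_h = if (fouling) cfg$onset_h else NA_real_,
    carbon_sign_change_h = if (fouling) pr$detach_h else NA_real_,
    perm_decline_h = if (fouling) pr$perm_decline_h else NA_real_,
    fcp_onset_h = if (fouling) pr$fcp_onset_h else NA_real_,
    carbon_true = carbon_true)
  class(out) <- c("process_series", "data.frame")
  out
}
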