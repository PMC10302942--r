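#' Organic-carbon mass-balance rate across the module
#'
#' Balances the organic carbon entering with the feed against the carbon
#' leaving with the retentate:
#' \deqn{\dot C = TOC_{Ret} \cdot \dot V_{Ret} - TOC_{Feed} \cdot \dot V_{Feed}
#'   \quad [\mathrm{mg/h}].}
#' A negative rate signals accumulation inside the module (the attachment
#' phase of a biofilm); a positive rate signals release of biomass into the
#' retentate (the detachment phase).
#'
#' @param toc_feed,toc_ret TOC concentrations, mg/L.
#' @param vdot_feed,vdot_ret volumetric flow rates, L/h.
#' @return Carbon rate in mg/h (vectorized); `NA` where any input is
#'   missing.
#' @export
carbon_rate <- function(toc_feed, toc_ret, vdot_feed, vdot_ret) {
  if (any(stats::na.omit(c(toc_feed, toc_ret, vdot_feed, vdot_ret)) < 0))
    stop("carbon_rate: TOC and flow values must be non-negative",
         call. = FALSE)
  toc_ret * vdot_ret - toc_feed * vdot_feed
}

#' Membrane permeability
#'
#' Permeate flow normalized by membrane area and net transmembrane
#' pressure:
#' \deqn{P_w = \frac{\dot V_p}{A \cdot TMP_{net}}
#'   \quad [\mathrm{L/(m^2\,h\,bar)}].}
#'
#' @param vdot_p permeate flow, L/h.
#' @param membrane_area membrane area, m^2 (must be positive).
#' @param tmp_net net transmembrane pressure, bar (must be positive).
#' @return Permeability (vectorized); `NA` where `vdot_p` is missing.
#' @export
permeability <- function(vdot_p, membrane_area, tmp_net) {
  if (any(stats::na.omit(membrane_area) <= 0))
    stop("permeability: membrane area must be positive", call. = FALSE)
  if (any(stats::na.omit(tmp_net) <= 0))
    stop("permeability: net transmembrane pressure must be positive ",
         "(division undefined)", call. = FALSE)
  vdot_p / (membrane_area * tmp_net)
}

#' Derive indicator series from process records
#'
#' Applies [carbon_rate()] and [permeability()] element-wise over a
#' time-sorted process table. Missing inputs yield missing outputs, never
#' silent zeros.
#'
#' @param samples data frame with columns `time_h`, `toc_feed`, `toc_ret`,
#'   `vdot_feed`, `vdot_ret`, `vdot_p`, `tmp_net`, `membrane_area`, and
#'   optionally `fcp` (passed through).
#' @return Data frame of class `derived_series` with columns `time_h`,
#'   `carbon_rate` (mg/h), `permeability` (L/(m^2 h bar)) and `fcp` when
#'   present.
#' @export
derive_series <- function(samples) {
  need <- c("time_h", "toc_feed", "toc_ret", "vdot_feed", "vdot_ret",
            "vdot_p", "tmp_net", "membrane_area")
  missing_cols <- setdiff(need, names(samples))
  if (length(missing_cols))
    stop("derive_series: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (is.unsorted(samples$time_h, strictly = FALSE))
    stop("derive_series: samples must be sorted by time_h", call. = FALSE)
  out <- data.frame(
    time_h = samples$time_h,
    carbon_rate = carbon_rate(samples$toc_feed, samples$toc_ret,
                              samples$vdot_feed, samples$vdot_ret),
    permeability = permeability(samples$vdot_p, samples$membrane_area,
                                samples$tmp_net))
  if ("fcp" %in% names(samples)) out$fcp <- samples$fcp
  class(out) <- c("derived_series", "data.frame")
  out
}
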