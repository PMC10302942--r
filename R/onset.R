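#' Detect fouling onset in an indicator time series
#'
#' Baseline-threshold rule: the mean and standard deviation of the first
#' `baseline_window` samples define a band `mean -/+ k * sd`; the onset is
#' the first time the signal leaves the band in the stated direction for at
#' least `persistence` consecutive samples. The persistence requirement
#' suppresses isolated excursions (noise spikes, a single misregistered
#' frame).
#'
#' Indicator baselines are meaningful only after the fiber-conditioning and
#' membrane-compaction period; use `start_h` to discard the earlier samples
#' (96 h is the conditioning horizon of the default scenario).
#'
#' @param time_h sample times, hours (ascending).
#' @param values signal values.
#' @param direction `"decrease"` (transmission, correlation, permeability)
#'   or `"increase"` (feed-channel pressure drop, carbon rate).
#' @param baseline_window number of leading samples forming the baseline.
#' @param k threshold width in baseline standard deviations.
#' @param persistence consecutive exceeding samples required.
#' @param start_h drop samples earlier than this time before analysis.
#' @param detrend_diurnal if `TRUE`, subtract a 24 h rolling median before
#'   detection to suppress the daily temperature cycle.
#' @param signal name of the signal, carried into the report.
#' @return Object of class `onset_report`: list with `signal`, `direction`,
#'   `onset_time_h` (`NA` if never), `baseline_mean`, `baseline_sd`,
#'   `threshold`, `k`, `persistence`.
#' @export
detect_onset <- function(time_h, values, direction = c("decrease", "increase"),
                         baseline_window = 24L, k = 3, persistence = 5L,
                         start_h = NULL, detrend_diurnal = FALSE,
                         signal = deparse(substitute(values))) {
  direction <- match.arg(direction)
  force(signal)
  keep <- !is.na(values)
  if (!is.null(start_h)) keep <- keep & time_h >= start_h
  t <- time_h[keep]; y <- values[keep]
  if (length(y) <= baseline_window + persistence)
    stop("detect_onset: series too short for baseline_window + persistence",
         call. = FALSE)
  if (detrend_diurnal) {
    dt <- stats::median(diff(t))
    w <- max(3L, round(24 / dt))
    if (w %% 2L == 0L) w <- w + 1L
    y <- y - stats::runmed(y, w)
  }
  base <- y[seq_len(baseline_window)]
  mu <- mean(base); sigma <- stats::sd(base)
  thr <- if (direction == "decrease") mu - k * sigma else mu + k * sigma
  exceed <- if (direction == "decrease") y < thr else y > thr
  exceed[seq_len(baseline_window)] <- FALSE

  onset <- NA_real_
  r <- rle(exceed)
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= persistence)
  if (length(hit)) onset <- t[ends[hit[1L]] - r$lengths[hit[1L]] + 1L]

  structure(list(signal = signal, direction = direction,
                 onset_time_h = onset, baseline_mean = mu,
                 baseline_sd = sigma, threshold = thr, k = k,
                 persistence = persistence,
                 baseline_window = baseline_window),
            class = "onset_report")
}

#' @export
print.onset_report <- function(x, ...) {
  cat(sprintf("onset report for '%s' (%s):\n", x$signal, x$direction))
  cat(sprintf("  baseline %.5g +/- %.3g (n = %d), threshold %.5g (k = %g)\n",
              x$baseline_mean, x$baseline_sd, x$baseline_window,
              x$threshold, x$k))
  if (is.na(x$onset_time_h)) cat("  no onset detected\n")
  else cat(sprintf("  onset at %g h (persistence %d samples)\n",
                   x$onset_time_h, x$persistence))
  invisible(x)
}

#' Detect a plateau (steady-state level) in a series
#'
#' Finds the earliest time from which the rolling least-squares slope over
#' `window` samples stays within `+/- slope_tol`, i.e. the signal has
#' stopped changing — e.g. a fiber whose sensing zone is completely
#' overgrown, or a coverage-saturated blue-layer correlation.
#'
#' @param time_h,values the series.
#' @param window samples per rolling fit.
#' @param slope_tol absolute slope tolerance (signal units per hour).
#' @param onset_time_h optional: only consider times at or after this
#'   (typically a detected onset).
#' @return Plateau start time in hours, or `NA` when the series never
#'   flattens.
#' @export
detect_plateau <- function(time_h, values, window = 24L, slope_tol,
                           onset_time_h = NULL) {
  keep <- !is.na(values)
  t <- time_h[keep]; y <- values[keep]
  n <- length(y)
  if (n <= window) return(NA_real_)
  from <- 1L
  if (!is.null(onset_time_h) && !is.na(onset_time_h))
    from <- which(t >= onset_time_h)[1L]
  if (is.na(from)) return(NA_real_)
  for (j in from:(n - window + 1L)) {
    ti <- t[j:(j + window - 1L)]
    yi <- y[j:(j + window - 1L)]
    slope <- stats::cov(ti, yi) / stats::var(ti)
    if (is.finite(slope) && abs(slope) <= slope_tol) return(t[j])
  }
  NA_real_
}

#' Evaluate cleaning-in-place recovery
#'
#' For each cleaning event, compares the signal level just before and just
#' after the event with the pre-fouling baseline and reports the fraction
#' of the cumulative signal loss that the cleaning regained:
#' \deqn{recovery = \frac{post - pre}{baseline - pre},}
#' with `pre` and `post` medians over `flank` samples on either side of the
#' event and `baseline` the median of the first `baseline_window` samples.
#' The recovery is clamped to `[0, 1]`; an event with no signal change
#' scores 0, full return to baseline scores 1. A declining recovery across
#' successive cleanings indicates a maturing, EPS-stabilized biofilm.
#'
#' @param time_h,values the (sensor-fiber) series.
#' @param cip_times event times, hours; must lie inside the series range.
#' @param flank samples flanking each event used for the medians.
#' @param baseline_window leading samples defining the clean baseline.
#' @return Data frame of class `cip_report`: `time_h`, `pre`, `post`,
#'   `recovery`, ordered by time.
#' @export
evaluate_cip <- function(time_h, values, cip_times, flank = 5L,
                         baseline_window = 24L) {
  keep <- !is.na(values)
  t <- time_h[keep]; y <- values[keep]
  baseline <- stats::median(y[seq_len(min(baseline_window, length(y)))])
  cip_times <- sort(cip_times)
  out <- data.frame(time_h = cip_times, pre = NA_real_, post = NA_real_,
                    recovery = NA_real_)
  for (i in seq_along(cip_times)) {
    ev <- cip_times[i]
    if (ev <= min(t) || ev > max(t))
      stop("evaluate_cip: event at ", ev, " h lies outside the series range",
           call. = FALSE)
    before <- which(t < ev)
    after <- which(t >= ev)
    pre <- stats::median(y[utils::tail(before, flank)])
    post <- stats::median(y[utils::head(after, flank)])
    loss <- baseline - pre
    rec <- if (abs(loss) < 1e-12) 0 else (post - pre) / loss
    out$pre[i] <- pre; out$post[i] <- post
    out$recovery[i] <- min(max(rec, 0), 1)
  }
  class(out) <- c("cip_report", "data.frame")
  out
}
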