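## Template-matching registration: every sensed frame is aligned to a
## reference frame by locating a user-selected feature region via normalized
## cross-correlation, then cropping so the feature occupies the same
## coordinates in every output frame. The motion model is pure integer
## translation.

#' Template region of interest
#'
#' A rectangular feature region on the reference frame, selected by the
#' user (typically a distinctive piece of the spacer mesh). Coordinates are
#' 0-based, row-major; the region is the half-open block
#' `[row0, row0+height) x [col0, col0+width)`.
#'
#' @param row0,col0 top-left corner, 0-based pixels.
#' @param height,width region size in pixels; at least 8 each.
#' @return An object of class `template_roi`.
#' @export
template_roi <- function(row0, col0, height, width) {
  if (height < 8 || width < 8)
    stop("template_roi: degenerate template (height and width must be >= 8)",
         call. = FALSE)
  if (row0 < 0 || col0 < 0)
    stop("template_roi: row0/col0 must be >= 0", call. = FALSE)
  structure(list(row0 = as.integer(row0), col0 = as.integer(col0),
                 height = as.integer(height), width = as.integer(width)),
            class = "template_roi")
}

#' Extract the template from a reference image
#'
#' @param reference grayscale matrix (see [to_grayscale()]).
#' @param roi a [template_roi()]; must lie inside the reference.
#' @return The cropped template matrix. A constant (zero-variance) region is
#'   rejected, since normalized cross-correlation is undefined for it.
#' @export
extract_template <- function(reference, roi) {
  stopifnot(inherits(roi, "template_roi"))
  H <- nrow(reference); W <- ncol(reference)
  if (roi$row0 + roi$height > H || roi$col0 + roi$width > W)
    stop("extract_template: roi exceeds reference bounds", call. = FALSE)
  tpl <- reference[(roi$row0 + 1L):(roi$row0 + roi$height),
                   (roi$col0 + 1L):(roi$col0 + roi$width), drop = FALSE]
  if (stats::var(as.vector(tpl)) <= 0)
    stop("extract_template: featureless template (zero variance); ",
         "normalized cross-correlation is undefined", call. = FALSE)
  tpl
}

## Sliding-window sums over all valid h x w placements, via a summed-area
## table. Returns an (H-h+1) x (W-w+1) matrix.
window_sums <- function(m, h, w) {
  H <- nrow(m); W <- ncol(m)
  S <- matrix(0, H + 1L, W + 1L)
  S[-1L, -1L] <- t(apply(apply(m, 2, cumsum), 1, cumsum))
  u <- 1L:(H - h + 1L); v <- 1L:(W - w + 1L)
  S[u + h, v + w, drop = FALSE] - S[u, v + w, drop = FALSE] -
    S[u + h, v, drop = FALSE] + S[u, v, drop = FALSE]
}

## Linear cross-correlation of image f with kernel k over valid placements,
## computed by 2-D FFT (zero padding to composite sizes). Exact up to
## double-precision rounding.
xcorr_valid <- function(f, k) {
  H <- nrow(f); W <- ncol(f); h <- nrow(k); w <- ncol(k)
  P1 <- stats::nextn(H); P2 <- stats::nextn(W)
  fp <- matrix(0, P1, P2); fp[1:H, 1:W] <- f
  kp <- matrix(0, P1, P2); kp[1:h, 1:w] <- k
  cc <- Re(stats::fft(stats::fft(fp) * Conj(stats::fft(kp)),
                      inverse = TRUE)) / (P1 * P2)
  cc[1:(H - h + 1L), 1:(W - w + 1L), drop = FALSE]
}

#' Normalized cross-correlation map
#'
#' Slides the template across the sensed image and scores every fully
#' interior ("valid") placement with the Pearson correlation coefficient
#' between the template and the image window under it:
#' \deqn{s(u,v) = \frac{\sum (f_{uv} - \bar f_{uv})(t - \bar t)}
#'   {\sqrt{\sum (f_{uv} - \bar f_{uv})^2 \sum (t - \bar t)^2}}.}
#' The sliding sums are evaluated with a summed-area table and an FFT-based
#' cross-correlation, which is algebraically identical to the direct
#' per-window computation. Windows with (numerically) zero variance score
#' `NA` and are excluded from peak search.
#'
#' @param template grayscale matrix, strictly smaller than `sensed` in both
#'   dimensions, with positive variance.
#' @param sensed grayscale matrix.
#' @return Matrix of class `ncc_map`, dimensions
#'   `(H - h + 1) x (W - w + 1)`; entry `[u, v]` scores the placement whose
#'   top-left corner is at 0-based `(u - 1, v - 1)`.
#' @export
ncc_map <- function(template, sensed) {
  h <- nrow(template); w <- ncol(template)
  H <- nrow(sensed); W <- ncol(sensed)
  if (h >= H || w >= W)
    stop("ncc_map: template must be strictly smaller than the sensed image ",
         "in both dimensions", call. = FALSE)
  n <- as.numeric(h) * w
  tc <- template - mean(template)
  den_t <- sum(tc^2)
  if (den_t <= 0)
    stop("ncc_map: featureless template (zero variance)", call. = FALSE)
  num <- xcorr_valid(sensed, tc)
  s1 <- window_sums(sensed, h, w)
  s2 <- window_sums(sensed^2, h, w)
  den_f <- pmax(s2 - s1^2 / n, 0)
  ## guard: windows whose variance is at the level of summation round-off
  ## are undefined, not evidence of (anti-)match
  tol <- n * max(abs(sensed))^2 * 1e-12 + 1e-300
  undef <- den_f <= tol
  den_f[undef] <- NA_real_
  scores <- num / sqrt(den_f * den_t)
  scores <- pmin(pmax(scores, -1), 1)
  structure(scores, class = c("ncc_map", "matrix"))
}

#' Locate the correlation peak
#'
#' Returns the placement with the maximal defined score; ties are broken by
#' the smallest row, then the smallest column. When `roi` is supplied, the
#' peak is expressed as a translation relative to the template's position in
#' the reference frame (how far the feature moved in the sensed image).
#'
#' @param map an [ncc_map()].
#' @param roi optional [template_roi()] giving the template's position in
#'   the reference frame. If the map was computed on a sub-window of the
#'   sensed image, give the window's top-left corner via `origin`.
#' @param origin 0-based `(row, col)` of the map's placement `(0, 0)` in
#'   the sensed frame (default `c(0, 0)`).
#' @return List of class `ncc_offset` with integer `drow`, `dcol` and
#'   `peak_score`.
#' @export
locate_peak <- function(map, roi = NULL, origin = c(0L, 0L)) {
  if (all(is.na(map)))
    stop("locate_peak: all placements undefined", call. = FALSE)
  mx <- max(map, na.rm = TRUE)
  idx <- which(!is.na(map) & map == mx, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  prow <- idx[1L, 1L] - 1L + origin[1L]
  pcol <- idx[1L, 2L] - 1L + origin[2L]
  drow <- prow; dcol <- pcol
  if (!is.null(roi)) {
    drow <- prow - roi$row0
    dcol <- pcol - roi$col0
  }
  structure(list(drow = as.integer(drow), dcol = as.integer(dcol),
                 peak_score = mx),
            class = "ncc_offset")
}

#' @export
print.ncc_offset <- function(x, ...) {
  cat(sprintf("offset (drow, dcol) = (%d, %d), peak NCC = %.4f\n",
              x$drow, x$dcol, x$peak_score))
  invisible(x)
}

#' Crop a frame into the common registered coordinate system
#'
#' Removes margins `(Mr, Mc)` from the frame, positioning the crop so the
#' estimated translation is compensated: the selected features occupy
#' identical coordinates in every registered frame. With the default
#' margins `(127, 175)`, a 2064 x 3088 input yields a 1937 x 2913 output.
#' The crop anchor for a zero offset is `floor(margin / 2)`; offsets beyond
#' `floor(margin / 2)` exceed the room for movement and are rejected.
#'
#' @param frame an [image_frame()].
#' @param offset an [ncc_offset()] (or list with `drow`, `dcol`) estimated
#'   on the grayscale pair; applied here to the colour frame.
#' @param margins integer `(Mr, Mc)` rows/columns removed in total.
#' @return A `registered_frame` (an [image_frame()] with the applied offset
#'   recorded in `$offset`).
#' @export
register_frame <- function(frame, offset, margins = c(127L, 175L)) {
  stopifnot(inherits(frame, "image_frame"))
  H <- dim(frame$pixels)[1L]; W <- dim(frame$pixels)[2L]
  Mr <- as.integer(margins[1L]); Mc <- as.integer(margins[2L])
  if (Mr <= 0L || Mc <= 0L || Mr >= H || Mc >= W)
    stop("register_frame: margins must be positive and smaller than the frame",
         call. = FALSE)
  ar <- Mr %/% 2L; ac <- Mc %/% 2L
  if (abs(offset$drow) > ar || abs(offset$dcol) > ac)
    stop(sprintf(
      "register_frame: excessive motion in frame '%s' (offset %d, %d exceeds margin room %d, %d)",
      frame$source_id, offset$drow, offset$dcol, ar, ac), call. = FALSE)
  rows <- (ar + offset$drow + 1L):(ar + offset$drow + H - Mr)
  cols <- (ac + offset$dcol + 1L):(ac + offset$dcol + W - Mc)
  out <- frame
  out$pixels <- frame$pixels[rows, cols, , drop = FALSE]
  out$offset <- offset
  class(out) <- c("registered_frame", "image_frame")
  out
}

## Estimate one frame's offset by NCC within a search window around the
## template's reference position. Only the window is converted to
## grayscale, so matching cost is independent of the frame size.
estimate_offset <- function(frame, template, roi, search_margin) {
  d <- dim(frame$pixels)
  r0 <- max(0L, roi$row0 - search_margin[1L])
  c0 <- max(0L, roi$col0 - search_margin[2L])
  r1 <- min(d[1L], roi$row0 + roi$height + search_margin[1L])
  c1 <- min(d[2L], roi$col0 + roi$width + search_margin[2L])
  p <- frame$pixels[(r0 + 1L):r1, (c0 + 1L):c1, , drop = FALSE]
  window <- (0.2989 * p[, , 1L] + 0.5870 * p[, , 2L] + 0.1140 * p[, , 3L]) / 255
  map <- ncc_map(template, window)
  locate_peak(map, roi = roi, origin = c(r0, c0))
}

#' Register an image time series
#'
#' Full registration pipeline: the template is extracted from the reference
#' frame (converted to grayscale), each sensed frame is matched by
#' normalized cross-correlation within a search window around the
#' template's reference position, and the estimated translation is applied
#' to the colour frame by [register_frame()]. The reference frame itself is
#' registered with offset `(0, 0)`.
#'
#' @param frames list of [image_frame()] objects, all with identical
#'   dimensions.
#' @param reference_index 1-based index of the reference frame.
#' @param roi a [template_roi()] on the reference frame.
#' @param margins `(Mr, Mc)` crop margins, see [register_frame()].
#' @param search_margin how far (pixels per axis) the template is searched
#'   around its reference position; defaults to `floor(margins / 2)`, the
#'   largest representable motion.
#' @param on_failure `"abort"` (default) stops on a frame whose estimated
#'   motion exceeds the margin room; `"drop"` skips it with a warning.
#' @return List of class `registered_series`: `frames` (registered frames),
#'   `offsets` (data frame `time_h, drow, dcol, peak_score`), `roi`,
#'   `margins`, `dropped` (character vector of skipped frame ids).
#' @export
register_series <- function(frames, reference_index = 1L, roi,
                            margins = c(127L, 175L), search_margin = NULL,
                            on_failure = c("abort", "drop")) {
  on_failure <- match.arg(on_failure)
  if (is.null(search_margin)) search_margin <- margins %/% 2L
  if (length(search_margin) == 1L) search_margin <- rep(search_margin, 2L)
  ref <- frames[[reference_index]]
  dims <- dim(ref$pixels)
  template <- extract_template(to_grayscale(ref), roi)

  out_frames <- list()
  offs <- data.frame(time_h = numeric(0), drow = integer(0),
                     dcol = integer(0), peak_score = numeric(0))
  dropped <- character(0)
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    if (!identical(dim(fr$pixels), dims))
      stop("register_series: frame '", fr$source_id,
           "' has different dimensions", call. = FALSE)
    off <- if (i == reference_index)
      structure(list(drow = 0L, dcol = 0L, peak_score = 1),
                class = "ncc_offset")
    else
      estimate_offset(fr, template, roi, search_margin)
    reg <- tryCatch(register_frame(fr, off, margins), error = function(e) e)
    if (inherits(reg, "error")) {
      if (on_failure == "abort") stop(reg)
      warning("register_series: dropping frame '", fr$source_id, "': ",
              conditionMessage(reg), call. = FALSE)
      dropped <- c(dropped, fr$source_id)
      next
    }
    out_frames[[length(out_frames) + 1L]] <- reg
    offs <- rbind(offs, data.frame(time_h = fr$time_h, drow = off$drow,
                                   dcol = off$dcol,
                                   peak_score = off$peak_score))
  }
  structure(list(frames = out_frames, offsets = offs, roi = roi,
                 margins = margins, dropped = dropped),
            class = "registered_series")
}

#' @export
print.registered_series <- function(x, ...) {
  d <- if (length(x$frames)) dim(x$frames[[1L]]$pixels) else c(NA, NA, NA)
  cat(sprintf("registered series: %d frames of %s x %s x 3\n",
              length(x$frames), d[1], d[2]))
  if (length(x$dropped))
    cat("  dropped:", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' Register a frame series from a manifest, streaming frame by frame
#'
#' Disk-backed variant of [register_series()] for long series that should
#' not be held in memory at once. Frames are loaded, matched and cropped one
#' at a time; registered frames are written to `out_dir` (when given) as
#' 8-bit RGB TIFFs together with `offsets.csv`.
#'
#' @inheritParams register_series
#' @param manifest path to a `manifest.csv` (see [read_manifest()]).
#' @param out_dir optional output directory for registered TIFFs; when
#'   `NULL`, registered frames are returned in memory.
#' @return A `registered_series` (with `frames = NULL` when `out_dir` is
#'   used; `dims` holds the registered frame dimensions).
#' @export
register_manifest <- function(manifest, roi, reference_index = 1L,
                              margins = c(127L, 175L), search_margin = NULL,
                              on_failure = c("abort", "drop"),
                              out_dir = NULL) {
  on_failure <- match.arg(on_failure)
  if (is.null(search_margin)) search_margin <- margins %/% 2L
  if (length(search_margin) == 1L) search_margin <- rep(search_margin, 2L)
  m <- read_manifest(manifest)
  ref <- load_frame(m$filename[reference_index], m$time_h[reference_index])
  dims <- dim(ref$pixels)
  template <- extract_template(to_grayscale(ref), roi)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)

  keep <- is.null(out_dir)
  out_frames <- if (keep) list() else NULL
  offs <- NULL
  dropped <- character(0)
  reg_dims <- NULL
  for (i in seq_len(nrow(m))) {
    fr <- if (i == reference_index) ref
          else load_frame(m$filename[i], m$time_h[i])
    off <- if (i == reference_index)
      structure(list(drow = 0L, dcol = 0L, peak_score = 1),
                class = "ncc_offset")
    else
      estimate_offset(fr, template, roi, search_margin)
    reg <- tryCatch(register_frame(fr, off, margins), error = function(e) e)
    if (inherits(reg, "error")) {
      if (on_failure == "abort") stop(reg)
      warning("register_manifest: dropping frame '", fr$source_id, "': ",
              conditionMessage(reg), call. = FALSE)
      dropped <- c(dropped, fr$source_id)
      next
    }
    reg_dims <- dim(reg$pixels)
    if (keep) out_frames[[length(out_frames) + 1L]] <- reg
    else write_frame(reg, file.path(out_dir, basename(fr$source_id)))
    offs <- rbind(offs, data.frame(time_h = fr$time_h, drow = off$drow,
                                   dcol = off$dcol,
                                   peak_score = off$peak_score))
  }
  if (!is.null(out_dir))
    utils::write.csv(offs, file.path(out_dir, "offsets.csv"),
                     row.names = FALSE)
  structure(list(frames = out_frames, offsets = offs, roi = roi,
                 margins = margins, dropped = dropped, dims = reg_dims),
            class = "registered_series")
}
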