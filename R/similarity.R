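#' Split a registered frame into its R, G and B layers
#'
#' @param frame an [image_frame()] (registered or raw).
#' @return Named list of three matrices `r`, `g`, `b`; intensities are
#'   preserved without rescaling.
#' @export
split_channels <- function(frame) {
  stopifnot(inherits(frame, "image_frame"))
  p <- frame$pixels
  list(r = p[, , 1L], g = p[, , 2L], b = p[, , 3L])
}

#' Two-dimensional Pearson correlation between two images
#'
#' The biofouling indicator: the Pearson correlation coefficient of two
#' equally sized image matrices,
#' \deqn{r = \frac{\sum_m \sum_n (A_{mn} - \bar A)(B_{mn} - \bar B)}
#'   {\sqrt{\left(\sum_m \sum_n (A_{mn} - \bar A)^2\right)
#'          \left(\sum_m \sum_n (B_{mn} - \bar B)^2\right)}},}
#' i.e. the ordinary Pearson coefficient of the flattened pixel vectors.
#' Centered sums are accumulated in double precision and the result is
#' clamped to `[-1, 1]`. Pearson r is invariant under positive affine
#' intensity changes, so uniform illumination drift does not register as
#' dissimilarity.
#'
#' @param A,B numeric matrices of identical dimensions.
#' @return The coefficient in `[-1, 1]`, or `NA` when either matrix has
#'   zero variance (a constant frame is an instrument fault, not evidence of
#'   similarity; the missing value is distinct from any numeric
#'   coefficient).
#' @export
pearson2d <- function(A, B) {
  if (!all(dim(A) == dim(B)))
    stop("pearson2d: matrices must have identical dimensions", call. = FALSE)
  Ac <- A - mean(A)
  Bc <- B - mean(B)
  da <- sum(Ac * Ac)
  db <- sum(Bc * Bc)
  if (da <= 0 || db <= 0) return(NA_real_)
  r <- sum(Ac * Bc) / sqrt(da * db)
  min(max(r, -1), 1)
}

#' Per-layer similarity time series against a reference frame
#'
#' Computes [pearson2d()] between each registered frame and the reference
#' frame, separately for the R, G and B layers. The declining blue-layer
#' coefficient is the image-analysis biofouling indicator: a biofilm shifts
#' the membrane surface from white to brown, attenuating blue most and red
#' least.
#'
#' @param registered a `registered_series` (from [register_series()]) or a
#'   plain list of frames with identical dimensions.
#' @param reference_index 1-based index of the reference frame (default the
#'   first, i.e. the clean initial image).
#' @return Data frame of class `similarity_series` with columns `time_h`,
#'   `r_red`, `r_green`, `r_blue`, `status` (`"ok"` or a reason for an
#'   undefined entry), sorted by time; attribute `reference_time_h`.
#' @export
similarity_series <- function(registered, reference_index = 1L) {
  frames <- if (inherits(registered, "registered_series")) registered$frames
            else registered
  if (length(frames) < 2L)
    stop("similarity_series: need at least two frames", call. = FALSE)
  dims <- dim(frames[[1L]]$pixels)
  ref <- split_channels(frames[[reference_index]])

  ## reference layers are centered once; for sum(Ac) = 0 the cross sum
  ## against B needs no centering of B, halving the per-frame work while
  ## remaining algebraically identical to pearson2d()
  refc <- lapply(ref, function(A) A - mean(A))
  refd <- vapply(refc, function(Ac) sum(Ac * Ac), numeric(1))
  p2d_ref <- function(Ac, da, B) {
    if (da <= 0) return(NA_real_)
    B <- as.numeric(B)   # integer sums of squares would overflow
    nb <- length(B)
    sb <- sum(B)
    db <- sum(B * B) - sb * sb / nb
    if (db <= 0) return(NA_real_)
    min(max(sum(Ac * B) / sqrt(da * db), -1), 1)
  }

  n <- length(frames)
  out <- data.frame(time_h = vapply(frames, function(f) f$time_h, numeric(1)),
                    r_red = NA_real_, r_green = NA_real_, r_blue = NA_real_,
                    status = "ok", stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    fr <- frames[[i]]
    if (!identical(dim(fr$pixels), dims))
      stop("similarity_series: frame '", fr$source_id,
           "' has different dimensions", call. = FALSE)
    ch <- split_channels(fr)
    r <- c(p2d_ref(refc$r, refd[["r"]], ch$r),
           p2d_ref(refc$g, refd[["g"]], ch$g),
           p2d_ref(refc$b, refd[["b"]], ch$b))
    out[i, c("r_red", "r_green", "r_blue")] <- r
    if (anyNA(r))
      out$status[i] <- paste0("undefined: zero variance in layer(s) ",
                              paste(c("R", "G", "B")[is.na(r)], collapse = ","))
  }
  out <- out[order(out$time_h), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "reference_time_h") <- frames[[reference_index]]$time_h
  class(out) <- c("similarity_series", "data.frame")
  out
}

#' @export
plot.similarity_series <- function(x, ...) {
  graphics::matplot(x$time_h, cbind(x$r_red, x$r_green, x$r_blue),
                    type = "l", lty = 1,
                    col = c("firebrick", "forestgreen", "royalblue"),
                    xlab = "time [h]", ylab = "Pearson r vs. reference", ...)
  graphics::legend("bottomleft", legend = c("red layer", "green layer",
                                            "blue layer"),
                   col = c("firebrick", "forestgreen", "royalblue"),
                   lty = 1, bty = "n")
  invisible(x)
}
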