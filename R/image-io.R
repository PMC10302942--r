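#' Construct an RGB image frame
#'
#' Lightweight container for one membrane-surface photograph: an
#' `H x W x 3` array of 8-bit intensities (channel order R, G, B) with its
#' acquisition time.
#'
#' @param pixels integer array `H x W x 3` with values in `[0, 255]`.
#' @param time_h acquisition time in hours.
#' @param source_id character label (typically the file name).
#' @return An object of class `image_frame`.
#' @export
image_frame <- function(pixels, time_h, source_id = "<memory>") {
  d <- dim(pixels)
  if (length(d) != 3L || d[3] != 3L)
    stop("image_frame: pixels must be an H x W x 3 array (R,G,B)",
         call. = FALSE)
  if (d[1] <= 0L || d[2] <= 0L)
    stop("image_frame: non-positive dimensions", call. = FALSE)
  rng <- range(pixels)
  if (!all(is.finite(rng)) || rng[1] < 0 || rng[2] > 255)
    stop("image_frame: intensities must lie in [0, 255]", call. = FALSE)
  structure(list(pixels = pixels, time_h = time_h, source_id = source_id),
            class = "image_frame")
}

#' @export
print.image_frame <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("image_frame %d x %d x 3 (8-bit RGB), t = %g h [%s]\n",
              d[1], d[2], x$time_h, x$source_id))
  invisible(x)
}

#' @export
dim.image_frame <- function(x) dim(x$pixels)

#' Read a frame manifest
#'
#' Reads a CSV manifest mapping acquisition times to frame files and returns
#' it sorted by time. Frame paths are resolved relative to the manifest's
#' directory.
#'
#' @param path path to a CSV with columns `time_h` and `filename`.
#' @return Data frame with columns `time_h` (ascending) and `filename`
#'   (absolute or manifest-relative paths).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_h", "filename")
  missing_cols <- setdiff(need, names(m))
  if (length(missing_cols))
    stop("manifest ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  dup <- duplicated(m$time_h)
  if (any(dup))
    stop("manifest has duplicate time_h: ",
         paste(unique(m$time_h[dup]), collapse = ", "),
         " (rows ", paste(which(dup), collapse = ", "), ")", call. = FALSE)
  m <- m[order(m$time_h), need, drop = FALSE]
  rownames(m) <- NULL
  m$filename <- ifelse(grepl("^(/|[A-Za-z]:)", m$filename), m$filename,
                       file.path(dirname(path), m$filename))
  m
}

#' Load an 8-bit RGB TIFF frame
#'
#' Anything other than an 8-bit, 3-channel TIFF is rejected rather than
#' silently converted, so a mis-exported camera file cannot corrupt the
#' similarity series.
#'
#' @param path TIFF file path.
#' @param time_h acquisition time to stamp on the frame.
#' @return An [image_frame()].
#' @export
load_frame <- function(path, time_h = NA_real_) {
  if (!file.exists(path)) stop("frame file not found: ", path, call. = FALSE)
  a <- tiff::readTIFF(path, info = TRUE)
  bps <- attr(a, "bits.per.sample")
  if (!is.null(bps) && any(bps != 8L))
    stop("frame ", path, ": expected 8 bits per sample, found ",
         paste(unique(bps), collapse = "/"), call. = FALSE)
  d <- dim(a)
  if (length(d) != 3L || d[3] != 3L)
    stop("frame ", path, ": expected an H x W x 3 RGB image, found ",
         paste(d, collapse = " x "), call. = FALSE)
  ## readTIFF scales 8-bit samples to [0,1]; restore the native levels
  a <- as.integer(round(a * 255))
  dim(a) <- d
  image_frame(a, time_h = time_h, source_id = basename(path))
}

#' Write a frame as an uncompressed 8-bit RGB TIFF
#'
#' @param frame an [image_frame()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_frame <- function(frame, path) {
  stopifnot(inherits(frame, "image_frame"))
  tiff::writeTIFF(frame$pixels / 255, path, bits.per.sample = 8L,
                  compression = "none")
  invisible(path)
}

#' Convert an RGB frame to grayscale
#'
#' Uses the ITU-R BT.601 luma weights and rescales to `[0, 1]`:
#' `gray = (0.2989 R + 0.5870 G + 0.1140 B) / 255`.
#'
#' @param frame an [image_frame()].
#' @return Numeric matrix `H x W` in `[0, 1]`.
#' @export
to_grayscale <- function(frame) {
  stopifnot(inherits(frame, "image_frame"))
  p <- frame$pixels
  (0.2989 * p[, , 1] + 0.5870 * p[, , 2] + 0.1140 * p[, , 3]) / 255
}
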