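## Synthetic membrane-surface image simulator.
##
## The scene lives on a canvas larger than the frame by the jitter margin on
## every side; camera motion is emulated by cropping the canvas at an integer
## offset, so the planted translation is exact ground truth for the
## registration stage.

## Bilinear upsampling of a coarse matrix to H x W via interpolation
## matrices (two dense matrix products; fast for coarse grids).
upsample_bilinear <- function(m, H, W) {
  interp_mat <- function(n_out, n_in) {
    x <- seq(1, n_in, length.out = n_out)
    lo <- pmin(floor(x), n_in - 1L)
    w <- x - lo
    R <- matrix(0, n_out, n_in)
    R[cbind(seq_len(n_out), lo)] <- 1 - w
    R[cbind(seq_len(n_out), lo + 1L)] <- w
    R
  }
  interp_mat(H, nrow(m)) %*% m %*% t(interp_mat(W, ncol(m)))
}

## Clean membrane texture on the canvas: a bright membrane sheet with
## low-frequency mottle plus the periodic diamond mesh of the feed spacer.
## The mottle makes every local window feature-rich enough for template
## matching to have a unique global optimum; the spacer provides the strong
## repeating structure a real feed-channel photograph shows.
clean_texture <- function(Hc, Wc, scale = 1) {
  cell <- max(8L, as.integer(round(32 * scale)))
  gh <- max(4L, ceiling(Hc / cell) + 1L)
  gw <- max(4L, ceiling(Wc / cell) + 1L)
  mottle <- upsample_bilinear(matrix(stats::rnorm(gh * gw), gh, gw), Hc, Wc)
  mottle <- mottle * 12

  p <- max(8L, as.integer(round(42 * scale)))   # spacer mesh period, px
  lw <- max(2L, round(p / 8))                   # filament line width, px
  ri <- seq_len(Hc)
  cj <- seq_len(Wc)
  d1 <- outer(ri, cj, "+") %% p
  d2 <- outer(ri, -cj, "+") %% p
  spacer <- (d1 < lw) | (d2 < lw)
  tex <- 205 + mottle
  tex[spacer] <- tex[spacer] - 55
  tex
}

## Biofilm patch set shared by the image, POF and process simulators:
## patches nucleate at Poisson times after onset, uniformly over the canvas,
## and their radii grow linearly. Drawn first from the root seed so every
## simulator sees the same biofilm.
sample_patches <- function(cfg, Hc, Wc) {
  set.seed(cfg$seed)
  window_h <- max(0, cfg$duration_h - cfg$onset_h)
  n <- if (cfg$nucleation_rate > 0 && window_h > 0)
    stats::rpois(1L, cfg$nucleation_rate * window_h) else 0L
  if (n == 0L)
    return(data.frame(t0 = numeric(0), row = numeric(0), col = numeric(0)))
  data.frame(t0 = sort(cfg$onset_h + stats::runif(n, 0, window_h)),
             row = stats::runif(n, 1, Hc),
             col = stats::runif(n, 1, Wc))
}

## Survival weight of biomass nucleated at t0, observed at t: every CIP
## event in (t0, t] removes fraction `efficacy` of what is present.
cip_weight <- function(cfg, t0, t) {
  w <- 1
  for (ev in cfg$cip_events)
    if (ev$time_h > t0 && ev$time_h <= t) w <- w * (1 - ev$efficacy)
  w
}

## Per-pixel biofilm coverage on the canvas at time t: occupancy is the
## CIP-weighted sum of patch disks, mapped through 1 - exp(-occupancy) so
## overlapping patches saturate instead of stacking.
coverage_canvas <- function(cfg, patches, Hc, Wc, t) {
  occ <- matrix(0, Hc, Wc)
  active <- which(patches$t0 <= t)
  for (i in active) {
    r <- cfg$patch_growth_rate * (t - patches$t0[i])
    if (r < 0.5) next
    w <- cip_weight(cfg, patches$t0[i], t)
    if (w <= 0) next
    r0 <- max(1L, floor(patches$row[i] - r)); r1 <- min(Hc, ceiling(patches$row[i] + r))
    c0 <- max(1L, floor(patches$col[i] - r)); c1 <- min(Wc, ceiling(patches$col[i] + r))
    if (r0 > r1 || c0 > c1) next
    dr2 <- (r0:r1 - patches$row[i])^2
    dc2 <- (c0:c1 - patches$col[i])^2
    disk <- outer(dr2, dc2, "+") <= r^2
    occ[r0:r1, c0:c1] <- occ[r0:r1, c0:c1] + w * disk
  }
  1 - exp(-occ)
}

## Expected area-fraction analogue of the canvas coverage, used for the
## fiber-transmission and process models (same patches, scalar summary).
coverage_fraction_scalar <- function(cfg, patches, Hc, Wc, t) {
  active <- which(patches$t0 <= t)
  if (!length(active)) return(0)
  occ <- 0
  for (i in active) {
    r <- cfg$patch_growth_rate * (t - patches$t0[i])
    occ <- occ + cip_weight(cfg, patches$t0[i], t) * pi * r^2 / (Hc * Wc)
  }
  1 - exp(-occ)
}

#' Biofilm coverage field for one time point
#'
#' Evaluates the latent per-pixel coverage (in `[0, 1]`) of the simulated
#' biofilm at time `time_h`, cropped to the frame of an un-jittered camera.
#'
#' @param config a [scenario_config()].
#' @param time_h time in hours.
#' @return Numeric matrix `frame_height x frame_width` with values in
#'   `[0, 1]`.
#' @export
coverage_field <- function(config, time_h) {
  J <- config$jitter_max
  Hc <- config$frame_height + 2L * J
  Wc <- config$frame_width + 2L * J
  patches <- sample_patches(config, Hc, Wc)
  cov <- coverage_canvas(config, patches, Hc, Wc, time_h)
  cov[(J + 1L):(J + config$frame_height), (J + 1L):(J + config$frame_width),
      drop = FALSE]
}

#' Simulate a membrane-surface image time series
#'
#' Generates 8-bit RGB photographs of a simulated membrane sheet and feed
#' spacer under accelerated biofouling. Frame 0 is the clean reference.
#' Each later frame carries a planted integer camera translation (uniform in
#' `[-jitter_max, jitter_max]` per axis), multiplicative illumination drift,
#' and i.i.d. Gaussian pixel noise. After the fouling onset, biofilm patches
#' darken the scene channel-wise: the blue layer is attenuated most and the
#' red layer least, reproducing the white-to-brown colour shift of a growing
#' biofilm.
#'
#' @param config a [scenario_config()].
#' @param out_dir optional directory; when given, frames are written as
#'   uncompressed 8-bit RGB TIFFs (`frame_00000.tiff`, ...) together with
#'   `manifest.csv` (columns `time_h,filename`) and `truth.json` (planted
#'   offsets, onset, per-frame coverage), and pixel data are not kept in
#'   memory.
#' @return A list of class `membrane_image_series` with elements
#'   \describe{
#'     \item{frames}{list of [image_frame()] objects (`NULL` entries when
#'       `out_dir` is used),}
#'     \item{planted_offsets}{data frame `time_h, drow, dcol` — ground-truth
#'       content translation of each frame relative to the reference,}
#'     \item{coverage}{data frame `time_h, coverage_frac` — mean biofilm
#'       coverage of the visible frame,}
#'     \item{manifest}{path of the manifest when `out_dir` is used,}
#'     \item{config}{the scenario.}
#'   }
#' @export
simulate_image_series <- function(config, out_dir = NULL) {
  cfg <- validate_scenario(config)
  J <- cfg$jitter_max
  H <- cfg$frame_height; W <- cfg$frame_width
  Hc <- H + 2L * J; Wc <- W + 2L * J
  scale <- H / 2064

  patches <- sample_patches(cfg, Hc, Wc)   # seeds the stream with cfg$seed
  tex <- clean_texture(Hc, Wc, scale)
  times <- scenario_times(cfg)
  n <- length(times)

  drow <- integer(n); dcol <- integer(n)
  if (n > 1L && J > 0L) {
    drow[-1L] <- sample.int(2L * J + 1L, n - 1L, replace = TRUE) - J - 1L
    dcol[-1L] <- sample.int(2L * J + 1L, n - 1L, replace = TRUE) - J - 1L
  }

  att <- cfg$channel_attenuation
  frames <- vector("list", n)
  cov_frac <- numeric(n)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  filenames <- sprintf("frame_%05d.tiff", seq_len(n) - 1L)

  for (i in seq_len(n)) {
    t <- times[i]
    rows <- (J - drow[i] + 1L):(J + H - drow[i])
    cols <- (J - dcol[i] + 1L):(J + W - dcol[i])
    tex_i <- tex[rows, cols, drop = FALSE]
    has_cov <- any(patches$t0 <= t)
    if (has_cov) {
      cov <- coverage_canvas(cfg, patches, Hc, Wc, t)
      cov_i <- cov[rows, cols, drop = FALSE]
      cov_frac[i] <- mean(cov_i)
    } else {
      cov_i <- NULL
      cov_frac[i] <- 0
    }
    illum <- 1 + cfg$illumination_drift * t / 100
    if (is.null(cov_i)) {
      base <- tex_i * illum
      pix <- c(base, base, base)
    } else {
      tc <- tex_i * cov_i
      pix <- c(tex_i - att[[1L]] * tc, tex_i - att[[2L]] * tc,
               tex_i - att[[3L]] * tc) * illum
    }
    if (cfg$noise_sd > 0)
      pix <- pix + stats::rnorm(length(pix), sd = cfg$noise_sd)
    pix <- as.integer(round(pmin.int(pmax.int(pix, 0), 255)))
    dim(pix) <- c(H, W, 3L)
    # internal constructor: bounds hold by construction (values clipped above)
    fr <- structure(list(pixels = pix, time_h = t, source_id = filenames[i]),
                    class = "image_frame")
    if (is.null(out_dir)) {
      frames[[i]] <- fr
    } else {
      write_frame(fr, file.path(out_dir, filenames[i]))
    }
  }

  planted <- data.frame(time_h = times, drow = drow, dcol = dcol)
  coverage <- data.frame(time_h = times, coverage_frac = cov_frac)
  manifest_path <- NULL
  if (!is.null(out_dir)) {
    manifest_path <- file.path(out_dir, "manifest.csv")
    utils::write.csv(data.frame(time_h = times, filename = filenames),
                     manifest_path, row.names = FALSE)
    truth <- list(onset_h = cfg$onset_h,
                  seed = cfg$seed,
                  rng = "R default (Mersenne-Twister), single root seed",
                  planted_offsets = planted,
                  coverage = coverage)
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         dataframe = "columns", auto_unbox = TRUE, digits = NA)
  }
  structure(list(frames = frames, planted_offsets = planted,
                 coverage = coverage, manifest = manifest_path,
                 config = cfg),
            class = "membrane_image_series")
}

#' @export
print.membrane_image_series <- function(x, ...) {
  cat(sprintf("Simulated membrane image series: %d frames of %d x %d px\n",
              nrow(x$planted_offsets), x$config$frame_height,
              x$config$frame_width))
  cat(sprintf("  final biofilm coverage fraction: %.3f\n",
              x$coverage$coverage_frac[nrow(x$coverage)]))
  if (!is.null(x$manifest)) cat("  written to:", dirname(x$manifest), "\n")
  invisible(x)
}
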