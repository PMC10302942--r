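# Shared fixtures: all synthetic, generated in code at test time.

scenario_with <- function(scale, defaults, seed, dots) {
  args <- utils::modifyList(defaults, dots)
  do.call(scaled_scenario, c(list(scale = scale, seed = seed), args))
}

# Small, fast scenario (1/16 linear scale) for unit tests.
tiny_scenario <- function(seed = 1, ...) {
  scenario_with(1 / 16, list(duration_h = 48, frame_interval_h = 4,
                             onset_h = 24), seed, list(...))
}

# Reduced-resolution replicate of the default accelerated-biofouling study
# (516 x 772 frames, 3 h imaging cadence, 360 h duration, onset at 120 h).
study_scenario <- function(seed = 1, ...) {
  scenario_with(0.25, list(duration_h = 360, frame_interval_h = 3,
                           onset_h = 120), seed, list(...))
}

# No-fouling control at small frame size.
null_scenario <- function(seed = 1, ...) {
  scenario_with(1 / 16, list(duration_h = 360, frame_interval_h = 3,
                             onset_h = 120, nucleation_rate = 0),
                seed, list(...))
}

# Brute-force per-window Pearson NCC: the independent oracle for ncc_map().
ncc_brute <- function(template, sensed) {
  h <- nrow(template); w <- ncol(template)
  H <- nrow(sensed); W <- ncol(sensed)
  out <- matrix(NA_real_, H - h + 1L, W - w + 1L)
  tv <- as.vector(template)
  for (u in seq_len(H - h + 1L)) {
    for (v in seq_len(W - w + 1L)) {
      win <- as.vector(sensed[u:(u + h - 1L), v:(v + w - 1L)])
      if (stats::var(win) <= 0 || stats::var(tv) <= 0) next
      out[u, v] <- stats::cor(win, tv)
    }
  }
  out
}

# Scalar-loop Pearson coefficient: the independent oracle for pearson2d().
pearson_loop <- function(A, B) {
  abar <- mean(A); bbar <- mean(B)
  num <- 0; da <- 0; db <- 0
  for (m in seq_len(nrow(A))) {
    for (n in seq_len(ncol(A))) {
      num <- num + (A[m, n] - abar) * (B[m, n] - bbar)
      da <- da + (A[m, n] - abar)^2
      db <- db + (B[m, n] - bbar)^2
    }
  }
  num / sqrt(da * db)
}

# Solid-colour frame helper.
flat_frame <- function(r, g, b, H = 12L, W = 10L, time_h = 0) {
  px <- array(0L, dim = c(H, W, 3L))
  px[, , 1] <- as.integer(r); px[, , 2] <- as.integer(g)
  px[, , 3] <- as.integer(b)
  image_frame(px, time_h = time_h)
}

# Random textured frame (integer 8-bit).
noise_frame <- function(seed, H = 24L, W = 20L, time_h = 0) {
  set.seed(seed)
  px <- array(as.integer(sample.int(256L, H * W * 3L, replace = TRUE) - 1L),
              dim = c(H, W, 3L))
  image_frame(px, time_h = time_h)
}
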