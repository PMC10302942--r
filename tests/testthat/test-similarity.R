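test_that("channel splitting preserves values and partitions the frame", {
  fr <- flat_frame(255, 0, 0)
  ch <- split_channels(fr)
  expect_true(all(ch$r == 255) && all(ch$g == 0) && all(ch$b == 0))

  fr2 <- noise_frame(3)
  ch2 <- split_channels(fr2)
  rebuilt <- array(0L, dim = dim(fr2$pixels))
  rebuilt[, , 1] <- ch2$r; rebuilt[, , 2] <- ch2$g; rebuilt[, , 3] <- ch2$b
  expect_identical(rebuilt, fr2$pixels)
})

test_that("pearson2d reproduces hand-evaluated and degenerate cases", {
  A <- matrix(1:9, 3, 3, byrow = TRUE)
  B <- matrix(9:1, 3, 3, byrow = TRUE)   # B = 10 - A
  expect_equal(pearson2d(A, B), -1)
  expect_equal(pearson2d(A, A), 1)
  expect_equal(pearson2d(A, 2.5 * A + 3), 1, tolerance = 1e-12)
  expect_equal(pearson2d(A, -0.5 * A + 1), -1, tolerance = 1e-12)
  expect_true(is.na(pearson2d(A, matrix(7, 3, 3))))
  expect_error(pearson2d(A, matrix(1:6, 2, 3)), "identical dimensions")
})

test_that("pearson2d equals the scalar-loop oracle on random matrices", {
  set.seed(99)
  worst <- 0
  for (trial in 1:200) {
    n <- sample(2:16, 1); m <- sample(2:16, 1)
    A <- matrix(runif(n * m), n, m)
    B <- matrix(runif(n * m), n, m)
    worst <- max(worst, abs(pearson2d(A, B) - pearson_loop(A, B)),
                 abs(pearson2d(A, B) - pearson2d(B, A)))
  }
  expect_lt(worst, 1e-10)
})

test_that("series of reference copies scores 1 in all layers", {
  fr <- noise_frame(5, time_h = 0)
  frames <- lapply(0:3, function(t) { f <- fr; f$time_h <- t; f })
  s <- similarity_series(frames)
  expect_equal(s$r_red, rep(1, 4))
  expect_equal(s$r_green, rep(1, 4))
  expect_equal(s$r_blue, rep(1, 4))
  expect_true(all(s$status == "ok"))
})

test_that("constant frames are flagged undefined, not scored", {
  frames <- list(noise_frame(6, time_h = 0), flat_frame(50, 50, 50, H = 24L,
                                                        W = 20L, time_h = 1))
  s <- similarity_series(frames)
  expect_true(is.na(s$r_blue[2]))
  expect_match(s$status[2], "zero variance")
  expect_equal(s$status[1], "ok")
})

test_that("fast similarity path agrees with pearson2d frame by frame", {
  cfg <- tiny_scenario(seed = 8)
  sim <- simulate_image_series(cfg)
  s <- similarity_series(sim$frames)
  ref <- split_channels(sim$frames[[1]])
  for (i in c(2, length(sim$frames))) {
    ch <- split_channels(sim$frames[[i]])
    expect_equal(s$r_red[i], pearson2d(ref$r, ch$r), tolerance = 1e-12)
    expect_equal(s$r_blue[i], pearson2d(ref$b, ch$b), tolerance = 1e-12)
  }
})

test_that("uniform illumination drift alone barely moves the coefficients", {
  cfg <- tiny_scenario(seed = 9, duration_h = 96, frame_interval_h = 8,
                       nucleation_rate = 0, jitter_max = 0L,
                       illumination_drift = 0.05, noise_sd = 0)
  sim <- simulate_image_series(cfg)
  s <- similarity_series(sim$frames)
  expect_true(all(s$r_red >= 0.999 & s$r_green >= 0.999 & s$r_blue >= 0.999))
})

test_that("blue coefficient is non-increasing once coverage grows (noise-free)", {
  cfg <- scaled_scenario(scale = 1 / 8, seed = 10, duration_h = 300,
                         frame_interval_h = 12, onset_h = 60,
                         noise_sd = 0, jitter_max = 0L)
  sim <- simulate_image_series(cfg)
  s <- similarity_series(sim$frames)
  # monotone decline holds while coverage rises and is not yet saturated;
  # once the film approaches uniform cover the attenuation becomes a
  # near-affine intensity change and r partially rebounds
  grow <- s$time_h >= 72 & sim$coverage$coverage_frac <= 0.6
  expect_true(all(diff(s$r_blue[grow]) <= 1e-6))
  n <- max(which(grow))
  expect_true(s$r_blue[n] <= s$r_green[n] && s$r_green[n] <= s$r_red[n])
})
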