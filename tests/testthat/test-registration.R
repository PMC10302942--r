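test_that("template extraction is a pixel-exact crop and rejects flat regions", {
  set.seed(1)
  g <- matrix(runif(40 * 50), 40, 50)
  roi <- template_roi(5, 10, 12, 16)
  tpl <- extract_template(g, roi)
  expect_identical(tpl, g[6:17, 11:26])

  flat <- matrix(0.5, 40, 50)
  expect_error(extract_template(flat, roi), "featureless")
  expect_error(extract_template(g, template_roi(35, 10, 12, 16)), "bounds")
  expect_error(template_roi(0, 0, 4, 16), "degenerate")
})

test_that("ncc_map matches the brute-force per-window Pearson oracle", {
  set.seed(42)
  for (trial in 1:25) {
    H <- sample(10:24, 1); W <- sample(10:24, 1)
    h <- sample(3:(H - 1), 1); w <- sample(3:(W - 1), 1)
    sensed <- matrix(runif(H * W), H, W)
    template <- matrix(runif(h * w), h, w)
    fast <- ncc_map(template, sensed)
    slow <- ncc_brute(template, sensed)
    expect_lt(max(abs(unclass(fast) - slow), na.rm = TRUE), 1e-10)
  }
})

test_that("a template cut from the image scores 1 at its own location", {
  set.seed(7)
  sensed <- matrix(runif(30 * 30), 30, 30)
  tpl <- sensed[11:18, 6:15]
  m <- ncc_map(tpl, sensed)
  expect_equal(m[11, 6], 1, tolerance = 1e-12)
  pk <- locate_peak(m)
  expect_equal(c(pk$drow, pk$dcol), c(10L, 5L))
})

test_that("NCC is invariant to positive affine intensity changes", {
  set.seed(8)
  sensed <- matrix(runif(20 * 25), 20, 25)
  tpl <- matrix(runif(6 * 7), 6, 7)
  m1 <- ncc_map(tpl, sensed)
  m2 <- ncc_map(tpl, 3.2 * sensed + 0.7)
  expect_equal(unclass(m1), unclass(m2), tolerance = 1e-10)
})

test_that("peak location breaks ties by smallest row then column", {
  m <- matrix(0, 8, 8)
  m[4, 8] <- 1; m[6, 3] <- 1   # equal maxima at 0-based (3,7) and (5,2)
  class(m) <- c("ncc_map", "matrix")
  pk <- locate_peak(m)
  expect_equal(c(pk$drow, pk$dcol), c(3L, 7L))
  expect_error(locate_peak(matrix(NA_real_, 3, 3)), "undefined")
})

test_that("degenerate templates and oversize templates are rejected", {
  expect_error(ncc_map(matrix(1, 4, 4), matrix(runif(36), 6, 6)),
               "featureless")
  expect_error(ncc_map(matrix(runif(64), 8, 8), matrix(runif(48), 6, 8)),
               "strictly smaller")
})

test_that("constant windows are excluded from the peak search", {
  sensed <- matrix(0.5, 12, 12)
  sensed[7:10, 7:10] <- matrix(runif(16), 4)
  tpl <- sensed[7:9, 7:9]
  m <- ncc_map(tpl, sensed)
  expect_true(any(is.na(m)))
  pk <- locate_peak(m)
  expect_equal(c(pk$drow, pk$dcol), c(6L, 6L))
})

test_that("registered crop has the documented size, anchor and motion guard", {
  px <- array(0L, dim = c(2064, 3088, 3))
  px[, , 1] <- as.integer(matrix(seq_len(2064) %% 251, 2064, 3088))
  fr <- image_frame(px, 0)
  reg <- register_frame(fr, list(drow = 0L, dcol = 0L), margins = c(127L, 175L))
  expect_equal(dim(reg$pixels), c(1937L, 2913L, 3L))
  # anchor floor(margin/2): first registered row is input row 64 (1-based)
  expect_identical(reg$pixels[1, 1, 1], px[64, 88, 1])

  expect_error(register_frame(fr, list(drow = 100L, dcol = 0L),
                              margins = c(127L, 175L)),
               "excessive motion")
})

test_that("planted integer translations are recovered exactly without noise", {
  cfg <- scaled_scenario(scale = 1 / 8, seed = 11, duration_h = 30,
                         frame_interval_h = 1, onset_h = 1000, noise_sd = 0)
  sim <- simulate_image_series(cfg)
  roi <- template_roi(100, 160, 40, 40)
  reg <- register_series(sim$frames, 1, roi, margins = c(16L, 22L))
  m <- merge(reg$offsets, sim$planted_offsets, by = "time_h")
  expect_equal(mean(m$drow.x == m$drow.y & m$dcol.x == m$dcol.y), 1)
  expect_true(all(reg$offsets$peak_score[-1] > 0.99))
  # all registered frames share identical dimensions: input minus margins
  dims <- unique(t(vapply(reg$frames, function(f) dim(f$pixels), integer(3))))
  expect_equal(nrow(dims), 1L)
  expect_equal(as.integer(dims), c(258L - 16L, 386L - 22L, 3L))
})

test_that("registered frames agree pixelwise on the feature region", {
  cfg <- scaled_scenario(scale = 1 / 8, seed = 12, duration_h = 10,
                         frame_interval_h = 1, onset_h = 1000)
  sim <- simulate_image_series(cfg)
  roi <- template_roi(100, 160, 40, 40)
  reg <- register_series(sim$frames, 1, roi, margins = c(16L, 22L))
  a <- reg$frames[[2]]$pixels[100:139, 160:199, ]
  b <- reg$frames[[5]]$pixels[100:139, 160:199, ]
  expect_lt(mean(abs(a - b)), 2 * cfg$noise_sd)
})

test_that("drop policy skips frames with excessive motion and logs them", {
  cfg <- scaled_scenario(scale = 1 / 8, seed = 13, duration_h = 8,
                         frame_interval_h = 1, onset_h = 1000, noise_sd = 0)
  sim <- simulate_image_series(cfg)
  # sabotage one frame with a shift far beyond the margin room
  bad <- sim$frames[[4]]
  bad$pixels <- bad$pixels[c(30:258, 1:29), , , drop = FALSE]
  sim$frames[[4]] <- bad
  roi <- template_roi(100, 160, 40, 40)
  expect_error(register_series(sim$frames, 1, roi, margins = c(16L, 22L),
                               search_margin = 40L),
               "excessive motion")
  expect_warning(
    reg <- register_series(sim$frames, 1, roi, margins = c(16L, 22L),
                           search_margin = 40L, on_failure = "drop"),
    "dropping")
  expect_equal(length(reg$frames), length(sim$frames) - 1L)
  expect_equal(length(reg$dropped), 1L)
})
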