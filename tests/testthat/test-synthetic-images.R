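test_that("identical configuration reproduces identical frame stacks", {
  a <- simulate_image_series(tiny_scenario(seed = 7))
  b <- simulate_image_series(tiny_scenario(seed = 7))
  expect_identical(lapply(a$frames, `[[`, "pixels"),
                   lapply(b$frames, `[[`, "pixels"))
  expect_identical(a$planted_offsets, b$planted_offsets)
})

test_that("no-fouling scenario keeps channel means constant within noise", {
  cfg <- tiny_scenario(seed = 2, nucleation_rate = 0, illumination_drift = 0)
  sim <- simulate_image_series(cfg)
  blue_means <- vapply(sim$frames, function(f) mean(f$pixels[, , 3]), numeric(1))
  expect_equal(sim$coverage$coverage_frac, rep(0, nrow(sim$coverage)))
  # jitter shuffles which part of the static scene is visible; the mean
  # intensity of a stationary texture stays put up to noise
  expect_lt(diff(range(blue_means)), 3 * cfg$noise_sd)
})

test_that("fouling attenuates blue most and red least", {
  cfg <- scaled_scenario(scale = 1 / 8, seed = 3, duration_h = 360,
                         frame_interval_h = 24, onset_h = 120)
  sim <- simulate_image_series(cfg)
  first <- sim$frames[[1]]$pixels
  last <- sim$frames[[length(sim$frames)]]$pixels
  rel_loss <- vapply(1:3, function(ch)
    1 - mean(last[, , ch]) / mean(first[, , ch]), numeric(1))
  expect_gt(rel_loss[3], rel_loss[1])              # blue falls more than red
  expect_true(rel_loss[3] >= rel_loss[2] && rel_loss[2] >= rel_loss[1])
})

test_that("coverage is monotone between CIP events and drops at them", {
  cfg <- scaled_scenario(scale = 1 / 8, seed = 5, duration_h = 240,
                         frame_interval_h = 6, onset_h = 60,
                         cip_events = list(list(time_h = 150, efficacy = 0.8)))
  sim <- simulate_image_series(cfg)
  cov <- sim$coverage
  pre <- cov$coverage_frac[cov$time_h < 150]
  expect_true(all(diff(pre) >= 0))
  expect_true(all(cov$coverage_frac >= 0 & cov$coverage_frac <= 1))
  at_event <- cov$coverage_frac[cov$time_h == 150]
  before <- cov$coverage_frac[cov$time_h == 144]
  expect_lt(at_event, before)
})

test_that("planted offsets are bounded by jitter_max and frame 0 is clean reference", {
  cfg <- tiny_scenario(seed = 9)
  sim <- simulate_image_series(cfg)
  off <- sim$planted_offsets
  expect_identical(c(off$drow[1], off$dcol[1]), c(0L, 0L))
  expect_true(all(abs(off$drow) <= cfg$jitter_max))
  expect_true(all(abs(off$dcol) <= cfg$jitter_max))
  expect_equal(sim$frames[[1]]$time_h, 0)
})

test_that("disk output writes frames, manifest and ground truth", {
  dir <- withr::local_tempdir()
  cfg <- tiny_scenario(seed = 4)
  sim <- simulate_image_series(cfg, out_dir = dir)
  m <- read_manifest(file.path(dir, "manifest.csv"))
  expect_equal(nrow(m), length(seq(0, cfg$duration_h, by = cfg$frame_interval_h)))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  expect_equal(truth$onset_h, cfg$onset_h)
  expect_equal(truth$planted_offsets$drow, sim$planted_offsets$drow)
  # round trip through the 8-bit TIFF writer/reader is lossless
  in_mem <- simulate_image_series(cfg)
  f3 <- load_frame(m$filename[3], m$time_h[3])
  expect_identical(f3$pixels, in_mem$frames[[3]]$pixels)
})
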