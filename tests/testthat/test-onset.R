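test_that("constant and pure-noise series yield no onset", {
  t <- 0:120
  expect_true(is.na(detect_onset(t, rep(5, 121), "decrease")$onset_time_h))
  set.seed(1)
  r <- detect_onset(t, rnorm(121), "increase")
  expect_true(is.na(r$onset_time_h))
  expect_error(detect_onset(0:10, rnorm(11), "decrease"), "too short")
})

test_that("a persistent step is localized at its first exceeding sample", {
  set.seed(2)
  t <- 0:300
  y <- rnorm(301, mean = 10, sd = 0.1)
  y[t >= 200] <- y[t >= 200] + 1    # 10-sigma step at t = 200
  r <- detect_onset(t, y, "increase", persistence = 3)
  expect_lte(abs(r$onset_time_h - 200), 2)
  expect_equal(r$direction, "increase")

  rdec <- detect_onset(t, 20 - y, "decrease", persistence = 3)
  expect_lte(abs(rdec$onset_time_h - 200), 2)
})

test_that("isolated spikes shorter than the persistence are ignored", {
  set.seed(3)
  t <- 0:200
  y <- rnorm(201, sd = 0.05)
  y[100:102] <- y[100:102] + 5   # 3-sample excursion < persistence 5
  r <- detect_onset(t, y, "increase", persistence = 5)
  expect_true(is.na(r$onset_time_h))
})

test_that("start_h discards the conditioning transient from the baseline", {
  t <- 0:300
  # conditioning decay under the daily temperature cycle
  y <- (0.8 + 0.2 * exp(-t / 24)) * (1 + 0.01 * sin(2 * pi * t / 24))
  r <- detect_onset(t, y, "decrease", start_h = 96)
  expect_true(is.na(r$onset_time_h))      # residual decay is inside the band
})

test_that("plateau detection finds saturation and rejects steady trends", {
  t <- 0:200
  y <- pmax(1 - t / 100, 0)               # falls until t = 100, then flat
  p <- detect_plateau(t, y, window = 24, slope_tol = 1e-6)
  expect_lte(p, 100 + 24)
  expect_gte(p, 100 - 1)

  lin <- detect_plateau(t, 1 - 0.01 * t, window = 24, slope_tol = 1e-6)
  expect_true(is.na(lin))
})

test_that("plateau search can be anchored after a detected onset", {
  t <- 0:300
  y <- c(rep(1, 100), 1 - 0.01 * (1:100), rep(0, 101))
  p <- detect_plateau(t, y, window = 20, slope_tol = 1e-8,
                      onset_time_h = 150)
  expect_gte(p, 199)
  expect_lte(p, 220)
})

test_that("CIP recovery is 1 for full return, 0 for no change", {
  t <- 0:100
  base <- rep(1, 101)
  y <- base
  y[t >= 40 & t < 70] <- 0.6               # loss, then full recovery at 70
  rep1 <- evaluate_cip(t, y, 70)
  expect_equal(rep1$recovery, 1)

  y2 <- base; y2[t >= 40] <- 0.6           # no change at the event
  rep2 <- evaluate_cip(t, y2, 70)
  expect_equal(rep2$recovery, 0)

  expect_error(evaluate_cip(t, y, 500), "outside")
})

test_that("partial cleanings rank by efficacy on the fiber trace", {
  cfg <- tiny_scenario(seed = 21, duration_h = 360, frame_interval_h = 1,
                       onset_h = 120,
                       cip_events = list(list(time_h = 170, efficacy = 0.9),
                                         list(time_h = 200, efficacy = 0.5)))
  pof <- simulate_pof_series(cfg, interval_h = 1)
  post <- pof[pof$time_h >= 96, ]
  rep <- evaluate_cip(post$time_h, post$sensor, c(170, 200))
  expect_gt(rep$recovery[1], rep$recovery[2])
  expect_true(all(rep$recovery >= 0 & rep$recovery <= 1))
})
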