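test_that("moving-average smoothing preserves constants, lines and range", {
  expect_equal(smooth_profile(rep(3.5, 40), 20), rep(3.5, 40))
  expect_equal(smooth_profile(1:10, 1), 1:10)
  # symmetric truncated window preserves linear trends everywhere
  y <- as.numeric(1:100)
  expect_equal(smooth_profile(y, 20), y)
  # direct convolution oracle on arbitrary data
  set.seed(1)
  z <- rnorm(60)
  sm <- smooth_profile(z, 20)
  oracle <- vapply(seq_along(z), function(i) {
    h <- min(10, i - 1, length(z) - i)
    mean(z[(i - h):(i + h)])
  }, numeric(1))
  expect_equal(sm, oracle, tolerance = 1e-12)
  # never extends the value range
  expect_gte(min(sm), min(z))
  expect_lte(max(sm), max(z))
  expect_error(smooth_profile(z, 0), "window")
})

test_that("baseline is the mean of the furthest valid samples", {
  expect_equal(estimate_baseline(rep(5, 30)), 5)
  expect_equal(estimate_baseline(c(rnorm(30), 1:20)), 10.5)
  expect_equal(estimate_baseline(1:20), mean(1:20))  # length exactly n_tail
  expect_error(estimate_baseline(1:10), "at least 20")
  # masked samples are skipped
  y <- c(1:20, rep(100, 5))
  m <- c(rep(TRUE, 20), rep(FALSE, 5))
  expect_equal(estimate_baseline(y, mask = m), 10.5)
})

test_that("baseline subtraction zeroes the tail and is self-consistent", {
  y <- c(10, 8, 6)
  expect_equal(subtract_baseline(y, 6), c(4, 2, 0))
  expect_equal(subtract_baseline(y, 0), y)
  z <- rnorm(50, mean = 7)
  b <- estimate_baseline(z)
  expect_equal(estimate_baseline(subtract_baseline(z, b)), 0)
})

test_that("half-maximal intensity sits midway between max and baseline", {
  expect_equal(compute_yfp50(100, 0), 50)
  expect_equal(compute_yfp50(130, 30), 80)
  flagged <- compute_yfp50(50, 50)
  expect_true(is.na(flagged))
  expect_equal(attr(flagged, "reason"), "no response")
  expect_error(compute_yfp50(10, 20), "below baseline")
})

test_that("dist50 locates the first half-max crossing from the peak", {
  # linear decay 100 -> 0 over 0-200 um: midpoint at 100 um
  d <- seq(0, 200, by = 1)
  lin <- compute_dist50(d, 100 - 0.5 * d, 50)
  expect_true(lin$valid)
  expect_equal(lin$dist50, 100)
  # exponential decay, 1-um sampling, against the dense-scan oracle
  y <- 100 * exp(-d / 100)
  oracle <- dense_crossing_oracle(function(x) 100 * exp(-x / 100), 50)
  est <- compute_dist50(d, y, 50)
  expect_equal(est$dist50, oracle, tolerance = 0.5)
  expect_equal(oracle, 100 * log(2), tolerance = 0.01)
  # monotonically increasing profile never crosses downward
  up <- compute_dist50(d, d, 100)
  expect_false(up$valid)
  expect_equal(up$reason, "no crossing")
})

test_that("non-contacting inference handles gaps and bad references", {
  d <- seq(0, 500, by = 1)
  y <- 100 * exp(-d / 100)           # field from the producer edge
  mask <- !(d >= 0 & d <= 50)        # gap [0, 50] masked
  est <- infer_dist50_noncontacting(d, y, 50, mask)
  expect_true(est$valid)
  expect_equal(est$dist50, 100 * log(2), tolerance = 0.5)
  # identical profile and reference give the contacting answer
  contacting <- compute_dist50(d, y, 50)
  expect_equal(est$dist50, contacting$dist50, tolerance = 1e-9)
  # reference above the profile maximum is flagged
  bad <- infer_dist50_noncontacting(d, y, 200, mask)
  expect_false(bad$valid)
  expect_equal(bad$reason, "reference above profile")
  # crossing that falls inside the masked gap is flagged
  wide <- !(d >= 60 & d <= 80)       # gap hides the 69.3 um crossing
  hidden <- infer_dist50_noncontacting(d, y, 50, wide)
  expect_false(hidden$valid)
  expect_equal(hidden$reason, "crossing in gap")
})

test_that("peak reporting breaks ties toward the origin", {
  d <- 0:10
  flat <- peak_signal(d, rep(2, 11))
  expect_equal(flat$value, 2)
  expect_equal(flat$distance, 0)
  spike <- peak_signal(d, c(rep(0, 5), 9, rep(0, 5)))
  expect_equal(spike$distance, 5)
  expect_equal(spike$value, 9)
})

test_that("min-max scaling spans [0, 1] and ignores affine transforms", {
  expect_equal(minmax_scale(c(2, 4, 6)), c(0, 0.5, 1))
  y <- c(0, 0.25, 1)
  expect_equal(minmax_scale(y), y)
  z <- rnorm(50)
  expect_equal(minmax_scale(3 * z + 50), minmax_scale(z), tolerance = 1e-12)
  expect_error(minmax_scale(rep(1, 5)), "zero dynamic range")
})

test_that("replicate averaging reports pointwise mean, SD and support", {
  p1 <- list(distance = 0:2, value = c(1, 2, 3))
  p2 <- list(distance = 0:2, value = c(3, 2, 1))
  avg <- average_decays(list(p1, p2))
  expect_equal(avg$mean, c(2, 2, 2))
  expect_equal(avg$sd, c(sqrt(2), 0, sqrt(2)))
  expect_equal(avg$n, rep(2, 3))
  # identical replicates: SD 0 everywhere
  same <- average_decays(list(p1, p1, p1), min_n = 2)
  expect_true(all(same$sd == 0))
  # single profile: mean = profile, SD undefined, flagged
  solo <- average_decays(list(p1))
  expect_equal(solo$mean, c(1, 2, 3))
  expect_true(all(is.na(solo$sd)))
  expect_true(all(solo$flagged))
  expect_error(average_decays(list()), "empty")
})

test_that("dist50 is invariant under affine intensity transforms", {
  set.seed(99)
  d <- seq(0, 600, by = 1)
  y <- 800 * exp(-d / 120) + rnorm(length(d), 0, 10)
  base <- cross_section(d, list(YFP = y), origin_kind = "yfp-peak")
  trans <- cross_section(d, list(YFP = 3 * y + 50),
                         origin_kind = "yfp-peak")
  r1 <- analyze_decay(base)
  r2 <- analyze_decay(trans)
  expect_true(r1$valid && r2$valid)
  expect_equal(r2$dist50, r1$dist50, tolerance = 1e-6)
  expect_equal(r2$baseline, 3 * r1$baseline + 50, tolerance = 1e-9)
})

test_that("decay analysis recovers lambda ln 2 and flags no-response", {
  d <- seq(0, 700, by = 1)
  y <- 1000 * exp(-d / 100)
  prof <- cross_section(d, list(YFP = y), origin_kind = "yfp-peak")
  res <- analyze_decay(prof)
  expect_true(res$valid)
  expect_equal(res$dist50, 100 * log(2), tolerance = 1)
  # flat noisy profile gates on the response floor
  set.seed(3)
  flat <- cross_section(d, list(YFP = rnorm(length(d), 100, 5)),
                        origin_kind = "yfp-peak")
  rf <- analyze_decay(flat)
  expect_false(rf$valid)
  expect_equal(rf$reason, "no response")
})
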