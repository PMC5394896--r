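test_that("SQUID jump correction removes steps and nothing else", {
  # constant trace: untouched, no jumps
  res <- correct_squid_jumps(rep(5, 100))
  expect_equal(res$trace, rep(5, 100))
  expect_length(res$jumps, 0L)
  # ramp with an injected +5000 step: step removed, position reported
  n <- 400; s <- 3
  ramp <- s * (0:(n - 1))
  jumped <- ramp + 5000 * (seq_len(n) >= 150)
  res <- correct_squid_jumps(jumped, 3000, 21)
  expect_equal(res$jumps, 149L)
  expect_equal(res$trace, ramp)
  # strict threshold: differences of exactly 2999 do not count at 3000
  tr <- cumsum(c(0, rep(c(2999, -2999), 25)))
  expect_length(correct_squid_jumps(tr, 3000)$jumps, 0L)
  expect_error(correct_squid_jumps(1:10, median_window = 21L), "shorter")
})

test_that("jump correction is idempotent", {
  set.seed(5)
  for (i in 1:10) {
    tr <- cumsum(rnorm(300, sd = 200))
    pos <- sample(50:250, 2)
    tr[pos[1]:300] <- tr[pos[1]:300] + 6000
    tr[pos[2]:300] <- tr[pos[2]:300] - 8000
    once <- correct_squid_jumps(tr)
    expect_true(all(abs(diff(once$trace)) <= 3000))
    twice <- correct_squid_jumps(once$trace)
    expect_identical(twice$trace, once$trace)
    expect_length(twice$jumps, 0L)
  }
})

test_that("amplitude screening flags exactly the offending trials", {
  dat <- array(rnorm(5 * 2 * 20), dim = c(5, 2, 20))
  ep <- trial_epochs(dat, 200, c(0, 100), rep(1:5, 1))
  expect_length(
    unlist(suppressMessages(screen_amplitude(ep, 3000))$exclusion_flags), 0L
  )
  dat[3, 1, 7] <- 3001
  ep <- trial_epochs(dat, 200, c(0, 100), rep(1:5, 1))
  flagged <- suppressMessages(screen_amplitude(ep, 3000))
  expect_equal(which(lengths(flagged$exclusion_flags) > 0), 3L)
  expect_equal(flagged$exclusion_flags[[3]], "amplitude_artifact")
  # an infinite threshold never flags
  dat[3, 1, 7] <- 1e9
  ep <- trial_epochs(dat, 200, c(0, 100), rep(1:5, 1))
  expect_length(
    unlist(suppressMessages(screen_amplitude(ep, Inf))$exclusion_flags), 0L
  )
})

test_that("filtering, baseline correction and decimation behave as specified", {
  # DC-only input is annihilated by baseline correction
  ep <- trial_epochs(array(7, dim = c(2, 1, 480)), 200, c(-400, 2000), c(1, 2))
  out <- filter_baseline_downsample(ep, 80, c(-300, 0), 200)
  expect_equal(max(abs(out$data)), 0, tolerance = 1e-10)
  # baseline-window mean is exactly zero afterwards
  set.seed(8)
  ep <- trial_epochs(array(rnorm(2 * 480) + 5, dim = c(2, 1, 480)),
                     200, c(-400, 2000), c(1, 2))
  out <- filter_baseline_downsample(ep, 80, c(-300, 0), 200)
  tms <- sample_times(out)
  bl <- tms >= -300 & tms < 0
  expect_equal(mean(out$data[1, 1, bl]), 0, tolerance = 1e-12)
  # sinusoid at the cutoff frequency attenuates to 1/sqrt(2) (first-order
  # magnitude response at the cutoff, single pass)
  fs <- 1200; f0 <- 80
  x <- sin(2 * pi * f0 * (0:3599) / fs)
  dat <- array(0, dim = c(1, 1, 3600)); dat[1, 1, ] <- x
  ep <- trial_epochs(dat, fs, c(0, 3000), 1)
  filt <- filter_baseline_downsample(ep, f0, NULL, fs)
  amp <- max(abs(filt$data[1, 1, 2000:3500]))
  expect_equal(amp, 1 / sqrt(2), tolerance = 0.02)
  # 1200 Hz decimated to 200 Hz keeps exactly one sample in six
  dec <- filter_baseline_downsample(ep, 80, NULL, 200)
  expect_equal(dim(dec$data)[3], 600L)
  expect_equal(dec$sample_rate, 200)
  # invalid configurations
  expect_error(filter_baseline_downsample(ep, 80, NULL, 170), "divide")
  expect_error(filter_baseline_downsample(ep, 80, c(-300, 0), 200), "outside")
  expect_error(filter_baseline_downsample(ep, 700, NULL, 200), "Nyquist")
})

test_that("time binning reproduces the standard bin counts and averages", {
  set.seed(4)
  ep <- trial_epochs(array(rnorm(3 * 2 * 480), dim = c(3, 2, 480)),
                     200, c(-400, 2000), c(1, 1, 2))
  b <- bin_time(ep, 10)
  expect_equal(dim(b$data)[3], 240L)
  expect_equal(b$bin_centers_ms[1], -395)
  expect_equal(tail(b$bin_centers_ms, 1), 1995)
  b2 <- bin_time(ep, 10, c(0, 2000))
  expect_equal(dim(b2$data)[3], 200L)
  expect_equal(b2$bin_centers_ms[1], 5)
  # each 10 ms bin at 200 Hz is the mean of exactly 2 samples
  expect_equal(b$data[1, 1, 1], mean(ep$data[1, 1, 1:2]))
  expect_equal(b2$data[2, 2, 1], mean(ep$data[2, 2, 81:82]))
  # a constant channel keeps its value in every bin
  ep$data[3, 1, ] <- 4.5
  expect_equal(as.vector(bin_time(ep, 10)$data[3, 1, ]), rep(4.5, 240))
  expect_error(bin_time(ep, 7), "remainder")
})

test_that("binning commutes with averaging across trials", {
  set.seed(6)
  ep <- trial_epochs(array(rnorm(8 * 2 * 40), dim = c(8, 2, 40)),
                     200, c(0, 200), rep(1:4, 2))
  b <- bin_time(ep, 10)
  bin_of_mean <- bin_time(
    trial_epochs(array(apply(ep$data, c(2, 3), mean), dim = c(1, 2, 40)),
                 200, c(0, 200), 1), 10
  )
  mean_of_bin <- apply(b$data, c(2, 3), mean)
  expect_equal(bin_of_mean$data[1, , ], mean_of_bin, tolerance = 1e-12)
})

test_that("exclusion bookkeeping reports per-reason percentages of all trials", {
  dat <- array(0, dim = c(100, 1, 10))
  flags <- rep(list(character(0)), 100)
  flags[[4]] <- "jump_artifact"
  flags[[9]] <- "jump_artifact"
  ep <- trial_epochs(dat, 200, c(0, 50), rep(1:10, 10), flags)
  res <- apply_exclusions(ep)
  expect_equal(res$report$percent[res$report$reason == "jump_artifact"], 2.0)
  expect_equal(res$n_kept, 98L)
  # no flags: identity
  ep0 <- trial_epochs(dat, 200, c(0, 50), rep(1:10, 10))
  expect_equal(apply_exclusions(ep0)$n_kept, 100L)
  # a doubly flagged trial is removed once but counted under both reasons
  flags[[4]] <- c("jump_artifact", "incorrect_response")
  ep2 <- trial_epochs(dat, 200, c(0, 50), rep(1:10, 10), flags)
  res2 <- apply_exclusions(ep2)
  expect_equal(res2$n_kept, 98L)
  expect_equal(res2$report$n[res2$report$reason == "jump_artifact"], 2L)
  expect_equal(res2$report$n[res2$report$reason == "incorrect_response"], 1L)
  # excluding everything is an error
  ep3 <- trial_epochs(dat, 200, c(0, 50), rep(1:10, 10),
                      rep(list("misdetected_marker"), 100))
  expect_error(apply_exclusions(ep3), "all trials")
})
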