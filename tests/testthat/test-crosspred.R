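test_that("the diagonal equals the in-bin encoding fit", {
  nb <- planted_binned(beta = 0.6, p = 3L, B = 6L, seed = 400)
  y <- nb$stimuli$y_mean
  xp <- cross_predict(nb$binned, y, n_perm = 100, seed = 401)
  tr <- fit_trace(nb$binned, y, model = "encoding")
  expect_equal(diag(xp$ev), tr$ev, tolerance = 1e-10)
})

test_that("a stationary pattern cross-predicts across the whole window", {
  nb <- planted_binned(beta = 1.2, p = 3L, B = 6L, trials_per = 36L,
                       seed = 410)
  y <- nb$stimuli$y_mean
  xp <- cross_predict(nb$binned, y, n_perm = 150, seed = 411)
  expect_true(all(xp$ev_thresholded > 0))
  # approximately symmetric
  M <- xp$ev_thresholded
  expect_lt(max(abs(M - t(M))) / max(M), 0.5)
})

test_that("orthogonally rotated patterns share no cross-prediction", {
  # two bins, pattern (1, 0) then (0, 1): high SNR, zero transfer
  nb <- null_binned(p = 2L, B = 2L, trials_per = 36L, seed = 420)
  y <- nb$stimuli$y_mean
  nb$binned$data[, 1, 1] <- nb$binned$data[, 1, 1] + 2 * y
  nb$binned$data[, 2, 2] <- nb$binned$data[, 2, 2] + 2 * y
  xp <- cross_predict(nb$binned, y, n_perm = 150, seed = 421)
  expect_gt(xp$ev_thresholded[1, 1], 0)
  expect_gt(xp$ev_thresholded[2, 2], 0)
  expect_equal(xp$ev_thresholded[1, 2], 0)
  expect_equal(xp$ev_thresholded[2, 1], 0)
})

test_that("null data are almost entirely zeroed off the diagonal", {
  # the diagonal itself is the in-bin fit evaluated on its own labels, so
  # its permutation p is structurally small; the zeroing calibration is an
  # off-diagonal property
  rates <- vapply(1:5, function(i) {
    nb <- null_binned(p = 3L, B = 8L, seed = 430 + i)
    xp <- cross_predict(nb$binned, nb$stimuli$y_mean, n_perm = 120,
                        seed = 440 + i)
    off <- xp$ev_thresholded[row(xp$ev) != col(xp$ev)]
    mean(off == 0)
  }, numeric(1))
  # survival should be near the nominal 5%; the tight calibration (200
  # replicates, binomial CI) lives in the acceptance suite
  expect_gt(mean(rates), 0.90)
})

test_that("thresholding is monotone in the p cut-off", {
  nb <- planted_binned(beta = 0.3, p = 3L, B = 6L, seed = 450)
  xp <- cross_predict(nb$binned, nb$stimuli$y_mean, n_perm = 150, seed = 451)
  strict <- xp$ev
  strict[xp$p > 0.01 | xp$ev < 0] <- 0
  loose <- xp$ev
  loose[xp$p > 0.10 | xp$ev < 0] <- 0
  expect_true(all(loose[strict != 0] != 0))
})

test_that("cross-feature evaluation reduces to the identity when features match", {
  nb <- planted_binned(beta = 0.5, p = 3L, B = 4L, seed = 460)
  y <- nb$stimuli$y_mean
  a <- cross_predict(nb$binned, y, n_perm = 120, seed = 7)
  b <- cross_predict_between_features(nb$binned, y, y, n_perm = 120, seed = 7)
  expect_equal(a$ev, b$ev, tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-12)
})

test_that("mean-reward models do not explain variability-coded data", {
  # channels planted on variability only: mean-reward models transfer a
  # negligible fraction of the variability signal (chance alignment of the
  # noise-level mean coefficients can pass the permutation test in a few
  # cells, but with explained variance orders of magnitude below the
  # within-feature fit)
  nb <- planted_binned(y_col = "y_cv", beta = 15, p = 3L, B = 4L,
                       trials_per = 36L, seed = 470)
  within <- cross_predict(nb$binned, nb$stimuli$y_cv, n_perm = 150,
                          seed = 471)
  xp <- cross_predict_between_features(nb$binned, nb$stimuli$y_mean,
                                       nb$stimuli$y_cv, n_perm = 150,
                                       seed = 471)
  expect_gt(mean(xp$ev_thresholded == 0), 0.5)
  expect_lt(sum(xp$ev_thresholded), 0.02 * sum(within$ev_thresholded))
  # the same holds against sign-flipped variability
  xp_neg <- cross_predict_between_features(nb$binned, nb$stimuli$y_mean,
                                           -nb$stimuli$y_cv, n_perm = 150,
                                           seed = 472)
  expect_lt(sum(xp_neg$ev_thresholded), 0.02 * sum(within$ev_thresholded))
})

test_that("a sign-flipped encoding does not defeat the linear model", {
  nb <- planted_binned(beta = -0.8, p = 3L, B = 3L, trials_per = 36L,
                       seed = 480)
  y <- nb$stimuli$y_mean
  xp <- cross_predict(nb$binned, y, n_perm = 150, seed = 481)
  expect_true(all(diag(xp$ev_thresholded) > 0))
})

test_that("row normalization rescales by the source-bin fit", {
  nb <- planted_binned(beta = 0.8, p = 3L, B = 4L, seed = 490)
  xp <- cross_predict(nb$binned, nb$stimuli$y_mean, n_perm = 120, seed = 491)
  norm <- normalize_by_source_fit(xp)
  expect_true(all(diag(norm$ev_thresholded) %in% c(0, 1)))
  expect_true(norm$normalized)
  # a stationary pattern has normalized off-diagonals near one
  offd <- norm$ev_thresholded[upper.tri(norm$ev_thresholded)]
  expect_gt(mean(offd), 0.5)
})

test_that("time-label permutation preserves the total off-diagonal sum", {
  # exhaustively on a 4-bin toy matrix: all 24 permutations
  set.seed(500)
  M <- matrix(abs(rnorm(16)), 4, 4)
  perms <- as.matrix(expand.grid(rep(list(1:4), 4)))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 4L), ]
  expect_equal(nrow(perms), 24L)
  total_off <- sum(M) - sum(diag(M))
  halves <- c(FALSE, FALSE, TRUE, TRUE)
  stats <- apply(perms, 1, function(pm) {
    Mp <- M[pm, pm]
    expect_equal(sum(Mp) - sum(diag(Mp)), total_off, tolerance = 1e-12)
    (sum(Mp[halves, halves]) - sum(diag(Mp)[halves])) -
      (sum(Mp[!halves, !halves]) - sum(diag(Mp)[!halves]))
  })
  # the half-block statistic really varies over permutations
  expect_gt(stats::sd(stats), 0)
  # sampled permutation p agrees with the exhaustive null
  xpm <- structure(
    list(ev = M, p = matrix(0.01, 4, 4), ev_thresholded = M,
         bin_centers_ms = c(5, 15, 25, 35), normalized = FALSE),
    class = "crosspred_matrix"
  )
  st <- stability_statistic(xpm, split_ms = 20, n_perm = 20000, seed = 1)
  exact_p <- mean(stats >= st$statistic)
  expect_equal(st$p.value, exact_p, tolerance = 0.02)
})

test_that("stability is detected for drift-then-freeze and not for stationary data", {
  spec <- small_spec(n_trials = 36L, n_channels = 6L, window = c(0, 160))
  roles <- data.frame(feature = rep("y_mean", 6L), channel = 1:6,
                      role = "direct", parent = NA)
  run_once <- function(drift, seed) {
    truth <- ground_truth(6L, roles = roles, beta = 1.2, noise_sd = 1,
                          drift = drift)
    sim <- simulate_dataset(spec, truth, seed = seed)
    b <- bin_time(sim$epochs, 10)
    xp <- cross_predict(b, sim$stimuli$y_mean, n_perm = 120, seed = seed + 1)
    stability_statistic(xp, split_ms = 80, n_perm = 2000, seed = seed + 2)
  }
  st_freeze <- run_once("freeze", 510)
  expect_gt(st_freeze$statistic, 0)
  expect_lt(st_freeze$p.value, 0.05)
  st_flat <- run_once("none", 511)
  expect_gt(st_flat$p.value, 0.05)
})

test_that("an all-zero matrix yields p = 1 with a warning", {
  xpm <- structure(
    list(ev = matrix(0, 4, 4), p = matrix(1, 4, 4),
         ev_thresholded = matrix(0, 4, 4),
         bin_centers_ms = c(5, 15, 25, 35), normalized = FALSE),
    class = "crosspred_matrix"
  )
  expect_warning(st <- stability_statistic(xpm, split_ms = 20, n_perm = 1000),
                 "all zero")
  expect_equal(st$p.value, 1)
  expect_equal(st$statistic, 0)
})
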