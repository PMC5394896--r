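test_that("decorrelation removes the mean-level component exactly", {
  spec <- design_spec(n_subjects = 6L, n_trials_per_subject = 36L)
  stim <- stimulus_table(spec, seed = 1)
  # SD within mean level 2 pounds: {0.16, 0.32, 0.48} -> {-0.16, 0, 0.16}
  sd_dec <- decorrelate_metric(stim$y_sd, stim$y_mean)
  lvl2 <- stim$y_mean == 2
  expect_equal(sort(unique(round(sd_dec[lvl2], 10))), c(-0.16, 0, 0.16))
  # zero mean within every level, hence orthogonal to level indicators
  for (m in c(1, 2, 3)) {
    expect_equal(mean(sd_dec[stim$y_mean == m]), 0, tolerance = 1e-12)
    expect_equal(sum(sd_dec * (stim$y_mean == m)), 0, tolerance = 1e-9)
  }
  # idempotent
  expect_equal(decorrelate_metric(sd_dec, stim$y_mean), sd_dec)
  # CV is already balanced: decorrelation leaves the deviations unchanged
  cv_dec <- decorrelate_metric(stim$y_cv, stim$y_mean)
  expect_equal(cv_dec, stim$y_cv - mean(stim$y_cv))
  # constant metric maps to zero
  expect_equal(decorrelate_metric(rep(3, 10), rep(1:2, 5)), rep(0, 10))
})

test_that("AIC from residual sums of squares follows the Gaussian form", {
  # one extra parameter at equal fit costs exactly 2
  expect_equal(aic_from_rss(10, 50, 4) - aic_from_rss(10, 50, 3), 2)
  # halving the rss at n = 100 lowers AIC by 100 log 2
  expect_equal(aic_from_rss(5, 100, 3) - aic_from_rss(10, 100, 3),
               -100 * log(2))
  expect_error(aic_from_rss(0, 10, 1), "positive")
  # differences agree with R's logLik-based AIC for lm fits
  set.seed(33)
  x <- rnorm(40); z <- rnorm(40); y <- x + rnorm(40)
  m1 <- lm(y ~ x); m2 <- lm(y ~ x + z)
  d_mine <- aic_from_rss(sum(resid(m2)^2), 40, 3) -
    aic_from_rss(sum(resid(m1)^2), 40, 2)
  expect_equal(d_mine, AIC(m2) - AIC(m1), tolerance = 1e-10)
  # invariance of differences to the omitted additive constant
  full_const <- function(rss, n, k) {
    n * log(2 * pi) + n * log(rss / n) + n + 2 * (k + 1)
  }
  d_full <- full_const(sum(resid(m2)^2), 40, 3) -
    full_const(sum(resid(m1)^2), 40, 2)
  expect_equal(d_mine, d_full, tolerance = 1e-10)
})

test_that("the generating variability metric wins the pooled AIC comparison", {
  for (gen in c("y_cv", "y_sd_dec", "y_v_dec")) {
    nb <- planted_binned(y_col = gen, beta = 25, p = 3L, B = 6L,
                         trials_per = 36L,
                         seed = 600 + match(gen, c("y_cv", "y_sd_dec", "y_v_dec")))
    res <- compare_variability_metrics(nb$binned, nb$stimuli, scope = "pooled")
    want <- c(y_cv = "cv", y_sd_dec = "sd_dec", y_v_dec = "v_dec")[[gen]]
    expect_equal(attr(res, "winner"), want)
  }
})

test_that("per-channel comparisons expose metric heterogeneity", {
  # channel 1 planted on decorrelated SD, channel 2 on CV
  nb <- null_binned(p = 3L, B = 6L, trials_per = 36L, seed = 610)
  stim <- nb$stimuli
  nb$binned$data[, 1, ] <- nb$binned$data[, 1, ] + 25 * stim$y_sd_dec
  nb$binned$data[, 2, ] <- nb$binned$data[, 2, ] + 25 * (stim$y_cv - 0.16)
  res <- compare_variability_metrics(nb$binned, stim, scope = "per_channel")
  expect_equal(res$best[1], "sd_dec")
  expect_equal(res$best[2], "cv")
})

test_that("all-null data produce no systematic metric winner", {
  winners <- vapply(1:12, function(i) {
    nb <- null_binned(p = 2L, B = 4L, seed = 620 + i)
    attr(compare_variability_metrics(nb$binned, nb$stimuli), "winner")
  }, character(1))
  # "none" should dominate and no metric should win repeatedly on noise
  expect_gte(sum(winners == "none"), 8L)
  expect_lt(max(table(factor(winners[winners != "none"],
                             c("cv", "sd_dec", "v_dec")))), 4L)
})

test_that("preferential encoding separates mean-coding from variability-coding channels", {
  nb <- null_binned(p = 3L, B = 6L, trials_per = 36L, seed = 630)
  stim <- nb$stimuli
  nb$binned$data[, 1, ] <- nb$binned$data[, 1, ] + 1.5 * stim$y_mean
  nb$binned$data[, 2, ] <- nb$binned$data[, 2, ] + 25 * stim$y_cv
  res <- preferential_encoding(nb$binned, stim)
  expect_equal(res$preference[1], "Mag")
  expect_equal(res$preference[2], "Var")
})
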