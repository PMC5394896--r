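test_that("Pillai trace and its F transform match the manova oracle", {
  set.seed(21)
  for (i in 1:12) {
    p <- sample(2:4, 1)
    nb <- planted_binned(beta = runif(1, 0, 0.6), p = p, B = 1L,
                         n_direct = 1L, seed = 100 + i)
    x <- nb$binned$data[, , 1, drop = TRUE]
    y <- nb$stimuli$y_mean
    s <- factor(nb$stimuli$subject)
    mine <- fit_encoding(x, y, s)
    or <- summary(stats::manova(x ~ y + s), test = "Pillai")$stats["y", ]
    expect_equal(mine$pillai, unname(or["Pillai"]), tolerance = 1e-10)
    expect_equal(mine$statistic, unname(or["approx F"]), tolerance = 1e-10)
    expect_equal(mine$df1, unname(or["num Df"]))
    expect_equal(mine$df2, unname(or["den Df"]))
    expect_equal(mine$p.value, unname(or["Pr(>F)"]), tolerance = 1e-10)
  }
})

test_that("categorical feature coding matches the manova oracle too", {
  set.seed(22)
  nb <- planted_binned(beta = 0.4, p = 3L, B = 1L, seed = 31)
  x <- nb$binned$data[, , 1]
  yf <- factor(nb$stimuli$mean_idx)
  s <- factor(nb$stimuli$subject)
  mine <- fit_encoding(x, nb$stimuli$mean_idx, s, coding = "factor")
  or <- summary(stats::manova(x ~ yf + s), test = "Pillai")$stats["yf", ]
  expect_equal(mine$pillai, unname(or["Pillai"]), tolerance = 1e-10)
  expect_equal(mine$statistic, unname(or["approx F"]), tolerance = 1e-10)
  expect_equal(mine$df1, unname(or["num Df"]))
})

test_that("single-channel encoding reduces to the univariate ANOVA", {
  nb <- planted_binned(beta = 0.5, p = 1L, B = 1L, seed = 41)
  x <- matrix(nb$binned$data[, 1, 1], ncol = 1)
  y <- nb$stimuli$y_mean
  s <- factor(nb$stimuli$subject)
  enc <- fit_encoding(x, y, s)
  m_f <- lm(x[, 1] ~ y + s)
  an <- anova(m_f)
  expect_equal(enc$statistic, an["y", "F value"], tolerance = 1e-10)
  expect_equal(enc$p.value, an["y", "Pr(>F)"], tolerance = 1e-10)
  # Pillai equals the partial eta squared of the Y term
  eta2 <- an["y", "Sum Sq"] / (an["y", "Sum Sq"] + an["Residuals", "Sum Sq"])
  expect_equal(enc$pillai, eta2, tolerance = 1e-10)
})

test_that("decoding block F matches the nested-model anova oracle", {
  set.seed(23)
  for (i in 1:6) {
    nb <- planted_binned(beta = runif(1, 0, 0.8), p = 3L, seed = 200 + i,
                         B = 1L)
    x <- nb$binned$data[, , 1]
    y <- nb$stimuli$y_mean
    s <- factor(nb$stimuli$subject)
    dec <- fit_decoding(x, y, s)
    m_r <- lm(y ~ s)
    m_f <- lm(y ~ x + s)
    or <- anova(m_r, m_f)
    expect_equal(dec$statistic, or$F[2], tolerance = 1e-10)
    expect_equal(dec$p.value, or$`Pr(>F)`[2], tolerance = 1e-10)
    expect_equal(dec$r.squared,
                 1 - sum(resid(m_f)^2) / sum(resid(m_r)^2),
                 tolerance = 1e-10)
  }
})

test_that("deterministic decoding gives R squared of one and F/t identities hold", {
  nb <- null_binned(p = 3L, B = 1L, seed = 51)
  x <- nb$binned$data[, , 1]
  # Y an exact linear function of the channels
  y_lin <- drop(x %*% c(1, -2, 0.5))
  dec <- fit_decoding(x, y_lin, nb$stimuli$subject)
  expect_equal(dec$r.squared, 1, tolerance = 1e-10)
  # one channel equal to Y plus noise: decoding F equals squared coefficient t
  set.seed(52)
  y <- nb$stimuli$y_mean
  x1 <- matrix(y + rnorm(length(y)), ncol = 1)
  dec1 <- fit_decoding(x1, y, nb$stimuli$subject)
  m <- lm(y ~ x1 + factor(nb$stimuli$subject))
  tstat <- summary(m)$coefficients[2, 3]
  expect_equal(dec1$statistic, tstat^2, tolerance = 1e-10)
})

test_that("leave-one-out decoding F equals the squared coefficient t", {
  set.seed(24)
  nb <- planted_binned(beta = 0.6, p = 4L, B = 1L, seed = 61)
  x <- nb$binned$data[, , 1]
  y <- nb$stimuli$y_mean
  s <- nb$stimuli$subject
  m <- lm(y ~ x + factor(s))
  tsq <- summary(m)$coefficients[2:5, 3]^2
  df2 <- m$df.residual
  for (k in 1:4) {
    p_loo <- channel_contribution_decoding(x, y, s, k)
    expect_equal(p_loo, unname(pf(tsq[k], 1, df2, lower.tail = FALSE)),
                 tolerance = 1e-10)
  }
  # a channel duplicated (up to tiny noise) by another carries no unique
  # signal: its leave-one-out test is null despite the strong planted effect
  x_dup <- cbind(x, x[, 1] + rnorm(nrow(x), sd = 1e-4))
  expect_gt(channel_contribution_decoding(x_dup, y, s, 1), 0.05)
  expect_gt(channel_contribution_decoding(x_dup, y, s, 5), 0.05)
  # whereas without the duplicate the planted channel is decisive
  expect_lt(channel_contribution_decoding(x, y, s, 1), 1e-4)
})

test_that("single-channel encoding contribution matches lm and finds planted relations", {
  nb <- planted_binned(beta = 0.7, p = 3L, B = 1L, seed = 71)
  y <- nb$stimuli$y_mean
  s <- nb$stimuli$subject
  xk <- nb$binned$data[, 1, 1]
  p_mine <- channel_contribution_encoding(xk, y, s)
  or <- anova(lm(xk ~ y + factor(s)))["y", "Pr(>F)"]
  expect_equal(p_mine, or, tolerance = 1e-10)
  # a channel equal to Y exactly is numerically certain
  expect_lt(channel_contribution_encoding(y, y, s), 1e-100)
  # constant channel: p = 1 with a warning
  expect_warning(p1 <- channel_contribution_encoding(rep(2, length(y)), y, s),
                 "constant")
  expect_equal(p1, 1)
})

test_that("adding a pure-noise channel leaves other channels' encoding tests alone", {
  nb <- planted_binned(beta = 0.5, p = 2L, B = 1L, seed = 81)
  y <- nb$stimuli$y_mean
  s <- nb$stimuli$subject
  p_before <- channel_contribution_encoding(nb$binned$data[, 1, 1], y, s)
  # the single-channel test involves only that channel, so any other
  # channels (noise or not) cannot change it
  set.seed(82)
  p_after <- channel_contribution_encoding(nb$binned$data[, 1, 1], y, s)
  expect_identical(p_before, p_after)
})

test_that("rank-deficient data matrices are rejected with the offending channel", {
  nb <- null_binned(p = 3L, B = 1L, seed = 91)
  x <- nb$binned$data[, , 1]
  x[, 3] <- x[, 1] + x[, 2]
  y <- nb$stimuli$y_mean
  s <- nb$stimuli$subject
  expect_error(fit_encoding(x, y, s), "rank deficient")
  expect_error(fit_decoding(x, y, s), "rank deficient")
})

test_that("encoding and decoding p-values are uniform under the null", {
  # simulated null bins; KS test against uniform at alpha = 0.01
  set.seed(25)
  nb <- null_binned(p = 3L, B = 1L, seed = 95)
  y <- nb$stimuli$y_mean
  s <- nb$stimuli$subject
  n <- length(y)
  pvals_enc <- numeric(400)
  pvals_dec <- numeric(400)
  for (i in seq_len(400)) {
    x <- matrix(rnorm(n * 3), n, 3)
    pvals_enc[i] <- fit_encoding(x, y, s)$p.value
    pvals_dec[i] <- fit_decoding(x, y, s)$p.value
  }
  expect_gt(stats::ks.test(pvals_enc, "punif")$p.value, 0.01)
  expect_gt(stats::ks.test(pvals_dec, "punif")$p.value, 0.01)
})

test_that("fit_trace agrees with the per-bin fits", {
  nb <- planted_binned(beta = 0.4, p = 3L, B = 5L, seed = 97)
  y <- nb$stimuli$y_mean
  tr <- fit_trace(nb$binned, y)
  for (b in c(1L, 3L, 5L)) {
    enc <- fit_encoding(nb$binned$data[, , b], y, nb$stimuli$subject)
    expect_equal(tr$statistic[b], enc$statistic, tolerance = 1e-10)
    expect_equal(tr$p[b], enc$p.value, tolerance = 1e-10)
  }
})
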