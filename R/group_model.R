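#' Per-time-bin encoding MANOVA on group-concatenated data
#'
#' Fits the multivariate linear model `X ~ Y + S`, where `X` is the
#' trials-by-channels data matrix of one time bin pooled over all subjects,
#' `Y` the per-trial stimulus feature and `S` per-subject fixed intercepts.
#' The hypothesis (H) and error (E) cross-product matrices for the `Y` term
#' give the Pillai-Bartlett trace `V = sum(lambda_i / (1 + lambda_i))` over
#' the eigenvalues of `E^{-1} H`, tested with the standard F approximation
#' (exact for a single-degree-of-freedom hypothesis).
#'
#' @param x Numeric matrix, trials x channels.
#' @param y Per-trial feature values. Numeric by default; with
#'   `coding = "factor"` the feature enters as a categorical term.
#' @param subject Per-trial subject labels.
#' @param coding `"numeric"` (single-df covariate, the default) or
#'   `"factor"`.
#' @param channel_p Also compute per-channel contribution p-values
#'   (uncorrected single-channel regressions `X_k ~ Y + S`)?
#' @return List with `pillai`, `statistic` (approximate F), `df1`, `df2`,
#'   `p.value`, `ev` (proportion of total within-subject variance explained
#'   by `Y`, `tr(H)/tr(H + E)`), and optionally `channel_p`.
#' @export
fit_encoding <- function(x, y, subject, coding = c("numeric", "factor"),
                         channel_p = FALSE) {
  coding <- match.arg(coding)
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  des <- encoding_design(y, subject, n, coding)
  if (n < p + des$rank_reduced + ncol(des$Yd) + 1L) {
    stop("fewer trials than model parameters plus channels; cannot fit MANOVA")
  }
  # residualize against the subject intercepts (reduced model)
  Xr <- qr.resid(des$qr_reduced, x)
  Yr <- qr.resid(des$qr_reduced, des$Yd)
  qy <- qr(Yr)
  if (qy$rank < ncol(Yr)) stop("feature term is collinear with the subject intercepts")
  Xf <- qr.resid(qy, Xr)                 # residuals of the full model
  E <- crossprod(Xf)
  H <- crossprod(Xr) - E
  # collinear channels make E singular
  qe <- qr(E)
  if (qe$rank < p) {
    stop(sprintf("data matrix is rank deficient; offending channel(s): %s",
                 paste(setdiff(seq_len(p), sort(qe$pivot[seq_len(qe$rank)])),
                       collapse = ", ")))
  }
  eig <- Re(eigen(solve(E, H), only.values = TRUE)$values)
  eig <- pmax(eig, 0)
  q <- ncol(des$Yd)                      # hypothesis df
  df_res <- n - des$rank_reduced - q
  V <- sum(eig / (1 + eig))
  s <- min(p, q)
  m <- 0.5 * (abs(p - q) - 1)
  nn <- 0.5 * (df_res - p - 1)
  df1 <- s * (2 * m + s + 1)
  df2 <- s * (2 * nn + s + 1)
  Fv <- (df2 / df1) * V / (s - V)
  out <- list(pillai = V, statistic = Fv, df1 = df1, df2 = df2,
              p.value = pf(Fv, df1, df2, lower.tail = FALSE),
              ev = sum(diag(H)) / sum(diag(H + E)))
  if (channel_p) {
    out$channel_p <- vapply(seq_len(p), function(k) {
      channel_contribution_encoding(x[, k], y, subject, coding = coding)
    }, numeric(1))
  }
  out
}

encoding_design <- function(y, subject, n, coding) {
  if (length(y) != n || length(subject) != n) {
    stop("y and subject must have one entry per trial")
  }
  S <- stats::model.matrix(~ 0 + factor(subject))
  Yd <- if (coding == "numeric") {
    matrix(as.numeric(y), ncol = 1L)
  } else {
    stats::model.matrix(~ factor(y))[, -1L, drop = FALSE]
  }
  qs <- qr(S)
  list(Yd = Yd, qr_reduced = qs, rank_reduced = qs$rank)
}

#' Per-time-bin decoding ANOVA
#'
#' Fits `Y ~ X + S` by least squares and tests the block of all channel
#' coefficients against the subject-intercepts-only model with an F test.
#' `r.squared` is the partial R-squared of the channel block
#' (`1 - RSS_full / RSS_subject-only`).
#'
#' @inheritParams fit_encoding
#' @param channel_p Also compute per-channel leave-one-out F-test p-values?
#' @return List with `statistic`, `df1`, `df2`, `p.value`, `r.squared`, and
#'   optionally `channel_p`.
#' @export
fit_decoding <- function(x, y, subject, channel_p = FALSE) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  des <- encoding_design(y, subject, n, "numeric")
  if (n <= p + des$rank_reduced) stop("fewer trials than model parameters")
  Xr <- qr.resid(des$qr_reduced, x)
  Yr <- qr.resid(des$qr_reduced, des$Yd)
  qx <- qr(Xr)
  if (qx$rank < p) {
    stop(sprintf("data matrix is rank deficient; offending channel(s): %s",
                 paste(setdiff(seq_len(p), sort(qx$pivot[seq_len(qx$rank)])),
                       collapse = ", ")))
  }
  rss_r <- sum(Yr^2)
  res_f <- qr.resid(qx, Yr)
  rss_f <- sum(res_f^2)
  df2 <- n - des$rank_reduced - p
  Fv <- ((rss_r - rss_f) / p) / (rss_f / df2)
  out <- list(statistic = Fv, df1 = p, df2 = df2,
              p.value = pf(Fv, p, df2, lower.tail = FALSE),
              r.squared = 1 - rss_f / rss_r)
  if (channel_p) {
    out$channel_p <- vapply(seq_len(p), function(k) {
      channel_contribution_decoding(x, y, subject, k)
    }, numeric(1))
  }
  out
}

#' Encoding contribution of a single channel
#'
#' Tests the feature term of the regression `X_k ~ Y + S` for one channel;
#' the p-value is uncorrected. Detects any marginal relation between channel
#' and feature, whether direct or mediated by another channel.
#'
#' @param x_k Numeric vector, one channel's data in one bin.
#' @param y,subject,coding As in [fit_encoding()].
#' @return The p-value of the feature term (1 with a warning for a constant
#'   channel).
#' @export
channel_contribution_encoding <- function(x_k, y, subject,
                                          coding = c("numeric", "factor")) {
  coding <- match.arg(coding)
  n <- length(x_k)
  des <- encoding_design(y, subject, n, coding)
  xr <- qr.resid(des$qr_reduced, matrix(x_k, ncol = 1L))
  if (sum(xr^2) < .Machine$double.eps * n) {
    warning("channel is constant within subjects; p-value set to 1")
    return(1)
  }
  Yr <- qr.resid(des$qr_reduced, des$Yd)
  qy <- qr(Yr)
  res <- qr.resid(qy, xr)
  rss_f <- sum(res^2)
  rss_r <- sum(xr^2)
  q <- ncol(des$Yd)
  df2 <- n - des$rank_reduced - q
  Fv <- ((rss_r - rss_f) / q) / (rss_f / df2)
  pf(Fv, q, df2, lower.tail = FALSE)
}

#' Decoding contribution of a single channel (leave-one-out F test)
#'
#' Compares the full decoding model `Y ~ X + S` with the reduced model
#' lacking channel `k` by a 1-df F test. Equals the squared t statistic of
#' channel `k`'s coefficient in the full model. A channel only carrying the
#' feature via another channel contributes nothing unique and tests null;
#' a channel correlated with an encoding channel's noise ("brain state
#' context") improves the prediction and tests significant despite zero
#' marginal dependence on the feature.
#'
#' @param x Trials x channels matrix.
#' @param y,subject As in [fit_encoding()].
#' @param k Channel index to leave out.
#' @return The p-value of the leave-one-out F test.
#' @export
channel_contribution_decoding <- function(x, y, subject, k) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  stopifnot(k >= 1L, k <= p)
  des <- encoding_design(y, subject, n, "numeric")
  Xr <- qr.resid(des$qr_reduced, x)
  Yr <- qr.resid(des$qr_reduced, des$Yd)
  rss_f <- sum(qr.resid(qr(Xr), Yr)^2)
  rss_r <- sum(qr.resid(qr(Xr[, -k, drop = FALSE]), Yr)^2)
  df2 <- n - des$rank_reduced - p
  Fv <- (rss_r - rss_f) / (rss_f / df2)
  pf(Fv, 1, df2, lower.tail = FALSE)
}

# ---- fast per-bin statistics used by permutation machinery -----------------
#
# For a numeric (single-df) feature the encoding F and the decoding block F
# coincide: after within-subject centering, with T = X'X, c = X'y and
# yty = y'y, the Pillai trace is V = c' T^-1 c / yty and
# F = ((n - n_sub - p)/p) * V/(1 - V) with df (p, n - n_sub - p).
# Permuting y within subject leaves yty and T unchanged, so all permutation
# statistics come from one cross-product per bin.

# Precompute per-bin quantities for fast repeated statistics.
bin_precompute <- function(binned) {
  d <- binned$data
  n <- dim(d)[1L]; p <- dim(d)[2L]; B <- dim(d)[3L]
  lapply(seq_len(B), function(b) {
    Xt <- center_by_subject(d[, , b, drop = TRUE], binned$subject)
    if (p == 1L) Xt <- matrix(Xt, ncol = 1L)
    R <- chol(crossprod(Xt))
    list(Xt = Xt, R = R)
  })
}

# Pillai V for every column of ymat (already subject-centered), one bin.
bin_pillai <- function(pre, ymat, yty) {
  cc <- crossprod(pre$Xt, ymat)                       # p x n_perm
  w <- backsolve(pre$R, cc, transpose = TRUE)
  colSums(w^2) / yty
}

pillai_to_f <- function(V, n, p, n_sub) {
  df2 <- n - n_sub - p
  list(f = (df2 / p) * V / (1 - V), df1 = p, df2 = df2)
}

# Draw a within-subject permutation of indices 1..n.
permute_within_subject <- function(subject) {
  idx <- seq_along(subject)
  for (s in unique(subject)) {
    i <- idx[subject == s]
    idx[subject == s] <- sample(i)
  }
  idx
}

#' Encoding/decoding statistic traces over all time bins
#'
#' Convenience wrapper computing, per bin, the overall model test for a
#' numeric feature (for which the encoding MANOVA F and the decoding block F
#' coincide) plus the explained variance.
#'
#' @param binned A `binned_dataset`.
#' @param y Per-trial numeric feature values.
#' @param model `"encoding"` or `"decoding"` (statistics coincide for a
#'   numeric single-df feature; the label is recorded in the output).
#' @return Data frame with one row per bin: `bin`, `bin_center_ms`,
#'   `statistic`, `df1`, `df2`, `p`, `ev`.
#' @export
fit_trace <- function(binned, y, model = c("encoding", "decoding")) {
  model <- match.arg(model)
  stopifnot(inherits(binned, "binned_dataset"))
  subject <- binned$subject
  n <- dim(binned$data)[1L]; p <- dim(binned$data)[2L]
  n_sub <- length(unique(subject))
  yt <- center_by_subject(matrix(as.numeric(y), ncol = 1L), subject)
  yty <- sum(yt^2)
  if (yty <= 0) stop("feature is constant within subjects")
  pre <- bin_precompute(binned)
  rows <- lapply(seq_along(pre), function(b) {
    V <- bin_pillai(pre[[b]], yt, yty)
    ff <- pillai_to_f(V, n, p, n_sub)
    sst <- sum(pre[[b]]$Xt^2)
    cc <- crossprod(pre[[b]]$Xt, yt)
    # encoding: share of total within-subject data variance explained by Y;
    # decoding: partial R^2 of the channel block (equals V here)
    ev <- if (model == "encoding") drop(crossprod(cc)) / yty / sst else V
    data.frame(bin = b, bin_center_ms = binned$bin_centers_ms[b],
               statistic = ff$f, df1 = ff$df1, df2 = ff$df2,
               p = pf(ff$f, ff$df1, ff$df2, lower.tail = FALSE),
               ev = ev)
  })
  out <- do.call(rbind, rows)
  attr(out, "model") <- model
  out
}
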