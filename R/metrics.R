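#' Decorrelate a variability metric from mean reward
#'
#' SD and variance of the reward distribution scale with mean reward in a
#' factorial design crossing mean with coefficient of variation. Subtracting
#' the metric's mean within each mean-reward level leaves values with
#' exactly zero mean in every level, hence zero correlation with any
#' function of the mean level. The operation is idempotent, and a metric
#' already orthogonal to mean level (such as CV in a balanced design) keeps
#' its within-level deviations unchanged.
#'
#' @param values Per-trial metric values.
#' @param mean_level Per-trial mean-reward level.
#' @return Per-trial decorrelated metric values.
#' @export
decorrelate_metric <- function(values, mean_level) {
  stopifnot(length(values) == length(mean_level))
  values - stats::ave(values, mean_level)
}

#' Akaike Information Criterion from a residual sum of squares
#'
#' Gaussian-likelihood form with constant terms omitted:
#' `AIC = n * log(rss / n) + 2k`. Differences between models fitted to the
#' same data are unaffected by the omitted additive constant.
#'
#' @param rss Residual sum of squares (> 0).
#' @param n Number of observations (> k).
#' @param k Number of estimated mean parameters.
#' @return The AIC value.
#' @export
aic_from_rss <- function(rss, n, k) {
  stopifnot(n > k)
  if (any(rss <= 0)) stop("rss must be positive (a saturated model has no finite AIC)")
  n * log(rss / n) + 2 * k
}

# Per-bin residual sums of squares of the encoding model X ~ y + S, using the
# subject-centered identity RSS = SST - c'c / y'y (total over channels).
encoding_rss_trace <- function(binned, y, channel = NULL) {
  subject <- binned$subject
  yt <- center_by_subject(matrix(as.numeric(y), ncol = 1L), subject)
  yty <- sum(yt^2)
  if (yty <= 0) stop("metric is constant within subjects")
  B <- dim(binned$data)[3L]
  vapply(seq_len(B), function(b) {
    xb <- binned$data[, , b, drop = TRUE]
    if (is.null(dim(xb))) xb <- matrix(xb, ncol = 1L)
    if (!is.null(channel)) xb <- xb[, channel, drop = FALSE]
    xt <- center_by_subject(xb, subject)
    cc <- crossprod(xt, yt)
    sum(xt^2) - drop(crossprod(cc)) / yty
  }, numeric(1))
}

#' Compare candidate reward-variability metrics by summed AIC
#'
#' Fits, per time bin, the encoding model with each candidate metric as the
#' predictor -- coefficient of variation (CV), SD decorrelated from mean
#' reward, and variance decorrelated from mean reward -- converts residual
#' sums of squares to AIC, and sums over the analyzed bins. `scope =
#' "pooled"` uses the total multivariate residual sum of squares over all
#' channels (observations are trial-channel cells); `scope = "per_channel"`
#' compares the metrics within each single-channel regression. A metric is
#' declared the winner only when its summed AIC beats every other by more
#' than `delta` (default 3).
#'
#' @param binned A `binned_dataset`.
#' @param stimuli Stimulus table with columns `y_mean`, `y_cv`, `y_sd`,
#'   `y_v` (as produced by [stimulus_table()]).
#' @param scope `"pooled"` or `"per_channel"`.
#' @param bins Indices of bins entering the sum (e.g. cluster-significant
#'   bins); default all bins.
#' @param delta Minimum summed-AIC margin to declare a preference.
#' @return For `"pooled"`: data frame of summed AIC per metric with a
#'   `winner` attribute. For `"per_channel"`: data frame with one row per
#'   channel (`channel`, AIC per metric, `best`, `margin`).
#' @export
compare_variability_metrics <- function(binned, stimuli,
                                        scope = c("pooled", "per_channel"),
                                        bins = NULL, delta = 3) {
  scope <- match.arg(scope)
  stopifnot(inherits(binned, "binned_dataset"))
  n <- dim(binned$data)[1L]; p <- dim(binned$data)[2L]
  bins <- bins %||% seq_len(dim(binned$data)[3L])
  n_sub <- length(unique(binned$subject))
  metrics <- list(
    cv = stimuli$y_cv,
    sd_dec = decorrelate_metric(stimuli$y_sd, stimuli$y_mean),
    v_dec = decorrelate_metric(stimuli$y_v, stimuli$y_mean)
  )
  if (scope == "pooled") {
    k <- p * (1 + n_sub)
    aic <- vapply(metrics, function(m) {
      rss <- encoding_rss_trace(binned, m)[bins]
      sum(aic_from_rss(rss, n = n * p, k = k))
    }, numeric(1))
    res <- data.frame(metric = names(aic), aic_sum = unname(aic),
                      stringsAsFactors = FALSE)
    ord <- order(res$aic_sum)
    margin <- res$aic_sum[ord[2L]] - res$aic_sum[ord[1L]]
    attr(res, "winner") <- if (margin > delta) res$metric[ord[1L]] else "none"
    attr(res, "margin") <- margin
    res
  } else {
    k <- 1 + n_sub
    rows <- lapply(seq_len(p), function(ch) {
      aic <- vapply(metrics, function(m) {
        rss <- encoding_rss_trace(binned, m, channel = ch)[bins]
        sum(aic_from_rss(rss, n = n, k = k))
      }, numeric(1))
      ord <- order(aic)
      margin <- aic[ord[2L]] - aic[ord[1L]]
      data.frame(channel = ch, aic_cv = aic[["cv"]], aic_sd = aic[["sd_dec"]],
                 aic_v = aic[["v_dec"]],
                 best = if (margin > delta) names(metrics)[ord[1L]] else "none",
                 margin = margin, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
}

#' Preferential encoding of mean reward versus variability per channel
#'
#' For each channel, sums AIC across the analyzed bins for single-channel
#' encoding models with mean reward versus the variability metric as
#' predictor, and declares a preference (`Mag` or `Var`) when the summed
#' AIC difference exceeds `delta`; `none` otherwise.
#'
#' @param binned A `binned_dataset`.
#' @param stimuli Stimulus table (`y_mean` and the variability column).
#' @param variability Name of the variability column (default `"y_cv"`).
#' @param bins Bins entering the sum; default all.
#' @param delta Minimum AIC margin (default 3).
#' @return Data frame: `channel`, `aic_mag`, `aic_var`, `preference`.
#' @export
preferential_encoding <- function(binned, stimuli, variability = "y_cv",
                                  bins = NULL, delta = 3) {
  stopifnot(inherits(binned, "binned_dataset"))
  n <- dim(binned$data)[1L]; p <- dim(binned$data)[2L]
  bins <- bins %||% seq_len(dim(binned$data)[3L])
  n_sub <- length(unique(binned$subject))
  k <- 1 + n_sub
  y_mag <- stimuli$y_mean
  y_var <- stimuli[[variability]]
  rows <- lapply(seq_len(p), function(ch) {
    a_mag <- sum(aic_from_rss(encoding_rss_trace(binned, y_mag, channel = ch)[bins],
                              n = n, k = k))
    a_var <- sum(aic_from_rss(encoding_rss_trace(binned, y_var, channel = ch)[bins],
                              n = n, k = k))
    pref <- if (abs(a_mag - a_var) <= delta) "none" else if (a_mag < a_var) "Mag" else "Var"
    data.frame(channel = ch, aic_mag = a_mag, aic_var = a_var,
               preference = pref, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
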