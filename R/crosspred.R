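#' Cross-prediction (temporal generalization) of encoding models
#'
#' Fits the encoding model at every source time bin and scores how well its
#' feature pattern predicts the data at every target bin. After
#' within-subject centering (subject intercepts are nuisance and are refit
#' at the target bin), the source-bin coefficient vector `b_s` predicts the
#' target data as `y * b_s'`, and explained variance is the multivariate
#' `R^2 = 1 - SSR/SST` summed over channels, with `SST` about subject means;
#' it is negative when the transferred pattern mispredicts. Per target bin,
#' a permutation null is built by permuting trial labels (within subject)
#' and recomputing the explained variance; `p` is the proportion of null
#' values at least as large as the observed one (with add-one smoothing).
#' Entries with `p > alpha` or negative explained variance are set to zero
#' in the thresholded matrix.
#'
#' An optional second feature (`y_eval`) scores models fitted on `y` against
#' data arranged by another feature, e.g. to test whether mean-reward models
#' explain variability-coded data (possibly sign-flipped).
#'
#' @param binned A `binned_dataset`.
#' @param y Per-trial numeric feature the models are fitted on.
#' @param n_perm Number of trial-label permutations (>= 100; default 1000).
#' @param alpha Zeroing threshold on the permutation p-value.
#' @param seed Integer seed.
#' @param y_eval Optional numeric feature used as the design at the target
#'   bins (defaults to `y`, the ordinary within-feature cross-prediction).
#' @return An object of class `crosspred_matrix`: list with `ev` (source x
#'   target explained variance), `p` (permutation p-values),
#'   `ev_thresholded`, `bin_centers_ms`, `normalized = FALSE`, and settings.
#' @export
cross_predict <- function(binned, y, n_perm = 1000L, alpha = 0.05,
                          seed = 1L, y_eval = NULL) {
  stopifnot(inherits(binned, "binned_dataset"), n_perm >= 100L)
  subject <- binned$subject
  n <- dim(binned$data)[1L]; p <- dim(binned$data)[2L]
  B <- dim(binned$data)[3L]
  if (n <= length(unique(subject)) + p) {
    stop("fewer trials than model parameters at the target bins")
  }
  yt <- center_by_subject(matrix(as.numeric(y), ncol = 1L), subject)
  yty <- sum(yt^2)
  if (yty <= 0) stop("feature is constant within subjects")
  ye <- if (is.null(y_eval)) yt else {
    center_by_subject(matrix(as.numeric(y_eval), ncol = 1L), subject)
  }
  yety <- sum(ye^2)
  with_seed(seed, {
    # per-bin centered data, cross-products and totals
    Xt <- lapply(seq_len(B), function(b) {
      xb <- center_by_subject(binned$data[, , b, drop = TRUE], subject)
      if (p == 1L) xb <- matrix(xb, ncol = 1L) else xb
    })
    cc <- lapply(Xt, function(x) crossprod(x, yt))       # fit cross-products
    sst <- vapply(Xt, function(x) sum(x^2), numeric(1))
    bmat <- vapply(cc, function(ci) drop(ci) / yty, numeric(p))  # p x B coefs
    if (p == 1L) bmat <- matrix(bmat, nrow = 1L)
    # permuted evaluation designs (same label permutations for every bin)
    YP <- vapply(seq_len(n_perm), function(i) ye[permute_within_subject(subject)],
                 numeric(n))
    ev <- matrix(0, B, B)
    pmat <- matrix(1, B, B)
    for (tgt in seq_len(B)) {
      Ct <- crossprod(Xt[[tgt]], ye)                     # p x 1, observed
      Cp <- crossprod(Xt[[tgt]], YP)                     # p x n_perm
      for (src in seq_len(B)) {
        b_s <- bmat[, src]
        bb <- sum(b_s^2)
        ev_obs <- (2 * sum(b_s * Ct) - yety * bb) / sst[tgt]
        ev_perm <- (2 * drop(crossprod(b_s, Cp)) - yety * bb) / sst[tgt]
        ev[src, tgt] <- ev_obs
        pmat[src, tgt] <- (1 + sum(ev_perm >= ev_obs)) / (n_perm + 1)
      }
    }
    thr <- ev
    thr[pmat > alpha | ev < 0] <- 0
    structure(
      list(ev = ev, p = pmat, ev_thresholded = thr,
           bin_centers_ms = binned$bin_centers_ms,
           normalized = FALSE, n_perm = n_perm, alpha = alpha, seed = seed,
           cross_feature = !is.null(y_eval)),
      class = "crosspred_matrix"
    )
  })
}

#' Cross-feature cross-prediction
#'
#' Scores encoding models fitted on one feature against data arranged by
#' another feature (optionally sign-flipped), using the same explained
#' variance and permutation machinery as [cross_predict()]. With
#' `y_eval = y_fit` this reduces exactly to the within-feature matrix.
#'
#' @param binned A `binned_dataset`.
#' @param y_fit Feature the encoding models are fitted on.
#' @param y_eval Feature defining the evaluation design at the target bins.
#' @param ... Passed to [cross_predict()] (`n_perm`, `alpha`, `seed`).
#' @return A `crosspred_matrix`.
#' @export
cross_predict_between_features <- function(binned, y_fit, y_eval, ...) {
  cross_predict(binned, y_fit, y_eval = y_eval, ...)
}

#' Normalize a cross-prediction matrix by the source-bin model fit
#'
#' Divides each row (one source model) by its diagonal entry, the explained
#' variance of the model in the bin where it was fitted, so that
#' cross-prediction strength is expressed relative to the in-bin fit. Rows
#' whose diagonal is zero (after thresholding) are left at zero and flagged.
#'
#' @param xpm A `crosspred_matrix`.
#' @return The matrix with `ev_thresholded` row-normalized,
#'   `normalized = TRUE`, and `zero_rows` listing skipped source bins.
#' @export
normalize_by_source_fit <- function(xpm) {
  stopifnot(inherits(xpm, "crosspred_matrix"))
  d <- diag(xpm$ev_thresholded)
  zero <- which(d <= 0)
  out <- xpm$ev_thresholded
  for (i in seq_along(d)) {
    if (d[i] > 0) out[i, ] <- out[i, ] / d[i]
  }
  xpm$ev_thresholded <- out
  xpm$normalized <- TRUE
  xpm$zero_rows <- zero
  xpm
}

#' Half-window temporal-stability statistic of a cross-prediction matrix
#'
#' Sums the off-diagonal thresholded cross-prediction values whose source
#' and target bins both fall in the second half of the anticipation window
#' and subtracts the corresponding first-half sum. Significance is assessed
#' by jointly permuting the time-bin labels of rows and columns and
#' recomputing the difference; the same permutation machinery applied to the
#' diagonal tests for a difference in in-bin encoding strength.
#'
#' @param xpm A `crosspred_matrix` (thresholded entries are used).
#' @param split_ms Boundary between the two halves, ms (default 1000).
#' @param n_perm Number of time-label permutations (>= 1000; default 1e5).
#' @param seed Integer seed.
#' @param alternative `"greater"` (default: more stable second half) or
#'   `"two.sided"`.
#' @return An object of class `stability_result`: list with `statistic`,
#'   `p.value`, `diag_statistic`, `diag_p.value`, `split_ms`, `n_perm`,
#'   `normalized` (carried over from the input matrix).
#' @export
stability_statistic <- function(xpm, split_ms = 1000, n_perm = 1e5L,
                                seed = 1L, alternative = c("greater", "two.sided")) {
  stopifnot(inherits(xpm, "crosspred_matrix"), n_perm >= 1000L)
  alternative <- match.arg(alternative)
  M <- xpm$ev_thresholded
  B <- nrow(M)
  centers <- xpm$bin_centers_ms
  second <- centers >= split_ms
  if (!any(second) || all(second)) {
    stop("split_ms must fall inside the analysis window")
  }
  offdiag_block <- function(M, members) {
    sum(M[members, members]) - sum(diag(M)[members])
  }
  diag_block <- function(M, members) sum(diag(M)[members])
  if (all(M == 0)) {
    warning("cross-prediction matrix is all zero; stability p-value set to 1")
    return(structure(
      list(statistic = 0, p.value = 1, diag_statistic = 0, diag_p.value = 1,
           split_ms = split_ms, n_perm = n_perm, normalized = xpm$normalized),
      class = "stability_result"
    ))
  }
  obs <- offdiag_block(M, second) - offdiag_block(M, !second)
  obs_d <- diag_block(M, second) - diag_block(M, !second)
  dM <- diag(M)
  with_seed(seed, {
    null_off <- numeric(n_perm)
    null_diag <- numeric(n_perm)
    idx2 <- which(second); idx1 <- which(!second)
    for (i in seq_len(n_perm)) {
      pm <- sample.int(B)
      s2 <- pm[idx2]; s1 <- pm[idx1]
      null_off[i] <- (sum(M[s2, s2]) - sum(dM[s2])) -
        (sum(M[s1, s1]) - sum(dM[s1]))
      null_diag[i] <- sum(dM[s2]) - sum(dM[s1])
    }
    pval <- function(null, obs) {
      if (alternative == "greater") {
        (1 + sum(null >= obs)) / (n_perm + 1)
      } else {
        (1 + sum(abs(null) >= abs(obs))) / (n_perm + 1)
      }
    }
    structure(
      list(statistic = obs, p.value = pval(null_off, obs),
           diag_statistic = obs_d, diag_p.value = pval(null_diag, obs_d),
           split_ms = split_ms, n_perm = n_perm, normalized = xpm$normalized),
      class = "stability_result"
    )
  })
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf(
    "stability_result: off-diagonal (second - first half) = %.4g, p = %.4g\n",
    x$statistic, x$p.value))
  cat(sprintf("  diagonal = %.4g, p = %.4g (%d permutations%s)\n",
              x$diag_statistic, x$diag_p.value, x$n_perm,
              if (isTRUE(x$normalized)) ", source-fit normalized" else ""))
  invisible(x)
}
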