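#' Cluster-level permutation correction over time bins
#'
#' Computes the per-bin model statistic (encoding MANOVA / decoding ANOVA F
#' for a numeric feature), forms candidate clusters as maximal runs of
#' consecutive bins with uncorrected `p < cluster_alpha`, and scores each
#' cluster by its mass (sum of F values). The null distribution of the
#' maximum cluster mass is built by permuting trial labels of `Y` within
#' subject (preserving the subject-intercept structure), and each observed
#' cluster receives `p = (1 + #{null maxima >= mass}) / (n_perm + 1)`.
#'
#' @param binned A `binned_dataset`.
#' @param y Per-trial numeric feature values.
#' @param model `"encoding"` or `"decoding"`.
#' @param n_perm Number of permutations (>= 100; default 1000).
#' @param cluster_alpha Cluster-forming threshold on uncorrected p.
#' @param alpha Cluster-level significance threshold.
#' @param seed Integer seed.
#' @return An object of class `cluster_result`: list with `trace` (per-bin
#'   statistics from [fit_trace()]), `clusters` (data frame: `start_bin`,
#'   `end_bin`, `mass`, `p`), `sig_bins` (indices of bins in significant
#'   clusters), `mask` (logical per bin), and the settings used.
#' @export
cluster_permutation <- function(binned, y, model = c("encoding", "decoding"),
                                n_perm = 1000L, cluster_alpha = 0.05,
                                alpha = 0.05, seed = 1L) {
  model <- match.arg(model)
  stopifnot(inherits(binned, "binned_dataset"),
            n_perm >= 100L, cluster_alpha > 0, cluster_alpha < 1,
            alpha > 0, alpha < 1)
  subject <- binned$subject
  n <- dim(binned$data)[1L]; p <- dim(binned$data)[2L]
  B <- dim(binned$data)[3L]
  n_sub <- length(unique(subject))
  yt <- center_by_subject(matrix(as.numeric(y), ncol = 1L), subject)
  yty <- sum(yt^2)
  if (yty <= .Machine$double.eps * n) {
    stop("feature labels are constant within subjects; permutation test is degenerate")
  }
  with_seed(seed, {
    pre <- bin_precompute(binned)
    # all permutations at once: n x n_perm matrix of permuted labels
    YP <- vapply(seq_len(n_perm), function(i) yt[permute_within_subject(subject)],
                 numeric(n))
    fcrit_thresh <- stats::qf(cluster_alpha, p, n - n_sub - p, lower.tail = FALSE)
    Fobs <- numeric(B)
    Fperm <- matrix(0, B, n_perm)
    for (b in seq_len(B)) {
      Vo <- bin_pillai(pre[[b]], yt, yty)
      Fobs[b] <- pillai_to_f(Vo, n, p, n_sub)$f
      Vp <- bin_pillai(pre[[b]], YP, yty)
      Fperm[b, ] <- pillai_to_f(Vp, n, p, n_sub)$f
    }
    obs_clusters <- find_clusters(Fobs, fcrit_thresh)
    null_max <- apply(Fperm, 2L, function(fv) {
      cl <- find_clusters(fv, fcrit_thresh)
      if (nrow(cl) == 0L) 0 else max(cl$mass)
    })
    if (nrow(obs_clusters) > 0L) {
      obs_clusters$p <- vapply(obs_clusters$mass, function(m) {
        (1 + sum(null_max >= m)) / (n_perm + 1)
      }, numeric(1))
    } else {
      obs_clusters$p <- numeric(0)
    }
    mask <- rep(FALSE, B)
    for (i in seq_len(nrow(obs_clusters))) {
      if (obs_clusters$p[i] < alpha) {
        mask[obs_clusters$start_bin[i]:obs_clusters$end_bin[i]] <- TRUE
      }
    }
    trace <- fit_trace(binned, y, model = model)
    structure(
      list(trace = trace, clusters = obs_clusters,
           sig_bins = which(mask), mask = mask,
           model = model, n_perm = n_perm,
           cluster_alpha = cluster_alpha, alpha = alpha, seed = seed),
      class = "cluster_result"
    )
  })
}

# Maximal runs of consecutive supra-threshold bins, scored by mass.
find_clusters <- function(stat, threshold) {
  above <- stat > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(
    start_bin = starts[keep],
    end_bin = ends[keep],
    mass = vapply(keep, function(i) sum(stat[starts[i]:ends[i]]), numeric(1))
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result (%s model, %d permutations):\n", x$model, x$n_perm))
  if (nrow(x$clusters) == 0L) {
    cat("  no supra-threshold clusters\n")
  } else {
    print(x$clusters)
  }
  invisible(x)
}

#' Causal classification of a channel from paired contribution p-values
#'
#' Implements the decision rules combining the per-channel encoding
#' contribution test and the leave-one-out decoding test. With significance
#' threshold `alpha` (strict: significant means `p < alpha`) and
#' indeterminate band `[alpha, band_hi]`:
#' * encoding significant, decoding significant: `direct`
#' * encoding significant, decoding in the band: `possible_direct`
#' * encoding significant, decoding above the band: `indirect`
#' * decoding significant, encoding in the band: `possible_direct`
#' * decoding significant, encoding above the band: `context`
#' * both non-significant: `undetermined`
#'
#' @param p_enc Encoding contribution p-value.
#' @param p_dec Leave-one-out decoding p-value.
#' @param alpha Significance threshold (default 0.05).
#' @param band_hi Upper edge of the indeterminate band (default 0.10;
#'   p-values equal to `band_hi` fall inside the band).
#' @return One of `"direct"`, `"possible_direct"`, `"indirect"`,
#'   `"context"`, `"undetermined"`. Vectorized over `p_enc`/`p_dec`.
#' @export
classify_channel <- function(p_enc, p_dec, alpha = 0.05, band_hi = 0.10) {
  stopifnot(alpha < band_hi)
  n <- max(length(p_enc), length(p_dec))
  p_enc <- rep_len(p_enc, n); p_dec <- rep_len(p_dec, n)
  enc_sig <- p_enc < alpha
  dec_sig <- p_dec < alpha
  out <- rep("undetermined", n)
  out[enc_sig & dec_sig] <- "direct"
  out[enc_sig & !dec_sig & p_dec <= band_hi] <- "possible_direct"
  out[enc_sig & p_dec > band_hi] <- "indirect"
  out[dec_sig & !enc_sig & p_enc <= band_hi] <- "possible_direct"
  out[dec_sig & !enc_sig & p_enc > band_hi] <- "context"
  out
}

#' Classify every channel at every cluster-significant bin
#'
#' Runs the single-channel encoding contribution test and the leave-one-out
#' decoding test for each channel in each bin where the overall multivariate
#' model is significant after cluster correction, and applies
#' [classify_channel()]. Bins outside significant clusters are labelled
#' `undetermined` with `NA` p-values.
#'
#' @param binned A `binned_dataset`.
#' @param y Per-trial numeric feature values.
#' @param subject Per-trial subject labels (defaults to `binned$subject`).
#' @param cluster A `cluster_result` for this feature.
#' @param alpha,band_hi As in [classify_channel()].
#' @return Long-format data frame: `bin`, `bin_center_ms`, `channel`,
#'   `p_enc`, `p_dec`, `label`.
#' @export
classify_all <- function(binned, y, cluster, subject = binned$subject,
                         alpha = 0.05, band_hi = 0.10) {
  stopifnot(inherits(binned, "binned_dataset"),
            inherits(cluster, "cluster_result"))
  B <- dim(binned$data)[3L]; p <- dim(binned$data)[2L]
  rows <- lapply(seq_len(B), function(b) {
    out <- data.frame(bin = b, bin_center_ms = binned$bin_centers_ms[b],
                      channel = seq_len(p), p_enc = NA_real_,
                      p_dec = NA_real_, label = "undetermined",
                      stringsAsFactors = FALSE)
    if (!cluster$mask[b]) return(out)
    xb <- binned$data[, , b, drop = TRUE]
    if (p == 1L) xb <- matrix(xb, ncol = 1L)
    out$p_enc <- vapply(seq_len(p), function(k) {
      channel_contribution_encoding(xb[, k], y, subject)
    }, numeric(1))
    out$p_dec <- leave_one_out_p(xb, y, subject)
    out$label <- classify_channel(out$p_enc, out$p_dec, alpha, band_hi)
    out
  })
  do.call(rbind, rows)
}

# All leave-one-out decoding p-values of one bin via the squared-t identity:
# the 1-df F for dropping channel k equals the squared t of its coefficient.
leave_one_out_p <- function(x, y, subject) {
  n <- nrow(x); p <- ncol(x)
  des <- encoding_design(y, subject, n, "numeric")
  Xr <- qr.resid(des$qr_reduced, x)
  Yr <- qr.resid(des$qr_reduced, des$Yd)
  G <- crossprod(Xr)
  Ginv <- chol2inv(chol(G))
  b <- Ginv %*% crossprod(Xr, Yr)
  df2 <- n - des$rank_reduced - p
  rss <- sum(Yr^2) - drop(crossprod(crossprod(Xr, Yr), b))
  sigma2 <- rss / df2
  t2 <- drop(b)^2 / (sigma2 * diag(Ginv))
  pf(t2, 1, df2, lower.tail = FALSE)
}

#' Modal label per channel over significant bins
#'
#' Summarizes a [classify_all()] table to the most frequent informative
#' label per channel across cluster-significant bins, falling back to
#' `undetermined` for channels never labelled.
#'
#' @param labels Output of [classify_all()].
#' @return Data frame with `channel` and `modal_label`.
#' @export
modal_labels <- function(labels) {
  sp <- split(labels$label[!is.na(labels$p_enc)],
              labels$channel[!is.na(labels$p_enc)])
  all_ch <- sort(unique(labels$channel))
  lab <- vapply(as.character(all_ch), function(ch) {
    v <- sp[[ch]]
    if (is.null(v) || length(v) == 0L) return("undetermined")
    names(sort(table(v), decreasing = TRUE))[1L]
  }, character(1))
  data.frame(channel = all_ch, modal_label = unname(lab),
             stringsAsFactors = FALSE)
}
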