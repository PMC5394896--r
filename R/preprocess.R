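#' Container for per-trial channel-by-sample epochs
#'
#' @param data Numeric array, trials x channels x samples.
#' @param sample_rate Sampling rate, Hz.
#' @param epoch_window Epoch start/end in ms relative to cue onset. The
#'   sample count must equal `diff(epoch_window) / 1000 * sample_rate`;
#'   sample `k` covers time `start + (k-1) / sample_rate * 1000` ms.
#' @param subject Per-trial subject labels.
#' @param exclusion_flags Optional list (one character vector per trial) of
#'   exclusion reason codes, a subset of `jump_artifact`,
#'   `amplitude_artifact`, `incorrect_response`, `misdetected_marker`.
#' @return An object of class `trial_epochs`.
#' @export
trial_epochs <- function(data, sample_rate, epoch_window, subject,
                         exclusion_flags = NULL) {
  stopifnot(length(dim(data)) == 3L)
  n_expected <- diff(epoch_window) / 1000 * sample_rate
  if (!isTRUE(all.equal(dim(data)[3L], n_expected))) {
    stop(sprintf("expected %g samples for a %g ms epoch at %g Hz, got %d",
                 n_expected, diff(epoch_window), sample_rate, dim(data)[3L]))
  }
  if (length(subject) != dim(data)[1L]) {
    stop("subject must have one entry per trial")
  }
  if (is.null(exclusion_flags)) {
    exclusion_flags <- rep(list(character(0)), dim(data)[1L])
  }
  valid <- c("jump_artifact", "amplitude_artifact", "incorrect_response",
             "misdetected_marker")
  if (!all(unlist(exclusion_flags) %in% valid)) {
    stop("unknown exclusion reason code")
  }
  structure(
    list(data = data, sample_rate = sample_rate,
         epoch_window = as.numeric(epoch_window),
         subject = subject, exclusion_flags = exclusion_flags),
    class = "trial_epochs"
  )
}

#' @export
print.trial_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("trial_epochs: %d trials x %d channels x %d samples @ %g Hz, window %g..%g ms\n",
              d[1L], d[2L], d[3L], x$sample_rate,
              x$epoch_window[1L], x$epoch_window[2L]))
  n_fl <- sum(lengths(x$exclusion_flags) > 0L)
  if (n_fl > 0L) cat(sprintf("  %d trials flagged for exclusion\n", n_fl))
  invisible(x)
}

# Median filter with reflect padding; window must be odd.
median_filter_reflect <- function(x, window) {
  if (window %% 2L == 0L) stop("median filter window must be odd")
  h <- (window - 1L) %/% 2L
  n <- length(x)
  if (window >= n) stop("median filter window must be shorter than the series")
  padded <- c(x[(h + 1L):2L], x, x[(n - 1L):(n - h)])
  stats::runmed(padded, window, endrule = "keep")[(h + 1L):(h + n)]
}

#' Correct step artifacts (SQUID jumps) in a single-channel trace
#'
#' Detects sudden jumps as first differences whose absolute value strictly
#' exceeds `jump_threshold`. If any are found, the first-difference series is
#' median-filtered (reflect padding) and the trace is reconstructed as the
#' cumulative sum of the filtered differences, anchored at the original first
#' sample. A trace without supra-threshold differences is returned unchanged,
#' which makes the correction idempotent.
#'
#' @param trace Numeric vector, one channel's continuous recording.
#' @param jump_threshold Difference magnitude that counts as a jump (strict
#'   inequality); default 3000 signal units.
#' @param median_window Median filter length in samples, odd; default 21.
#' @return List with `trace` (corrected series) and `jumps` (positions `j`
#'   such that the step occurred between samples `j` and `j + 1`).
#' @export
correct_squid_jumps <- function(trace, jump_threshold = 3000,
                                median_window = 21L) {
  stopifnot(jump_threshold > 0)
  if (median_window >= length(trace)) {
    stop("median_window must be shorter than the trace")
  }
  d <- diff(trace)
  jumps <- which(abs(d) > jump_threshold)
  if (length(jumps) == 0L) {
    return(list(trace = trace, jumps = integer(0)))
  }
  dm <- median_filter_reflect(d, median_window)
  list(trace = c(trace[1L], trace[1L] + cumsum(dm)), jumps = jumps)
}

#' Flag trials containing extreme amplitudes
#'
#' Marks every trial whose data contain any sample with absolute value
#' strictly above `abs_threshold` with the `amplitude_artifact` reason code.
#'
#' @param epochs A [trial_epochs()] object.
#' @param abs_threshold Amplitude threshold (signal units), default 3000.
#' @return The epochs with updated `exclusion_flags`; the number of newly
#'   flagged trials is reported via `message()`.
#' @export
screen_amplitude <- function(epochs, abs_threshold = 3000) {
  stopifnot(inherits(epochs, "trial_epochs"), abs_threshold > 0)
  mx <- apply(abs(epochs$data), 1L, max)
  hit <- which(mx > abs_threshold)
  for (i in hit) {
    epochs$exclusion_flags[[i]] <-
      union(epochs$exclusion_flags[[i]], "amplitude_artifact")
  }
  message(sprintf("amplitude screening: %d of %d trials flagged (threshold %g)",
                  length(hit), dim(epochs$data)[1L], abs_threshold))
  epochs
}

#' Low-pass filter, baseline-correct and down-sample epochs
#'
#' Applies a first-order Butterworth low-pass per trial and channel
#' (single-pass forward by default; `two_pass = TRUE` applies it forward and
#' backward for zero phase), decimates to `target_rate` by keeping every
#' k-th sample, and subtracts the per-trial, per-channel mean over
#' `baseline_window` computed on the retained samples, so the output's
#' baseline-window mean is exactly zero.
#'
#' @param epochs A [trial_epochs()] object.
#' @param cutoff Low-pass cutoff frequency, Hz (default 80); must be below
#'   the input Nyquist frequency.
#' @param baseline_window Baseline interval in ms, inside the epoch; default
#'   `c(-300, 0)`. `NULL` skips baseline correction.
#' @param target_rate Output sampling rate, Hz; must divide the input rate.
#' @param two_pass Apply the filter forward and backward (zero phase)?
#' @return A [trial_epochs()] object at `target_rate`.
#' @export
filter_baseline_downsample <- function(epochs, cutoff = 80,
                                       baseline_window = c(-300, 0),
                                       target_rate = 200,
                                       two_pass = FALSE) {
  stopifnot(inherits(epochs, "trial_epochs"))
  fs <- epochs$sample_rate
  if (cutoff >= fs / 2) stop("cutoff must be below the Nyquist frequency")
  dec <- fs / target_rate
  if (abs(dec - round(dec)) > 1e-9) {
    stop(sprintf("target_rate %g does not divide sample_rate %g", target_rate, fs))
  }
  dec <- as.integer(round(dec))
  bf <- signal::butter(1, cutoff / (fs / 2), type = "low")
  d <- epochs$data
  n_trials <- dim(d)[1L]; n_chan <- dim(d)[2L]; n_s <- dim(d)[3L]
  out_idx <- seq(1L, n_s, by = dec)
  res <- array(0, dim = c(n_trials, n_chan, length(out_idx)))
  for (i in seq_len(n_trials)) {
    for (ch in seq_len(n_chan)) {
      x <- d[i, ch, ]
      # filter relative to the first sample: starts the recursion at the
      # DC steady state, so a constant trace passes through unchanged
      y <- if (two_pass) {
        signal::filtfilt(bf, x - x[1L]) + x[1L]
      } else {
        as.numeric(signal::filter(bf, x - x[1L])) + x[1L]
      }
      res[i, ch, ] <- y[out_idx]
    }
  }
  out <- trial_epochs(res, sample_rate = target_rate,
                      epoch_window = epochs$epoch_window,
                      subject = epochs$subject,
                      exclusion_flags = epochs$exclusion_flags)
  if (!is.null(baseline_window)) {
    if (baseline_window[1L] < epochs$epoch_window[1L] ||
        baseline_window[2L] > epochs$epoch_window[2L]) {
      stop("baseline window lies outside the epoch")
    }
    t_ms <- sample_times(out)
    bidx <- which(t_ms >= baseline_window[1L] & t_ms < baseline_window[2L])
    if (length(bidx) == 0L) stop("baseline window contains no samples")
    base <- apply(out$data[, , bidx, drop = FALSE], c(1L, 2L), mean)
    out$data <- out$data - as.vector(base)  # recycles over samples
  }
  out
}

#' Sample times of an epochs object
#'
#' @param epochs A [trial_epochs()] object.
#' @return Times in ms (left edge of each sample) relative to cue onset.
#' @export
sample_times <- function(epochs) {
  dt <- 1000 / epochs$sample_rate
  seq(epochs$epoch_window[1L], by = dt, length.out = dim(epochs$data)[3L])
}

#' Drop flagged trials and report exclusion percentages
#'
#' Removes every trial with at least one exclusion flag. A trial flagged for
#' several reasons is removed once but counted under each reason, so the
#' per-reason percentages need not sum to the total removed.
#'
#' @param epochs A [trial_epochs()] object.
#' @param stimuli Optional stimulus table subset alongside the epochs.
#' @return List with `epochs` (and `stimuli` if given) restricted to kept
#'   trials, and `report`: a data frame of per-reason counts and percentages
#'   of the original trial count.
#' @export
apply_exclusions <- function(epochs, stimuli = NULL) {
  stopifnot(inherits(epochs, "trial_epochs"))
  n <- dim(epochs$data)[1L]
  reasons <- c("jump_artifact", "amplitude_artifact", "incorrect_response",
               "misdetected_marker")
  counts <- vapply(reasons, function(r) {
    sum(vapply(epochs$exclusion_flags, function(fl) r %in% fl, logical(1)))
  }, numeric(1))
  keep <- lengths(epochs$exclusion_flags) == 0L
  if (!any(keep)) stop("all trials excluded")
  out <- trial_epochs(epochs$data[keep, , , drop = FALSE],
                      sample_rate = epochs$sample_rate,
                      epoch_window = epochs$epoch_window,
                      subject = epochs$subject[keep],
                      exclusion_flags = epochs$exclusion_flags[keep])
  report <- data.frame(
    reason = reasons,
    n = as.integer(counts),
    percent = 100 * counts / n,
    stringsAsFactors = FALSE
  )
  res <- list(epochs = out, report = report,
              n_original = n, n_kept = sum(keep))
  if (!is.null(stimuli)) res$stimuli <- stimuli[keep, , drop = FALSE]
  res
}

#' Average epochs into consecutive non-overlapping time bins
#'
#' Bins are left-closed, right-open intervals `[t, t + bin_width_ms)` tiling
#' `analysis_window`; each bin is the arithmetic mean of the samples falling
#' in it, and its center is reported at `t + bin_width_ms / 2`. At the
#' default 200 Hz and 10 ms width, each bin averages 2 samples; a -400 to
#' 2000 ms window yields 240 bins and a 0 to 2000 ms window 200 bins.
#'
#' @param epochs A [trial_epochs()] object.
#' @param bin_width_ms Bin width in ms; must divide the analysis window.
#' @param analysis_window Interval in ms to bin; defaults to the full epoch.
#' @return A `binned_dataset`: list with `data` (trials x channels x bins),
#'   `bin_width_ms`, `bin_centers_ms`, `subject`.
#' @export
bin_time <- function(epochs, bin_width_ms = 10, analysis_window = NULL) {
  stopifnot(inherits(epochs, "trial_epochs"))
  analysis_window <- analysis_window %||% epochs$epoch_window
  span <- diff(analysis_window)
  n_bins <- span / bin_width_ms
  if (abs(n_bins - round(n_bins)) > 1e-9) {
    stop(sprintf("bin width %g ms does not divide the %g ms window (remainder %g ms)",
                 bin_width_ms, span, span %% bin_width_ms))
  }
  n_bins <- as.integer(round(n_bins))
  t_ms <- sample_times(epochs)
  edges <- analysis_window[1L] + bin_width_ms * (0:n_bins)
  idx <- findInterval(t_ms, edges, left.open = FALSE)  # bin of each sample
  inside <- idx >= 1L & idx <= n_bins & t_ms < analysis_window[2L]
  d <- epochs$data
  n_trials <- dim(d)[1L]; n_chan <- dim(d)[2L]
  res <- array(0, dim = c(n_trials, n_chan, n_bins))
  for (b in seq_len(n_bins)) {
    cols <- which(inside & idx == b)
    if (length(cols) == 0L) stop("a bin contains no samples; check sampling rate")
    if (length(cols) == 1L) {
      res[, , b] <- d[, , cols]
    } else {
      res[, , b] <- apply(d[, , cols, drop = FALSE], c(1L, 2L), mean)
    }
  }
  structure(
    list(data = res,
         bin_width_ms = bin_width_ms,
         bin_centers_ms = edges[-length(edges)] + bin_width_ms / 2,
         subject = epochs$subject),
    class = "binned_dataset"
  )
}

#' Construct a binned dataset directly
#'
#' Wraps an already-binned trials x channels x bins array, e.g. when
#' simulating at bin resolution without the sample-level preprocessing chain.
#'
#' @param data Numeric array, trials x channels x bins.
#' @param bin_centers_ms Bin centers in ms.
#' @param subject Per-trial subject labels.
#' @param bin_width_ms Bin width in ms.
#' @return A `binned_dataset` object.
#' @export
binned_dataset <- function(data, bin_centers_ms, subject, bin_width_ms = 10) {
  stopifnot(length(dim(data)) == 3L,
            dim(data)[3L] == length(bin_centers_ms),
            dim(data)[1L] == length(subject))
  structure(
    list(data = data, bin_width_ms = bin_width_ms,
         bin_centers_ms = as.numeric(bin_centers_ms), subject = subject),
    class = "binned_dataset"
  )
}

#' @export
print.binned_dataset <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("binned_dataset: %d trials x %d channels x %d bins (%g ms bins, centers %g..%g ms)\n",
              d[1L], d[2L], d[3L], x$bin_width_ms,
              x$bin_centers_ms[1L], x$bin_centers_ms[d[3L]]))
  invisible(x)
}
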