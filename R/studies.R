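# Simulation studies backing the package's calibration and recovery claims.
# Each function runs a replicated experiment at a fixed desk-scale design
# (6 subjects, 108-216 trials, a handful of channels) and returns per-
# replicate outcomes; the methods vignette documents the chosen sizes.

study_spec <- function(trials_per = 18L, n_channels = 3L, window = c(0, 100)) {
  design_spec(n_subjects = 6L, n_trials_per_subject = trials_per,
              n_channels = n_channels, sample_rate = 200,
              epoch_window = window)
}

# Well-separated per-replicate seeds: arithmetic like seed + i for several
# streams lets streams collide across replicates, which correlates
# replicates; draw all sub-seeds from the master seed instead.
subseeds <- function(seed, n_rep, k) {
  with_seed(seed, matrix(sample.int(2^30, n_rep * k), n_rep, k))
}

#' Null calibration of the per-bin encoding and decoding p-values
#'
#' Simulates independent null time bins (Gaussian data, no planted effect)
#' under the balanced factorial design and records the overall encoding and
#' decoding p-values; under the null both should be uniform on (0, 1).
#'
#' @param n_rep Number of simulated null bins.
#' @param seed Integer seed.
#' @param n_channels Channels per bin.
#' @return Data frame with columns `p_enc`, `p_dec`.
#' @export
study_null_pvalues <- function(n_rep = 1000L, seed = 1L, n_channels = 3L) {
  spec <- study_spec(n_channels = n_channels)
  ss <- subseeds(seed, 1L, 2L)
  stim <- stimulus_table(spec, seed = ss[1L, 1L])
  n <- nrow(stim)
  with_seed(ss[1L, 2L], {
    res <- vapply(seq_len(n_rep), function(i) {
      x <- matrix(rnorm(n * n_channels), n, n_channels)
      c(fit_encoding(x, stim$y_mean, stim$subject)$p.value,
        fit_decoding(x, stim$y_mean, stim$subject)$p.value)
    }, numeric(2))
    data.frame(p_enc = res[1L, ], p_dec = res[2L, ])
  })
}

#' Family-wise error rate of the cluster-level permutation test
#'
#' Simulates datasets with no effect anywhere and records, per replicate,
#' whether any cluster reached significance; the rate estimates the
#' family-wise error of the correction over time bins.
#'
#' @param n_rep Number of replicate datasets.
#' @param seed Integer seed.
#' @param n_bins Time bins per dataset.
#' @param n_perm Permutations per cluster test.
#' @param alpha Cluster-level threshold.
#' @return Logical vector, one entry per replicate.
#' @export
study_cluster_fwer <- function(n_rep = 200L, seed = 1L, n_bins = 25L,
                               n_perm = 120L, alpha = 0.05) {
  spec <- study_spec(n_channels = 2L, window = c(0, n_bins * 10))
  ss <- subseeds(seed, n_rep, 3L)
  vapply(seq_len(n_rep), function(i) {
    stim <- stimulus_table(spec, seed = ss[i, 1L])
    n <- nrow(stim)
    dat <- with_seed(ss[i, 2L],
                     array(rnorm(n * 2L * n_bins), dim = c(n, 2L, n_bins)))
    b <- binned_dataset(dat, seq(5, by = 10, length.out = n_bins),
                        stim$subject)
    cl <- cluster_permutation(b, stim$y_mean, n_perm = n_perm,
                              alpha = alpha, seed = ss[i, 3L])
    any(cl$clusters$p < alpha)
  }, logical(1))
}

#' Off-diagonal zeroing rate of the cross-prediction matrix under the null
#'
#' Simulates datasets without any planted effect, runs the cross-prediction
#' analysis, and records the fraction of off-diagonal cells that survive the
#' zeroing rule (`p <= alpha` and non-negative explained variance); the
#' survival rate should be at most nominal.
#'
#' @param n_rep Number of replicate datasets.
#' @param seed Integer seed.
#' @param n_bins Bins per dataset.
#' @param n_perm Trial-label permutations.
#' @return Numeric vector of per-replicate off-diagonal survival rates.
#' @export
study_null_zeroing <- function(n_rep = 200L, seed = 1L, n_bins = 6L,
                               n_perm = 120L) {
  spec <- study_spec(n_channels = 2L, window = c(0, n_bins * 10))
  ss <- subseeds(seed, n_rep, 3L)
  vapply(seq_len(n_rep), function(i) {
    stim <- stimulus_table(spec, seed = ss[i, 1L])
    n <- nrow(stim)
    dat <- with_seed(ss[i, 2L],
                     array(rnorm(n * 2L * n_bins), dim = c(n, 2L, n_bins)))
    b <- binned_dataset(dat, seq(5, by = 10, length.out = n_bins),
                        stim$subject)
    xp <- cross_predict(b, stim$y_mean, n_perm = n_perm, seed = ss[i, 3L])
    off <- xp$ev_thresholded[row(xp$ev) != col(xp$ev)]
    mean(off != 0)
  }, numeric(1))
}

#' Recovery of planted direct, indirect and context channels
#'
#' Generates structured datasets (one direct, one indirect, one context
#' channel for mean reward plus pure-noise channels) at an effect size where
#' both channel tests have high power, runs cluster correction plus the
#' causal classification, and records whether all three structured channels
#' received their ground-truth modal label.
#'
#' @param n_rep Number of replicate datasets.
#' @param seed Integer seed.
#' @param beta Planted effect amplitude (signal units per pound).
#' @param noise_sd Idiosyncratic noise SD.
#' @param n_perm Cluster permutations.
#' @return Logical vector, one entry per replicate.
#' @export
study_label_recovery <- function(n_rep = 100L, seed = 1L, beta = 1.5,
                                 noise_sd = 0.5, n_perm = 120L) {
  spec <- study_spec(n_channels = 6L)
  roles <- data.frame(
    feature = rep("y_mean", 3L), channel = 1:3,
    role = c("direct", "indirect", "context"), parent = c(NA, 1L, 1L)
  )
  truth <- ground_truth(6L, roles = roles, beta = beta, noise_sd = noise_sd,
                        shared_noise_sd = 1)
  ss <- subseeds(seed, n_rep, 2L)
  vapply(seq_len(n_rep), function(i) {
    sim <- simulate_dataset(spec, truth, seed = ss[i, 1L])
    b <- bin_time(sim$epochs, 10)
    cl <- cluster_permutation(b, sim$stimuli$y_mean, n_perm = n_perm,
                              seed = ss[i, 2L])
    if (length(cl$sig_bins) == 0L) return(FALSE)
    ml <- modal_labels(classify_all(b, sim$stimuli$y_mean, cl))
    all(ml$modal_label[1:3] == c("direct", "indirect", "context"))
  }, logical(1))
}

#' Power and calibration of the half-window stability statistic
#'
#' Generates datasets whose encoding pattern either drifts during the first
#' half of the window and freezes in the second (`drift = "freeze"`, the
#' temporal-stability alternative) or stays constant (`drift = "none"`, the
#' stationary null), and records the stability p-value, both raw and after
#' normalizing the cross-prediction matrix by the source-bin fit.
#'
#' @param n_rep Number of replicate datasets.
#' @param seed Integer seed.
#' @param drift `"freeze"` or `"none"`.
#' @param beta Effect amplitude.
#' @param n_perm_trial Trial-label permutations for the matrix.
#' @param n_perm_time Time-label permutations for the statistic.
#' @return Data frame with per-replicate `statistic`, `p`, `p_normalized`.
#' @export
study_stability <- function(n_rep = 100L, seed = 1L,
                            drift = c("freeze", "none"), beta = 1.2,
                            n_perm_trial = 120L, n_perm_time = 2000L) {
  drift <- match.arg(drift)
  spec <- study_spec(trials_per = 36L, n_channels = 6L, window = c(0, 160))
  roles <- data.frame(feature = rep("y_mean", 6L), channel = 1:6,
                      role = "direct", parent = NA)
  truth <- ground_truth(6L, roles = roles, beta = beta, noise_sd = 1,
                        drift = drift)
  ss <- subseeds(seed, n_rep, 4L)
  rows <- lapply(seq_len(n_rep), function(i) {
    sim <- simulate_dataset(spec, truth, seed = ss[i, 1L])
    b <- bin_time(sim$epochs, 10)
    xp <- cross_predict(b, sim$stimuli$y_mean, n_perm = n_perm_trial,
                        seed = ss[i, 2L])
    st <- stability_statistic(xp, split_ms = 80, n_perm = n_perm_time,
                              seed = ss[i, 3L])
    stn <- stability_statistic(normalize_by_source_fit(xp), split_ms = 80,
                               n_perm = n_perm_time, seed = ss[i, 4L])
    data.frame(statistic = st$statistic, p = st$p.value,
               p_normalized = stn$p.value)
  })
  do.call(rbind, rows)
}

#' Recovery of the generating reward-variability metric
#'
#' Plants one of the candidate metrics (CV, decorrelated SD, decorrelated
#' variance) on a subset of channels at high SNR and records which metric
#' wins the pooled summed-AIC comparison in each replicate.
#'
#' @param n_rep Number of replicate datasets.
#' @param seed Integer seed.
#' @param generating `"cv"`, `"sd_dec"` or `"v_dec"`.
#' @param beta Effect amplitude (signal units per metric unit).
#' @param n_bins Bins per dataset.
#' @return Character vector of per-replicate winners (`"none"` possible).
#' @export
study_metric_recovery <- function(n_rep = 100L, seed = 1L,
                                  generating = c("cv", "sd_dec", "v_dec"),
                                  beta = 25, n_bins = 6L) {
  generating <- match.arg(generating)
  col <- c(cv = "y_cv", sd_dec = "y_sd_dec", v_dec = "y_v_dec")[[generating]]
  spec <- study_spec(trials_per = 36L, n_channels = 3L,
                     window = c(0, n_bins * 10))
  ss <- subseeds(seed, n_rep, 2L)
  vapply(seq_len(n_rep), function(i) {
    stim <- stimulus_table(spec, seed = ss[i, 1L])
    n <- nrow(stim)
    dat <- with_seed(ss[i, 2L],
                     array(rnorm(n * 3L * n_bins), dim = c(n, 3L, n_bins)))
    dat[, 1L, ] <- dat[, 1L, ] + beta * stim[[col]]
    b <- binned_dataset(dat, seq(5, by = 10, length.out = n_bins),
                        stim$subject)
    attr(compare_variability_metrics(b, stim, scope = "pooled"), "winner")
  }, character(1))
}
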