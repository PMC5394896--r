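#' Planted ground truth for the synthetic-data generator
#'
#' Declares, per stimulus feature, which channels carry the feature and how:
#' a `direct` channel responds to the feature value itself
#' (`x = beta(t) * y + noise`); an `indirect` channel is an affine copy of a
#' named direct channel plus its own noise, so its dependence on the feature
#' is entirely mediated; a `context` channel loads on a direct channel's
#' shared noise component only, so it is correlated with the direct channel
#' but has zero marginal dependence on the feature. Unlisted channels are
#' pure noise.
#'
#' The effect time course `beta(t)` is zero before `onset_ms` and equal to
#' `beta` afterwards. When a feature has two or more direct channels, the
#' spatial pattern over those channels can drift: under `drift = "freeze"`
#' the pattern rotates smoothly (spherical interpolation between two random
#' unit patterns) across the first half of the epoch and is frozen over the
#' second half; under `drift = "linear"` it rotates across the whole epoch;
#' under `"none"` it is constant.
#'
#' @param n_channels Total number of channels.
#' @param roles `NULL` (all channels pure noise) or a data frame with columns
#'   `feature` (name of a column in the stimulus table, e.g. `"y_mean"`),
#'   `channel`, `role` (`"direct"`, `"indirect"`, `"context"`) and `parent`
#'   (`NA` for direct channels; the mediating/correlated direct channel
#'   otherwise).
#' @param beta Effect amplitude, signal units per feature unit. Scalar or
#'   named by feature.
#' @param onset_ms Effect onset relative to cue onset, ms. Scalar or named by
#'   feature.
#' @param noise_sd SD of idiosyncratic Gaussian noise per channel/sample.
#' @param shared_noise_sd SD of the shared "brain state" noise component each
#'   parent direct channel carries and its context channels load on.
#' @param context_loading Loading of context channels on their parent's
#'   shared noise.
#' @param indirect_gain Gain of indirect channels on their parent.
#' @param subject_pattern_sd SD of subject-specific perturbations of the
#'   direct-channel pattern.
#' @param drift Pattern drift schedule: `"none"`, `"freeze"` or `"linear"`.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(n_channels,
                         roles = NULL,
                         beta = 1,
                         onset_ms = 0,
                         noise_sd = 1,
                         shared_noise_sd = 0,
                         context_loading = 1,
                         indirect_gain = 1,
                         subject_pattern_sd = 0,
                         drift = c("none", "freeze", "linear")) {
  n_channels <- as.integer(n_channels)
  drift <- match.arg(drift)
  if (!is.null(roles)) {
    need <- c("feature", "channel", "role")
    if (!all(need %in% names(roles))) {
      stop("roles needs columns feature, channel, role (and optionally parent)")
    }
    if (is.null(roles$parent)) roles$parent <- NA_integer_
    if (any(roles$channel < 1L | roles$channel > n_channels)) {
      stop("roles references channels outside 1..n_channels")
    }
    bad <- !roles$role %in% c("direct", "indirect", "context")
    if (any(bad)) stop("role must be direct, indirect or context")
    dep <- roles$role %in% c("indirect", "context")
    if (any(dep & is.na(roles$parent))) {
      stop("indirect and context channels must name a parent direct channel")
    }
    for (i in which(dep)) {
      ok <- any(roles$feature == roles$feature[i] &
                  roles$role == "direct" &
                  roles$channel == roles$parent[i])
      if (!ok) {
        stop(sprintf(
          "channel %d (%s, %s) names parent %d which is not a direct channel for that feature",
          roles$channel[i], roles$role[i], roles$feature[i], roles$parent[i]
        ))
      }
    }
  }
  structure(
    list(
      n_channels = n_channels,
      roles = roles,
      beta = beta,
      onset_ms = onset_ms,
      noise_sd = noise_sd,
      shared_noise_sd = shared_noise_sd,
      context_loading = context_loading,
      indirect_gain = indirect_gain,
      subject_pattern_sd = subject_pattern_sd,
      drift = drift
    ),
    class = "ground_truth"
  )
}

scalar_for <- function(x, feature) {
  if (is.null(names(x))) return(unname(x[1L]))
  if (feature %in% names(x)) return(unname(x[[feature]]))
  unname(x[1L])
}

# Spherical interpolation between unit vectors a and b at fraction s in [0,1].
slerp <- function(a, b, s) {
  dotab <- sum(a * b)
  dotab <- max(min(dotab, 1), -1)
  omega <- acos(dotab)
  if (omega < 1e-12) return(a)
  (sin((1 - s) * omega) * a + sin(s * omega) * b) / sin(omega)
}

drift_fraction <- function(t_ms, window, drift) {
  span <- window[2L] - window[1L]
  switch(drift,
    none = rep(0, length(t_ms)),
    linear = (t_ms - window[1L]) / span,
    freeze = pmin((t_ms - window[1L]) / (span / 2), 1)
  )
}

#' Generate a synthetic multi-subject trial dataset with planted structure
#'
#' Draws per-trial channel-by-sample epochs according to a [design_spec()]
#' and a [ground_truth()]: direct channels carry `beta(t) * y` plus a shared
#' noise component and idiosyncratic noise; indirect channels are affine
#' copies of their parent direct channel plus noise; context channels load on
#' the parent's shared noise only. Per-subject feature values follow the
#' counterbalance mapping, so perceptual and reward features are orthogonal
#' only at the group level. The output is deterministic given `seed`.
#'
#' @param spec A [design_spec()].
#' @param truth A [ground_truth()] with `n_channels` matching `spec`.
#' @param seed Integer seed.
#' @return A list with components `epochs` (a [trial_epochs()] object),
#'   `stimuli` (the per-trial feature table) and `truth` (the input
#'   `ground_truth`, augmented with the realized per-feature pattern
#'   time courses in `attr(, "beta_t")`).
#' @export
simulate_dataset <- function(spec, truth, seed = 1L) {
  stopifnot(inherits(spec, "design_spec"), inherits(truth, "ground_truth"))
  if (truth$n_channels != spec$n_channels) {
    stop("truth$n_channels must equal spec$n_channels")
  }
  with_seed(seed, {
    stim <- stimulus_table(spec, seed = NULL)
    n_trials <- nrow(stim)
    p <- spec$n_channels
    dt <- 1000 / spec$sample_rate
    t_ms <- seq(spec$epoch_window[1L], spec$epoch_window[2L] - dt, by = dt)
    n_s <- length(t_ms)

    dat <- array(rnorm(n_trials * p * n_s, sd = truth$noise_sd),
                 dim = c(n_trials, p, n_s))

    beta_t <- list()
    roles <- truth$roles
    if (!is.null(roles) && nrow(roles) > 0L) {
      feats <- unique(roles$feature)
      # shared "brain state" noise per parent direct channel of any context
      parents <- unique(roles$parent[roles$role == "context"])
      shared <- list()
      for (d in parents) {
        shared[[as.character(d)]] <-
          matrix(rnorm(n_trials * n_s, sd = truth$shared_noise_sd),
                 n_trials, n_s)
      }
      for (f in feats) {
        rf <- roles[roles$feature == f, , drop = FALSE]
        dchan <- rf$channel[rf$role == "direct"]
        b <- scalar_for(truth$beta, f)
        onset <- scalar_for(truth$onset_ms, f)
        on <- as.numeric(t_ms >= onset)
        # pattern over direct channels, possibly drifting over the epoch
        k <- length(dchan)
        if (k >= 2L && truth$drift != "none") {
          w0 <- rnorm(k); w0 <- w0 / sqrt(sum(w0^2))
          w1 <- rnorm(k); w1 <- w1 - sum(w1 * w0) * w0  # full 90-degree path
          w1 <- w1 / sqrt(sum(w1^2))
          fr <- drift_fraction(t_ms, spec$epoch_window, truth$drift)
          W <- vapply(fr, function(s) slerp(w0, w1, s), numeric(k))  # k x n_s
        } else {
          W <- matrix(1 / sqrt(max(k, 1L)), nrow = max(k, 1L), ncol = n_s)
        }
        B <- matrix(0, p, n_s)
        if (k > 0L) {
          B[dchan, ] <- b * W * rep(on, each = k) * sqrt(k)
        }
        beta_t[[f]] <- B
        y <- stim[[f]]
        if (is.null(y)) stop(sprintf("feature '%s' not found in stimulus table", f))
        # subject-specific perturbation of the direct pattern
        sub_pert <- matrix(rnorm(spec$n_subjects * max(k, 1L),
                                 sd = truth$subject_pattern_sd),
                           spec$n_subjects, max(k, 1L))
        for (ci in seq_along(dchan)) {
          ch <- dchan[ci]
          eff <- outer(y, B[ch, ])                       # trials x samples
          if (truth$subject_pattern_sd > 0) {
            pert <- sub_pert[stim$subject, ci] * y
            eff <- eff + outer(pert, on)
          }
          dat[, ch, ] <- dat[, ch, ] + eff
          if (as.character(ch) %in% names(shared)) {
            dat[, ch, ] <- dat[, ch, ] + shared[[as.character(ch)]]
          }
        }
      }
      # context channels: parent's shared noise only (no feature dependence)
      for (i in which(roles$role == "context")) {
        ch <- roles$channel[i]
        sh <- shared[[as.character(roles$parent[i])]]
        dat[, ch, ] <- dat[, ch, ] + truth$context_loading * sh
      }
      # indirect channels: affine copy of the completed parent channel
      for (i in which(roles$role == "indirect")) {
        ch <- roles$channel[i]
        dat[, ch, ] <- dat[, ch, ] + truth$indirect_gain * dat[, roles$parent[i], ]
      }
    }

    epochs <- trial_epochs(
      data = dat,
      sample_rate = spec$sample_rate,
      epoch_window = spec$epoch_window,
      subject = stim$subject
    )
    attr(truth, "beta_t") <- beta_t
    list(epochs = epochs, stimuli = stim, truth = truth)
  })
}

#' Simulate certainty equivalents under exponential utility
#'
#' For each subject and each cue of the factorial design, computes the
#' noiseless certainty equivalent `c*` solving `u(c*) = E[u(outcome)]` under
#' the exponential utility with the subject's risk-sensitivity parameter, and
#' adds Gaussian elicitation noise. At `a = 0` the linear limit gives
#' `c* = E[outcome]`.
#'
#' @param true_a Risk-sensitivity parameter; scalar or one value per subject.
#' @param spec A [design_spec()].
#' @param noise_sd SD of elicitation noise (currency units).
#' @param seed Integer seed.
#' @return Data frame with columns `subject`, `cue`, `mean_level`,
#'   `cv_level`, `ev` (expected value), `ce` (elicited certainty equivalent).
#' @export
simulate_certainty_equivalents <- function(true_a, spec, noise_sd = 0,
                                           seed = 1L) {
  stopifnot(inherits(spec, "design_spec"))
  a <- rep_len(true_a, spec$n_subjects)
  cues <- expand.grid(mean_level = spec$mean_levels, cv_level = spec$cv_levels,
                      KEEP.OUT.ATTRS = FALSE)
  with_seed(seed, {
    rows <- lapply(seq_len(spec$n_subjects), function(s) {
      ce <- vapply(seq_len(nrow(cues)), function(i) {
        out <- reward_outcomes(cues$mean_level[i], cues$cv_level[i])
        certainty_equivalent(a[s], out)
      }, numeric(1))
      data.frame(
        subject = s,
        cue = seq_len(nrow(cues)),
        mean_level = cues$mean_level,
        cv_level = cues$cv_level,
        ev = cues$mean_level,
        ce = ce + rnorm(nrow(cues), sd = noise_sd),
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, rows)
  })
}
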