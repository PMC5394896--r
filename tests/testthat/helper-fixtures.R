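# Shared fixture builders. All data are generated in code at test time.

# Small balanced design: 6 subjects, a handful of trials per cell.
small_spec <- function(n_trials = 36L, n_channels = 4L, window = c(0, 200),
                       sample_rate = 200) {
  design_spec(n_subjects = 6L, n_trials_per_subject = n_trials,
              n_channels = n_channels, sample_rate = sample_rate,
              epoch_window = window)
}

# Binned pure-noise dataset with a matching stimulus table.
null_binned <- function(n_sub = 6L, trials_per = 18L, p = 3L, B = 10L,
                        seed = 1L) {
  spec <- design_spec(n_subjects = n_sub, n_trials_per_subject = trials_per,
                      n_channels = p, sample_rate = 200,
                      epoch_window = c(0, B * 10))
  stim <- stimulus_table(spec, seed = seed)
  n <- nrow(stim)
  set.seed(seed + 1000L)
  dat <- array(rnorm(n * p * B), dim = c(n, p, B))
  list(binned = binned_dataset(dat, seq(5, by = 10, length.out = B),
                               stim$subject),
       stimuli = stim, spec = spec)
}

# Binned dataset with channels 1..n_direct carrying `beta * y` in every bin.
planted_binned <- function(y_col = "y_mean", beta = 1, n_sub = 6L,
                           trials_per = 18L, p = 3L, B = 10L, n_direct = 1L,
                           noise_sd = 1, seed = 1L) {
  nb <- null_binned(n_sub, trials_per, p, B, seed)
  nb$binned$data <- nb$binned$data * noise_sd
  y <- nb$stimuli[[y_col]]
  for (k in seq_len(n_direct)) {
    nb$binned$data[, k, ] <- nb$binned$data[, k, ] + beta * y
  }
  nb
}

# Structured dataset (direct / indirect / context on y_mean) via the
# sample-level generator, binned at 10 ms.
structured_dataset <- function(seed, n_trials = 18L, n_channels = 6L,
                               window = c(0, 100), beta = 1.5,
                               noise_sd = 0.5, shared_sd = 1) {
  spec <- small_spec(n_trials = n_trials, n_channels = n_channels,
                     window = window)
  roles <- data.frame(
    feature = rep("y_mean", 3L),
    channel = 1:3,
    role = c("direct", "indirect", "context"),
    parent = c(NA, 1L, 1L)
  )
  truth <- ground_truth(n_channels, roles = roles, beta = beta,
                        noise_sd = noise_sd, shared_noise_sd = shared_sd)
  sim <- simulate_dataset(spec, truth, seed = seed)
  list(binned = bin_time(sim$epochs, 10), stimuli = sim$stimuli,
       truth = sim$truth)
}

# Outcome sets for the 3 x 3 cue grid, indexed like the cue column of
# simulate_certainty_equivalents().
cue_outcome_sets <- function(spec = design_spec()) {
  cues <- expand.grid(mean_level = spec$mean_levels,
                      cv_level = spec$cv_levels, KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(cues)), function(i) {
    reward_outcomes(cues$mean_level[i], cues$cv_level[i])
  })
}
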