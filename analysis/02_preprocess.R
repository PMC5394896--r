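#!/usr/bin/env Rscript

# Stage 2: preprocessing chain on the demonstration dataset.
#
# Injects a handful of step artifacts into the raw traces, corrects them via
# the median-filtered-derivative rule, screens amplitudes, applies the
# exclusion bookkeeping and bins the epochs into 10 ms bins. Writes the
# exclusion report and the per-stage trial counts.

suppressPackageStartupMessages(library(rewarddyn))
dir.create("results/demo", showWarnings = FALSE, recursive = TRUE)

config <- run_config(seed = 20260101L)
sim <- simulate_dataset(config$spec, config$truth, seed = config$seed)
ep <- sim$epochs

# inject step artifacts into 2% of trials, channel 1
set.seed(1)
n_trials <- dim(ep$data)[1]
bad <- sample(n_trials, round(0.02 * n_trials))
for (i in bad) {
  j <- sample(50:400, 1)
  ep$data[i, 1, j:dim(ep$data)[3]] <- ep$data[i, 1, j:dim(ep$data)[3]] + 5000
}

# jump detection/correction per trial trace; flag corrected trials
n_jumpy <- 0L
for (i in seq_len(n_trials)) {
  res <- correct_squid_jumps(ep$data[i, 1, ])
  if (length(res$jumps) > 0L) {
    ep$data[i, 1, ] <- res$trace
    ep$exclusion_flags[[i]] <- union(ep$exclusion_flags[[i]], "jump_artifact")
    n_jumpy <- n_jumpy + 1L
  }
}
cat(sprintf("jump correction: %d of %d trials affected (%.1f%%)\n",
            n_jumpy, n_trials, 100 * n_jumpy / n_trials))

ep <- screen_amplitude(ep, abs_threshold = 3000)
exc <- apply_exclusions(ep, sim$stimuli)
write.csv(exc$report, "results/demo/exclusion_report.csv", row.names = FALSE)
print(exc$report)
cat(sprintf("%d of %d trials retained\n", exc$n_kept, exc$n_original))

binned <- bin_time(exc$epochs, 10, c(-400, 2000))
cat(sprintf("binned: %d bins of %g ms (%d samples each at %g Hz)\n",
            dim(binned$data)[3], binned$bin_width_ms,
            as.integer(binned$bin_width_ms * exc$epochs$sample_rate / 1000),
            exc$epochs$sample_rate))
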