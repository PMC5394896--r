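#' Specify a multi-subject factorial reward-anticipation design
#'
#' Describes the trial structure the synthetic-data generator emulates: a
#' group of subjects, each seeing every cell of a mean-reward-by-variability
#' factorial equally often, with cue features (disc fill, disc color) mapped
#' onto the reward dimensions by a counterbalancing scheme that makes the
#' perceptual and reward factors orthogonal at the group level while they are
#' perfectly confounded within any single subject.
#'
#' Defaults reproduce the source-level study conditions: 18 subjects, 450
#' trials each, 13 channels, a 0--2000 ms anticipation epoch sampled at
#' 200 Hz, mean-reward levels of 1, 2, 3 (in pounds) and coefficient-of-
#' variation levels of 0.08, 0.16, 0.24.
#'
#' @param n_subjects Number of subjects; must be a multiple of 6 so that the
#'   two fill-to-mean mappings cross the three color-to-variability rotations
#'   an equal number of times (group-level orthogonality is exact only then).
#' @param n_trials_per_subject Trials per subject; must be a multiple of the
#'   number of factorial cells so that every cue appears equally often.
#' @param n_channels Number of data channels (sensors or sources).
#' @param sample_rate Sampling rate of the generated epochs, Hz.
#' @param epoch_window Epoch start and end in ms relative to cue onset.
#' @param mean_levels Mean-reward levels (currency units).
#' @param cv_levels Coefficient-of-variation levels (dimensionless).
#' @return An object of class `design_spec`.
#' @seealso [counterbalance_table()], [simulate_dataset()]
#' @export
design_spec <- function(n_subjects = 18L,
                        n_trials_per_subject = 450L,
                        n_channels = 13L,
                        sample_rate = 200,
                        epoch_window = c(0, 2000),
                        mean_levels = c(1, 2, 3),
                        cv_levels = c(0.08, 0.16, 0.24)) {
  n_subjects <- as.integer(n_subjects)
  n_trials_per_subject <- as.integer(n_trials_per_subject)
  if (length(mean_levels) < 2L || length(cv_levels) < 2L) {
    stop("mean_levels and cv_levels each need at least 2 entries")
  }
  if (n_subjects %% 6L != 0L) {
    stop(sprintf(
      paste0("n_subjects = %d cannot be counterbalanced: the fill-to-mean ",
             "mapping (2 variants) crossed with the color-to-variability ",
             "rotation (3 variants) requires a multiple of 6 ",
             "(valid counts: 6, 12, 18, 24, ...)"),
      n_subjects
    ))
  }
  n_cells <- length(mean_levels) * length(cv_levels)
  if (n_trials_per_subject %% n_cells != 0L) {
    stop(sprintf("n_trials_per_subject = %d is not a multiple of the %d design cells",
                 n_trials_per_subject, n_cells))
  }
  if (length(epoch_window) != 2L || diff(epoch_window) <= 0) {
    stop("epoch_window must be (start_ms, end_ms) with end > start")
  }
  structure(
    list(
      n_subjects = n_subjects,
      n_trials_per_subject = n_trials_per_subject,
      n_channels = as.integer(n_channels),
      sample_rate = sample_rate,
      epoch_window = as.numeric(epoch_window),
      mean_levels = as.numeric(mean_levels),
      cv_levels = as.numeric(cv_levels),
      counterbalance = counterbalance_table(n_subjects)
    ),
    class = "design_spec"
  )
}

#' Counterbalancing table for cue-outcome mappings
#'
#' Assigns each subject one of two fill-to-mean mappings (`+1`: empty/half/full
#' signal low/medium/high reward; `-1`: the empty/full assignment reversed,
#' half always medium), one of three cyclic color-to-variability rotations,
#' and a response-hand assignment, cycling through the six mapping
#' combinations so that every combination occurs equally often. Pooled across
#' subjects, fill is then exactly uncorrelated with mean reward and each color
#' is paired with each variability level equally often.
#'
#' @param n_subjects Number of subjects, a multiple of 6.
#' @return A data frame with columns `subject`, `fill_map` (+1/-1),
#'   `color_rot` (0, 1, 2) and `hand` ("fill_left"/"fill_right").
#' @export
counterbalance_table <- function(n_subjects) {
  n_subjects <- as.integer(n_subjects)
  if (n_subjects %% 6L != 0L) {
    stop("counterbalancing requires a multiple of 6 subjects (6, 12, 18, ...)")
  }
  combos <- expand.grid(fill_map = c(1L, -1L), color_rot = 0:2,
                        KEEP.OUT.ATTRS = FALSE)
  idx <- rep_len(seq_len(nrow(combos)), n_subjects)
  data.frame(
    subject = seq_len(n_subjects),
    fill_map = combos$fill_map[idx],
    color_rot = combos$color_rot[idx],
    hand = rep_len(c("fill_left", "fill_right"), n_subjects),
    stringsAsFactors = FALSE
  )
}

#' Discrete reward-outcome set with exact mean and coefficient of variation
#'
#' Builds the symmetric, equally spaced, equiprobable outcome set
#' `{mean - d, mean, mean + d}` (for `n_outcomes = 3`) whose population mean
#' equals `mean` and whose population coefficient of variation (SD/mean, SD
#' taken over the discrete uniform distribution on the set) equals `cv`
#' exactly; `d = cv * mean * sqrt(3/2)`. For other `n_outcomes` the set is the
#' equally spaced symmetric grid with the same two moments.
#'
#' @param mean Expected value of the outcome set (currency, > 0).
#' @param cv Coefficient of variation (>= 0).
#' @param n_outcomes Number of outcomes (>= 2); default 3.
#' @return Numeric vector of strictly positive outcomes, sorted increasing.
#' @examples
#' reward_outcomes(2, 0.16)                 # exact CV: sd(x)*sqrt(2/3)/mean
#' @export
reward_outcomes <- function(mean, cv, n_outcomes = 3L) {
  stopifnot(length(mean) == 1L, length(cv) == 1L)
  if (mean <= 0) stop("mean must be positive")
  if (cv < 0) stop("cv must be non-negative")
  n <- as.integer(n_outcomes)
  if (n < 2L) stop("n_outcomes must be at least 2")
  pos <- seq_len(n) - (n + 1) / 2           # symmetric integer grid
  # population variance of the uniform grid = step^2 * (n^2 - 1)/12
  step <- if (cv == 0) 0 else cv * mean / sqrt((n^2 - 1) / 12)
  out <- mean + step * pos
  if (out[1L] <= 0) {
    stop(sprintf(
      "lowest outcome %.4f is not positive: need cv * sqrt((n^2-1)/12) * (n-1)/2 < 1 (cv = %.3f)",
      out[1L], cv
    ))
  }
  out
}

#' Per-trial stimulus/feature table for a design
#'
#' Expands a [design_spec()] into the trial-level table of feature values
#' `Y` used by the encoding/decoding models: mean reward, coefficient of
#' variation, the derived SD and variance metrics, and the perceptual
#' features (fill, color) implied by each subject's counterbalance mapping.
#' Trial order within subject is randomized.
#'
#' @param spec A [design_spec()].
#' @param seed Optional integer seed controlling trial-order randomization.
#' @return A data frame with one row per trial: `subject`, `trial`,
#'   `mean_idx`, `cv_idx`, `y_mean`, `y_cv`, `y_sd`, `y_v`, the decorrelated
#'   metrics `y_sd_dec`/`y_v_dec` (see [decorrelate_metric()]), `fill`,
#'   `color`, `hand`, `correct`.
#' @export
stimulus_table <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "design_spec"))
  cb <- spec$counterbalance
  n_mean <- length(spec$mean_levels)
  n_cv <- length(spec$cv_levels)
  reps <- spec$n_trials_per_subject / (n_mean * n_cv)
  cells <- expand.grid(mean_idx = seq_len(n_mean), cv_idx = seq_len(n_cv),
                       KEEP.OUT.ATTRS = FALSE)
  with_seed(seed, {
    rows <- lapply(seq_len(spec$n_subjects), function(s) {
      ord <- sample.int(nrow(cells) * reps)
      cell <- cells[rep(seq_len(nrow(cells)), reps)[ord], , drop = FALSE]
      fill <- if (cb$fill_map[s] == 1L) cell$mean_idx else n_mean + 1L - cell$mean_idx
      color <- ((cell$cv_idx - 1L + cb$color_rot[s]) %% n_cv) + 1L
      data.frame(
        subject = s,
        trial = seq_len(nrow(cell)),
        mean_idx = cell$mean_idx,
        cv_idx = cell$cv_idx,
        y_mean = spec$mean_levels[cell$mean_idx],
        y_cv = spec$cv_levels[cell$cv_idx],
        fill = fill,
        color = color,
        hand = cb$hand[s],
        correct = TRUE,
        stringsAsFactors = FALSE
      )
    })
    tab <- do.call(rbind, rows)
    tab$y_sd <- tab$y_cv * tab$y_mean
    tab$y_v <- tab$y_sd^2
    tab$y_sd_dec <- decorrelate_metric(tab$y_sd, tab$y_mean)
    tab$y_v_dec <- decorrelate_metric(tab$y_v, tab$y_mean)
    rownames(tab) <- NULL
    tab[, c("subject", "trial", "mean_idx", "cv_idx", "y_mean", "y_cv",
            "y_sd", "y_v", "y_sd_dec", "y_v_dec", "fill", "color", "hand",
            "correct")]
  })
}
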