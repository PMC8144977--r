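#' Generate a vivid-novel-oddball (ViNO) spatial-cueing design
#'
#' Builds the event timing for a Posner-style spatial cueing task with rare
#' full-screen oddball-image bursts. Each trial lasts 7.8 s: a jittered
#' orienting phase (cue 1.5-3.0 s plus ISI, always summing to 5.2 s), a
#' 0.5 s target (T or L, upright or inverted), a 0.5 s mask and a 1.6 s ITI.
#' A run holds 48 trials in 6 blocks of 8, with exactly 33 valid trials
#' (68.75%) and exactly 8 oddball trials (1 in 6); invalid targets appear at
#' one of the three locations in the uncued hemifield. Oddball trials carry
#' five session-unique image ids. Runs start and end with 7.8 s of fixation.
#'
#' @param n_runs Number of runs (>= 1).
#' @param seed Integer seed; the design is a pure function of
#'   `(n_runs, seed)`.
#' @return Object of class `vino_design` with `trials` (one row per trial),
#'   `tr`, `n_trs_per_run`, `fixation_duration` and `n_runs`. Locations 1-3
#'   are in the left hemifield, 4-6 in the right.
#' @export
#' @examples
#' d <- generate_vino_design(n_runs = 4, seed = 2)
#' mean(d$trials$validity == "valid")   # 0.6875
generate_vino_design <- function(n_runs, seed) {
  if (!is.numeric(n_runs) || length(n_runs) != 1L || n_runs < 1) {
    .stopf("n_runs must be a positive integer")
  }
  n_runs <- as.integer(n_runs)
  set.seed(as.integer(seed))

  tr <- 2.6
  n_trials <- 48L
  trial_dur <- 7.8
  orient_dur <- 5.2
  fixation <- 7.8
  n_valid <- 33L
  n_oddball <- n_trials / 6L
  next_image_id <- 1L

  runs <- vector("list", n_runs)
  for (run in seq_len(n_runs)) {
    validity <- rep("valid", n_trials)
    validity[sample.int(n_trials, n_trials - n_valid)] <- "invalid"
    oddball <- rep(FALSE, n_trials)
    oddball[sample.int(n_trials, n_oddball)] <- TRUE

    cue_location <- sample(1:6, n_trials, replace = TRUE)
    cue_duration <- stats::runif(n_trials, 1.5, 3.0)
    isi <- orient_dur - cue_duration
    letter <- sample(c("T", "L"), n_trials, replace = TRUE)
    orientation <- sample(c("upright", "inverted"), n_trials, replace = TRUE)

    target_location <- cue_location
    inv <- which(validity == "invalid")
    for (i in inv) {
      uncued <- if (cue_location[i] <= 3L) 4:6 else 1:3
      target_location[i] <- sample(uncued, 1L)
    }

    image_ids <- rep(NA_character_, n_trials)
    for (i in which(oddball)) {
      ids <- next_image_id:(next_image_id + 4L)
      image_ids[i] <- paste(ids, collapse = ",")
      next_image_id <- next_image_id + 5L
    }

    onset <- fixation + (seq_len(n_trials) - 1L) * trial_dur
    runs[[run]] <- data.frame(
      run = run,
      trial_index = seq_len(n_trials),
      block = rep(1:6, each = 8L),
      onset = onset,
      cue_location = cue_location,
      cue_duration = cue_duration,
      isi = isi,
      target_onset = onset + orient_dur,
      target_duration = 0.5,
      target_letter = letter,
      target_orientation = orientation,
      target_location = target_location,
      validity = validity,
      oddball = oddball,
      oddball_image_ids = image_ids,
      stringsAsFactors = FALSE
    )
  }

  structure(
    list(
      trials = do.call(rbind, runs),
      tr = tr,
      trial_duration = trial_dur,
      fixation_duration = fixation,
      n_trs_per_run = as.integer((2 * fixation + n_trials * trial_dur) / tr),
      n_runs = n_runs
    ),
    class = "vino_design"
  )
}

#' @export
print.vino_design <- function(x, ...) {
  cat(sprintf("<vino_design> %d run(s) x %d trials, %d TRs/run (TR = %g s)\n",
              x$n_runs, nrow(x$trials) / x$n_runs, x$n_trs_per_run, x$tr))
  invisible(x)
}
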