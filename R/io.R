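#' Read and write event tables
#'
#' Events use the BIDS events dialect: tab-delimited with a header and at
#' least `onset`, `duration`, `trial_type` columns; times in seconds,
#' 0-based from run start, intervals half-open `[onset, onset + duration)`.
#' Writing is at full numeric precision so the round trip is lossless.
#' Unsorted onsets are accepted on read and sorted with a warning; negative
#' durations are an error.
#'
#' @param path File path.
#' @return `read_events` returns the validated event data.frame.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) .stopf("events file not found: %s", path)
  ev <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("onset", "duration", "trial_type")
  miss <- setdiff(need, names(ev))
  if (length(miss)) .stopf("events file is missing column(s): %s", paste(miss, collapse = ", "))
  if (any(ev$duration < 0)) .stopf("negative durations in events file")
  if (is.unsorted(ev$onset)) {
    .warnf("event onsets were not sorted; sorting by onset")
    ev <- ev[order(ev$onset), ]
    rownames(ev) <- NULL
  }
  ev
}

#' @rdname read_events
#' @param events Event data.frame with at least `onset`, `duration`,
#'   `trial_type`.
#' @export
write_events <- function(events, path) {
  need <- c("onset", "duration", "trial_type")
  miss <- setdiff(need, names(events))
  if (length(miss)) .stopf("events are missing column(s): %s", paste(miss, collapse = ", "))
  if (any(events$duration < 0)) .stopf("negative durations")
  utils::write.table(events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert a task design to an event table
#'
#' For the MOT design, `collapse_phases = TRUE` (the GLM convention)
#' returns one event per trial spanning the whole 18.2 s trial with
#' `trial_type` attend/passive; otherwise one row per trial phase. For the
#' ViNO design, each trial yields a target event typed by cue validity
#' (`valid`/`invalid`) and a mask event typed by oddball status
#' (`oddball`/`non_oddball`), matching the condition predictors of the
#' task's GLM.
#'
#' @param design A `mot_design` or `vino_design`.
#' @param run Run number to extract.
#' @param collapse_phases MOT only; see above.
#' @return Event data.frame with `onset`, `duration`, `trial_type` and
#'   attribute columns.
#' @export
design_to_events <- function(design, run = 1L, collapse_phases = TRUE) {
  UseMethod("design_to_events")
}

#' @export
design_to_events.mot_design <- function(design, run = 1L, collapse_phases = TRUE) {
  tr <- design$trials[design$trials$run == run, ]
  if (!nrow(tr)) .stopf("run %d not present in design", run)
  if (collapse_phases) {
    out <- data.frame(
      onset = tr$onset,
      duration = design$trial_duration,
      trial_type = tr$condition,
      trial_index = tr$trial_index,
      probe_is_target = tr$probe_is_target,
      stringsAsFactors = FALSE
    )
  } else {
    out <- do.call(rbind, lapply(seq_len(nrow(tr)), function(i) {
      data.frame(
        onset = c(tr$cue_onset[i], tr$motion_onset[i], tr$probe_onset[i]),
        duration = c(3.0, tr$motion_duration[i], tr$probe_duration[i]),
        trial_type = paste(tr$condition[i], c("cue", "motion", "probe"), sep = "_"),
        trial_index = tr$trial_index[i],
        stringsAsFactors = FALSE
      )
    }))
  }
  rownames(out) <- NULL
  out
}

#' @export
design_to_events.vino_design <- function(design, run = 1L, collapse_phases = TRUE) {
  tr <- design$trials[design$trials$run == run, ]
  if (!nrow(tr)) .stopf("run %d not present in design", run)
  target_ev <- data.frame(
    onset = tr$target_onset,
    duration = tr$target_duration,
    trial_type = tr$validity,
    trial_index = tr$trial_index,
    stringsAsFactors = FALSE
  )
  mask_ev <- data.frame(
    onset = tr$target_onset + tr$target_duration,
    duration = 0.5,
    trial_type = ifelse(tr$oddball, "oddball", "non_oddball"),
    trial_index = tr$trial_index,
    stringsAsFactors = FALSE
  )
  out <- rbind(target_ev, mask_ev)
  out <- out[order(out$onset), ]
  rownames(out) <- NULL
  out
}

#' Write a derived report table
#'
#' Tab-delimited UTF-8 with a header row; floating values at 6 significant
#' digits so reruns diff cleanly.
#'
#' @param x Data.frame.
#' @param path File path.
#' @export
write_report_table <- function(x, path) {
  num <- vapply(x, is.numeric, TRUE)
  x[num] <- lapply(x[num], signif, digits = 6)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
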