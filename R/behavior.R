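#' Score behavioural responses for a task design
#'
#' Computes per-subject behavioural summaries before any group averaging.
#' For an MOT design: hit rate and false-alarm rate over attend trials and
#' the tracking-capacity estimate Cowan's k = (hit rate - false-alarm rate)
#' x 4.0 (four tracked targets). For a ViNO design: accuracy fraction, mean
#' reaction time on valid and invalid trials (correct responses within the
#' response window only) and the validity effect
#' `mean_rt_invalid - mean_rt_valid`.
#'
#' Trials without a usable response (no response recorded, or a ViNO
#' response after the 2.6 s window, which counts as a miss) are excluded
#' from all denominators and reported via a message.
#'
#' @param responses Data.frame with one row per trial: columns `run`,
#'   `trial_index`, `response` (`"yes"`/`"no"` for MOT, `"T"`/`"L"` for
#'   ViNO, `NA` for no response) and, for ViNO, `rt` (seconds from target
#'   onset).
#' @param design A `mot_design` or `vino_design`.
#' @param subject,group Optional identifiers copied into the summary.
#' @param rt_window ViNO response window in seconds.
#' @return One-row data.frame of class `behavioral_summary`.
#' @export
score_behavior <- function(responses, design, subject = NA, group = NA,
                           rt_window = 2.6) {
  UseMethod("score_behavior", design)
}

#' @export
score_behavior.default <- function(responses, design, ...) {
  .stopf("no behaviour scorer for class '%s'", class(design)[1])
}

.merge_responses <- function(responses, trials) {
  need <- c("run", "trial_index", "response")
  miss <- setdiff(need, names(responses))
  if (length(miss)) .stopf("responses are missing column(s): %s", paste(miss, collapse = ", "))
  m <- merge(trials, responses, by = c("run", "trial_index"), all.x = TRUE)
  m[order(m$run, m$trial_index), ]
}

#' @export
score_behavior.mot_design <- function(responses, design, subject = NA,
                                      group = NA, rt_window = 2.6) {
  m <- .merge_responses(responses, design$trials)
  att <- m[m$condition == "attend", ]
  missing <- is.na(att$response)
  if (any(missing)) {
    message(sprintf("score_behavior: excluding %d attend trial(s) without a response",
                    sum(missing)))
  }
  att <- att[!missing, ]
  said_yes <- att$response == "yes"
  is_target <- as.logical(att$probe_is_target)
  hit_rate <- mean(said_yes[is_target])
  fa_rate <- mean(said_yes[!is_target])
  out <- data.frame(
    subject = subject, group = group, task = "mot",
    hit_rate = hit_rate, false_alarm_rate = fa_rate,
    k = (hit_rate - fa_rate) * 4.0,
    n_trials_scored = nrow(att),
    stringsAsFactors = FALSE
  )
  class(out) <- c("behavioral_summary", class(out))
  out
}

#' @export
score_behavior.vino_design <- function(responses, design, subject = NA,
                                       group = NA, rt_window = 2.6) {
  m <- .merge_responses(responses, design$trials)
  if (!"rt" %in% names(m)) m$rt <- NA_real_
  usable <- !is.na(m$response) & !is.na(m$rt) & m$rt <= rt_window & m$rt >= 0
  if (any(!usable)) {
    message(sprintf("score_behavior: excluding %d trial(s) with no response inside the %g s window",
                    sum(!usable), rt_window))
  }
  m <- m[usable, ]
  if (nrow(m) == 0L) .stopf("no scorable trials")
  correct <- m$response == m$target_letter
  rt_ms <- m$rt * 1000
  mean_rt <- function(keep) {
    if (!any(keep)) NA_real_ else mean(rt_ms[keep])
  }
  rt_valid <- mean_rt(correct & m$validity == "valid")
  rt_invalid <- mean_rt(correct & m$validity == "invalid")
  out <- data.frame(
    subject = subject, group = group, task = "vino",
    accuracy = mean(correct),
    mean_rt_valid = rt_valid,
    mean_rt_invalid = rt_invalid,
    validity_effect = rt_invalid - rt_valid,
    n_trials_scored = nrow(m),
    stringsAsFactors = FALSE
  )
  class(out) <- c("behavioral_summary", class(out))
  out
}

#' Simulate button-press responses for an MOT design
#'
#' Bernoulli observer: on attend trials the subject answers "yes" with
#' probability `hit_rate` when the probe is a tracked target and with
#' probability `false_alarm_rate` otherwise; passive trials get an arbitrary
#' press.
#'
#' @param design A `mot_design`.
#' @param hit_rate,false_alarm_rate Response probabilities in `[0, 1]`.
#' @param seed Integer seed.
#' @return Data.frame with `run`, `trial_index`, `response`.
#' @export
simulate_mot_responses <- function(design, hit_rate, false_alarm_rate, seed) {
  stopifnot(hit_rate >= 0, hit_rate <= 1,
            false_alarm_rate >= 0, false_alarm_rate <= 1)
  set.seed(as.integer(seed))
  tr <- design$trials
  p_yes <- ifelse(tr$condition == "attend",
                  ifelse(as.logical(tr$probe_is_target), hit_rate, false_alarm_rate),
                  0.5)
  data.frame(
    run = tr$run,
    trial_index = tr$trial_index,
    response = ifelse(stats::runif(nrow(tr)) < p_yes, "yes", "no"),
    stringsAsFactors = FALSE
  )
}

#' Simulate responses for a ViNO design
#'
#' Correct with probability `accuracy`; reaction times are Gaussian with
#' separate means for valid and invalid trials (milliseconds), truncated at
#' zero.
#'
#' @param design A `vino_design`.
#' @param accuracy Probability of a correct identification.
#' @param rt_valid_ms,rt_invalid_ms Mean RTs in milliseconds.
#' @param rt_sd_ms RT standard deviation in milliseconds.
#' @param seed Integer seed.
#' @return Data.frame with `run`, `trial_index`, `response`, `rt` (seconds).
#' @export
simulate_vino_responses <- function(design, accuracy = 0.87, rt_valid_ms = 801,
                                    rt_invalid_ms = 851, rt_sd_ms = 120, seed = 1) {
  stopifnot(accuracy >= 0, accuracy <= 1)
  set.seed(as.integer(seed))
  tr <- design$trials
  correct <- stats::runif(nrow(tr)) < accuracy
  other <- ifelse(tr$target_letter == "T", "L", "T")
  mu <- ifelse(tr$validity == "valid", rt_valid_ms, rt_invalid_ms)
  rt <- pmax(stats::rnorm(nrow(tr), mu, rt_sd_ms), 50) / 1000
  data.frame(
    run = tr$run,
    trial_index = tr$trial_index,
    response = ifelse(correct, tr$target_letter, other),
    rt = rt,
    stringsAsFactors = FALSE
  )
}
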