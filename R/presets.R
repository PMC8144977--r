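#' Group presets for the synthetic cohort generator
#'
#' A preset bundles the generator parameters for one subject group: sample
#' size, the subject-level distribution of the true dorsal-attention vs
#' default-mode (DAN-DMN) correlation, run structure, motion-spike and
#' noise settings, and the task-response parameters. The three shipped
#' presets encode the study conditions of the three cohorts compared in the
#' resting-state analysis:
#'
#' * `preset_meditator()`: n = 13, r ~ Normal(-0.55, 0.18), two 139-TR runs
#'   at TR 2.6 s (two 6-minute runs, 278 timepoints in total).
#' * `preset_inlab()`: n = 21, r ~ Normal(-0.41, 0.21), same run structure.
#' * `preset_hcp()`: n = 168, r ~ Normal(-0.39, 0.19), four 346-TR runs
#'   (a four-runs-of-fifteen-minutes regime expressed at TR 2.6 s).
#'
#' Task-effect sizes are percent-signal-change amplitudes of the attend
#' condition relative to passive, per network (DAN positive, DMN negative).
#'
#' @param name Preset name.
#' @param n_subjects Number of subjects.
#' @param r_mean,r_sd Mean and SD of the subject-level true DAN-DMN
#'   correlation (`|r_mean| < 1`, `r_sd > 0`); sampled values are clipped
#'   to (-0.999, 0.999).
#' @param n_runs,n_timepoints,tr Run structure.
#' @param motion_spike_rate Per-timepoint probability of a motion spike.
#' @param spike_amplitude Spike step size in millimetres (above the 0.5 mm
#'   censoring threshold by default).
#' @param drift_amplitude Amplitude of low-frequency drift (z units).
#' @param noise_sd Parcel-level noise SD (z units).
#' @param confound_leak_sd SD of per-parcel confound leakage coefficients.
#' @param bold_spike_sd BOLD artifact SD at spiked timepoints (z units).
#' @param hit_rate,false_alarm_rate Programmed MOT response rates.
#' @param task_effects Named percent-signal-change amplitudes
#'   (`DAN`, `DMN`, `VAN`) for attend vs passive.
#' @param baseline Baseline signal level for task runs.
#' @return A list of class `group_preset`.
#' @export
group_preset <- function(name, n_subjects, r_mean, r_sd,
                         n_runs = 2L, n_timepoints = 139L, tr = 2.6,
                         motion_spike_rate = 0.05, spike_amplitude = 1.0,
                         drift_amplitude = 0.5, noise_sd = 1.0,
                         confound_leak_sd = 0.3, bold_spike_sd = 3.0,
                         hit_rate = 0.6, false_alarm_rate = 0.35,
                         task_effects = c(DAN = 0.5, DMN = -0.15, VAN = 0),
                         baseline = 100) {
  if (abs(r_mean) >= 1) .stopf("|r_mean| must be < 1")
  if (r_sd <= 0) .stopf("r_sd must be positive")
  if (n_subjects < 1) .stopf("n_subjects must be >= 1")
  if (motion_spike_rate < 0 || motion_spike_rate >= 1) .stopf("invalid motion_spike_rate")
  if (noise_sd < 0 || drift_amplitude < 0) .stopf("noise and drift amplitudes must be >= 0")
  structure(
    list(name = name, n_subjects = as.integer(n_subjects),
         r_mean = r_mean, r_sd = r_sd,
         n_runs = as.integer(n_runs), n_timepoints = as.integer(n_timepoints),
         tr = tr, motion_spike_rate = motion_spike_rate,
         spike_amplitude = spike_amplitude,
         drift_amplitude = drift_amplitude, noise_sd = noise_sd,
         confound_leak_sd = confound_leak_sd, bold_spike_sd = bold_spike_sd,
         hit_rate = hit_rate, false_alarm_rate = false_alarm_rate,
         task_effects = task_effects, baseline = baseline),
    class = "group_preset"
  )
}

#' @export
print.group_preset <- function(x, ...) {
  cat(sprintf("<group_preset> %s: n = %d, r ~ N(%.2f, %.2f), %d run(s) x %d TRs @ %g s\n",
              x$name, x$n_subjects, x$r_mean, x$r_sd, x$n_runs, x$n_timepoints, x$tr))
  invisible(x)
}

#' @rdname group_preset
#' @export
preset_meditator <- function(n_subjects = 13) {
  group_preset("meditator", n_subjects, r_mean = -0.55, r_sd = 0.18,
               hit_rate = 0.64, false_alarm_rate = 0.33,
               task_effects = c(DAN = 0.5870, DMN = -0.1938, VAN = 0))
}

#' @rdname group_preset
#' @export
preset_inlab <- function(n_subjects = 21) {
  group_preset("inlab", n_subjects, r_mean = -0.41, r_sd = 0.21,
               hit_rate = 0.57, false_alarm_rate = 0.39,
               task_effects = c(DAN = 0.4342, DMN = -0.0965, VAN = 0))
}

#' @rdname group_preset
#' @export
preset_hcp <- function(n_subjects = 168) {
  group_preset("hcp", n_subjects, r_mean = -0.39, r_sd = 0.19,
               n_runs = 4L, n_timepoints = 346L)
}

#' @rdname group_preset
#' @export
shipped_presets <- function() {
  list(meditator = preset_meditator(), inlab = preset_inlab(), hcp = preset_hcp())
}
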