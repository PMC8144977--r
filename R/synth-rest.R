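# Band-limited unit-variance noise columns: white noise band-pass filtered
# with the same Butterworth family the pipeline uses, generated with padding
# so edge transients fall outside the returned window. Returns n x k, each
# column centred with unit sample SD.
.band_noise_mat <- function(n, k, tr, band = c(0.01, 0.08), order = 4L, pad = 150L) {
  X <- matrix(stats::rnorm((n + 2L * pad) * k), ncol = k)
  Y <- t(.bandpass_run(t(X), tr, band, order))
  Y <- Y[(pad + 1L):(pad + n), , drop = FALSE]
  Y <- scale(Y)
  attributes(Y)[c("scaled:center", "scaled:scale")] <- NULL
  Y
}

.band_noise <- function(n, tr, band = c(0.01, 0.08), order = 4L, pad = 150L) {
  .band_noise_mat(n, 1L, tr, band, order, pad)[, 1L]
}

# Latent pair with an exact in-sample correlation r: the second latent is
# built from the component of an independent band-limited series orthogonal
# to the first, so that cor(a, b) == r to machine precision on this window.
.latent_pair_from <- function(a, e, r) {
  a <- a - mean(a)
  a <- a / stats::sd(a)
  e <- e - mean(e)
  e <- e - a * sum(a * e) / sum(a * a)
  e <- e / stats::sd(e)
  list(a = a, b = r * a + sqrt(1 - r^2) * e, e = e)
}

.latent_pair <- function(n, r, tr, band) {
  Z <- .band_noise_mat(n, 2L, tr, band)
  .latent_pair_from(Z[, 1L], Z[, 2L], r)
}

# Smooth base motion: slow random walk, translations in mm, rotations in
# radians, with framewise increments far below the censoring threshold.
.base_motion <- function(tp) {
  trans <- apply(matrix(stats::rnorm(tp * 3L, 0, 0.004), tp, 3L), 2L, cumsum)
  rot <- apply(matrix(stats::rnorm(tp * 3L, 0, 0.0002), tp, 3L), 2L, cumsum)
  cbind(trans, rot)
}

#' Generate one synthetic resting-state subject
#'
#' Builds parcel time series, a motion trace and a confound table with the
#' statistical structure every pipeline stage assumes, for the given group
#' preset. Per hemisphere, the dorsal-attention and default-mode parcels
#' share a latent band-limited pair whose in-sample correlation equals the
#' subject's true r, drawn from `Normal(r_mean, r_sd)` and clipped to
#' (-0.999, 0.999); the same draw is used for both hemispheres. On top of
#' the latents the generator adds parcel-level noise (centred within each
#' network so network means stay exactly on the latents), low-frequency
#' drift, leakage of the global/white-matter/ventricle confound analogues
#' and of motion, plus high-motion spikes: step changes in the motion
#' parameters above the framewise-displacement threshold with a coincident
#' BOLD artifact. Parcels outside the two networks of interest carry a
#' balancing component that makes the across-parcel mean of the structured
#' signal exactly zero, so the injected correlation is preserved through
#' mean-signal regression.
#'
#' @param preset A [group_preset()].
#' @param subject_seed Integer seed; the subject is a pure function of
#'   `(preset, subject_seed)`.
#' @param atlas Atlas lookup.
#' @return List with `ts` (`parcel_ts`), `motion` (`motion_trace`),
#'   `confounds` (timepoints x 15 matrix), `true_r` (named per-hemisphere
#'   vector) and `spike_timepoints` (concatenated indices).
#' @export
generate_rest_subject <- function(preset, subject_seed, atlas = synthetic_atlas()) {
  stopifnot(inherits(preset, "group_preset"))
  .check_atlas(atlas)
  set.seed(as.integer(subject_seed))

  P <- nrow(atlas)
  tp <- preset$n_timepoints
  n_runs <- preset$n_runs
  tr <- preset$tr
  band <- c(0.01, 0.08)
  true_r <- .clip_r(stats::rnorm(1, preset$r_mean, preset$r_sd))

  hemis <- c("L", "R")
  nets <- yeo7_networks()
  idx_net <- lapply(hemis, function(h) {
    lapply(stats::setNames(nets, nets), function(nw) {
      which(atlas$hemisphere == h & atlas$network == nw)
    })
  })
  names(idx_net) <- hemis
  other_nets <- setdiff(nets, c("DorsAttn", "Default"))
  groups <- lapply(hemis, function(h) idx_net[[h]])
  group_ids <- unlist(lapply(groups, function(g) g), recursive = FALSE)

  # centre per-parcel coefficients within each network-hemisphere group so
  # that network-mean series carry exactly the latents (the generator's
  # core contract: nuisance structure lives at the parcel level and cancels
  # in the network average; the pipeline removes what it can of the rest)
  center_groups <- function(M) {
    for (ids in group_ids) {
      M[ids, ] <- M[ids, , drop = FALSE] -
        matrix(colMeans(M[ids, , drop = FALSE]), length(ids), ncol(M), byrow = TRUE)
    }
    M
  }

  # per-subject leakage and drift coefficients (constant across runs)
  leak <- center_groups(matrix(stats::rnorm(P * 3L, 0, preset$confound_leak_sd), P, 3L))
  motion_leak <- center_groups(matrix(stats::rnorm(P * 6L, 0, 0.05), P, 6L))
  drift_coef <- center_groups(matrix(stats::rnorm(P * 3L, 0, preset$drift_amplitude), P, 3L))
  # one slow sinusoid shape per network-hemisphere group
  drift_freq_grp <- stats::runif(length(group_ids), 0.002, 0.008)
  drift_phase_grp <- stats::runif(length(group_ids), 0, 2 * pi)
  drift_freq <- drift_phase <- numeric(P)
  for (gi in seq_along(group_ids)) {
    drift_freq[group_ids[[gi]]] <- drift_freq_grp[gi]
    drift_phase[group_ids[[gi]]] <- drift_phase_grp[gi]
  }

  ts_runs <- vector("list", n_runs)
  motion_runs <- vector("list", n_runs)
  conf_runs <- vector("list", n_runs)
  spike_tps <- integer(0)

  for (run in seq_len(n_runs)) {
    # ---- motion with injected spikes
    M <- .base_motion(tp)
    spikes <- which(stats::runif(tp) < preset$motion_spike_rate)
    spikes <- spikes[spikes > 1L]
    for (t0 in spikes) {
      j <- sample(1:3, 1L)
      step <- sample(c(-1, 1), 1L) * preset$spike_amplitude * (1 + 0.2 * stats::runif(1))
      M[t0:tp, j] <- M[t0:tp, j] + step
    }
    spike_tps <- c(spike_tps, spikes + (run - 1L) * tp)

    # ---- nuisance signals (AR(1) analogues)
    ar1 <- function() {
      x <- as.numeric(stats::filter(stats::rnorm(tp), 0.9, "recursive"))
      (x - mean(x)) / .safe_sd(x)
    }
    g <- ar1(); wm <- ar1(); vent <- ar1()

    # ---- structured signal per hemisphere
    Y <- matrix(0, P, tp)
    for (h in hemis) {
      Z <- .band_noise_mat(tp, 2L + length(other_nets), tr, band)
      pair <- .latent_pair_from(Z[, 1L], Z[, 2L], true_r)
      latents <- list(DorsAttn = pair$a, Default = pair$b)

      # Background-network latents: independent band-limited series with the
      # (a, e) plane projected out, recentred so the count-weighted sum of
      # all network latents is (near) zero, then rescaled to unit variance.
      # The across-parcel mean of the structured signal is then essentially
      # pure nuisance and, because every parcel carries unit-variance
      # content, per-run z-scoring preserves the balance, so the injected
      # network correlation survives mean-signal regression.
      n_a <- length(idx_net[[h]][["DorsAttn"]])
      n_b <- length(idx_net[[h]][["Default"]])
      target <- n_a * pair$a + n_b * pair$b
      n_oth <- vapply(other_nets, function(nw) length(idx_net[[h]][[nw]]), 0L)
      n_bg <- sum(n_oth)
      ztil <- sapply(seq_along(other_nets), function(k) {
        z <- Z[, 2L + k]
        z <- z - mean(z)
        z <- z - pair$a * sum(pair$a * z) / sum(pair$a^2)
        z <- z - pair$e * sum(pair$e * z) / sum(pair$e^2)
        z / stats::sd(z)
      })
      # w_k have count-weighted sum zero and are orthogonal to the (a, e)
      # plane; scaling them individually keeps the sum's latent content
      # exactly -target while giving every background parcel unit variance.
      vsum <- drop(ztil %*% n_oth)
      var_t <- stats::var(target)
      for (k in seq_along(other_nets)) {
        w <- ztil[, k] - vsum / n_bg
        alpha <- sqrt(max(1 - var_t / n_bg^2, 0.01)) / .safe_sd(w)
        latents[[other_nets[k]]] <- alpha * w - target / n_bg
      }
      for (nw in nets) {
        ids <- idx_net[[h]][[nw]]
        Y[ids, ] <- matrix(latents[[nw]], length(ids), tp, byrow = TRUE)
      }

      # parcel noise, centred within each network so network means carry
      # exactly the latents
      for (nw in nets) {
        ids <- idx_net[[h]][[nw]]
        E <- matrix(stats::rnorm(length(ids) * tp, 0, preset$noise_sd),
                    length(ids), tp)
        E <- E - matrix(colMeans(E), length(ids), tp, byrow = TRUE)
        Y[ids, ] <- Y[ids, ] + E
      }
    }

    # ---- drift, confound leakage, spike artifacts
    t_norm <- seq(-1, 1, length.out = tp)
    t_sec <- (seq_len(tp) - 1L) * tr
    drift <- drift_coef[, 1L] %o% t_norm + drift_coef[, 2L] %o% (t_norm^2) +
      drift_coef[, 3L] %o% rep(1, tp) * sin(drift_freq %o% (2 * pi * t_sec) +
                                              matrix(drift_phase, P, tp))
    Y <- Y + drift
    Y <- Y + leak %*% rbind(g, wm, vent)
    Mz <- scale(M)
    Y <- Y + motion_leak %*% t(Mz)
    if (length(spikes)) {
      art <- center_groups(matrix(stats::rnorm(P * length(spikes), 0,
                                               preset$bold_spike_sd),
                                  P, length(spikes)))
      Y[, spikes] <- Y[, spikes] + art
    }

    ts_runs[[run]] <- Y
    motion_runs[[run]] <- M
    conf_runs[[run]] <- cbind(g, wm, vent)
  }

  motion <- motion_trace(do.call(rbind, motion_runs), tr, rep(tp, n_runs))
  nuis <- do.call(rbind, conf_runs)
  confounds <- confound_set(motion, nuis[, 1L], nuis[, 2L], nuis[, 3L])
  list(
    ts = parcel_ts(do.call(cbind, ts_runs), tr, rep(tp, n_runs), atlas$parcel_id),
    motion = motion,
    confounds = confounds,
    true_r = c(L = true_r, R = true_r),
    spike_timepoints = spike_tps
  )
}

#' Generate one synthetic task subject
#'
#' Parcel time series for an MOT session: condition regressors are built by
#' convolving the attend/passive boxcars with the gamma HRF, and networks
#' respond with the preset's percent-signal-change amplitudes (dorsal
#' attention positive, default mode negative for attend vs passive) around
#' the preset baseline. Behavioural responses follow the preset's
#' programmed hit and false-alarm rates.
#'
#' @param design A `mot_design`.
#' @param preset A [group_preset()].
#' @param subject_seed Integer seed.
#' @param atlas Atlas lookup.
#' @param noise_sd Noise SD in raw signal units (defaults to 1% of
#'   baseline).
#' @return List with `ts` (`parcel_ts`, one run per design run), `motion`
#'   (`motion_trace`) and `responses` (data.frame).
#' @export
generate_task_subject <- function(design, preset, subject_seed,
                                  atlas = synthetic_atlas(),
                                  noise_sd = preset$baseline / 100) {
  stopifnot(inherits(design, "mot_design"), inherits(preset, "group_preset"))
  .check_atlas(atlas)
  if (abs(design$tr - preset$tr) > 1e-9) {
    .stopf("design TR (%g) and preset TR (%g) differ", design$tr, preset$tr)
  }
  set.seed(as.integer(subject_seed))

  P <- nrow(atlas)
  n_tr <- design$n_trs_per_run
  tr <- design$tr
  rois <- roi_definitions(atlas)
  eff <- preset$task_effects

  ts_runs <- vector("list", design$n_runs)
  motion_runs <- vector("list", design$n_runs)
  for (run in seq_len(design$n_runs)) {
    trials <- design$trials[design$trials$run == run, ]
    x_cond <- lapply(c(attend = "attend", passive = "passive"), function(cn) {
      ev <- trials[trials$condition == cn, ]
      .convolve_events(ev$onset, rep(design$trial_duration, nrow(ev)),
                       n_tr, tr, hrf_params())
    })
    amp <- matrix(0, P, 2L)  # columns: attend, passive (psc units)
    amp[match(rois$DAN, atlas$parcel_id), 1L] <- eff[["DAN"]]
    amp[match(rois$DMN, atlas$parcel_id), 1L] <- eff[["DMN"]]
    if ("VAN" %in% names(eff) && eff[["VAN"]] != 0) {
      amp[match(rois$VAN, atlas$parcel_id), 1L] <- eff[["VAN"]]
    }
    signal_mat <- preset$baseline *
      (1 + (amp[, 1L] %o% x_cond$attend + amp[, 2L] %o% x_cond$passive) / 100)
    Y <- signal_mat + matrix(stats::rnorm(P * n_tr, 0, noise_sd), P, n_tr)
    ts_runs[[run]] <- Y
    motion_runs[[run]] <- .base_motion(n_tr)
  }

  responses <- simulate_mot_responses(design, preset$hit_rate,
                                      preset$false_alarm_rate,
                                      seed = as.integer(subject_seed) %% 1000003L + 1L)
  list(
    ts = parcel_ts(do.call(cbind, ts_runs), tr, rep(n_tr, design$n_runs),
                   atlas$parcel_id),
    motion = motion_trace(do.call(rbind, motion_runs), tr,
                          rep(n_tr, design$n_runs)),
    responses = responses
  )
}
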