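#' Framewise displacement from realignment parameters
#'
#' FD at timepoint t is the sum of the absolute first differences of the
#' six motion parameters, with the three rotations first converted from
#' radians to millimetres as arc length on a sphere (`angle * radius_mm`;
#' 50 mm by convention). The first timepoint of every run has FD = 0.
#' Timepoints with FD above `threshold` are flagged for censoring.
#'
#' @param motion A `motion_trace`.
#' @param radius_mm Sphere radius for the rotation-to-millimetre conversion.
#' @param threshold Censoring threshold in millimetres (default 0.5).
#' @return Object of class `fd_series`: `fd` (mm), logical `censor` flags,
#'   `threshold`, `run_lengths`.
#' @export
framewise_displacement <- function(motion, radius_mm = 50, threshold = 0.5) {
  if (!inherits(motion, "motion_trace")) .stopf("motion must be a motion_trace")
  P <- motion$params
  if (!all(is.finite(P))) .stopf("motion contains non-finite values")
  conv <- P
  conv[, 4:6] <- conv[, 4:6] * radius_mm
  fd <- numeric(nrow(P))
  bounds <- .run_bounds(motion$run_lengths)
  for (b in seq_len(nrow(bounds))) {
    idx <- bounds[b, "start"]:bounds[b, "end"]
    if (length(idx) < 2L) .stopf("runs must have at least 2 timepoints")
    d <- abs(diff(conv[idx, , drop = FALSE]))
    fd[idx] <- c(0, rowSums(d))
  }
  structure(
    list(fd = fd, censor = fd > threshold, threshold = threshold,
         run_lengths = motion$run_lengths),
    class = "fd_series"
  )
}

#' @export
print.fd_series <- function(x, ...) {
  cat(sprintf("<fd_series> %d timepoints, %d flagged above %g mm\n",
              length(x$fd), sum(x$censor), x$threshold))
  invisible(x)
}

#' Confound table from motion and nuisance signals
#'
#' Assembles the 15-column confound set used by [nuisance_regress()]:
#' global-mean, white-matter and ventricle analogues, the six motion
#' parameters and their six temporal derivatives (backward differences,
#' zero at each run start).
#'
#' @param motion A `motion_trace`.
#' @param global_signal,wm,ventricle Numeric vectors aligned to the motion
#'   trace.
#' @return Timepoints x 15 numeric matrix.
#' @export
confound_set <- function(motion, global_signal, wm, ventricle) {
  n <- nrow(motion$params)
  stopifnot(length(global_signal) == n, length(wm) == n, length(ventricle) == n)
  derivs <- matrix(0, n, 6L)
  bounds <- .run_bounds(motion$run_lengths)
  for (b in seq_len(nrow(bounds))) {
    idx <- bounds[b, "start"]:bounds[b, "end"]
    derivs[idx[-1L], ] <- diff(motion$params[idx, , drop = FALSE])
  }
  out <- cbind(global = global_signal, white_matter = wm, ventricle = ventricle,
               motion$params, derivs)
  colnames(out) <- c("global", "white_matter", "ventricle",
                     colnames(motion$params),
                     paste0("d_", colnames(motion$params)))
  out
}

#' Regress nuisance confounds out of parcel time series
#'
#' Per run and per parcel, replaces the series by the residuals of an OLS
#' regression on an intercept plus the confound columns (head motion and
#' derivatives, global/white-matter/ventricle signals). Collinear confound
#' columns are dropped with a warning.
#'
#' @param ts A `parcel_ts`.
#' @param confounds Timepoints x k numeric matrix aligned to `ts` (see
#'   [confound_set()]).
#' @return A `parcel_ts` of residuals.
#' @export
nuisance_regress <- function(ts, confounds) {
  confounds <- as.matrix(confounds)
  if (nrow(confounds) != ncol(ts$data)) {
    .stopf("confounds have %d rows but series have %d timepoints",
           nrow(confounds), ncol(ts$data))
  }
  out <- ts$data
  bounds <- .run_bounds(ts$run_lengths)
  for (b in seq_len(nrow(bounds))) {
    idx <- bounds[b, "start"]:bounds[b, "end"]
    X <- cbind(intercept = 1, confounds[idx, , drop = FALSE])
    qrx <- qr(X)
    if (qrx$rank < ncol(X)) {
      drop_cols <- colnames(X)[qrx$pivot[(qrx$rank + 1L):ncol(X)]]
      .warnf("dropping collinear confound column(s) in run %d: %s",
             b, paste(drop_cols, collapse = ", "))
      X <- X[, qrx$pivot[seq_len(qrx$rank)], drop = FALSE]
      qrx <- qr(X)
    }
    out[, idx] <- t(qr.resid(qrx, t(ts$data[, idx, drop = FALSE])))
  }
  parcel_ts(out, ts$tr, ts$run_lengths, ts$parcel_ids)
}

# Single-pass IIR filter (zero initial conditions) applied column-wise to a
# time x channels matrix; numerically identical to signal::filter on each
# column but vectorized through stats::filter, which handles multivariate
# input.
.iir_cols <- function(M, b, a) {
  nb <- length(b)
  pad <- matrix(0, nb - 1L, ncol(M))
  u <- stats::filter(rbind(pad, M), b / a[1L], method = "convolution", sides = 1)
  u <- u[-seq_len(nb - 1L), , drop = FALSE]
  as.matrix(stats::filter(u, -a[-1L] / a[1L], method = "recursive"))
}

# Zero-phase (forward-backward) Butterworth bandpass applied per parcel
# within one run; same forward/backward scheme as signal::filtfilt, with
# end padding of twice the filter length.
.bandpass_run <- function(block, tr, band, order) {
  nyq <- 1 / (2 * tr)
  bf <- signal::butter(order, band / nyq, type = "pass")
  b <- bf$b
  a <- bf$a
  n <- ncol(block)
  M <- t(block)  # time x parcels
  M <- rbind(M, matrix(0, 2L * max(length(a), length(b)), ncol(M)))
  y <- .iir_cols(M, b, a)
  y <- .iir_cols(y[rev(seq_len(nrow(y))), , drop = FALSE], b, a)
  t(y[rev(seq_len(nrow(y))), , drop = FALSE][seq_len(n), , drop = FALSE])
}

#' Censor high-motion timepoints and band-pass filter
#'
#' Within each run: flagged timepoints are replaced by linear interpolation
#' between the nearest unflagged neighbours (nearest-value extension at run
#' edges) so that motion artifacts do not spread during filtering; a
#' zero-phase Butterworth band-pass (default 4th order, 0.01-0.08 Hz) is
#' applied per parcel; the flagged timepoints are then deleted. Runs are
#' filtered independently.
#'
#' @param ts A `parcel_ts`.
#' @param fd An `fd_series` aligned to `ts` (its `censor` flags drive the
#'   scrubbing).
#' @param band Passband in Hz, `c(low, high)`; `high` must lie below the
#'   Nyquist frequency `1/(2 * tr)`.
#' @param order Butterworth order.
#' @return A `parcel_ts` containing only retained timepoints; attribute
#'   `retained` holds their original (concatenated) indices and attribute
#'   `censored` the deleted ones.
#' @export
censor_and_filter <- function(ts, fd, band = c(0.01, 0.08), order = 4L) {
  if (!inherits(fd, "fd_series")) .stopf("fd must be an fd_series")
  if (length(fd$fd) != ncol(ts$data)) .stopf("fd and time series lengths differ")
  nyq <- 1 / (2 * ts$tr)
  if (band[2] >= nyq) .stopf("band high edge %g Hz must be below Nyquist %g Hz", band[2], nyq)
  if (band[1] <= 0 || band[1] >= band[2]) .stopf("invalid passband")

  bounds <- .run_bounds(ts$run_lengths)
  blocks <- list()
  retained_global <- integer(0)
  new_lengths <- integer(0)
  for (b in seq_len(nrow(bounds))) {
    idx <- bounds[b, "start"]:bounds[b, "end"]
    flags <- fd$censor[idx]
    if (all(flags)) .stopf("run %d is entirely flagged for motion", b)
    block <- ts$data[, idx, drop = FALSE]
    if (any(flags)) {
      good <- which(!flags)
      for (t0 in which(flags)) {
        left <- good[good < t0]
        right <- good[good > t0]
        if (!length(left)) {
          block[, t0] <- block[, right[1L]]
        } else if (!length(right)) {
          block[, t0] <- block[, left[length(left)]]
        } else {
          l <- left[length(left)]
          r <- right[1L]
          w <- (t0 - l) / (r - l)
          block[, t0] <- (1 - w) * block[, l] + w * block[, r]
        }
      }
    }
    block <- .bandpass_run(block, ts$tr, band, order)
    keep <- which(!flags)
    blocks[[b]] <- block[, keep, drop = FALSE]
    retained_global <- c(retained_global, idx[keep])
    new_lengths <- c(new_lengths, length(keep))
  }
  out <- parcel_ts(do.call(cbind, blocks), ts$tr, new_lengths, ts$parcel_ids)
  attr(out, "retained") <- retained_global
  attr(out, "censored") <- setdiff(seq_len(sum(ts$run_lengths)), retained_global)
  out
}

#' Harmonize runs and concatenate to a fixed length
#'
#' Each run is z-scored per parcel across its retained timepoints
#' ("normalized across time"), runs are concatenated in order, the series
#' is truncated to the first `n_keep` retained timepoints so every subject
#' contributes the same number of samples, and the mean signal across
#' parcels is regressed out of every parcel.
#'
#' @param ts A `parcel_ts` (typically the output of [censor_and_filter()]).
#' @param n_keep Number of retained timepoints to keep (default 250).
#' @param regress_mean Regress the across-parcel mean signal out of the
#'   truncated series (default `TRUE`).
#' @return A `parcel_ts` with exactly `n_keep` timepoints.
#' @export
harmonize_and_concatenate <- function(ts, n_keep = 250L, regress_mean = TRUE) {
  total <- ncol(ts$data)
  if (total < n_keep) {
    .stopf("only %d retained timepoints; %d more needed to keep %d",
           total, n_keep - total, n_keep)
  }
  out <- ts$data
  bounds <- .run_bounds(ts$run_lengths)
  for (b in seq_len(nrow(bounds))) {
    idx <- bounds[b, "start"]:bounds[b, "end"]
    block <- out[, idx, drop = FALSE]
    mu <- rowMeans(block)
    sd_ <- apply(block, 1L, stats::sd)
    sd_[sd_ < .Machine$double.eps] <- 1
    out[, idx] <- (block - mu) / sd_
  }
  out <- out[, seq_len(n_keep), drop = FALSE]
  # trim run lengths to the kept window
  cum <- cumsum(ts$run_lengths)
  kept_lengths <- pmax(pmin(cum, n_keep) - c(0L, utils::head(cum, -1L)), 0L)
  kept_lengths <- kept_lengths[kept_lengths > 0L]

  if (regress_mean) {
    m <- colMeans(out)
    if (stats::var(m) > 1e-14) {
      X <- cbind(1, m)
      out <- t(qr.resid(qr(X), t(out)))
    }
  }
  parcel_ts(out, ts$tr, kept_lengths, ts$parcel_ids)
}

#' Per-hemisphere network connectivity
#'
#' Within each hemisphere, parcels of the dorsal attention network and of
#' the default mode network are averaged into one series each and the two
#' series are Pearson-correlated.
#'
#' @param ts A `parcel_ts` whose rows follow `atlas$parcel_id` order.
#' @param atlas Atlas lookup assigning every parcel a network and
#'   hemisphere.
#' @param networks Length-2 character vector naming the two networks to
#'   correlate (defaults to the dorsal attention and default mode labels).
#' @return Data.frame with one row per hemisphere: `hemisphere`, `r`,
#'   `n_timepoints`.
#' @export
network_connectivity <- function(ts, atlas,
                                 networks = c("DorsAttn", "Default")) {
  .check_atlas(atlas)
  if (nrow(ts$data) != nrow(atlas)) {
    .stopf("time series have %d parcels but atlas lists %d", nrow(ts$data), nrow(atlas))
  }
  rows <- lapply(c("L", "R"), function(h) {
    i1 <- which(atlas$hemisphere == h & atlas$network == networks[1])
    i2 <- which(atlas$hemisphere == h & atlas$network == networks[2])
    if (!length(i1) || !length(i2)) {
      .stopf("hemisphere %s has no parcels for %s", h,
             networks[c(length(i1) == 0L, length(i2) == 0L)][1])
    }
    s1 <- colMeans(ts$data[i1, , drop = FALSE])
    s2 <- colMeans(ts$data[i2, , drop = FALSE])
    data.frame(hemisphere = h, r = stats::cor(s1, s2),
               n_timepoints = ncol(ts$data), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Full resting-state connectivity pipeline for one subject
#'
#' Chains the preprocessing stages in order: confound regression
#' ([nuisance_regress()]), framewise-displacement computation and
#' censoring with linear interpolation followed by band-pass filtering and
#' removal of flagged timepoints ([censor_and_filter()]), per-run
#' z-scoring, concatenation, truncation to `n_keep` retained timepoints and
#' mean-signal regression ([harmonize_and_concatenate()]), and
#' per-hemisphere network correlation ([network_connectivity()]).
#'
#' @param ts,motion,confounds Subject data (see [generate_rest_subject()]).
#' @param atlas Atlas lookup.
#' @param fd_threshold Censoring threshold in mm.
#' @param radius_mm Rotation-to-mm conversion radius.
#' @param band Passband in Hz.
#' @param n_keep Harmonized sample count.
#' @param filter_order Butterworth order.
#' @param regress_mean Apply the post-concatenation mean-signal regression.
#' @return Data.frame with one row per hemisphere (`hemisphere`, `r`,
#'   `n_timepoints`).
#' @export
rsfc_subject <- function(ts, motion, confounds, atlas = synthetic_atlas(),
                         fd_threshold = 0.5, radius_mm = 50,
                         band = c(0.01, 0.08), n_keep = 250L,
                         filter_order = 4L, regress_mean = TRUE) {
  clean <- nuisance_regress(ts, confounds)
  fd <- framewise_displacement(motion, radius_mm = radius_mm,
                               threshold = fd_threshold)
  filtered <- censor_and_filter(clean, fd, band = band, order = filter_order)
  harmonized <- harmonize_and_concatenate(filtered, n_keep = n_keep,
                                          regress_mean = regress_mean)
  network_connectivity(harmonized, atlas)
}
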