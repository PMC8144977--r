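#' Gamma haemodynamic response function
#'
#' Two-parameter gamma HRF with onset delay `delta` and time constant
#' `tau`: `h(t) = ((t - delta)/tau)^exponent * exp(-(t - delta)/tau)` for
#' `t >= delta` and 0 before the delay, scaled to unit peak. With the
#' defaults (delta = 2.25 s, tau = 1.25 s, exponent = 2) the peak falls at
#' `delta + exponent * tau` = 4.75 s.
#'
#' @param t Time in seconds (vector, `t >= 0`).
#' @param params List from [hrf_params()].
#' @return Amplitude values in `[0, 1]`.
#' @export
#' @examples
#' gamma_hrf(4.75)  # 1 at the peak
gamma_hrf <- function(t, params = hrf_params()) {
  if (any(t < 0)) .stopf("gamma_hrf requires t >= 0")
  delta <- params$delta
  tau <- params$tau
  a <- params$exponent
  s <- pmax(t - delta, 0) / tau
  peak <- a^a * exp(-a)
  ifelse(t < delta, 0, s^a * exp(-s) / peak)
}

#' @rdname gamma_hrf
#' @param delta Onset delay in seconds.
#' @param tau Time constant in seconds.
#' @param exponent Shape exponent (the conventional value 2 by default).
#' @export
hrf_params <- function(delta = 2.25, tau = 1.25, exponent = 2) {
  if (tau <= 0) .stopf("tau must be positive")
  list(delta = delta, tau = tau, exponent = exponent)
}

# Condition regressor: boxcar convolved with the gamma HRF on a grid
# oversampled `oversample`-fold relative to the TR, then sampled back at the
# acquisition times i*tr, i = 0..n_tr-1. Scaled by dt / integral(h) so that a
# sustained block plateaus at 1; betas are then directly interpretable as
# plateau amplitudes (and percent signal change after division by baseline).
.convolve_events <- function(onsets, durations, n_tr, tr, hrf, oversample = 10L) {
  dt <- tr / oversample
  n_fine <- n_tr * oversample
  t_fine <- (seq_len(n_fine) - 1L) * dt
  box <- numeric(n_fine)
  for (k in seq_along(onsets)) {
    idx <- which(t_fine >= onsets[k] & t_fine < onsets[k] + durations[k])
    box[idx] <- box[idx] + 1
  }
  t_h <- seq(0, hrf$delta + 12 * hrf$tau, by = dt)
  h <- gamma_hrf(t_h, hrf)
  gain <- sum(h) * dt
  conv <- stats::convolve(box, rev(h), type = "open")[seq_len(n_fine)] * dt / gain
  conv[((seq_len(n_tr) - 1L) * oversample) + 1L]
}

#' Build a GLM design matrix from an event table
#'
#' One column per non-baseline condition (any `trial_type` other than
#' `"fixation"`), formed by convolving the condition boxcar with the gamma
#' HRF at 10x oversampling (onsets need not be TR-locked). Head-motion
#' nuisance regressors are the first three left singular vectors of the
#' column-centred six-parameter motion matrix; singular vectors whose
#' singular value is numerically zero (e.g. for rank-deficient motion) are
#' dropped with a warning. An intercept and optional polynomial drift
#' columns complete the matrix, which must be of full column rank.
#'
#' @param events Data.frame with `onset`, `duration`, `trial_type` (seconds,
#'   0-based from run start).
#' @param motion Optional `motion_trace` (or timepoints x 6 matrix) for the
#'   run.
#' @param n_tr Number of timepoints.
#' @param tr Repetition time in seconds.
#' @param hrf [hrf_params()].
#' @param n_motion_pcs Number of motion eigenvectors to retain.
#' @param drift_order Polynomial drift order (0 = intercept only).
#' @param oversample Oversampling factor for convolution.
#' @return Object of class `attnet_design`: the design matrix with
#'   attributes `condition_cols` and `tr`.
#' @export
build_design_matrix <- function(events, motion = NULL, n_tr, tr,
                                hrf = hrf_params(), n_motion_pcs = 3L,
                                drift_order = 0L, oversample = 10L) {
  need <- c("onset", "duration", "trial_type")
  miss <- setdiff(need, names(events))
  if (length(miss)) .stopf("events are missing column(s): %s", paste(miss, collapse = ", "))
  if (nrow(events) &&
      any(events$onset + events$duration > n_tr * tr + 1e-9)) {
    .stopf("events extend beyond the run (%g s)", n_tr * tr)
  }

  conditions <- setdiff(unique(events$trial_type), "fixation")
  cond_cols <- sapply(conditions, function(cn) {
    ev <- events[events$trial_type == cn, ]
    .convolve_events(ev$onset, ev$duration, n_tr, tr, hrf, oversample)
  })
  if (length(conditions) == 0L) {
    cond_cols <- matrix(numeric(0), nrow = n_tr, ncol = 0L)
  }
  cond_cols <- matrix(cond_cols, nrow = n_tr,
                      dimnames = list(NULL, conditions))

  X <- cbind(intercept = rep(1, n_tr), cond_cols)

  if (drift_order > 0L) {
    tt <- seq(-1, 1, length.out = n_tr)
    for (d in seq_len(drift_order)) {
      X <- cbind(X, tt^d)
      colnames(X)[ncol(X)] <- paste0("drift", d)
    }
  }

  if (!is.null(motion)) {
    M <- if (inherits(motion, "motion_trace")) motion$params else as.matrix(motion)
    if (nrow(M) != n_tr) .stopf("motion has %d timepoints, expected %d", nrow(M), n_tr)
    Mc <- scale(M, center = TRUE, scale = FALSE)
    sv <- svd(Mc)
    keep <- which(sv$d > max(sv$d) * 1e-8)
    keep <- keep[seq_len(min(length(keep), n_motion_pcs))]
    if (length(keep) < n_motion_pcs) {
      .warnf("motion matrix has rank %d; keeping %d motion eigenvector(s) instead of %d",
             length(keep), length(keep), n_motion_pcs)
    }
    if (length(keep)) {
      U <- sv$u[, keep, drop = FALSE]
      colnames(U) <- paste0("motion_pc", seq_along(keep))
      X <- cbind(X, U)
    }
  }

  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1L):ncol(X)]]
    .stopf("design matrix is rank deficient; collinear column(s): %s",
           paste(bad, collapse = ", "))
  }
  structure(X, condition_cols = conditions, tr = tr, class = c("attnet_design", "matrix"))
}

#' Fit an ordinary-least-squares GLM to parcel time series
#'
#' Per-parcel OLS with contrast t statistics. For contrast weights `c`,
#' `t = c'b / sqrt(sigma2 * c'(X'X)^-1 c)` with
#' `dof = timepoints - rank(X)` and two-sided p values.
#'
#' @param ts `parcel_ts` or parcels x timepoints matrix.
#' @param X Design matrix from [build_design_matrix()].
#' @param contrasts Named list of contrast weights; each element is either a
#'   full-length numeric vector over columns of `X` or a named vector over a
#'   subset of column names (zeros elsewhere), e.g.
#'   `list(attend_vs_passive = c(attend = 1, passive = -1))`.
#' @return Object of class `glm_result` with `betas` (parcels x regressors),
#'   `sigma2`, `dof`, and per-contrast `estimate`, `t`, `p` matrices
#'   (parcels x contrasts).
#' @export
fit_glm <- function(ts, X, contrasts = list()) {
  Y <- if (inherits(ts, "parcel_ts")) ts$data else as.matrix(ts)
  if (!all(is.finite(Y))) .stopf("time series contain non-finite values")
  if (!all(is.finite(X))) .stopf("design matrix contains non-finite values")
  n <- ncol(Y)
  if (nrow(X) != n) .stopf("design has %d rows but series have %d timepoints", nrow(X), n)

  qrx <- qr(X)
  rank <- qrx$rank
  if (rank < ncol(X)) .stopf("design matrix is rank deficient")
  B <- qr.coef(qrx, t(Y))                  # regressors x parcels
  res <- t(Y) - X %*% B
  dof <- n - rank
  sigma2 <- colSums(res^2) / dof
  xtx_inv <- chol2inv(qr.R(qrx))

  cmat <- lapply(contrasts, function(w) {
    full <- numeric(ncol(X))
    names(full) <- colnames(X)
    if (!is.null(names(w)) && all(names(w) %in% colnames(X))) {
      full[names(w)] <- w
    } else if (length(w) == ncol(X)) {
      full[] <- w
    } else {
      .stopf("contrast weights must be named by design columns or full length")
    }
    full
  })

  est <- tval <- pval <- matrix(NA_real_, nrow(Y), length(cmat),
                                dimnames = list(NULL, names(cmat)))
  for (k in seq_along(cmat)) {
    cv <- cmat[[k]]
    ce <- drop(crossprod(cv, B))                  # per parcel
    var_c <- drop(crossprod(cv, xtx_inv %*% cv))  # scalar
    se <- sqrt(sigma2 * var_c)
    est[, k] <- ce
    tval[, k] <- ce / se
    pval[, k] <- 2 * stats::pt(-abs(ce / se), dof)
  }

  structure(
    list(betas = t(B), sigma2 = sigma2, dof = dof,
         contrast = est, t = tval, p = pval,
         design_columns = colnames(X)),
    class = "glm_result"
  )
}

#' @export
print.glm_result <- function(x, ...) {
  cat(sprintf("<glm_result> %d parcels, %d regressors, dof = %d, contrasts: %s\n",
              nrow(x$betas), ncol(x$betas), x$dof,
              paste(colnames(x$contrast), collapse = ", ")))
  invisible(x)
}

#' ROI percent signal change for a contrast
#'
#' Per parcel, percent signal change is 100 x contrast estimate / baseline,
#' where the baseline is the intercept estimate (fixation being the
#' unmodelled baseline condition). The ROI value is the mean over the ROI's
#' parcels, computed separately per hemisphere.
#'
#' @param result A `glm_result` whose design included an `intercept` column.
#' @param atlas Atlas lookup covering all parcels.
#' @param contrast Contrast name present in `result`.
#' @param rois Named list of parcel-id vectors (default [roi_definitions()]
#'   of `atlas`).
#' @param subject,group Optional identifiers copied into the output.
#' @return Data.frame with one row per ROI x hemisphere:
#'   `subject, group, hemisphere, network, contrast, percent_signal_change`.
#' @export
roi_percent_signal_change <- function(result, atlas, contrast,
                                      rois = roi_definitions(atlas),
                                      subject = NA, group = NA) {
  .check_atlas(atlas)
  if (!contrast %in% colnames(result$contrast)) {
    .stopf("contrast '%s' not found in fit", contrast)
  }
  if (!"intercept" %in% colnames(result$betas)) {
    .stopf("fit has no intercept column to serve as baseline")
  }
  baseline <- result$betas[, "intercept"]
  if (any(baseline <= 0)) .stopf("baseline mean <= 0 for %d parcel(s)", sum(baseline <= 0))
  psc <- 100 * result$contrast[, contrast] / baseline

  rows <- list()
  for (roi in names(rois)) {
    ids <- rois[[roi]]
    if (!length(ids)) next
    for (h in c("L", "R")) {
      sel <- atlas$parcel_id %in% ids & atlas$hemisphere == h
      if (!any(sel)) .stopf("ROI %s has no parcels in hemisphere %s", roi, h)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = subject, group = group, hemisphere = h, network = roi,
        contrast = contrast,
        percent_signal_change = mean(psc[which(sel)]),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
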