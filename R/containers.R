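#' Parcel-by-timepoint BOLD container
#'
#' Light S3 container for a parcels x timepoints matrix sampled at a fixed
#' repetition time (TR), with run boundaries recorded so that per-run
#' operations (filtering, z-scoring) never cross runs.
#'
#' @param data Numeric matrix, parcels in rows, timepoints in columns.
#' @param tr Repetition time in seconds.
#' @param run_lengths Integer vector of per-run timepoint counts; must sum
#'   to `ncol(data)`.
#' @param parcel_ids Optional integer parcel ids (defaults to row order).
#' @return An object of class `parcel_ts`.
#' @export
parcel_ts <- function(data, tr, run_lengths = ncol(data), parcel_ids = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data)) .stopf("parcel_ts data must be numeric")
  run_lengths <- as.integer(run_lengths)
  if (any(run_lengths <= 0L)) .stopf("run lengths must be positive")
  if (sum(run_lengths) != ncol(data)) {
    .stopf("run lengths sum to %d but data has %d timepoints",
           sum(run_lengths), ncol(data))
  }
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0) .stopf("tr must be a positive scalar")
  if (is.null(parcel_ids)) parcel_ids <- seq_len(nrow(data))
  structure(
    list(data = data, tr = tr, run_lengths = run_lengths,
         parcel_ids = as.integer(parcel_ids)),
    class = "parcel_ts"
  )
}

#' @export
print.parcel_ts <- function(x, ...) {
  cat(sprintf("<parcel_ts> %d parcels x %d timepoints, TR = %g s, runs: %s\n",
              nrow(x$data), ncol(x$data), x$tr,
              paste(x$run_lengths, collapse = " + ")))
  invisible(x)
}

#' @export
dim.parcel_ts <- function(x) dim(x$data)

#' Head-motion trace container
#'
#' Six rigid-body realignment parameters per timepoint: three translations
#' in millimetres and three rotations in radians.
#'
#' @param params Numeric matrix, timepoints x 6, columns
#'   `trans_x, trans_y, trans_z, rot_x, rot_y, rot_z`.
#' @param tr Repetition time in seconds.
#' @param run_lengths Per-run timepoint counts summing to `nrow(params)`.
#' @return An object of class `motion_trace`.
#' @export
motion_trace <- function(params, tr, run_lengths = nrow(params)) {
  params <- as.matrix(params)
  if (ncol(params) != 6L) .stopf("motion trace must have 6 columns, got %d", ncol(params))
  if (!all(is.finite(params))) .stopf("motion trace contains non-finite values")
  run_lengths <- as.integer(run_lengths)
  if (sum(run_lengths) != nrow(params)) {
    .stopf("run lengths sum to %d but motion has %d timepoints",
           sum(run_lengths), nrow(params))
  }
  colnames(params) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  structure(list(params = params, tr = tr, run_lengths = run_lengths),
            class = "motion_trace")
}

#' @export
print.motion_trace <- function(x, ...) {
  cat(sprintf("<motion_trace> %d timepoints, TR = %g s, runs: %s\n",
              nrow(x$params), x$tr, paste(x$run_lengths, collapse = " + ")))
  invisible(x)
}
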