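#' @keywords internal
"_PACKAGE"

# Clip a correlation into the open interval (-limit, limit).
.clip_r <- function(r, limit = 0.999) pmin(pmax(r, -limit), limit)

# Sample standard deviation that tolerates constant vectors.
.safe_sd <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s)) 0 else s
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Start/end column indices of each run inside a concatenated series.
.run_bounds <- function(run_lengths) {
  ends <- cumsum(run_lengths)
  starts <- ends - run_lengths + 1L
  cbind(start = starts, end = ends)
}

# Derive a stream of child seeds from one master seed, all < 2^31.
.child_seeds <- function(master_seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(master_seed))
  sample.int(.Machine$integer.max, n)
}
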