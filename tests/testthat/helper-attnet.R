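# Shared fixtures and independent oracles used across the test files.

# Brute-force framewise displacement straight from the definition: convert
# rotations to mm on a sphere, absolute first differences, row sums, zero at
# each run start.
fd_oracle <- function(params, run_lengths, radius_mm = 50) {
  conv <- params
  conv[, 4:6] <- conv[, 4:6] * radius_mm
  fd <- numeric(nrow(params))
  start <- 1L
  for (len in run_lengths) {
    idx <- start:(start + len - 1L)
    fd[idx] <- c(0, rowSums(abs(apply(conv[idx, , drop = FALSE], 2L, diff))))
    start <- start + len
  }
  fd
}

# Exhaustive frame-by-frame re-check of the trajectory invariants.
check_trajectories <- function(traj) {
  pos <- traj$positions
  r <- traj$radius
  n_frames <- dim(pos)[2]
  min_gap <- Inf
  contained <- TRUE
  for (f in seq_len(n_frames)) {
    for (h in c("L", "R")) {
      idx <- which(traj$hemifield == h)
      p <- pos[idx, f, ]
      d <- as.matrix(stats::dist(p))
      min_gap <- min(min_gap, min(d[upper.tri(d)]))
      w <- traj$walls[[h]]
      contained <- contained &&
        all(p[, 1] >= w["xmin"] + r - 1e-9) && all(p[, 1] <= w["xmax"] - r + 1e-9) &&
        all(p[, 2] >= w["ymin"] + r - 1e-9) && all(p[, 2] <= w["ymax"] - r + 1e-9)
    }
  }
  list(min_gap = min_gap, contained = contained)
}

# Small balanced ROI table for the group statistics tests: one L and one R
# observation per subject, optional group offset and hemisphere effect.
make_psc_table <- function(n_a = 13, n_b = 13, group_effect = 0,
                           hemi_effect = 0, subj_sd = 1, noise_sd = 1,
                           seed = 1) {
  set.seed(seed)
  n <- n_a + n_b
  subj <- sprintf("s%03d", seq_len(n))
  group <- rep(c("a", "b"), c(n_a, n_b))
  u <- rnorm(n, 0, subj_sd)
  long <- expand.grid(subject = subj, hemisphere = c("L", "R"),
                      stringsAsFactors = FALSE)
  long <- long[order(long$subject), ]
  long$group <- group[match(long$subject, subj)]
  long$percent_signal_change <-
    u[match(long$subject, subj)] +
    ifelse(long$group == "a", group_effect, 0) +
    ifelse(long$hemisphere == "R", hemi_effect, 0) +
    rnorm(nrow(long), 0, noise_sd)
  long
}

# Classical repeated-measures (split-plot) ANOVA oracle via aov/Error().
rm_anova_oracle <- function(tab) {
  d <- data.frame(
    subject = factor(tab$subject), group = factor(tab$group),
    hemisphere = factor(tab$hemisphere), value = tab$percent_signal_change
  )
  fit <- stats::aov(value ~ group * hemisphere + Error(subject), data = d)
  s <- summary(fit)
  between <- s[["Error: subject"]][[1]]
  within <- s[["Error: Within"]][[1]]
  rownames(between) <- trimws(rownames(between))
  rownames(within) <- trimws(rownames(within))
  c(group = between["group", "F value"],
    hemisphere = within["hemisphere", "F value"],
    interaction = within["group:hemisphere", "F value"])
}
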