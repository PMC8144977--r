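#' Generate a multiple-object-tracking (MOT) design
#'
#' Builds the event timing for a sustained covert-attention tracking task.
#' Each trial lasts 18.2 s (seven 2.6 s TRs) and comprises a 3 s cue phase
#' (0.5 s pre-cue, 2.0 s cue, 0.5 s post-cue), a 12.7 s motion phase and a
#' 2.5 s probe phase. A run holds 16 trials, alternating "attend" (track
#' four cued discs, two per hemifield, out of twelve) and "passive" (all
#' discs cued; no tracking demand), preceded and followed by two fixation
#' TRs, giving 116 timepoints per run. On attend trials the probe disc is a
#' tracked target on exactly half the trials.
#'
#' @param n_runs Number of runs (>= 1).
#' @param seed Integer seed; the design is a pure function of
#'   `(n_runs, seed)`.
#' @param first_condition Condition of trial 1; trials then strictly
#'   alternate.
#' @return Object of class `mot_design`: a list with `trials` (one row per
#'   trial, onsets in seconds from run start), `tr`, `n_trs_per_run`,
#'   `n_fixation_trs` and `n_runs`.
#' @export
#' @examples
#' d <- generate_mot_design(n_runs = 1, seed = 1)
#' nrow(d$trials)      # 16
#' d$n_trs_per_run     # 116
generate_mot_design <- function(n_runs, seed, first_condition = "attend") {
  if (!is.numeric(n_runs) || length(n_runs) != 1L || n_runs < 1) {
    .stopf("n_runs must be a positive integer")
  }
  n_runs <- as.integer(n_runs)
  first_condition <- match.arg(first_condition, c("attend", "passive"))
  set.seed(as.integer(seed))

  tr <- 2.6
  n_trials <- 16L
  trial_dur <- 18.2
  fix_trs <- c(start = 2L, end = 2L)
  left_discs <- 1:6
  right_discs <- 7:12

  runs <- lapply(seq_len(n_runs), function(run) {
    cond <- rep(c(first_condition,
                  setdiff(c("attend", "passive"), first_condition)),
                length.out = n_trials)
    attend_idx <- which(cond == "attend")
    # probe identity balanced: half the attend trials probe a tracked target
    probe_is_target <- rep(NA, n_trials)
    hit_trials <- sample(attend_idx, length(attend_idx) / 2L)
    probe_is_target[attend_idx] <- attend_idx %in% hit_trials

    targets <- character(n_trials)
    probe <- integer(n_trials)
    for (i in seq_len(n_trials)) {
      if (cond[i] == "attend") {
        tg <- c(sample(left_discs, 2L), sample(right_discs, 2L))
        targets[i] <- paste(tg, collapse = ",")
        probe[i] <- if (probe_is_target[i]) sample(tg, 1L) else sample(setdiff(1:12, tg), 1L)
      } else {
        targets[i] <- paste(1:12, collapse = ",")
        probe[i] <- sample(1:12, 1L)
      }
    }
    onset <- fix_trs[["start"]] * tr + (seq_len(n_trials) - 1L) * trial_dur
    data.frame(
      run = run,
      trial_index = seq_len(n_trials),
      condition = cond,
      onset = onset,
      cue_onset = onset,
      pre_cue_duration = 0.5,
      cue_duration = 2.0,
      post_cue_duration = 0.5,
      motion_onset = onset + 3.0,
      motion_duration = 12.7,
      probe_onset = onset + 3.0 + 12.7,
      probe_duration = 2.5,
      targets = targets,
      probe = probe,
      probe_is_target = probe_is_target,
      stringsAsFactors = FALSE
    )
  })

  structure(
    list(
      trials = do.call(rbind, runs),
      tr = tr,
      trial_duration = trial_dur,
      n_trs_per_run = as.integer(round(fix_trs[["start"]] + n_trials * trial_dur / tr +
                                         fix_trs[["end"]])),
      n_fixation_trs = fix_trs,
      n_runs = n_runs
    ),
    class = "mot_design"
  )
}

#' @export
print.mot_design <- function(x, ...) {
  cat(sprintf("<mot_design> %d run(s) x %d trials, %d TRs/run (TR = %g s)\n",
              x$n_runs, nrow(x$trials) / x$n_runs, x$n_trs_per_run, x$tr))
  invisible(x)
}

#' Default MOT display geometry
#'
#' Hemifield rectangles (degrees of visual angle), disc radius and the
#' repulsion-dynamics constants. The exact values are display conventions;
#' the contract is the non-overlap and containment invariants of
#' [simulate_disc_trajectories()].
#'
#' @param radius Disc radius in degrees.
#' @param base_speed Constant disc speed in degrees/s.
#' @param repulsion_disc,repulsion_wall Force constants, inversely
#'   proportional to gap distance.
#' @export
mot_geometry <- function(radius = 0.6, base_speed = 4,
                         repulsion_disc = 2, repulsion_wall = 1.5) {
  list(
    radius = radius,
    base_speed = base_speed,
    repulsion_disc = repulsion_disc,
    repulsion_wall = repulsion_wall,
    # walls: xmin, xmax, ymin, ymax per hemifield
    walls = list(
      L = c(xmin = -10.5, xmax = -1.5, ymin = -6.75, ymax = 6.75),
      R = c(xmin = 1.5, xmax = 10.5, ymin = -6.75, ymax = 6.75)
    )
  )
}

#' Simulate MOT disc trajectories with a repulsion algorithm
#'
#' Twelve discs (six per hemifield) move at constant speed on independent
#' trajectories; pairwise and wall repulsion forces inversely proportional
#' to the gap distance steer the discs so that they never overlap and never
#' leave their assigned hemifield rectangle. A projection step enforces the
#' constraints exactly at every frame.
#'
#' @param design Optional `mot_design`; if supplied, the motion-phase
#'   duration is taken from it.
#' @param frame_rate Frames per second.
#' @param seed Integer seed.
#' @param duration Motion duration in seconds (default the MOT motion
#'   phase, 12.7 s).
#' @param geometry See [mot_geometry()].
#' @return Object of class `trajectory_set`: `positions` (disc x frame x 2
#'   array, degrees), `hemifield` per disc, `frame_rate`, `radius`, `walls`.
#' @export
simulate_disc_trajectories <- function(design = NULL, frame_rate = 60, seed = 1,
                                       duration = NULL, geometry = mot_geometry()) {
  if (is.null(duration)) {
    duration <- if (!is.null(design)) design$trials$motion_duration[1] else 12.7
  }
  set.seed(as.integer(seed))
  n_per_hemi <- 6L
  n_frames <- as.integer(floor(duration * frame_rate)) + 1L
  dt <- 1 / frame_rate
  r <- geometry$radius

  place_discs <- function(wall, n) {
    pos <- matrix(NA_real_, n, 2L)
    sep <- 2 * r * 1.25
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try in seq_len(2000L)) {
        p <- c(stats::runif(1, wall["xmin"] + r, wall["xmax"] - r),
               stats::runif(1, wall["ymin"] + r, wall["ymax"] - r))
        if (i == 1L || all(sqrt(rowSums((pos[seq_len(i - 1L), , drop = FALSE] -
                                           matrix(p, i - 1L, 2L, byrow = TRUE))^2)) >= sep)) {
          pos[i, ] <- p
          ok <- TRUE
          break
        }
      }
      if (!ok) .stopf("hemifield rectangle too small to place %d non-overlapping discs", n)
    }
    pos
  }

  hemis <- c(rep("L", n_per_hemi), rep("R", n_per_hemi))
  positions <- array(NA_real_, c(2L * n_per_hemi, n_frames, 2L))
  pos <- rbind(place_discs(geometry$walls$L, n_per_hemi),
               place_discs(geometry$walls$R, n_per_hemi))
  theta <- stats::runif(2L * n_per_hemi, 0, 2 * pi)
  vel <- geometry$base_speed * cbind(cos(theta), sin(theta))
  positions[, 1L, ] <- pos

  step_hemi <- function(p, v, wall) {
    n <- nrow(p)
    f <- matrix(0, n, 2L)
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        d <- p[i, ] - p[j, ]
        dist <- sqrt(sum(d^2))
        gap <- max(dist - 2 * r, 1e-3)
        push <- geometry$repulsion_disc / gap * d / max(dist, 1e-6)
        f[i, ] <- f[i, ] + push
        f[j, ] <- f[j, ] - push
      }
    }
    # wall repulsion along each axis
    f[, 1] <- f[, 1] + geometry$repulsion_wall / pmax(p[, 1] - r - wall["xmin"], 1e-3)
    f[, 1] <- f[, 1] - geometry$repulsion_wall / pmax(wall["xmax"] - r - p[, 1], 1e-3)
    f[, 2] <- f[, 2] + geometry$repulsion_wall / pmax(p[, 2] - r - wall["ymin"], 1e-3)
    f[, 2] <- f[, 2] - geometry$repulsion_wall / pmax(wall["ymax"] - r - p[, 2], 1e-3)

    v <- v + f * dt
    speed <- sqrt(rowSums(v^2))
    v <- v * geometry$base_speed / pmax(speed, 1e-9)
    p <- p + v * dt

    # hard projection: containment then pairwise separation, iterated
    for (iter in seq_len(50L)) {
      p[, 1] <- pmin(pmax(p[, 1], wall["xmin"] + r), wall["xmax"] - r)
      p[, 2] <- pmin(pmax(p[, 2], wall["ymin"] + r), wall["ymax"] - r)
      violated <- FALSE
      for (i in seq_len(n - 1L)) {
        for (j in (i + 1L):n) {
          d <- p[i, ] - p[j, ]
          dist <- sqrt(sum(d^2))
          if (dist < 2 * r) {
            violated <- TRUE
            dir <- if (dist > 1e-9) d / dist else c(1, 0)
            shift <- (2 * r - dist + 1e-6) / 2
            p[i, ] <- p[i, ] + dir * shift
            p[j, ] <- p[j, ] - dir * shift
          }
        }
      }
      if (!violated) break
    }
    list(p = p, v = v)
  }

  if (n_frames > 1L) {
    for (fr in 2L:n_frames) {
      for (h in c("L", "R")) {
        idx <- which(hemis == h)
        st <- step_hemi(pos[idx, , drop = FALSE], vel[idx, , drop = FALSE],
                        geometry$walls[[h]])
        pos[idx, ] <- st$p
        vel[idx, ] <- st$v
      }
      positions[, fr, ] <- pos
    }
  }

  structure(
    list(positions = positions, hemifield = hemis, frame_rate = frame_rate,
         radius = r, walls = geometry$walls),
    class = "trajectory_set"
  )
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("<trajectory_set> %d discs x %d frames at %g Hz (radius %g deg)\n",
              dim(x$positions)[1], dim(x$positions)[2], x$frame_rate, x$radius))
  invisible(x)
}
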