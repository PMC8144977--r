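test_that("MOT design satisfies run composition and timing invariants", {
  d <- generate_mot_design(n_runs = 1, seed = 1)
  expect_equal(nrow(d$trials), 16L)
  expect_equal(d$n_trs_per_run, 116L)
  expect_equal(d$trial_duration, 18.2)
  expect_equal(d$trial_duration / d$tr, 7)

  # counting oracle: brute-force tallies from the emitted trial rows
  expect_equal(sum(d$trials$condition == "attend"), 8L)
  expect_equal(sum(d$trials$condition == "passive"), 8L)
  # strict alternation
  expect_true(all(d$trials$condition[-1] != d$trials$condition[-16]))
  # phases partition the trial
  expect_equal(d$trials$motion_onset - d$trials$onset, rep(3.0, 16))
  expect_equal(d$trials$probe_onset - d$trials$onset, rep(15.7, 16))
  expect_equal(d$trials$pre_cue_duration + d$trials$cue_duration +
                 d$trials$post_cue_duration, rep(3.0, 16))
  # trials tile the run between the fixation blocks
  expect_equal(diff(d$trials$onset), rep(18.2, 15))
  expect_equal(d$trials$onset[1], 2 * 2.6)

  # attend trials: 4 targets, 2 per hemifield; probe identity balanced
  att <- d$trials[d$trials$condition == "attend", ]
  tg <- lapply(strsplit(att$targets, ","), as.integer)
  expect_true(all(vapply(tg, length, 0L) == 4L))
  expect_true(all(vapply(tg, function(x) sum(x <= 6), 0L) == 2L))
  expect_equal(sum(att$probe_is_target), 4L)
  ok_probe <- mapply(function(t, p, is_t) (p %in% t) == is_t,
                     tg, att$probe, att$probe_is_target)
  expect_true(all(ok_probe))

  # four runs span the printed session length
  d4 <- generate_mot_design(4, seed = 1)
  expect_equal(d4$n_runs * d4$n_trs_per_run, 464L)
})

test_that("MOT design is a pure function of its seed and rejects bad input", {
  expect_equal(generate_mot_design(2, seed = 7), generate_mot_design(2, seed = 7))
  expect_false(identical(generate_mot_design(2, seed = 7),
                         generate_mot_design(2, seed = 8)))
  expect_error(generate_mot_design(0, seed = 1), "positive")
})

test_that("disc trajectories never overlap and never leave their hemifield", {
  for (seed in 1:3) {
    traj <- simulate_disc_trajectories(frame_rate = 30, seed = seed)
    chk <- check_trajectories(traj)
    expect_gte(chk$min_gap, 2 * traj$radius)
    expect_true(chk$contained)
  }
  expect_equal(dim(simulate_disc_trajectories(frame_rate = 30, seed = 1)$positions)[1], 12L)
})

test_that("zero motion duration leaves discs at their initial placement", {
  traj <- simulate_disc_trajectories(frame_rate = 60, seed = 2, duration = 0)
  expect_equal(dim(traj$positions)[2], 1L)
  expect_true(all(is.finite(traj$positions)))
})

test_that("an undersized hemifield rectangle is rejected", {
  geom <- mot_geometry(radius = 3)
  expect_error(simulate_disc_trajectories(frame_rate = 30, seed = 1, geometry = geom),
               "too small")
})

test_that("ViNO design satisfies the session composition printed for four runs", {
  d <- generate_vino_design(n_runs = 4, seed = 2)
  expect_equal(nrow(d$trials), 192L)
  expect_equal(sum(d$trials$oddball), 32L)
  ids <- unlist(strsplit(stats::na.omit(d$trials$oddball_image_ids), ","))
  expect_equal(length(ids), 160L)
  expect_equal(length(unique(ids)), 160L)

  # per-run brute-force tallies
  for (run in 1:4) {
    tr <- d$trials[d$trials$run == run, ]
    expect_equal(nrow(tr), 48L)
    expect_equal(sum(tr$validity == "valid"), 33L)
    expect_equal(sum(tr$oddball), 8L)
    expect_equal(as.vector(table(tr$block)), rep(8L, 6L))
  }
  expect_equal(mean(d$trials$validity == "valid"), 0.6875)
})

test_that("ViNO trial timing is exact: orienting phase sums to 5.2 s inside a 7.8 s trial", {
  d <- generate_vino_design(2, seed = 5)
  expect_true(all(abs(d$trials$cue_duration + d$trials$isi - 5.2) < 1e-9))
  expect_true(all(d$trials$cue_duration >= 1.5 & d$trials$cue_duration <= 3.0))
  expect_equal(d$trial_duration, 7.8)
  expect_equal(d$n_trs_per_run, 150L)
  expect_equal(d$trials$onset[1], 7.8)
  # invalid targets appear in the uncued hemifield
  inv <- d$trials[d$trials$validity == "invalid", ]
  same_hemi <- (inv$cue_location <= 3) == (inv$target_location <= 3)
  expect_false(any(same_hemi))
  expect_false(any(inv$target_location == inv$cue_location))
  # valid targets appear at the cued location
  val <- d$trials[d$trials$validity == "valid", ]
  expect_true(all(val$target_location == val$cue_location))
  # determinism
  expect_equal(d, generate_vino_design(2, seed = 5))
})

test_that("Cowan's k scoring matches its defining formula", {
  d <- generate_mot_design(2, seed = 3)

  # ceiling: every attend probe answered correctly
  perfect <- data.frame(
    run = d$trials$run, trial_index = d$trials$trial_index,
    response = ifelse(d$trials$condition == "attend",
                      ifelse(d$trials$probe_is_target, "yes", "no"), "no"))
  s <- score_behavior(perfect, d)
  expect_equal(s$k, 4.0)
  expect_equal(s$hit_rate, 1)
  expect_equal(s$false_alarm_rate, 0)

  # hit rate equal to false-alarm rate collapses k to zero
  all_yes <- transform(perfect, response = "yes")
  expect_equal(score_behavior(all_yes, d)$k, 0)

  # direct evaluation of the formula at the printed group-mean rates
  expect_equal((0.64 - 0.33) * 4.0, 1.24)

  # missing attend trials are excluded from denominators, with a message
  miss <- perfect
  miss$response[miss$trial_index == 1] <- NA
  expect_message(s2 <- score_behavior(miss, d), "excluding")
  expect_equal(s2$n_trials_scored, sum(d$trials$condition == "attend") - 2L)
  expect_equal(s2$k, 4.0)
})

test_that("ViNO scoring computes accuracy, RT means and the validity effect", {
  d <- generate_vino_design(2, seed = 9)
  resp <- simulate_vino_responses(d, accuracy = 1, rt_valid_ms = 800,
                                  rt_invalid_ms = 850, rt_sd_ms = 1e-6, seed = 1)
  s <- score_behavior(resp, d)
  expect_equal(s$accuracy, 1)
  expect_equal(s$mean_rt_valid, 800, tolerance = 1e-6)
  expect_equal(s$mean_rt_invalid, 850, tolerance = 1e-6)
  expect_equal(s$validity_effect, s$mean_rt_invalid - s$mean_rt_valid)

  # responses after the 2.6 s window count as misses and are excluded
  late <- resp
  late$rt[1:5] <- 3.0
  expect_message(s3 <- score_behavior(late, d), "window")
  expect_equal(s3$n_trials_scored, nrow(d$trials) - 5L)
})
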