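test_that("group presets encode the three cohorts and validate their fields", {
  ps <- shipped_presets()
  expect_equal(vapply(ps, function(p) p$n_subjects, 0L),
               c(meditator = 13L, inlab = 21L, hcp = 168L))
  expect_equal(vapply(ps, function(p) p$r_mean, 0),
               c(meditator = -0.55, inlab = -0.41, hcp = -0.39))
  expect_equal(vapply(ps, function(p) p$r_sd, 0),
               c(meditator = 0.18, inlab = 0.21, hcp = 0.19))
  # in-lab regime: two runs, 278 timepoints in total at TR 2.6 s
  expect_equal(ps$meditator$n_runs * ps$meditator$n_timepoints, 278L)
  expect_equal(ps$hcp$n_runs, 4L)
  expect_error(group_preset("x", 5, r_mean = 1.2, r_sd = 0.1), "r_mean")
  expect_error(group_preset("x", 5, r_mean = 0, r_sd = 0), "r_sd")
})

test_that("rest subjects are reproducible and shaped by their preset", {
  p <- preset_meditator()
  s1 <- generate_rest_subject(p, 42)
  s2 <- generate_rest_subject(p, 42)
  expect_equal(s1, s2)
  expect_equal(dim(s1$ts$data), c(100L, 278L))
  expect_equal(s1$ts$run_lengths, c(139L, 139L))
  expect_equal(ncol(s1$confounds), 15L)
  expect_equal(dim(s1$motion$params), c(278L, 6L))
  expect_equal(s1$true_r[["L"]], s1$true_r[["R"]])
  expect_true(abs(s1$true_r[["L"]]) < 0.999)
})

test_that("network means carry the latent pair: raw network-mean correlation equals true r", {
  p <- group_preset("t", 1, r_mean = -0.5, r_sd = 0.1,
                    motion_spike_rate = 0, drift_amplitude = 0,
                    confound_leak_sd = 0, bold_spike_sd = 0)
  atlas <- synthetic_atlas()
  s <- generate_rest_subject(p, 7)
  for (h in c("L", "R")) {
    dan <- colMeans(s$ts$data[atlas$network == "DorsAttn" & atlas$hemisphere == h, 1:139])
    dmn <- colMeans(s$ts$data[atlas$network == "Default" & atlas$hemisphere == h, 1:139])
    expect_equal(cor(dan, dmn), s$true_r[[h]], tolerance = 1e-8)
  }
})

test_that("a null preset yields near-zero connectivity and a mirrored preset r near -1", {
  # noise-only null at many timepoints
  p0 <- group_preset("null", 1, r_mean = 0, r_sd = 1e-9,
                     n_runs = 1L, n_timepoints = 5000L,
                     motion_spike_rate = 0)
  s0 <- generate_rest_subject(p0, 3)
  rec0 <- network_connectivity(s0$ts, synthetic_atlas())
  expect_true(all(abs(rec0$r) < 3 / sqrt(5000) + 1e-6))

  # clipped mirror limit without noise: network means are near-exact negatives
  pm <- group_preset("mirror", 1, r_mean = -1 + 1e-12, r_sd = 1e-9,
                     noise_sd = 0, motion_spike_rate = 0,
                     drift_amplitude = 0, confound_leak_sd = 0,
                     bold_spike_sd = 0)
  sm <- generate_rest_subject(pm, 5)
  recm <- network_connectivity(sm$ts, synthetic_atlas())
  expect_true(all(recm$r < -0.998))
})

test_that("motion spikes coincide exactly with framewise-displacement exceedances", {
  p <- group_preset("t", 1, r_mean = -0.4, r_sd = 0.1,
                    motion_spike_rate = 0.06, spike_amplitude = 1.0)
  for (seed in c(2, 11)) {
    s <- generate_rest_subject(p, seed)
    fd <- framewise_displacement(s$motion)
    expect_equal(sort(which(fd$censor)), sort(s$spike_timepoints))
  }
})

test_that("task subjects recover injected effects exactly in the noiseless limit", {
  design <- generate_mot_design(1, seed = 4)
  p <- preset_meditator()
  atlas <- synthetic_atlas()
  s <- generate_task_subject(design, p, 8, noise_sd = 0)
  ev <- design_to_events(design, 1)
  X <- build_design_matrix(ev, n_tr = design$n_trs_per_run, tr = design$tr)
  fit <- fit_glm(s$ts$data[, 1:design$n_trs_per_run], X,
                 contrasts = list(avp = c(attend = 1, passive = -1)))
  psc <- roi_percent_signal_change(fit, atlas, "avp")
  expect_equal(psc$percent_signal_change[psc$network == "DAN"],
               rep(0.5870, 2), tolerance = 1e-6)
  expect_equal(psc$percent_signal_change[psc$network == "DMN"],
               rep(-0.1938, 2), tolerance = 1e-6)
})

test_that("zero task effect leaves contrast t statistics centred on zero", {
  design <- generate_mot_design(1, seed = 4)
  p <- group_preset("flat", 1, r_mean = -0.4, r_sd = 0.1,
                    task_effects = c(DAN = 0, DMN = 0, VAN = 0))
  tvals <- unlist(lapply(1:4, function(seed) {
    s <- generate_task_subject(design, p, seed)
    ev <- design_to_events(design, 1)
    X <- build_design_matrix(ev, n_tr = design$n_trs_per_run, tr = design$tr)
    fit <- fit_glm(s$ts$data[, 1:design$n_trs_per_run], X,
                   contrasts = list(avp = c(attend = 1, passive = -1)))
    fit$t[, "avp"]
  }))
  expect_lt(abs(mean(tvals)), 0.15)
  expect_gt(mean(abs(tvals) < 2.5), 0.95)
})

test_that("programmed response rates reproduce Cowan's k within binomial error", {
  # 8 runs give the 64 attend trials of the binomial oracle; with
  # hit = 0.64 and false-alarm = 0.33 over 32 trials each,
  # var(k) = 16 (p1 q1 + p2 q2) / 32, so the mean of 200 seeds has
  # SE = sqrt(0.2257) / sqrt(200) ~ 0.034.
  design <- generate_mot_design(8, seed = 1)
  expect_equal(sum(design$trials$condition == "attend"), 64L)
  ks <- vapply(1:200, function(seed) {
    resp <- simulate_mot_responses(design, 0.64, 0.33, seed)
    score_behavior(resp, design)$k
  }, 0)
  se <- sqrt(16 * (0.64 * 0.36 + 0.33 * 0.67) / 32) / sqrt(200)
  expect_lt(abs(mean(ks) - 1.24), 3.5 * se)
})

test_that("cohort datasets are written with a reproducible manifest", {
  tiny <- list(
    group_preset("ga", 2, r_mean = -0.5, r_sd = 0.1,
                 n_runs = 1L, n_timepoints = 60L),
    group_preset("gb", 3, r_mean = -0.3, r_sd = 0.1,
                 n_runs = 1L, n_timepoints = 60L)
  )
  d1 <- file.path(tempdir(), "cohort1")
  d2 <- file.path(tempdir(), "cohort2")
  unlink(c(d1, d2), recursive = TRUE)
  m1 <- generate_cohort(tiny, master_seed = 5, out_dir = d1)
  m2 <- generate_cohort(tiny, master_seed = 5, out_dir = d2)
  expect_equal(nrow(m1), 5L)
  expect_identical(readLines(file.path(d1, "manifest.tsv")),
                   readLines(file.path(d2, "manifest.tsv")))
  # refuses to clobber without the flag
  expect_error(generate_cohort(tiny, 5, d1), "overwrite")
  # shipped presets enumerate the three-cohort sample of 202 subjects
  expect_equal(sum(vapply(shipped_presets(), function(p) p$n_subjects, 0L)), 202L)

  # written subjects read back into working containers
  s <- read_cohort_subject(d1, m1$subject[1])
  expect_s3_class(s$ts, "parcel_ts")
  expect_equal(dim(s$ts$data), c(100L, 60L))
  orig <- simulate_cohort(tiny[[1]], 5)[[1]]
  expect_equal(s$ts$data, orig$ts$data, tolerance = 1e-6,
               ignore_attr = TRUE)
})
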