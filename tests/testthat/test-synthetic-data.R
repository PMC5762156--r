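# Ground-truth closure and determinism of the synthetic-data generators.

test_that("noiseless evoked traces carry the injected amplitudes and latencies exactly", {
  coh <- sham_noiseless(seed = 3)
  tr <- truth_row(coh)
  avg <- epoch_and_average(coh$recordings[[1]])
  for (ch in c(1, 8, 12, 16)) {
    trace <- avg$mean[ch, ]
    i_min <- which.min(trace)
    expect_equal(-trace[i_min], tr$neg_amp_mv[[1]][ch], tolerance = 1e-12)
    expect_equal(avg$time_ms[i_min], tr$neg_latency_ms)
    expect_equal(max(trace), tr$pos_amp_mv[[1]][ch], tolerance = 1e-12)
  }
  expect_gte(tr$neg_latency_ms, 17)
  expect_lte(tr$neg_latency_ms, 26)
  expect_gte(tr$pos_latency_ms, 40)
  expect_lte(tr$pos_latency_ms, 60)
})

test_that("condition amplitude scalings multiply the same seeded waveform", {
  sham <- sham_noiseless(seed = 9)
  stroke <- gen_evoked_lfp(cohort_config("stroke30d", n_subjects = 1,
                                         noise_sd = 0, seed = 9,
                                         neg_amp_scale = 0.5, pos_amp_scale = 1))
  expect_equal(truth_row(stroke)$neg_amp_mv[[1]],
               0.5 * truth_row(sham)$neg_amp_mv[[1]])
  expect_equal(truth_row(stroke)$neg_latency_ms, truth_row(sham)$neg_latency_ms)
})

test_that("generators are bit-identical under a repeated (config, seed)", {
  a <- gen_evoked_lfp(cohort_config("stroke5d", n_subjects = 2, seed = 21))
  b <- gen_evoked_lfp(cohort_config("stroke5d", n_subjects = 2, seed = 21))
  expect_identical(a$recordings[[2]]$voltages, b$recordings[[2]]$voltages)

  t1 <- gen_reach_trajectory(reach_config(seed = 5, noise_sd_xy = 0.2))
  t2 <- gen_reach_trajectory(reach_config(seed = 5, noise_sd_xy = 0.2))
  expect_identical(t1$x, t2$x)

  p1 <- gen_platform_trial(platform_config(seed = 5))
  p2 <- gen_platform_trial(platform_config(seed = 5))
  expect_identical(p1$force, p2$force)

  b1 <- gen_behavior_counts(c(l = 0.3), 0.4, 50, seed = 5)
  b2 <- gen_behavior_counts(c(l = 0.3), 0.4, 50, seed = 5)
  expect_identical(b1$steps, b2$steps)
})

test_that("unknown ISI values and invalid configs are rejected", {
  expect_error(gen_evoked_lfp(cohort_config("sham"), isi_list = 75), "Unknown ISI")
  expect_error(cohort_config("sham", ppd_ratio = 0), "ppd_ratio")
  expect_error(cohort_config("sham", ppd_ratio = 1.2), "ppd_ratio")
  expect_error(cohort_config("sham", noise_sd = -1), "noise_sd")
  expect_error(reach_config(total_duration = 0), "total_duration")
  expect_error(reach_config(n_submovements = 0), "n_submovements")
  expect_error(platform_config(pull_force = 0.19, friction_threshold = 0.2),
               "pull_force")
  expect_error(platform_config(attempt_peak_force = 0.25), "attempt_peak_force")
})

test_that("single-submovement speed profile has exactly one prominent maximum", {
  traj <- gen_reach_trajectory(reach_config(n_submovements = 1, seed = 2))
  sp <- speed_profile(traj)
  peaks <- strokelab:::find_peaks(sp$v, min_prominence = 0.1 * max(sp$v))
  expect_length(peaks, 1L)
})

test_that("reach ground truth matches the sampled geometry", {
  traj <- gen_reach_trajectory(reach_config(n_submovements = 2, seed = 4,
                                            total_duration = 2))
  gt <- attr(traj, "ground_truth")
  arc <- sum(sqrt(diff(traj$x)^2 + diff(traj$y)^2))
  expect_equal(arc, gt$arc_len_mm, tolerance = 0.02)
  # loop starts and ends at the origin
  expect_equal(traj$x[1], traj$x[nrow(traj)], tolerance = 1e-6)
  expect_lt(abs(traj$y[nrow(traj)]), 1e-6)
})

test_that("platform trials encode attempts and retraction as configured", {
  pt <- gen_platform_trial(platform_config(n_attempts = 3, seed = 1))
  gt <- attr(pt, "ground_truth")
  expect_equal(gt$n_attempts, 3)
  expect_equal(pt$position[1], 10)
  expect_equal(pt$position[nrow(pt)], 0)
  # monotone retraction after the pull onset
  pulling <- pt$t >= max(gt$attempt_times_s) + 1
  expect_true(all(diff(pt$position[pulling]) <= 1e-9))

  pt0 <- gen_platform_trial(platform_config(n_attempts = 0, seed = 1))
  expect_equal(attr(pt0, "ground_truth")$n_attempts, 0)
})

test_that("behavior tallies recover their generating rates", {
  b0 <- gen_behavior_counts(c(l = 0), 0.5, 100, seed = 1)
  expect_equal(b0$steps$foot_faults, 0L)
  b1 <- gen_behavior_counts(c(l = 1), 0.5, 50, seed = 1)
  expect_equal(b1$steps$foot_faults, 50L)
  bb <- gen_behavior_counts(c(l = 0.3), 0.5, 10000, seed = 8)
  pct <- foot_fault_percentage(bb)$foot_fault_pct
  expect_lt(abs(pct - 30), 1)
})

test_that("noiseless condition ordering propagates to measured positive FP", {
  lo <- gen_evoked_lfp(cohort_config("sham", n_subjects = 1, noise_sd = 0,
                                     seed = 12, pos_amp_scale = 1.0))
  hi <- gen_evoked_lfp(cohort_config("stroke30d", n_subjects = 1, noise_sd = 0,
                                     seed = 12, pos_amp_scale = 1.7))
  fp_lo <- measure_fp_components(epoch_and_average(lo$recordings[[1]]))
  fp_hi <- measure_fp_components(epoch_and_average(hi$recordings[[1]]))
  expect_true(all(fp_hi$pos_amplitude_mv > fp_lo$pos_amplitude_mv))
})

test_that("laminar recordings survive a CSV round trip", {
  coh <- sham_noiseless(seed = 17, n_trials = 2, trial_spacing = 1)
  rec <- coh$recordings[[1]]
  base <- file.path(withr::local_tempdir(), "rec")
  write_laminar_csv(rec, base)
  back <- read_laminar_csv(base)
  expect_equal(back$voltages, rec$voltages, tolerance = 1e-10)
  expect_equal(back$stim_times, rec$stim_times)
  expect_equal(back$sample_rate, rec$sample_rate)
})
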