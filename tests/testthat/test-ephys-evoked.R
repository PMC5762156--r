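# Evoked averaging, FP component measurement, paired-pulse ratio,
# layer pooling, input/output curves and irradiance arithmetic.

test_that("epoching a constant trace returns the constant with zero SEM", {
  rec <- laminar_recording(matrix(2.5, 4, 5000), 1000,
                           stim_times = c(1, 2, 3))
  avg <- epoch_and_average(rec, window = c(-50, 200))
  expect_true(all(avg$mean == 2.5))
  expect_true(all(avg$sem == 0))
  expect_equal(avg$n_trials, 3)
})

test_that("averaging noiseless identical trials reproduces the single-trial waveform", {
  coh <- sham_noiseless(seed = 6)
  rec <- coh$recordings[[1]]
  avg15 <- epoch_and_average(rec)
  rec1 <- rec
  rec1$stim_times <- rec$stim_times[1]
  avg1 <- epoch_and_average(rec1)
  expect_equal(avg15$mean, avg1$mean, tolerance = 1e-12)
  expect_true(all(abs(avg15$sem) < 1e-12))
})

test_that("pre-stimulus SEM matches sampling theory at known noise level", {
  sigma <- 0.2
  coh <- gen_evoked_lfp(cohort_config("sham", n_subjects = 1,
                                      noise_sd = sigma, seed = 31))
  avg <- epoch_and_average(coh$recordings[[1]])
  pre <- avg$time_ms < 0
  mean_sem <- mean(avg$sem[, pre])
  expect_lt(abs(mean_sem - sigma / sqrt(15)) / (sigma / sqrt(15)), 0.3)
})

test_that("stimuli too close to the record edge are excluded with a warning", {
  rec <- laminar_recording(matrix(0, 3, 1000), 1000, stim_times = c(0.02, 0.5))
  expect_warning(avg <- epoch_and_average(rec, window = c(-50, 200)),
                 "excluded")
  expect_equal(avg$n_trials, 1)
  rec2 <- laminar_recording(matrix(0, 3, 100), 1000, stim_times = 0.01)
  expect_error(suppressWarnings(epoch_and_average(rec2, window = c(-50, 200))),
               "No usable trials")
})

test_that("FP components are zero on a flat trace and exact on injected lobes", {
  flat <- laminar_recording(matrix(0, 3, 3000), 1000, stim_times = 1)
  fp0 <- measure_fp_components(epoch_and_average(flat))
  expect_true(all(fp0$neg_amplitude_mv == 0))
  expect_true(all(fp0$pos_amplitude_mv == 0))

  coh <- sham_noiseless(seed = 3)
  tr <- truth_row(coh)
  fp <- measure_fp_components(epoch_and_average(coh$recordings[[1]]))
  expect_equal(fp$neg_amplitude_mv, tr$neg_amp_mv[[1]], tolerance = 1e-6)
  expect_equal(fp$pos_amplitude_mv, tr$pos_amp_mv[[1]], tolerance = 1e-6)
  expect_true(all(fp$neg_latency_ms == tr$neg_latency_ms))
  expect_true(all(fp$pos_latency_ms == tr$pos_latency_ms))
  expect_true(all(fp$neg_latency_ms < fp$pos_latency_ms))
})

test_that("a positive-only trace yields zero negative amplitude", {
  tms <- seq(-100, 400, by = 1)
  epoch <- matrix(rep(0.7 * strokelab:::hann_bump(tms, 50, 10), each = 3),
                  nrow = 3)
  rec <- tiled_recording(epoch)
  fp <- measure_fp_components(epoch_and_average(rec))
  expect_true(all(fp$neg_amplitude_mv == 0))
  expect_equal(fp$pos_amplitude_mv, rep(0.7, 3), tolerance = 1e-9)
})

test_that("measurement windows outside the epoch or out of order error", {
  coh <- sham_noiseless(seed = 3)
  avg <- epoch_and_average(coh$recordings[[1]])
  expect_error(measure_fp_components(avg, pos_window = c(35, 500)), "outside")
  expect_error(measure_fp_components(avg, neg_window = c(-10, 35)), "ordered")
})

test_that("paired-pulse ratio recovers the injected depression exactly when noiseless", {
  coh <- gen_evoked_lfp(cohort_config("sham", n_subjects = 1, noise_sd = 0,
                                      ppd_ratio = 0.6, seed = 5),
                        isi_list = 50)
  avg <- epoch_and_average(coh$recordings[[1]], window = c(-50, 150))
  pp <- paired_pulse_ratio(avg)
  expect_equal(pp$ppr, rep(0.6, 16), tolerance = 1e-9)
  expect_true(all(pp$reliable))

  # identical responses give a ratio of exactly 1
  coh1 <- gen_evoked_lfp(cohort_config("sham", n_subjects = 1, noise_sd = 0,
                                       ppd_ratio = 1, seed = 5), isi_list = 100)
  avg1 <- epoch_and_average(coh1$recordings[[1]], window = c(-50, 250))
  expect_equal(paired_pulse_ratio(avg1)$ppr, rep(1, 16), tolerance = 1e-9)
})

test_that("an absent second response gives ppr 0; an absent first is flagged", {
  tms <- seq(-100, 400, by = 1)
  resp <- -strokelab:::hann_bump(tms, 20, 8) + 0.5 * strokelab:::hann_bump(tms, 45, 10)
  rec <- tiled_recording(matrix(rep(resp, each = 3), nrow = 3))
  avg <- epoch_and_average(rec, window = c(-50, 150))
  pp <- paired_pulse_ratio(avg, isi = 50)
  expect_equal(pp$ppr, rep(0, 3))

  flat <- tiled_recording(matrix(0, 3, length(tms)))
  ppf <- paired_pulse_ratio(epoch_and_average(flat, window = c(-50, 150)), isi = 50)
  expect_true(all(is.na(ppf$ppr)))
  expect_true(all(!ppf$reliable))
})

test_that("measured ppr decreases strictly with injected depression", {
  ratios <- c(1.0, 0.8, 0.6, 0.4)
  measured <- vapply(ratios, function(r) {
    coh <- gen_evoked_lfp(cohort_config("sham", n_subjects = 1, noise_sd = 0,
                                        ppd_ratio = r, seed = 7), isi_list = 50)
    avg <- epoch_and_average(coh$recordings[[1]], window = c(-50, 150))
    mean(paired_pulse_ratio(avg)$ppr)
  }, numeric(1))
  expect_true(all(diff(measured) < 0))
  expect_equal(measured, ratios, tolerance = 0.01)
})

test_that("scaling all voltages scales amplitudes and leaves ppr unchanged", {
  coh <- gen_evoked_lfp(cohort_config("sham", n_subjects = 1, noise_sd = 0,
                                      ppd_ratio = 0.7, seed = 13),
                        isi_list = 50)
  rec <- coh$recordings[[1]]
  rec_k <- rec
  rec_k$voltages <- 3 * rec$voltages
  avg <- epoch_and_average(rec, window = c(-50, 150))
  avg_k <- epoch_and_average(rec_k, window = c(-50, 150))
  fp <- measure_fp_components(avg)
  fp_k <- measure_fp_components(avg_k)
  expect_equal(fp_k$neg_amplitude_mv, 3 * fp$neg_amplitude_mv, tolerance = 1e-9)
  expect_equal(fp_k$pos_amplitude_mv, 3 * fp$pos_amplitude_mv, tolerance = 1e-9)
  expect_equal(paired_pulse_ratio(avg_k)$ppr, paired_pulse_ratio(avg)$ppr,
               tolerance = 1e-9)
})

test_that("layer pooling averages exactly and validates its partition", {
  expect_equal(pool_layers(rep(4, 16))$value, rep(4, 4))
  expect_equal(pool_layers(1:16)$value, c(2.5, 6.5, 10.5, 14.5))
  single <- pool_layers(c(1, 5, 9), as.list(setNames(1:3, c("a", "b", "c"))))
  expect_equal(single$value, c(1, 5, 9))
  expect_error(pool_layers(1:16, list(a = 1:8, b = 8:16)), "partition")
  expect_error(pool_layers(1:16, list(a = 1:8, b = 10:16)), "partition")
  expect_error(pool_layers(1:4, list(a = 1:4, b = integer(0))), "at least one")
})

test_that("saturation intensity follows the 95% plateau rule", {
  mk_avg <- function(amp) {
    tms <- seq(-100, 400, by = 1)
    shape <- -amp * strokelab:::hann_bump(tms, 20, 8)
    rec <- tiled_recording(matrix(rep(shape, each = 16), nrow = 16))
    epoch_and_average(rec)
  }
  io <- build_io_curve(lapply(c(1, 2, 2, 2), mk_avg), intensities = 1:4)
  expect_equal(attr(io, "saturation_intensity"), 2)
  io_lin <- build_io_curve(lapply(1:4, mk_avg), intensities = 1:4)
  expect_equal(attr(io_lin, "saturation_intensity"), 4)
  expect_error(build_io_curve(lapply(c(1, 2), mk_avg), intensities = 1:2),
               "3 intensities")
})

test_that("a generated intensity series saturates at the injected plateau", {
  ser <- gen_io_series(cohort_config("sham", n_subjects = 1, noise_sd = 0,
                                     seed = 19, n_trials = 3),
                       intensities_mw = 1:8, plateau_intensity = 5)
  io <- build_io_curve(lapply(ser$recordings, epoch_and_average),
                       intensities = 1:8)
  expect_lte(abs(attr(io, "saturation_intensity") - 5), 1)
  expect_equal(glance(io)$saturation_intensity,
               attr(io, "saturation_intensity"))
})

test_that("irradiance follows the linear fiber calibration", {
  expect_equal(irradiance(3, 10, 79.55), 23.865)
  expect_equal(irradiance(4, 10, 79.55), 31.82)
  expect_equal(irradiance(0, 10, 79.55), 0)
  expect_equal(irradiance(10), 79.55)
  expect_error(irradiance(-1), "non-negative")
})
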