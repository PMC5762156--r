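# Evoked-response quantification: epoching/averaging, field-potential
# component measurement (baseline-to-peak), paired-pulse ratio (peak-trough),
# layer pooling, input/output curves, and irradiance arithmetic.

#' Epoch a recording around its stimuli and average across trials
#'
#' Cuts a window around every stimulus onset (t = 0 at the stimulus — for
#' paired-pulse recordings, at the first pulse) and returns the per-channel
#' mean and standard error across trials.
#'
#' @param rec A [laminar_recording()].
#' @param window Epoch window in ms relative to the stimulus,
#'   `c(start, end)`. The default covers the baseline and both
#'   field-potential components.
#'
#' @return An `evoked_average`: list with `mean` and `sem` (channels x
#'   window-samples matrices, mV), `time_ms`, `sample_rate`, `n_trials`,
#'   `channel_depths`, `isi`, `condition`.
#' @export
epoch_and_average <- function(rec, window = c(-50, 200)) {
  stopifnot(inherits(rec, "laminar_recording"))
  if (length(window) != 2L || window[1] >= window[2] || window[1] > 0) {
    abort("`window` must be c(start, end) in ms with start <= 0 < end.")
  }
  if (length(rec$stim_times) == 0L) abort("Recording has no stimuli to epoch.")
  fs <- rec$sample_rate
  offs <- round(window[1] * fs / 1000):round(window[2] * fs / 1000)
  time_ms <- offs / fs * 1000
  n_samp <- ncol(rec$voltages)
  onsets <- round(rec$stim_times * fs) + 1L
  usable <- onsets + offs[1] >= 1L & onsets + offs[length(offs)] <= n_samp
  if (any(!usable)) {
    warn(sprintf("%d trial(s) too close to the record edge were excluded.",
                 sum(!usable)))
  }
  onsets <- onsets[usable]
  if (length(onsets) == 0L) abort("No usable trials: all stimuli fall too close to the record edge.")
  epochs <- vapply(onsets, function(on) rec$voltages[, on + offs, drop = FALSE],
                   matrix(0, nrow(rec$voltages), length(offs)))
  n_tr <- length(onsets)
  mean_trace <- apply(epochs, c(1, 2), mean)
  sem_trace <- if (n_tr > 1L) {
    apply(epochs, c(1, 2), sd) / sqrt(n_tr)
  } else {
    matrix(0, nrow(rec$voltages), length(offs))
  }
  structure(
    list(mean = mean_trace, sem = sem_trace, time_ms = time_ms,
         sample_rate = fs, n_trials = n_tr,
         channel_depths = rec$channel_depths, isi = rec$isi,
         condition = rec$condition),
    class = "evoked_average"
  )
}

#' @export
print.evoked_average <- function(x, ...) {
  cat(sprintf(
    "<evoked_average> %d channels, window [%g, %g] ms, %d trials, condition: %s\n",
    nrow(x$mean), min(x$time_ms), max(x$time_ms), x$n_trials, x$condition
  ))
  invisible(x)
}

#' @noRd
window_idx <- function(time_ms, lo, hi, include_hi = TRUE) {
  if (include_hi) which(time_ms >= lo & time_ms <= hi)
  else which(time_ms >= lo & time_ms < hi)
}

#' Measure evoked field-potential components
#'
#' Quantifies, per channel, the early negative and late positive components
#' of the averaged evoked response as baseline-to-peak amplitudes: the
#' baseline is the mean over `baseline_window`, the negative amplitude is
#' baseline minus the minimum over `neg_window`, the positive amplitude the
#' maximum over `pos_window` minus baseline (both clamped at 0), with
#' latencies at the extremum samples. Default search windows bracket the
#' typical component latencies (negative peak 17--26 ms, positive peak
#' 40--60 ms).
#'
#' @param avg An `evoked_average`.
#' @param baseline_window,neg_window,pos_window Windows in ms; must be
#'   ordered baseline < neg < pos and lie inside the epoch.
#'
#' @return An `fp_components` tibble: `channel`, `depth_um`, `baseline_mv`,
#'   `neg_amplitude_mv`, `neg_latency_ms`, `pos_amplitude_mv`,
#'   `pos_latency_ms`.
#' @export
measure_fp_components <- function(avg, baseline_window = c(-50, 0),
                                  neg_window = c(5, 35),
                                  pos_window = c(35, 80)) {
  stopifnot(inherits(avg, "evoked_average"))
  tms <- avg$time_ms
  for (w in list(baseline_window, neg_window, pos_window)) {
    if (w[1] < min(tms) || w[2] > max(tms)) {
      abort("A measurement window lies outside the epoch.")
    }
  }
  if (!(baseline_window[2] <= neg_window[1] && neg_window[2] <= pos_window[1])) {
    abort("Windows must be ordered: baseline < negative < positive.")
  }
  ib <- window_idx(tms, baseline_window[1], baseline_window[2], include_hi = FALSE)
  ineg <- window_idx(tms, neg_window[1], neg_window[2])
  ipos <- window_idx(tms, pos_window[1], pos_window[2])
  purrr::map_dfr(seq_len(nrow(avg$mean)), function(ch) {
    trace <- avg$mean[ch, ]
    base <- mean(trace[ib])
    i_min <- ineg[which.min(trace[ineg])]
    i_max <- ipos[which.max(trace[ipos])]
    tibble(
      channel = ch, depth_um = avg$channel_depths[ch], baseline_mv = base,
      neg_amplitude_mv = max(base - trace[i_min], 0),
      neg_latency_ms = tms[i_min],
      pos_amplitude_mv = max(trace[i_max] - base, 0),
      pos_latency_ms = tms[i_max]
    )
  }) -> out
  structure(out, class = c("fp_components", class(out)))
}

#' Paired-pulse ratio per channel
#'
#' Measures the first (A1) and second (A2) evoked responses of a
#' paired-pulse average and their ratio A2/A1. Both are measured peak-trough
#' (window maximum minus window minimum) so the altered baseline preceding
#' the second pulse cannot bias A2; `measurement = "baseline_to_peak"`
#' switches A1 to the baseline-referenced negative amplitude. Response
#' windows are `[5, isi)` ms after pulse 1 and `[5, min(isi, 80)]` ms after
#' pulse 2. Channels whose A1 falls below `noise_mult` x baseline SD are
#' flagged unreliable and get a missing ratio.
#'
#' @param avg An `evoked_average` of a paired-pulse recording (epoch must
#'   contain both responses).
#' @param isi Inter-stimulus interval in ms (50, 100 or 200); defaults to
#'   the value stored on the average.
#' @param measurement `"peak_trough"` (both responses) or
#'   `"baseline_to_peak"` (A1 only).
#' @param noise_mult Reliability floor in baseline SDs (default 3).
#'
#' @return A `ppr_result` tibble: `channel`, `depth_um`, `a1_mv`, `a2_mv`,
#'   `ppr`, `isi`, `reliable`.
#' @export
paired_pulse_ratio <- function(avg, isi = avg$isi,
                               measurement = c("peak_trough", "baseline_to_peak"),
                               noise_mult = 3) {
  stopifnot(inherits(avg, "evoked_average"))
  measurement <- match.arg(measurement)
  if (is.na(isi) || !(isi %in% ALLOWED_ISI_MS)) {
    abort("`isi` must be one of 50, 100, 200 ms.")
  }
  tms <- avg$time_ms
  w2_hi <- isi + min(isi, 80)
  if (max(tms) < w2_hi || min(tms) > -50) {
    abort("Epoch must cover [-50 ms, ISI + min(ISI, 80) ms] to hold both responses.")
  }
  i1 <- window_idx(tms, 5, isi, include_hi = FALSE)
  i2 <- window_idx(tms, isi + 5, w2_hi)
  ib <- window_idx(tms, -50, 0, include_hi = FALSE)
  purrr::map_dfr(seq_len(nrow(avg$mean)), function(ch) {
    trace <- avg$mean[ch, ]
    a1 <- if (measurement == "peak_trough") {
      max(trace[i1]) - min(trace[i1])
    } else {
      max(mean(trace[ib]) - min(trace[i1]), 0)
    }
    a2 <- max(trace[i2]) - min(trace[i2])
    floor_mv <- noise_mult * sd(trace[ib])
    reliable <- is.finite(a1) && a1 > floor_mv
    tibble(
      channel = ch, depth_um = avg$channel_depths[ch],
      a1_mv = a1, a2_mv = a2,
      ppr = if (reliable) a2 / a1 else NA_real_,
      isi = isi, reliable = reliable
    )
  }) -> out
  structure(out, class = c("ppr_result", class(out)))
}

#' Default channel-to-layer grouping
#'
#' Splits `n_channels` contiguous contacts into four pools — superficial,
#' superficial/middle, middle/deep and deep — of (near-)equal size.
#'
#' @param n_channels Number of probe contacts.
#' @return Named list of channel index vectors.
#' @export
default_layer_map <- function(n_channels = 16) {
  n_channels <- assert_count(n_channels, "n_channels", min = 4L)
  cuts <- round(seq(0, n_channels, length.out = 5))
  groups <- purrr::map2(cuts[-5] + 1L, cuts[-1], seq)
  setNames(groups, c("Sup", "Sup/Middle", "Middle/Deep", "Deep"))
}

#' Pool per-channel values into layer groups
#'
#' Averages a per-channel quantity (e.g. a field-potential amplitude) within
#' each layer group. The group map must partition the channels.
#'
#' @param values Numeric vector, one value per channel.
#' @param group_map Named list of channel indices; defaults to
#'   [default_layer_map()] for `length(values)` channels.
#'
#' @return A `layer_pools` tibble: `pool`, `value`, `n_channels`.
#' @export
pool_layers <- function(values, group_map = NULL) {
  if (!is.numeric(values)) abort("`values` must be a numeric per-channel vector.")
  n <- length(values)
  group_map <- group_map %||% default_layer_map(n)
  if (any(lengths(group_map) == 0L)) abort("Every group must contain at least one channel.")
  idx <- sort(unlist(group_map, use.names = FALSE))
  if (!identical(as.integer(idx), seq_len(n))) {
    abort("`group_map` must partition the channels exactly (no overlap, no gap).")
  }
  out <- tibble(
    pool = factor(names(group_map), levels = names(group_map)),
    value = unname(vapply(group_map, function(g) mean(values[g]), numeric(1))),
    n_channels = lengths(group_map)
  )
  structure(out, class = c("layer_pools", class(out)))
}

#' Input/output curve over stimulation intensities
#'
#' Builds the response-vs-intensity curve from single-pulse evoked averages
#' recorded at increasing light powers: the response is the deep-pool
#' negative-component amplitude, and the saturation intensity is the first
#' intensity whose amplitude reaches 95% of the maximum observed amplitude.
#'
#' @param avgs List of `evoked_average` objects, one per intensity, in
#'   increasing intensity order.
#' @param intensities Light powers in mW; defaults to `names(avgs)`.
#' @param saturation_frac Plateau criterion (default 0.95).
#'
#' @return An `io_curve` tibble (`intensity_mw`, `neg_amplitude_mv`) with
#'   attribute `saturation_intensity`; see [glance.io_curve()].
#' @export
build_io_curve <- function(avgs, intensities = NULL, saturation_frac = 0.95) {
  intensities <- intensities %||% as.numeric(names(avgs))
  if (length(avgs) < 3L) abort("At least 3 intensities are required.")
  if (anyNA(intensities) || any(diff(intensities) <= 0)) {
    abort("`intensities` must be strictly increasing.")
  }
  amps <- vapply(avgs, function(a) {
    fp <- measure_fp_components(a)
    pools <- pool_layers(fp$neg_amplitude_mv)
    pools$value[pools$pool == "Deep"]
  }, numeric(1))
  sat <- intensities[which(amps >= saturation_frac * max(amps))[1]]
  out <- tibble(intensity_mw = intensities, neg_amplitude_mv = unname(amps))
  structure(out, saturation_intensity = sat,
            class = c("io_curve", class(out)))
}

#' Convert light power to irradiance
#'
#' Linear fiber-optic calibration: `power * max_irradiance / max_power`.
#' Defaults reflect a fiber whose maximum emission of 10 mW corresponds to
#' 79.55 mW/mm^2 at the tip.
#'
#' @param power Light power(s) in mW (>= 0).
#' @param max_power Maximum emission power in mW.
#' @param max_irradiance Irradiance at `max_power`, mW/mm^2.
#'
#' @return Irradiance in mW/mm^2.
#' @examples
#' irradiance(3)  # 23.865 mW/mm^2, 30% of maximum
#' @export
irradiance <- function(power, max_power = 10, max_irradiance = 79.55) {
  assert_scalar_number(max_power, "max_power", lower = 0, strict_lower = TRUE)
  assert_scalar_number(max_irradiance, "max_irradiance", lower = 0)
  if (any(!is.finite(power)) || any(power < 0)) {
    abort("`power` must be non-negative.")
  }
  power * max_irradiance / max_power
}
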