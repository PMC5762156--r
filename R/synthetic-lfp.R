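# Synthetic optogenetically evoked laminar LFP recordings with exact ground
# truth. The generators are phenomenological: each stimulus evokes, on every
# channel, an early negative lobe (17-26 ms) and a late positive lobe
# (40-60 ms) whose shapes are raised-cosine (Hann) bumps. Compact support
# keeps the two lobes from perturbing each other's extrema, so on noiseless
# data the injected amplitudes and latencies are recovered exactly; injected
# latencies are snapped to the sample grid for the same reason.

BASE_NEG_AMP_MV <- 1.0  # deepest-layer negative-lobe amplitude before scaling
BASE_POS_AMP_MV <- 0.6
NEG_HALF_WIDTH_MS <- 8
POS_HALF_WIDTH_MS <- 10
ALLOWED_ISI_MS <- c(50, 100, 200)

# Raised-cosine bump: 1 at mu, smoothly 0 outside |t - mu| < w.
#' @noRd
hann_bump <- function(t_ms, mu, w) {
  d <- abs(t_ms - mu)
  out <- numeric(length(t_ms))
  inside <- d < w
  out[inside] <- cos(pi * d[inside] / (2 * w))^2
  out
}

# Smooth unimodal depth profile over channels, peaking in the deep
# (infragranular) quarter of the probe, max exactly 1.
#' @noRd
depth_profile <- function(n_channels, peak_channel) {
  ch <- seq_len(n_channels)
  p <- 0.2 + 0.8 * exp(-((ch - peak_channel)^2) / (2 * (n_channels / 4.5)^2))
  p / max(p)
}

#' Generate a cohort of synthetic evoked laminar recordings
#'
#' Simulates, for each subject in `config`, one recording per entry of
#' `isi_list`: a 16-channel laminar probe recording in which every stimulus
#' evokes a negative field-potential lobe (latency drawn in 18--25 ms,
#' amplitude = depth profile x `neg_amp_scale`) and a late positive lobe
#' (latency drawn in 42--48 ms, amplitude x `pos_amp_scale`). For paired
#' pulses the second response is the first scaled by `ppd_ratio`. When
#' `config$sample_rate >= 20000`, biphasic ~1 ms spike transients are
#' embedded at Poisson times rate-modulated by the negative lobe, giving
#' multi-unit analysis a known rate profile to recover.
#'
#' @param config A [cohort_config()].
#' @param isi_list Inter-stimulus intervals in ms; `NA` means single pulse.
#'   Allowed values: `NA`, 50, 100, 200.
#'
#' @return An `evoked_cohort`: list with `recordings` (named list of
#'   [laminar_recording()]s) and `truth` (tibble of all injected values, one
#'   row per recording, with per-channel amplitudes as list-columns).
#' @examples
#' coh <- gen_evoked_lfp(cohort_config("sham", n_subjects = 1, noise_sd = 0))
#' avg <- epoch_and_average(coh$recordings[[1]])
#' @export
gen_evoked_lfp <- function(config, isi_list = NA_real_) {
  stopifnot(inherits(config, "cohort_config"))
  bad <- !is.na(isi_list) & !(isi_list %in% ALLOWED_ISI_MS)
  if (any(bad)) {
    abort(sprintf(
      "Unknown ISI value(s): %s. Allowed: NA (single pulse), 50, 100, 200 ms.",
      paste(isi_list[bad], collapse = ", ")
    ))
  }
  max_isi <- if (all(is.na(isi_list))) 0 else max(isi_list, na.rm = TRUE)
  if (config$trial_spacing < (max_isi + 400) / 1000) {
    abort("`trial_spacing` too short to hold the paired response and epoch window.")
  }
  fs <- config$sample_rate
  withr::with_seed(config$seed, {
    recs <- list()
    truth <- list()
    for (s in seq_len(config$n_subjects)) {
      # per-subject physiology, identical across conditions for a given seed
      neg_lat <- round(runif(1, 18, 25) * fs / 1000) / fs * 1000
      pos_lat <- round(runif(1, 42, 48) * fs / 1000) / fs * 1000
      peak_ch <- 0.72 * config$n_channels + runif(1, -0.75, 0.75)
      profile <- depth_profile(config$n_channels, peak_ch)
      neg_amp <- BASE_NEG_AMP_MV * profile * config$neg_amp_scale
      pos_amp <- BASE_POS_AMP_MV * profile * config$pos_amp_scale
      for (isi in isi_list) {
        rec <- synth_recording(config, neg_lat, pos_lat, neg_amp, pos_amp,
                               profile, isi)
        id <- sprintf("s%02d%s", s,
                      if (is.na(isi)) "" else sprintf("_isi%d", as.integer(isi)))
        recs[[id]] <- rec
        truth[[id]] <- tibble(
          recording = id, subject = s, condition = config$condition,
          isi = as.numeric(isi), neg_latency_ms = neg_lat,
          pos_latency_ms = pos_lat, ppd_ratio = config$ppd_ratio,
          noise_sd = config$noise_sd,
          neg_amp_mv = list(neg_amp), pos_amp_mv = list(pos_amp)
        )
      }
    }
    structure(list(recordings = recs, truth = dplyr::bind_rows(truth)),
              class = "evoked_cohort")
  })
}

# One subject x protocol recording. Consumes RNG only for noise and spikes,
# after the subject-level draws, so noiseless outputs are condition-invariant
# for a fixed seed.
#' @noRd
synth_recording <- function(config, neg_lat, pos_lat, neg_amp, pos_amp,
                            profile, isi, amp_factor = 1,
                            stim_intensity = NA_real_) {
  fs <- config$sample_rate
  n_ch <- config$n_channels
  stim_times <- 0.5 + (seq_len(config$n_trials) - 1L) * config$trial_spacing
  n_samp <- ceiling((max(stim_times) + config$trial_spacing) * fs)
  t_ms_all <- (seq_len(n_samp) - 1L) / fs * 1000
  # one evoked response shape per channel, time-shifted per stimulus
  volt <- matrix(0, n_ch, n_samp)
  onsets_ms <- as.vector(outer(stim_times * 1000,
                               if (is.na(isi)) 0 else c(0, isi), `+`))
  gains <- rep(if (is.na(isi)) 1 else c(1, config$ppd_ratio),
               each = length(stim_times))
  for (k in seq_along(onsets_ms)) {
    on <- onsets_ms[k]
    i0 <- floor((on + neg_lat - NEG_HALF_WIDTH_MS) * fs / 1000)
    i1 <- ceiling((on + pos_lat + POS_HALF_WIDTH_MS) * fs / 1000) + 1L
    idx <- max(1L, i0):min(n_samp, i1)
    tt <- t_ms_all[idx] - on
    shape <- -hann_bump(tt, neg_lat, NEG_HALF_WIDTH_MS)
    shape_pos <- hann_bump(tt, pos_lat, POS_HALF_WIDTH_MS)
    volt[, idx] <- volt[, idx] +
      gains[k] * amp_factor * (outer(neg_amp, shape) + outer(pos_amp, shape_pos))
  }
  if (config$noise_sd > 0) {
    volt <- volt + matrix(rnorm(n_ch * n_samp, 0, config$noise_sd), n_ch, n_samp)
  }
  if (fs >= 20000) {
    volt <- add_spike_bursts(volt, fs, onsets_ms, gains, neg_lat, profile)
  }
  laminar_recording(
    voltages = volt, sample_rate = fs,
    stim_times = stim_times,
    stim_intensities = if (is.na(stim_intensity)) NULL
                       else rep(stim_intensity, length(stim_times)),
    isi = if (is.na(isi)) NA_real_ else as.numeric(isi),
    condition = config$condition
  )
}

# Biphasic ~1 ms extracellular spike transient sampled at `fs`.
#' @noRd
spike_waveform <- function(fs, dur_ms = 1.2) {
  tt <- seq(0, dur_ms / 1000, by = 1 / fs)
  0.15 * sin(2 * pi * tt / (dur_ms / 1000)) * sin(pi * tt / (dur_ms / 1000))^2
}

# Poisson spike bursts co-timed with the negative lobe: rate = baseline +
# burst bump scaled by the channel depth profile and the per-response gain.
#' @noRd
add_spike_bursts <- function(volt, fs, onsets_ms, gains, neg_lat, profile,
                             base_rate = 20, burst_rate = 600) {
  n_ch <- nrow(volt)
  n_samp <- ncol(volt)
  wf <- spike_waveform(fs)
  dur_s <- n_samp / fs
  for (ch in seq_len(n_ch)) {
    # homogeneous baseline spikes
    n_base <- rpois(1, base_rate * dur_s)
    times <- runif(n_base, 0, dur_s)
    # burst spikes per response, drawn by thinning a Hann-bump rate profile
    for (k in seq_along(onsets_ms)) {
      peak <- burst_rate * profile[ch] * gains[k]
      win <- (onsets_ms[k] + neg_lat + c(-1, 1) * NEG_HALF_WIDTH_MS) / 1000
      n_cand <- rpois(1, peak * diff(win))
      cand <- runif(n_cand, win[1], win[2])
      acc <- runif(n_cand) < hann_bump(cand * 1000 - onsets_ms[k], neg_lat,
                                       NEG_HALF_WIDTH_MS)
      times <- c(times, cand[acc])
    }
    idx0 <- round(times * fs)
    for (i0 in idx0) {
      sel <- (i0 + 1L):min(i0 + length(wf), n_samp)
      if (length(sel) < 1L || sel[1] > n_samp || sel[1] < 1L) next
      volt[ch, sel] <- volt[ch, sel] + profile[ch] * wf[seq_along(sel)]
    }
  }
  volt
}

#' Generate an input/output intensity series for one subject
#'
#' Produces single-pulse recordings at increasing light powers whose evoked
#' amplitudes ramp linearly up to `plateau_intensity` and saturate there,
#' emulating an input/output curve with a known saturation point.
#'
#' @param config A [cohort_config()]; subject 1 of the cohort is used.
#' @param intensities_mw Strictly increasing light powers in milliwatts.
#' @param plateau_intensity Intensity (mW) at which the response ceiling is
#'   reached.
#'
#' @return List with `recordings` (one per intensity, named by intensity) and
#'   `truth` (tibble including `plateau_intensity`).
#' @export
gen_io_series <- function(config, intensities_mw, plateau_intensity) {
  stopifnot(inherits(config, "cohort_config"))
  if (length(intensities_mw) < 3L || any(diff(intensities_mw) <= 0)) {
    abort("`intensities_mw` must be >= 3 strictly increasing values.")
  }
  assert_scalar_number(plateau_intensity, "plateau_intensity", lower = 0,
                       strict_lower = TRUE)
  fs <- config$sample_rate
  withr::with_seed(config$seed, {
    neg_lat <- round(runif(1, 18, 25) * fs / 1000) / fs * 1000
    pos_lat <- round(runif(1, 42, 48) * fs / 1000) / fs * 1000
    peak_ch <- 0.72 * config$n_channels + runif(1, -0.75, 0.75)
    profile <- depth_profile(config$n_channels, peak_ch)
    neg_amp <- BASE_NEG_AMP_MV * profile * config$neg_amp_scale
    pos_amp <- BASE_POS_AMP_MV * profile * config$pos_amp_scale
    recs <- lapply(intensities_mw, function(int) {
      synth_recording(config, neg_lat, pos_lat, neg_amp, pos_amp, profile,
                      isi = NA_real_,
                      amp_factor = min(int, plateau_intensity) / plateau_intensity,
                      stim_intensity = int)
    })
    names(recs) <- as.character(intensities_mw)
    list(
      recordings = recs,
      truth = tibble(
        intensity_mw = intensities_mw,
        amp_factor = pmin(intensities_mw, plateau_intensity) / plateau_intensity,
        plateau_intensity = plateau_intensity,
        neg_latency_ms = neg_lat, pos_latency_ms = pos_lat,
        neg_amp_mv = list(neg_amp), pos_amp_mv = list(pos_amp)
      )
    )
  })
}
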