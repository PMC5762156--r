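# Multi-unit activity: band-pass the wide-band signal into the spiking band,
# estimate power by a centered sliding RMS per trial, then trial-average.

#' Compute a multi-unit activity profile
#'
#' Band-pass filters the recording into the spiking band (zero-phase
#' forward-backward Butterworth, so latencies are not shifted), epochs
#' around the stimuli, computes a centered sliding-window RMS per trial and
#' channel, and averages across trials. Optionally normalizes each channel
#' to its maximum in the first-response window, making depth profiles
#' comparable across channels.
#'
#' @param rec A [laminar_recording()] sampled fast enough for the band.
#' @param band Pass band in Hz (default 300--10,000, the conventional
#'   spiking band). The upper edge must not exceed Nyquist; if it equals
#'   Nyquist a high-pass is used.
#' @param rms_window RMS window length in ms (default 1 ms).
#' @param normalize_to_first_peak Divide each channel by its maximum within
#'   `first_response_window`.
#' @param window Epoch window in ms relative to the stimulus.
#' @param first_response_window Window (ms) defining the first-response peak
#'   used for normalization.
#' @param filter_order Butterworth order (applied twice by filtering both
#'   directions).
#'
#' @return An `mua_profile`: list with `mua` (channels x window-samples,
#'   microvolts RMS, or unitless if normalized), `time_ms`, `rms_window_ms`,
#'   `normalized`, `channel_depths`, `n_trials`.
#' @export
compute_mua <- function(rec, band = c(300, 10000), rms_window = 1,
                        normalize_to_first_peak = FALSE,
                        window = c(-50, 200),
                        first_response_window = c(0, 80),
                        filter_order = 3) {
  stopifnot(inherits(rec, "laminar_recording"))
  fs <- rec$sample_rate
  if (band[1] <= 0 || band[2] <= band[1]) abort("`band` must be 0 < low < high.")
  nyq <- fs / 2
  if (band[2] > nyq) {
    abort(sprintf(
      "Nyquist violation: band upper edge %g Hz exceeds sample_rate/2 = %g Hz.",
      band[2], nyq
    ))
  }
  filt <- if (band[2] == nyq) {
    signal::butter(filter_order, band[1] / nyq, type = "high")
  } else {
    signal::butter(filter_order, band / nyq, type = "pass")
  }
  filtered <- t(apply(rec$voltages, 1, function(x) {
    signal::filtfilt(filt, x)
  }))
  frec <- rec
  frec$voltages <- filtered
  fs_ms <- fs / 1000
  offs <- round(window[1] * fs_ms):round(window[2] * fs_ms)
  time_ms <- offs / fs_ms
  w_samp <- max(1L, round(rms_window * fs_ms))
  onsets <- round(rec$stim_times * fs) + 1L
  usable <- onsets + offs[1] >= 1L & onsets + offs[length(offs)] <= ncol(filtered)
  onsets <- onsets[usable]
  if (length(onsets) == 0L) abort("No usable trials inside the record.")
  n_ch <- nrow(filtered)
  acc <- matrix(0, n_ch, length(offs))
  for (on in onsets) {
    seg2 <- filtered[, on + offs, drop = FALSE]^2
    acc <- acc + sqrt(t(apply(seg2, 1, moving_average, window = w_samp)))
  }
  mua <- acc / length(onsets) * 1000  # mV RMS -> uV RMS
  if (normalize_to_first_peak) {
    ifr <- window_idx(time_ms, first_response_window[1], first_response_window[2])
    peaks <- apply(mua[, ifr, drop = FALSE], 1, max)
    peaks[peaks == 0] <- 1  # silent channel: leave at zero rather than divide by 0
    mua <- mua / peaks
  }
  structure(
    list(mua = mua, time_ms = time_ms, rms_window_ms = rms_window,
         normalized = normalize_to_first_peak,
         channel_depths = rec$channel_depths, n_trials = length(onsets)),
    class = "mua_profile"
  )
}
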