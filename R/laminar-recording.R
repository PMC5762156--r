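# Container for a multichannel extracellular recording with stimulus events.
#
# Voltages are stored as a channels x samples matrix in millivolts; a long
# tibble of 16 x 10^5 samples would waste memory for no analytic gain, so the
# matrix is the one non-tabular container in the package. Everything derived
# from it is a tibble.

#' Construct a laminar recording
#'
#' Bundle a multichannel voltage matrix with its sampling and stimulation
#' metadata. Channel 1 is the most superficial contact; `channel_depths` must
#' be strictly increasing and uniformly spaced, as for a linear silicon probe.
#'
#' @param voltages Numeric matrix, channels x samples, in millivolts.
#' @param sample_rate Sampling rate in Hz.
#' @param channel_depths Contact depths in micrometres, strictly increasing,
#'   uniformly spaced. Defaults to 100 um spacing starting at 100 um.
#' @param stim_times Stimulus onset times in seconds (for paired-pulse
#'   protocols, the onset of the *first* pulse of each trial), strictly
#'   increasing and inside the record.
#' @param stim_intensities Optional per-stimulus light power in milliwatts.
#' @param isi Inter-stimulus interval in ms for paired-pulse recordings,
#'   or `NA` for single-pulse protocols.
#' @param condition Free-text condition label (e.g. `"sham"`).
#'
#' @return An object of class `laminar_recording`.
#' @export
laminar_recording <- function(voltages, sample_rate, channel_depths = NULL,
                              stim_times = numeric(0), stim_intensities = NULL,
                              isi = NA_real_, condition = NA_character_) {
  if (!is.matrix(voltages) || !is.numeric(voltages)) {
    abort("`voltages` must be a numeric channels x samples matrix.")
  }
  n_ch <- nrow(voltages)
  if (n_ch < 3L) abort("At least 3 channels are required.")
  assert_scalar_number(sample_rate, "sample_rate", lower = 0, strict_lower = TRUE)
  if (is.null(channel_depths)) channel_depths <- 100 * seq_len(n_ch)
  if (length(channel_depths) != n_ch) {
    abort("`channel_depths` must have one entry per channel.")
  }
  d <- diff(channel_depths)
  if (any(d <= 0)) abort("`channel_depths` must be strictly increasing.")
  if (n_ch > 2L && max(abs(d - d[1])) > 1e-6 * d[1]) {
    abort("`channel_depths` must be uniformly spaced.")
  }
  dur <- ncol(voltages) / sample_rate
  if (length(stim_times)) {
    if (any(diff(stim_times) <= 0)) abort("`stim_times` must be strictly increasing.")
    if (any(stim_times < 0 | stim_times > dur)) {
      abort("`stim_times` must lie inside the record.")
    }
  }
  if (!is.null(stim_intensities) && length(stim_intensities) != length(stim_times)) {
    abort("`stim_intensities` must match `stim_times` in length.")
  }
  structure(
    list(
      voltages = voltages,
      sample_rate = sample_rate,
      channel_depths = as.numeric(channel_depths),
      stim_times = as.numeric(stim_times),
      stim_intensities = stim_intensities,
      isi = isi,
      condition = condition
    ),
    class = "laminar_recording"
  )
}

#' @export
print.laminar_recording <- function(x, ...) {
  cat(sprintf(
    "<laminar_recording> %d channels x %d samples @ %g Hz (%.1f s), %d stimuli%s, condition: %s\n",
    nrow(x$voltages), ncol(x$voltages), x$sample_rate,
    ncol(x$voltages) / x$sample_rate, length(x$stim_times),
    if (is.na(x$isi)) "" else sprintf(" (paired, ISI %g ms)", x$isi),
    x$condition
  ))
  invisible(x)
}

#' Write / read a laminar recording as a CSV pair
#'
#' The samples table holds one row per sample (`time_s`, then one `chNN`
#' column per contact, millivolts); the events table one row per stimulus.
#' Metadata travel in a JSON sidecar next to the two CSVs.
#'
#' @param rec A [laminar_recording()].
#' @param path Base path; `<path>_samples.csv`, `<path>_events.csv` and
#'   `<path>_meta.json` are written.
#' @return `path`, invisibly (`write_laminar_csv`); a `laminar_recording`
#'   (`read_laminar_csv`).
#' @export
write_laminar_csv <- function(rec, path) {
  stopifnot(inherits(rec, "laminar_recording"))
  n <- ncol(rec$voltages)
  samples <- as_tibble(t(rec$voltages), .name_repair = "minimal")
  names(samples) <- sprintf("ch%02d", seq_len(nrow(rec$voltages)))
  samples <- dplyr::bind_cols(
    tibble(time_s = (seq_len(n) - 1L) / rec$sample_rate), samples
  )
  readr::write_csv(samples, paste0(path, "_samples.csv"))
  events <- tibble(
    stim_time_s = rec$stim_times,
    intensity_mw = rec$stim_intensities %||% rep(NA_real_, length(rec$stim_times))
  )
  readr::write_csv(events, paste0(path, "_events.csv"))
  meta <- list(
    sample_rate = rec$sample_rate, channel_depths = rec$channel_depths,
    isi = rec$isi, condition = rec$condition
  )
  jsonlite::write_json(meta, paste0(path, "_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_laminar_csv
#' @export
read_laminar_csv <- function(path) {
  samples <- readr::read_csv(paste0(path, "_samples.csv"),
                             show_col_types = FALSE)
  events <- readr::read_csv(paste0(path, "_events.csv"),
                            show_col_types = FALSE)
  meta <- jsonlite::read_json(paste0(path, "_meta.json"), simplifyVector = TRUE)
  volt <- t(as.matrix(samples[, -1, drop = FALSE]))
  dimnames(volt) <- NULL
  intens <- events$intensity_mw
  if (all(is.na(intens))) intens <- NULL
  laminar_recording(
    voltages = volt, sample_rate = meta$sample_rate,
    channel_depths = meta$channel_depths, stim_times = events$stim_time_s,
    stim_intensities = intens,
    isi = if (is.null(meta$isi) || is.na(meta$isi)) NA_real_ else meta$isi,
    condition = meta$condition %||% NA_character_
  )
}
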