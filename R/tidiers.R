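# broom-style tidy()/glance() methods turning matrix-backed results into
# long tibbles.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an evoked average into a long tibble
#'
#' @param x An `evoked_average`.
#' @param ... Unused.
#' @return Tibble: `channel`, `depth_um`, `time_ms`, `mean_mv`, `sem_mv`.
#' @export
tidy.evoked_average <- function(x, ...) {
  n_ch <- nrow(x$mean)
  tibble(
    channel = rep(seq_len(n_ch), times = length(x$time_ms)),
    depth_um = rep(x$channel_depths, times = length(x$time_ms)),
    time_ms = rep(x$time_ms, each = n_ch),
    mean_mv = as.vector(x$mean),
    sem_mv = as.vector(x$sem)
  )
}

#' @rdname tidy.evoked_average
#' @export
glance.evoked_average <- function(x, ...) {
  tibble(
    n_channels = nrow(x$mean), n_trials = x$n_trials,
    window_start_ms = min(x$time_ms), window_end_ms = max(x$time_ms),
    isi = x$isi, condition = x$condition
  )
}

#' Tidy a CSD map into a long tibble
#'
#' @param x A `csd_map`.
#' @param ... Unused.
#' @return Tibble: `channel`, `depth_um`, `time_ms`, `csd` (sink-positive).
#' @export
tidy.csd_map <- function(x, ...) {
  n_ch <- nrow(x$csd)
  tibble(
    channel = rep(seq_len(n_ch), times = length(x$time_ms)),
    depth_um = rep(x$channel_depths, times = length(x$time_ms)),
    time_ms = rep(x$time_ms, each = n_ch),
    csd = as.vector(x$csd)
  )
}

#' Tidy a multi-unit activity profile into a long tibble
#'
#' @param x An `mua_profile`.
#' @param ... Unused.
#' @return Tibble: `channel`, `depth_um`, `time_ms`, `mua`.
#' @export
tidy.mua_profile <- function(x, ...) {
  n_ch <- nrow(x$mua)
  tibble(
    channel = rep(seq_len(n_ch), times = length(x$time_ms)),
    depth_um = rep(x$channel_depths, times = length(x$time_ms)),
    time_ms = rep(x$time_ms, each = n_ch),
    mua = as.vector(x$mua)
  )
}

#' Summary of an input/output curve
#'
#' @param x An `io_curve`.
#' @param ... Unused.
#' @return One-row tibble: `saturation_intensity`, `max_amplitude_mv`,
#'   `n_intensities`.
#' @export
glance.io_curve <- function(x, ...) {
  tibble(
    saturation_intensity = attr(x, "saturation_intensity"),
    max_amplitude_mv = max(x$neg_amplitude_mv),
    n_intensities = nrow(x)
  )
}
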