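# ggplot2 visualizations for each result type.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_raster geom_point
#'   geom_ribbon facet_wrap labs scale_y_reverse scale_fill_gradient2
#'   geom_vline theme_minimal
NULL

#' Plot an evoked average as a stacked laminar montage
#'
#' One trace per channel, offset by depth, with a +/- SEM ribbon.
#'
#' @param object An `evoked_average`.
#' @param spacing_mv Vertical offset between adjacent channels.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.evoked_average <- function(object, spacing_mv = NULL, ...) {
  d <- tidy(object)
  spacing_mv <- spacing_mv %||% (3 * max(abs(d$mean_mv)) / 2)
  d$offset <- -(d$channel - 1) * spacing_mv
  ggplot(d, aes(x = .data$time_ms, y = .data$mean_mv + .data$offset,
                group = .data$channel)) +
    geom_ribbon(aes(ymin = .data$mean_mv - .data$sem_mv + .data$offset,
                    ymax = .data$mean_mv + .data$sem_mv + .data$offset),
                alpha = 0.25) +
    geom_line() +
    geom_vline(xintercept = 0, linetype = "dashed") +
    labs(x = "Time from stimulus (ms)", y = "Channel (superficial to deep)",
         title = sprintf("Evoked average (%s, %d trials)",
                         object$condition, object$n_trials)) +
    theme_minimal()
}

#' Plot a CSD map
#'
#' Depth-by-time heat map with sinks (positive values under the inverted
#' convention) in warm colors.
#'
#' @param object A `csd_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.csd_map <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(x = .data$time_ms, y = .data$depth_um, fill = .data$csd)) +
    geom_raster() +
    scale_y_reverse() +
    scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    labs(x = "Time from stimulus (ms)", y = "Depth (µm)",
         fill = "CSD\n(sink +)",
         title = sprintf("Inverse CSD (%s method)", object$method)) +
    theme_minimal()
}

#' Plot a multi-unit activity profile
#'
#' @param object An `mua_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mua_profile <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(x = .data$time_ms, y = .data$depth_um, fill = .data$mua)) +
    geom_raster() +
    scale_y_reverse() +
    labs(x = "Time from stimulus (ms)", y = "Depth (µm)",
         fill = if (object$normalized) "MUA\n(norm.)" else "MUA\n(µV RMS)",
         title = "Multi-unit activity") +
    theme_minimal()
}

#' Plot a speed profile
#'
#' Tangential speed over time with detected peaks highlighted.
#'
#' @param object A `speed_profile`.
#' @param peak_prominence_frac Prominence floor used to mark peaks.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.speed_profile <- function(object, peak_prominence_frac = 0.1, ...) {
  pk <- find_peaks(object$v, min_prominence = peak_prominence_frac * max(object$v))
  ggplot(object, aes(x = .data$t, y = .data$v)) +
    geom_line() +
    geom_point(data = object[pk, ], color = "red", size = 2) +
    labs(x = "Time (s)", y = "Tangential speed (mm/s)",
         title = sprintf("Speed profile (%d peaks)", length(pk))) +
    theme_minimal()
}

#' Plot a reach trajectory
#'
#' @param object A `reach_trajectory`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.reach_trajectory <- function(object, ...) {
  ggplot(object, aes(x = .data$x, y = .data$y)) +
    geom_line() +
    geom_point(data = object[1, ], color = "red", size = 2) +
    labs(x = "x (mm, toward pellet)", y = "y (mm, up)",
         title = sprintf("Reach trajectory %s", attr(object, "trial_id"))) +
    theme_minimal()
}

#' Plot a platform trial
#'
#' Force and handle position over time on facing panels.
#'
#' @param object A `platform_trial`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.platform_trial <- function(object, ...) {
  d <- tidyr::pivot_longer(as_tibble(object), c("force", "position"),
                           names_to = "signal")
  ggplot(d, aes(x = .data$t, y = .data$value)) +
    geom_line() +
    facet_wrap(~signal, ncol = 1, scales = "free_y") +
    labs(x = "Time (s)", y = NULL, title = "Platform trial") +
    theme_minimal()
}

#' Plot an input/output curve
#'
#' @param object An `io_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.io_curve <- function(object, ...) {
  ggplot(object, aes(x = .data$intensity_mw, y = .data$neg_amplitude_mv)) +
    geom_line() +
    geom_point() +
    geom_vline(xintercept = attr(object, "saturation_intensity"),
               linetype = "dashed", color = "red") +
    labs(x = "Stimulation intensity (mW)",
         y = "Negative FP amplitude (mV, deep pool)",
         title = "Input/output curve") +
    theme_minimal()
}
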