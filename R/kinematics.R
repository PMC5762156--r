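# Skilled-reaching kinematics: color-contrast paw tracking and the four
# trajectory metrics (ArcLen, AUC, Mean Speed, Smoothness).

#' Track the dye-marked paw across video frames
#'
#' Per frame, builds a binary mask of pixels whose green dominance
#' (`G - max(R, B)` on the 8-bit scale) exceeds `threshold`, takes the
#' centroid of the largest connected component as the paw position, and
#' converts to millimetres. Frames with an empty mask are linearly
#' interpolated from their neighbours and flagged; a trial with more than
#' `max_empty_frac` empty frames is rejected.
#'
#' @param frames `h x w x 3 x n_frames` numeric array (8-bit scale) or a
#'   list of `h x w x 3` arrays.
#' @param mm_per_px Pixel-to-millimetre calibration.
#' @param frame_rate Acquisition rate in Hz.
#' @param threshold Green-dominance threshold (8-bit units).
#' @param max_empty_frac Rejection limit on the fraction of empty-mask
#'   frames (default 0.25).
#' @param origin_px Pixel (col, row) mapped to (x, y) = (0, 0); y points up.
#' @param trial_id,outcome Metadata stored on the trajectory.
#'
#' @return A `reach_trajectory` tibble (`t`, `x`, `y`, `interpolated`).
#' @export
track_paw <- function(frames, mm_per_px, frame_rate = 120, threshold = 50,
                      max_empty_frac = 0.25, origin_px = NULL,
                      trial_id = NA_character_,
                      outcome = c("correct", "incorrect")) {
  outcome <- match.arg(outcome)
  if (!requireNamespace("EBImage", quietly = TRUE)) {
    abort("Package 'EBImage' is required for paw tracking.")
  }
  if (is.list(frames)) {
    frames <- array(unlist(frames), dim = c(dim(frames[[1]]), length(frames)))
  }
  if (length(dim(frames)) != 4L || dim(frames)[3] != 3L) {
    abort("`frames` must be an h x w x 3 x n array (or list of h x w x 3 arrays).")
  }
  assert_scalar_number(mm_per_px, "mm_per_px", lower = 0, strict_lower = TRUE)
  h <- dim(frames)[1]
  n <- dim(frames)[4]
  origin_px <- origin_px %||% c(0, h)
  cent <- matrix(NA_real_, n, 2)  # col, row
  for (i in seq_len(n)) {
    fr <- frames[, , , i]
    dominance <- fr[, , 2] - pmax(fr[, , 1], fr[, , 3])
    mask <- dominance > threshold
    if (!any(mask)) next
    labels <- EBImage::bwlabel(mask)
    sizes <- tabulate(labels[labels > 0])
    big <- which.max(sizes)
    sel <- which(labels == big, arr.ind = TRUE)
    cent[i, ] <- c(mean(sel[, 2]), mean(sel[, 1]))
  }
  empty <- is.na(cent[, 1])
  if (mean(empty) > max_empty_frac) {
    abort(sprintf(
      "Trial rejected: %d of %d frames (%.0f%%) have no trackable paw mask (limit %.0f%%).",
      sum(empty), n, 100 * mean(empty), 100 * max_empty_frac
    ), class = "strokelab_track_rejected")
  }
  if (any(empty)) {
    ok <- which(!empty)
    cent[, 1] <- approx(ok, cent[ok, 1], xout = seq_len(n), rule = 2)$y
    cent[, 2] <- approx(ok, cent[ok, 2], xout = seq_len(n), rule = 2)$y
  }
  new_reach_trajectory(
    t = (seq_len(n) - 1L) / frame_rate,
    x = (cent[, 1] - origin_px[1]) * mm_per_px,
    y = (origin_px[2] - cent[, 2]) * mm_per_px,
    frame_rate = frame_rate, trial_id = trial_id, outcome = outcome,
    interpolated = empty
  )
}

#' Tangential speed profile of a trajectory
#'
#' Speed by central differences of position (one-sided at the ends), then
#' moving-average smoothing.
#'
#' @param traj A `reach_trajectory` (or data frame with `t`, `x`, `y`).
#' @param smoothing_window Odd window length in samples (default 5 at
#'   120 Hz; 1 disables smoothing).
#'
#' @return A `speed_profile` tibble: `t` (s), `v` (mm/s), with attribute
#'   `smoothing_window`.
#' @export
speed_profile <- function(traj, smoothing_window = 5) {
  smoothing_window <- assert_count(smoothing_window, "smoothing_window", min = 1L)
  if (smoothing_window %% 2L == 0L) abort("`smoothing_window` must be odd.")
  n <- nrow(traj)
  if (n < max(5L, smoothing_window)) {
    abort("Trajectory shorter than the smoothing window.")
  }
  dt <- traj$t[2] - traj$t[1]
  v <- numeric(n)
  v[2:(n - 1)] <- sqrt((traj$x[3:n] - traj$x[1:(n - 2)])^2 +
                       (traj$y[3:n] - traj$y[1:(n - 2)])^2) / (2 * dt)
  v[1] <- sqrt((traj$x[2] - traj$x[1])^2 + (traj$y[2] - traj$y[1])^2) / dt
  v[n] <- sqrt((traj$x[n] - traj$x[n - 1])^2 + (traj$y[n] - traj$y[n - 1])^2) / dt
  v <- moving_average(v, smoothing_window)
  out <- tibble(t = traj$t, v = v)
  structure(out, smoothing_window = smoothing_window,
            class = c("speed_profile", class(out)))
}

#' Reaching kinematic metrics
#'
#' Computes the four trajectory metrics: `arc_len`, the summed Euclidean
#' segment lengths of the whole reach-and-retract path; `auc`, the absolute
#' shoelace area of the polygon formed by the path closed with the
#' endpoint-to-startpoint chord; `mean_speed`, the average tangential
#' speed; and `smoothness`, the number of local speed maxima with
#' topographic prominence at least `peak_prominence_frac` of the maximum
#' speed (fewer peaks = smoother movement).
#'
#' @param traj A `reach_trajectory`.
#' @param speed Optional precomputed [speed_profile()]; computed from
#'   `traj` if omitted.
#' @param peak_prominence_frac Prominence floor as a fraction of the peak
#'   speed (default 0.1).
#'
#' @return A `kinematic_metrics` tibble (one row): `trial_id`,
#'   `arc_len_mm`, `auc_mm2`, `mean_speed_mms`, `smoothness`.
#' @export
kinematic_metrics <- function(traj, speed = NULL, peak_prominence_frac = 0.1) {
  if (nrow(traj) < 2L || nrow(unique(traj[, c("x", "y")])) < 2L) {
    abort("Degenerate trajectory: fewer than 2 distinct points.")
  }
  speed <- speed %||% speed_profile(traj)
  arc_len <- sum(sqrt(diff(traj$x)^2 + diff(traj$y)^2))
  x <- traj$x
  y <- traj$y
  # shoelace on the polygon closed by the endpoint-to-startpoint chord
  auc <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  peaks <- find_peaks(speed$v, min_prominence = peak_prominence_frac * max(speed$v))
  out <- tibble(
    trial_id = attr(traj, "trial_id") %||% NA_character_,
    arc_len_mm = arc_len, auc_mm2 = auc,
    mean_speed_mms = mean(speed$v), smoothness = length(peaks)
  )
  structure(out, class = c("kinematic_metrics", class(out)))
}

#' Subtract per-animal baselines from a metric series
#'
#' Expresses longitudinal metric values as change from baseline: each value
#' minus the mean of that animal's baseline sessions, per metric.
#'
#' @param data Tibble with one row per animal x session x metric value.
#' @param value Column holding the metric value (tidy-eval).
#' @param session Column identifying the session.
#' @param baseline_sessions Sessions to average as baseline.
#' @param ... Grouping columns (e.g. animal, metric name).
#'
#' @return `data` with an added `<value>_norm` column.
#' @export
baseline_normalize <- function(data, value, session, baseline_sessions, ...) {
  value <- rlang::enquo(value)
  session <- rlang::enquo(session)
  groups <- rlang::enquos(...)
  out <- data |>
    dplyr::group_by(!!!groups) |>
    dplyr::mutate(
      .baseline = {
        sel <- (!!session) %in% baseline_sessions
        if (!any(sel)) abort("No baseline sessions found for a group.")
        mean((!!value)[sel], na.rm = TRUE)
      },
      "{rlang::as_name(value)}_norm" := (!!value) - .data$.baseline
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-".baseline")
  out
}
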