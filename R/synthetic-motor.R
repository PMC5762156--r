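# Synthetic skilled-reaching trajectories, robotic-platform force/position
# traces, and behavioral event tallies, all seeded and carrying ground truth.

#' Generate a synthetic reaching trajectory
#'
#' Builds an out-and-back paw path in the sagittal plane: out along the
#' upper arc of a smooth elliptical loop to the pellet at `path_extent` mm,
#' back along the lower arc (the tangent turns continuously, so the
#' turnaround never collapses the measured tangential speed). The speed is
#' a sum of `n_submovements` well-separated Gaussian bells, so the profile
#' has exactly `n_submovements` local maxima; bell amplitudes are rescaled
#' so the integrated speed equals the geometric loop length.
#'
#' @param config A [reach_config()].
#' @param trial_id Identifier stored on the trajectory.
#' @param outcome `"correct"` or `"incorrect"` (kinematics are computed on
#'   correct trials only).
#'
#' @return A `reach_trajectory`: tibble with columns `t` (s), `x`, `y` (mm),
#'   plus attributes `frame_rate`, `trial_id`, `outcome` and `ground_truth`
#'   (list: `arc_len_mm`, `auc_mm2`, `n_submovements`, `peak_speed_mms`,
#'   `mean_speed_mms`).
#' @examples
#' traj <- gen_reach_trajectory(reach_config(n_submovements = 3, seed = 7))
#' kinematic_metrics(traj)
#' @export
gen_reach_trajectory <- function(config, trial_id = "trial1",
                                 outcome = c("correct", "incorrect")) {
  stopifnot(inherits(config, "reach_config"))
  outcome <- match.arg(outcome)
  E <- config$path_extent
  H <- 0.35 * E  # semi-minor axis of the elliptical loop
  # dense canonical loop, parameterized by cumulative arc length
  theta <- seq(0, 2 * pi, length.out = 8001L)
  xs <- E / 2 * (1 - cos(theta))
  ys <- H * sin(theta)
  seg <- sqrt(diff(xs)^2 + diff(ys)^2)
  cum_len <- c(0, cumsum(seg))
  L <- cum_len[length(cum_len)]
  auc_true <- pi * (E / 2) * H  # ellipse area

  Tdur <- config$total_duration
  n <- config$n_submovements
  t <- seq(0, Tdur, by = 1 / config$frame_rate)
  if (length(t) < 5L) abort("Trajectory must have at least 5 samples; lengthen `total_duration`.")
  centers <- (seq_len(n) - 0.5) * Tdur / n
  sdw <- Tdur / (8 * n)
  v <- rowSums(vapply(centers, function(c0) {
    config$peak_speed * exp(-((t - c0)^2) / (2 * sdw^2))
  }, numeric(length(t))))
  # distance along the loop: trapezoid-integrated speed, scaled to close the loop
  s_raw <- c(0, cumsum((v[-1] + v[-length(v)]) / 2 / config$frame_rate))
  scale <- L / s_raw[length(s_raw)]
  s <- s_raw * scale
  withr::with_seed(config$seed, {
    x <- approx(cum_len, xs, xout = s, rule = 2)$y
    y <- approx(cum_len, ys, xout = s, rule = 2)$y
    if (config$noise_sd_xy > 0) {
      x <- x + rnorm(length(x), 0, config$noise_sd_xy)
      y <- y + rnorm(length(y), 0, config$noise_sd_xy)
    }
    new_reach_trajectory(
      t = t, x = x, y = y, frame_rate = config$frame_rate,
      trial_id = trial_id, outcome = outcome,
      ground_truth = list(
        arc_len_mm = L, auc_mm2 = auc_true, n_submovements = n,
        peak_speed_mms = max(v) * scale, mean_speed_mms = L / Tdur
      )
    )
  })
}

#' @noRd
new_reach_trajectory <- function(t, x, y, frame_rate, trial_id = NA_character_,
                                 outcome = "correct", ground_truth = NULL,
                                 interpolated = NULL) {
  out <- tibble(t = t, x = x, y = y)
  if (!is.null(interpolated)) out$interpolated <- interpolated
  structure(out,
            frame_rate = frame_rate, trial_id = trial_id, outcome = outcome,
            ground_truth = ground_truth,
            class = c("reach_trajectory", class(out)))
}

#' Generate a synthetic robotic-platform trial
#'
#' One forelimb-retraction trial on the platform: the handle starts at full
#' extension; `n_attempts` sub-threshold force peaks (1 s apart) leave the
#' position unchanged, then one supra-threshold pull retracts the handle to
#' the start position along a linear ramp. Sub-noise-floor Gaussian force
#' jitter (SD 0.002 N) is added so traces are not sterile.
#'
#' @param config A [platform_config()].
#'
#' @return A `platform_trial`: tibble with columns `t` (s), `force` (N),
#'   `position` (mm), plus attributes `friction_threshold`,
#'   `target_extension` and `ground_truth` (list: `t_target_s`,
#'   `n_attempts`, `attempt_times_s`).
#' @export
gen_platform_trial <- function(config) {
  stopifnot(inherits(config, "platform_config"))
  fs <- config$sample_rate
  attempt_times <- if (config$n_attempts > 0) seq_len(config$n_attempts) else numeric(0)
  pull_onset <- config$n_attempts + 1
  pull_dur <- 1.0
  t_complete <- pull_onset + pull_dur
  t <- seq(0, t_complete + 0.5, by = 1 / fs)
  force <- numeric(length(t))
  for (a in attempt_times) {
    force <- force + config$attempt_peak_force * hann_bump(t, a, 0.15)
  }
  force <- force + config$pull_force * hann_bump(t, pull_onset + pull_dur / 2,
                                                 pull_dur / 2 + 0.1)
  position <- rep(config$extension, length(t))
  pulling <- t >= pull_onset & t <= t_complete
  position[pulling] <- config$extension * (1 - (t[pulling] - pull_onset) / pull_dur)
  position[t > t_complete] <- 0
  withr::with_seed(config$seed, {
    force <- force + rnorm(length(t), 0, 0.002)
  })
  out <- tibble(t = t, force = force, position = position)
  structure(out,
            friction_threshold = config$friction_threshold,
            target_extension = config$extension,
            ground_truth = list(
              t_target_s = t_complete, n_attempts = config$n_attempts,
              attempt_times_s = attempt_times
            ),
            class = c("platform_trial", class(out)))
}

#' Generate synthetic behavioral event tallies
#'
#' Binomially samples Gridwalk step outcomes per limb, cylinder wall
#' contacts, and skilled-reaching outcomes, with the generating rates kept
#' as ground truth.
#'
#' @param p_fault_per_limb Named vector of per-limb foot-fault probabilities
#'   (e.g. `c(left = 0.3, right = 0.1)`).
#' @param p_impaired_use Probability that a cylinder wall contact uses the
#'   impaired forelimb.
#' @param n_events Number of steps per limb / wall contacts / reach attempts.
#' @param seed Integer seed.
#' @param p_incorrect_reach Probability that a reach attempt is incorrect.
#'
#' @return A `behavior_counts`: list of tibbles `steps` (limb,
#'   correct_steps, foot_faults), `cylinder` (n_impaired, n_unimpaired),
#'   `reaching` (n_correct, n_incorrect, n_attempts_total), plus a
#'   `ground_truth` element with the generating rates.
#' @export
gen_behavior_counts <- function(p_fault_per_limb, p_impaired_use, n_events,
                                seed = 1L, p_incorrect_reach = 0.2) {
  if (any(p_fault_per_limb < 0 | p_fault_per_limb > 1)) {
    abort("`p_fault_per_limb` must be probabilities in [0, 1].")
  }
  assert_scalar_number(p_impaired_use, "p_impaired_use", lower = 0, upper = 1)
  assert_scalar_number(p_incorrect_reach, "p_incorrect_reach", lower = 0, upper = 1)
  n_events <- assert_count(n_events, "n_events", min = 1L)
  if (is.null(names(p_fault_per_limb))) {
    names(p_fault_per_limb) <- paste0("limb", seq_along(p_fault_per_limb))
  }
  withr::with_seed(seed, {
    faults <- rbinom(length(p_fault_per_limb), n_events, p_fault_per_limb)
    n_imp <- rbinom(1, n_events, p_impaired_use)
    n_inc <- rbinom(1, n_events, p_incorrect_reach)
    structure(
      list(
        steps = tibble(
          limb = names(p_fault_per_limb),
          correct_steps = n_events - faults, foot_faults = faults
        ),
        cylinder = tibble(n_impaired = n_imp, n_unimpaired = n_events - n_imp),
        reaching = tibble(
          n_correct = n_events - n_inc, n_incorrect = n_inc,
          n_attempts_total = n_events
        ),
        ground_truth = list(
          p_fault_per_limb = p_fault_per_limb,
          p_impaired_use = p_impaired_use,
          p_incorrect_reach = p_incorrect_reach, n_events = n_events
        )
      ),
      class = "behavior_counts"
    )
  })
}

#' Render a trajectory as synthetic video frames
#'
#' Paints a green disc (the dye-marked paw) at each trajectory position on a
#' gray background, producing the frame stack consumed by [track_paw()].
#' Pixel row 1 is the top of the image; the y axis points upward.
#'
#' @param positions Tibble/data frame with `x`, `y` in mm.
#' @param mm_per_px Spatial calibration.
#' @param dims Image height and width in pixels, `c(h, w)`.
#' @param radius_px Disc radius in pixels.
#' @param origin_px Pixel (col, row) corresponding to (x, y) = (0, 0).
#'
#' @return A `h x w x 3 x n_frames` numeric array with 8-bit-scale values.
#' @export
render_reach_frames <- function(positions, mm_per_px = 0.1, dims = c(80, 120),
                                radius_px = 5, origin_px = c(20, 60)) {
  h <- dims[1]; w <- dims[2]
  n <- nrow(positions)
  frames <- array(60, dim = c(h, w, 3, n))
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  for (i in seq_len(n)) {
    cx <- origin_px[1] + positions$x[i] / mm_per_px
    cy <- origin_px[2] - positions$y[i] / mm_per_px
    disc <- (rows - cy)^2 + (cols - cx)^2 <= radius_px^2
    fr <- frames[, , , i]
    g <- fr[, , 2]
    g[disc] <- 220
    fr[, , 2] <- g
    r <- fr[, , 1]; r[disc] <- 40; fr[, , 1] <- r
    b <- fr[, , 3]; b[disc] <- 40; fr[, , 3] <- b
    frames[, , , i] <- fr
  }
  frames
}
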