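# Configuration records for the synthetic-data generators. Each constructor
# validates its invariants once so downstream code can trust the values.

# Condition presets encode the direction (not the magnitude) of the group
# effects: early-negative FP dampened after stroke, late-positive FP enhanced
# at 30 days, paired-pulse ratio lowered by the stronger interhemispheric
# inhibition; the combined-rehabilitation group normalizes the positive wave
# and the PPR while the negative wave recovers only partly.
condition_presets <- list(
  sham       = list(neg_amp_scale = 1.00, pos_amp_scale = 1.00, ppd_ratio = 0.80),
  stroke5d   = list(neg_amp_scale = 0.35, pos_amp_scale = 1.20, ppd_ratio = 0.70),
  stroke30d  = list(neg_amp_scale = 0.60, pos_amp_scale = 1.70, ppd_ratio = 0.55),
  robot_bont = list(neg_amp_scale = 0.65, pos_amp_scale = 1.05, ppd_ratio = 0.78)
)

#' Cohort configuration for synthetic evoked-LFP recordings
#'
#' Defines one experimental group for [gen_evoked_lfp()]. Amplitude scalings
#' and the paired-pulse depression ratio default to condition presets that
#' reproduce the direction of the reported group effects (weaker early
#' negative component after stroke, stronger late positive component at 30
#' days, lower paired-pulse ratio); magnitudes are phenomenological.
#'
#' @param condition One of `"sham"`, `"stroke5d"`, `"stroke30d"`,
#'   `"robot_bont"`.
#' @param n_subjects Number of animals in the group.
#' @param seed Integer seed; identical `(config, seed)` gives bit-identical
#'   output.
#' @param neg_amp_scale,pos_amp_scale Multipliers on the negative / positive
#'   field-potential component amplitudes (default from the condition preset).
#' @param ppd_ratio Second-response / first-response amplitude ratio injected
#'   in paired-pulse trials, in (0, 1].
#' @param noise_sd Additive white-noise SD in millivolts.
#' @param n_trials Stimulus repetitions per protocol (15, spaced by
#'   `trial_spacing`).
#' @param trial_spacing Seconds between repetitions (5 s).
#' @param sample_rate Synthesis rate in Hz. 1 kHz suffices for LFP-band
#'   content; use >= 20 kHz to embed spike bursts for multi-unit analysis.
#' @param n_channels Number of probe contacts (16-channel linear probe).
#'
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(condition = c("sham", "stroke5d", "stroke30d", "robot_bont"),
                          n_subjects = 5, seed = 1L,
                          neg_amp_scale = NULL, pos_amp_scale = NULL,
                          ppd_ratio = NULL, noise_sd = 0.05,
                          n_trials = 15, trial_spacing = 5,
                          sample_rate = 1000, n_channels = 16) {
  condition <- match.arg(condition)
  preset <- condition_presets[[condition]]
  neg_amp_scale <- neg_amp_scale %||% preset$neg_amp_scale
  pos_amp_scale <- pos_amp_scale %||% preset$pos_amp_scale
  ppd_ratio <- ppd_ratio %||% preset$ppd_ratio
  n_subjects <- assert_count(n_subjects, "n_subjects", min = 1L)
  assert_scalar_number(neg_amp_scale, "neg_amp_scale", lower = 0)
  assert_scalar_number(pos_amp_scale, "pos_amp_scale", lower = 0)
  assert_scalar_number(ppd_ratio, "ppd_ratio", lower = 0, upper = 1,
                       strict_lower = TRUE)
  assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  n_trials <- assert_count(n_trials, "n_trials", min = 1L)
  assert_scalar_number(trial_spacing, "trial_spacing", lower = 0,
                       strict_lower = TRUE)
  assert_scalar_number(sample_rate, "sample_rate", lower = 0, strict_lower = TRUE)
  n_channels <- assert_count(n_channels, "n_channels", min = 3L)
  structure(
    list(
      condition = condition, n_subjects = n_subjects, seed = as.integer(seed),
      neg_amp_scale = neg_amp_scale, pos_amp_scale = pos_amp_scale,
      ppd_ratio = ppd_ratio, noise_sd = noise_sd, n_trials = n_trials,
      trial_spacing = trial_spacing, sample_rate = sample_rate,
      n_channels = n_channels
    ),
    class = "cohort_config"
  )
}

#' Reach-trajectory configuration
#'
#' Defines one synthetic skilled-reaching trial for [gen_reach_trajectory()].
#' The tangential speed is a sum of `n_submovements` well-separated
#' bell-shaped pulses; the path goes out along a smooth arch to the pellet
#' and returns straight, enclosing a known area.
#'
#' @param n_submovements Number of speed bells (>= 1).
#' @param total_duration Movement duration in seconds.
#' @param peak_speed Nominal bell peak speed in mm/s (uniformly rescaled so
#'   the integrated speed equals the geometric path length; the achieved peak
#'   speed is reported in the ground truth).
#' @param path_extent Out-reach extent in mm.
#' @param noise_sd_xy Isotropic positional jitter SD in mm.
#' @param frame_rate Sampling rate in Hz (120 fps camera).
#' @param seed Integer seed.
#'
#' @return A `reach_config` list.
#' @export
reach_config <- function(n_submovements = 3, total_duration = 1.0,
                         peak_speed = 80, path_extent = 10,
                         noise_sd_xy = 0, frame_rate = 120, seed = 1L) {
  n_submovements <- assert_count(n_submovements, "n_submovements", min = 1L)
  assert_scalar_number(total_duration, "total_duration", lower = 0,
                       strict_lower = TRUE)
  assert_scalar_number(peak_speed, "peak_speed", lower = 0, strict_lower = TRUE)
  assert_scalar_number(path_extent, "path_extent", lower = 0, strict_lower = TRUE)
  assert_scalar_number(noise_sd_xy, "noise_sd_xy", lower = 0)
  assert_scalar_number(frame_rate, "frame_rate", lower = 0, strict_lower = TRUE)
  structure(
    list(
      n_submovements = n_submovements, total_duration = total_duration,
      peak_speed = peak_speed, path_extent = path_extent,
      noise_sd_xy = noise_sd_xy, frame_rate = frame_rate, seed = as.integer(seed)
    ),
    class = "reach_config"
  )
}

#' Robotic-platform trial configuration
#'
#' Defines one synthetic forelimb-retraction trial for [gen_platform_trial()]:
#' `n_attempts` sub-threshold force peaks that fail to move the handle,
#' followed by one supra-threshold pull that retracts it by `extension` mm.
#'
#' @param n_attempts Failed attempts before the successful pull (>= 0).
#' @param attempt_peak_force Peak force of each attempt in newtons; must stay
#'   below `friction_threshold`.
#' @param pull_force Force of the successful pull in newtons; must reach
#'   `friction_threshold`.
#' @param friction_threshold Static-friction threshold (0.2 N).
#' @param extension Handle extension in mm (10 mm, full forelimb extension).
#' @param sample_rate Sampling rate in Hz.
#' @param seed Integer seed.
#'
#' @return A `platform_config` list.
#' @export
platform_config <- function(n_attempts = 3, attempt_peak_force = 0.12,
                            pull_force = 0.35, friction_threshold = 0.2,
                            extension = 10, sample_rate = 100, seed = 1L) {
  n_attempts <- assert_count(n_attempts, "n_attempts", min = 0L)
  assert_scalar_number(attempt_peak_force, "attempt_peak_force", lower = 0)
  assert_scalar_number(pull_force, "pull_force", lower = 0)
  assert_scalar_number(friction_threshold, "friction_threshold", lower = 0,
                       strict_lower = TRUE)
  assert_scalar_number(extension, "extension", lower = 0, strict_lower = TRUE)
  assert_scalar_number(sample_rate, "sample_rate", lower = 0, strict_lower = TRUE)
  if (attempt_peak_force >= friction_threshold) {
    abort("`attempt_peak_force` must be below `friction_threshold` (attempts must fail).")
  }
  if (pull_force < friction_threshold) {
    abort("`pull_force` must reach `friction_threshold` (the pull must succeed).")
  }
  structure(
    list(
      n_attempts = n_attempts, attempt_peak_force = attempt_peak_force,
      pull_force = pull_force, friction_threshold = friction_threshold,
      extension = extension, sample_rate = sample_rate, seed = as.integer(seed)
    ),
    class = "platform_config"
  )
}
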