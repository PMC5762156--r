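# Shared fixtures, built once per test run.

# One-subject noiseless sham cohort: single pulse, defaults otherwise.
sham_noiseless <- function(seed = 3, ...) {
  gen_evoked_lfp(cohort_config("sham", n_subjects = 1, noise_sd = 0,
                               seed = seed, ...))
}

truth_row <- function(cohort, i = 1) cohort$truth[i, ]

# Minimal hand-built recording: given a per-channel matrix of one epoch
# (channels x samples starting 100 ms before the stimulus), tile it at
# n_trials stimuli so epoching recovers it exactly.
tiled_recording <- function(epoch_mv, sample_rate = 1000, n_trials = 3,
                            spacing = 1) {
  n_ch <- nrow(epoch_mv)
  n_samp <- ceiling((n_trials * spacing + 0.5) * sample_rate)
  volt <- matrix(0, n_ch, n_samp)
  stim_times <- 0.2 + (seq_len(n_trials) - 1) * spacing
  pre <- round(0.1 * sample_rate)
  for (st in stim_times) {
    i0 <- round(st * sample_rate) + 1 - pre
    volt[, i0:(i0 + ncol(epoch_mv) - 1)] <- epoch_mv
  }
  laminar_recording(volt, sample_rate, stim_times = stim_times)
}

# Dense sampling of a polygonal path (for closed-form kinematics checks).
polyline_trajectory <- function(vertices, points_per_edge = 200,
                                frame_rate = 120) {
  xs <- numeric(0); ys <- numeric(0)
  for (i in seq_len(nrow(vertices) - 1)) {
    s <- seq(0, 1, length.out = points_per_edge + 1)[-1]
    xs <- c(xs, vertices[i, 1] + s * (vertices[i + 1, 1] - vertices[i, 1]))
    ys <- c(ys, vertices[i, 2] + s * (vertices[i + 1, 2] - vertices[i, 2]))
  }
  xs <- c(vertices[1, 1], xs); ys <- c(vertices[1, 2], ys)
  structure(
    tibble::tibble(t = (seq_along(xs) - 1) / frame_rate, x = xs, y = ys),
    frame_rate = frame_rate, trial_id = "poly", outcome = "correct",
    class = c("reach_trajectory", class(tibble::tibble()))
  )
}
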