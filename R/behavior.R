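# Behavioral scoring: Gridwalk foot faults, cylinder forelimb-use asymmetry,
# skilled-reaching error rate, robotic-platform trial metrics, lesion volume,
# and the two-sample t-test power computation.

#' Percentage of Gridwalk foot faults per limb
#'
#' `100 * faults / (faults + correct_steps)` for the requested limb. A limb
#' with zero total steps yields `NA` with a warning.
#'
#' @param counts A `behavior_counts` (see [gen_behavior_counts()]) or a
#'   tibble with columns `limb`, `correct_steps`, `foot_faults`.
#' @param limb Limb name(s) to score; defaults to all limbs present.
#'
#' @return Tibble: `limb`, `foot_fault_pct`.
#' @export
foot_fault_percentage <- function(counts, limb = NULL) {
  steps <- if (inherits(counts, "behavior_counts")) counts$steps else counts
  if (!is.null(limb)) steps <- dplyr::filter(steps, .data$limb %in% !!limb)
  if (nrow(steps) == 0L) abort("No matching limb in `counts`.")
  out <- steps |>
    dplyr::mutate(
      total = .data$correct_steps + .data$foot_faults,
      foot_fault_pct = dplyr::if_else(
        .data$total > 0, 100 * .data$foot_faults / .data$total, NA_real_
      )
    )
  if (any(out$total == 0)) warn("Limb(s) with zero total steps scored as NA.")
  dplyr::select(out, "limb", "foot_fault_pct")
}

#' Forelimb-use asymmetry index from cylinder wall contacts
#'
#' `(n_unimpaired - n_impaired) / (n_unimpaired + n_impaired)`, in
#' \[-1, 1\]. Positive values indicate preference for the unimpaired limb
#' (the usual post-stroke direction); zero contacts yield `NA`.
#'
#' @param counts A `behavior_counts` or tibble with `n_impaired`,
#'   `n_unimpaired`.
#'
#' @return Numeric asymmetry index (vectorized over rows).
#' @export
asymmetry_index <- function(counts) {
  cyl <- if (inherits(counts, "behavior_counts")) counts$cylinder else counts
  total <- cyl$n_impaired + cyl$n_unimpaired
  ifelse(total > 0, (cyl$n_unimpaired - cyl$n_impaired) / total, NA_real_)
}

#' Skilled-reaching error percentage
#'
#' `100 * n_incorrect / n_attempts_total`; zero attempts yield `NA`.
#'
#' @param counts A `behavior_counts` or tibble with `n_incorrect`,
#'   `n_attempts_total`.
#'
#' @return Numeric percentage (vectorized over rows).
#' @export
reach_error_percentage <- function(counts) {
  rc <- if (inherits(counts, "behavior_counts")) counts$reaching else counts
  ifelse(rc$n_attempts_total > 0,
         100 * rc$n_incorrect / rc$n_attempts_total, NA_real_)
}

#' Robotic-platform trial metrics
#'
#' From a synchronized force/position trace: `n_attempts` counts force
#' peaks above `noise_floor` (with topographic prominence at least
#' `noise_floor`, so noise riding on a peak is not double-counted) during
#' which the handle does not move more than `position_epsilon` within
#' +/- `coincidence_window` seconds; `t_target` is the time from trial
#' start until the handle position first returns within `position_epsilon`
#' of zero (full retraction). If retraction never completes, `t_target` is
#' `NA` and attempts are still reported.
#'
#' @param trial A `platform_trial` (tibble with `t`, `force`, `position`).
#' @param noise_floor Minimum attempt peak force in newtons (default 0.05).
#' @param position_epsilon Handle-movement tolerance in mm (default 0.5).
#' @param coincidence_window Half-width (s) of the stationarity check
#'   around each force peak (default 0.1).
#'
#' @return A `platform_metrics` tibble (one row): `t_target_s`,
#'   `n_attempts`.
#' @export
platform_metrics <- function(trial, noise_floor = 0.05, position_epsilon = 0.5,
                             coincidence_window = 0.1) {
  stopifnot(all(c("t", "force", "position") %in% names(trial)))
  dt <- trial$t[2] - trial$t[1]
  half <- max(1L, round(coincidence_window / dt))
  peaks <- find_peaks(trial$force, min_prominence = noise_floor,
                      min_height = noise_floor)
  n <- nrow(trial)
  stationary <- vapply(peaks, function(i) {
    sel <- max(1L, i - half):min(n, i + half)
    (max(trial$position[sel]) - min(trial$position[sel])) <= position_epsilon
  }, logical(1))
  retracted <- which(abs(trial$position) <= position_epsilon)
  t_target <- if (length(retracted)) trial$t[retracted[1]] - trial$t[1] else NA_real_
  out <- tibble(t_target_s = t_target, n_attempts = sum(stationary))
  structure(out, class = c("platform_metrics", class(out)))
}

#' Lesion volume from sampled section areas
#'
#' Every sixth section is sampled, so the volume is the summed damaged
#' areas times section thickness times the spacing factor:
#' `sum(areas) * section_thickness * spacing_factor`.
#'
#' @param areas Damaged areas in mm^2, one per sampled section.
#' @param section_thickness Section thickness in mm (default 0.05).
#' @param spacing_factor Sampling interval between analyzed sections
#'   (default 6).
#'
#' @return Lesion volume in mm^3.
#' @examples
#' lesion_volume(c(1.0, 1.2, 0.8))  # 0.9 mm^3
#' @export
lesion_volume <- function(areas, section_thickness = 0.05, spacing_factor = 6) {
  if (length(areas) < 1L || any(!is.finite(areas))) {
    abort("`areas` must be at least one finite value.")
  }
  if (any(areas < 0)) abort("Section areas must be non-negative.")
  assert_scalar_number(section_thickness, "section_thickness", lower = 0,
                       strict_lower = TRUE)
  assert_scalar_number(spacing_factor, "spacing_factor", lower = 0,
                       strict_lower = TRUE)
  sum(areas) * section_thickness * spacing_factor
}

#' Power of the two-sample t-test
#'
#' Exact power via the noncentral t distribution with `df = 2n - 2` and
#' noncentrality `d * sqrt(n / 2)`, for Cohen's d effect size and equal
#' group sizes. The one-tailed default reflects a directional hypothesis of
#' improvement; with `d = 1.75`, `n = 5` and `alpha = 0.05` it gives a
#' power of about 0.81.
#'
#' @param d Cohen's d effect size (>= 0).
#' @param n_per_group Animals per group (>= 2).
#' @param alpha Significance level.
#' @param tails `"one"` (default) or `"two"`.
#'
#' @return Power as a probability.
#' @examples
#' ttest_power(1.75, 5)  # ~0.81
#' @export
ttest_power <- function(d, n_per_group, alpha = 0.05, tails = c("one", "two")) {
  tails <- match.arg(tails)
  assert_scalar_number(d, "d", lower = 0)
  n_per_group <- assert_count(n_per_group, "n_per_group", min = 2L)
  assert_scalar_number(alpha, "alpha", lower = 0, upper = 1, strict_lower = TRUE)
  if (alpha >= 1) abort("`alpha` must be in (0, 1).")
  df <- 2 * n_per_group - 2
  ncp <- d * sqrt(n_per_group / 2)
  if (tails == "one") {
    1 - pt(qt(1 - alpha, df), df, ncp = ncp)
  } else {
    crit <- qt(1 - alpha / 2, df)
    1 - pt(crit, df, ncp = ncp) + pt(-crit, df, ncp = ncp)
  }
}
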