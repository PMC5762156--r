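# End-to-end synthetic-study pipeline: generate every input for a
# configured set of groups, run the ephys / kinematics / behavior analyses,
# and write tidy per-subject tables plus group summaries and a manifest.
# Inferential statistics are deliberately left to downstream tools; the
# pipeline emits mean +/- SEM summaries only.

# Direction-only motor/behavior presets per condition (magnitudes are
# phenomenological; directions follow the reported group effects: stroke
# animals show more foot faults, stronger limb-use asymmetry, more reaching
# errors, more platform attempts, longer retraction times and less smooth,
# longer reach trajectories; treated animals sit between stroke and sham).
motor_presets <- list(
  sham       = list(n_submovements = 2, path_extent = 10, n_attempts = 1,
                    p_fault = 0.05, p_impaired_use = 0.50, p_incorrect = 0.15),
  stroke5d   = list(n_submovements = 6, path_extent = 14, n_attempts = 5,
                    p_fault = 0.35, p_impaired_use = 0.25, p_incorrect = 0.55),
  stroke30d  = list(n_submovements = 5, path_extent = 13, n_attempts = 4,
                    p_fault = 0.30, p_impaired_use = 0.30, p_incorrect = 0.45),
  robot_bont = list(n_submovements = 3, path_extent = 11, n_attempts = 2,
                    p_fault = 0.12, p_impaired_use = 0.42, p_incorrect = 0.25)
)

#' Study configuration for the synthetic pipeline
#'
#' @param groups Tibble with columns `condition` (one of the
#'   [cohort_config()] conditions), `n` (subjects) and `seed`. Conditions
#'   must be unique.
#' @param isi Paired-pulse inter-stimulus interval analyzed by the
#'   pipeline (ms).
#' @param noise_sd Evoked-LFP noise SD in mV.
#' @param n_behavior_events Events sampled per behavioral test.
#'
#' @return A `study_config` list.
#' @export
study_config <- function(groups, isi = 50, noise_sd = 0.05,
                         n_behavior_events = 50) {
  if (!is.data.frame(groups) || nrow(groups) == 0L) {
    abort("`groups` must be a non-empty data frame (condition, n, seed).")
  }
  if (!all(c("condition", "n", "seed") %in% names(groups))) {
    abort("`groups` needs columns `condition`, `n`, `seed`.")
  }
  if (anyDuplicated(groups$condition)) abort("Group conditions must be unique.")
  if (!all(groups$condition %in% names(condition_presets))) {
    abort("Unknown condition in `groups`.")
  }
  structure(
    list(groups = as_tibble(groups), isi = isi, noise_sd = noise_sd,
         n_behavior_events = n_behavior_events),
    class = "study_config"
  )
}

#' Run the full synthetic-study pipeline
#'
#' For every group: generates evoked laminar recordings (single-pulse and
#' paired-pulse), reach trajectories, platform trials and behavioral
#' tallies; runs field-potential component measurement with layer pooling,
#' paired-pulse ratios, kinematic metrics, platform metrics and behavioral
#' scores; and returns tidy per-subject tables with group mean +/- SEM
#' summaries. Deterministic given the configuration. If `out_dir` is given,
#' all tables are written as CSV together with a JSON manifest recording
#' seeds and the package version.
#'
#' @param config A [study_config()].
#' @param out_dir Optional output directory (created if missing).
#'
#' @return A `study_report` list of tibbles: `fp_pools`, `ppr`,
#'   `kinematics`, `platform`, `behavior`, and `summaries` (named list of
#'   group summaries), plus `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  fp_rows <- list(); ppr_rows <- list(); kin_rows <- list()
  plat_rows <- list(); beh_rows <- list()
  for (g in seq_len(nrow(config$groups))) {
    grp <- config$groups[g, ]
    preset <- motor_presets[[grp$condition]]
    cfg <- cohort_config(grp$condition, n_subjects = grp$n, seed = grp$seed,
                         noise_sd = config$noise_sd)
    coh <- gen_evoked_lfp(cfg, isi_list = c(NA, config$isi))
    for (id in names(coh$recordings)) {
      rec <- coh$recordings[[id]]
      row <- coh$truth[coh$truth$recording == id, ]
      if (is.na(row$isi)) {
        avg <- epoch_and_average(rec)
        fp <- measure_fp_components(avg)
        for (comp in c("neg", "pos")) {
          pools <- pool_layers(fp[[paste0(comp, "_amplitude_mv")]])
          fp_rows[[length(fp_rows) + 1L]] <- tibble(
            condition = grp$condition, subject = row$subject,
            component = comp, pool = as.character(pools$pool),
            amplitude_mv = pools$value
          )
        }
      } else {
        avg <- epoch_and_average(rec, window = c(-50, row$isi + 100))
        ppr <- paired_pulse_ratio(avg, isi = row$isi)
        pools <- pool_layers(ppr$ppr)
        ppr_rows[[length(ppr_rows) + 1L]] <- tibble(
          condition = grp$condition, subject = row$subject, isi = row$isi,
          pool = as.character(pools$pool), ppr = pools$value
        )
      }
    }
    for (s in seq_len(grp$n)) {
      sseed <- grp$seed * 1000L + s
      traj <- gen_reach_trajectory(reach_config(
        n_submovements = preset$n_submovements,
        path_extent = preset$path_extent, seed = sseed
      ), trial_id = sprintf("%s_s%02d", grp$condition, s))
      kin_rows[[length(kin_rows) + 1L]] <- dplyr::mutate(
        kinematic_metrics(traj),
        condition = grp$condition, subject = s, .before = 1
      )
      trial <- gen_platform_trial(platform_config(
        n_attempts = preset$n_attempts, seed = sseed
      ))
      plat_rows[[length(plat_rows) + 1L]] <- dplyr::mutate(
        platform_metrics(trial),
        condition = grp$condition, subject = s, .before = 1
      )
      counts <- gen_behavior_counts(
        p_fault_per_limb = c(impaired = preset$p_fault),
        p_impaired_use = preset$p_impaired_use,
        n_events = config$n_behavior_events, seed = sseed,
        p_incorrect_reach = preset$p_incorrect
      )
      beh_rows[[length(beh_rows) + 1L]] <- tibble(
        condition = grp$condition, subject = s,
        foot_fault_pct = foot_fault_percentage(counts)$foot_fault_pct[1],
        asymmetry_index = asymmetry_index(counts),
        reach_error_pct = reach_error_percentage(counts)
      )
    }
  }
  fp_pools <- dplyr::bind_rows(fp_rows)
  ppr <- dplyr::bind_rows(ppr_rows)
  kinematics <- dplyr::bind_rows(kin_rows)
  platform <- dplyr::bind_rows(plat_rows)
  behavior <- dplyr::bind_rows(beh_rows)
  summaries <- list(
    fp_pools = summarize_groups(fp_pools, amplitude_mv,
                                condition, component, pool),
    ppr = summarize_groups(ppr, ppr, condition, pool),
    kinematics = dplyr::bind_rows(lapply(
      c("arc_len_mm", "auc_mm2", "mean_speed_mms", "smoothness"),
      function(m) dplyr::mutate(
        summarize_groups(kinematics, !!rlang::sym(m), condition),
        metric = m, .before = 1
      )
    )),
    platform = dplyr::bind_rows(
      dplyr::mutate(summarize_groups(platform, t_target_s, condition),
                    metric = "t_target_s", .before = 1),
      dplyr::mutate(summarize_groups(platform, n_attempts, condition),
                    metric = "n_attempts", .before = 1)
    ),
    behavior = dplyr::bind_rows(lapply(
      c("foot_fault_pct", "asymmetry_index", "reach_error_pct"),
      function(m) dplyr::mutate(
        summarize_groups(behavior, !!rlang::sym(m), condition),
        metric = m, .before = 1
      )
    ))
  )
  manifest <- list(
    package = "strokelab",
    version = as.character(utils::packageVersion("strokelab")),
    groups = config$groups, isi = config$isi, noise_sd = config$noise_sd,
    n_behavior_events = config$n_behavior_events
  )
  report <- structure(
    list(fp_pools = fp_pools, ppr = ppr, kinematics = kinematics,
         platform = platform, behavior = behavior, summaries = summaries,
         manifest = manifest),
    class = "study_report"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in c("fp_pools", "ppr", "kinematics", "platform", "behavior")) {
      readr::write_csv(report[[nm]], file.path(out_dir, paste0(nm, ".csv")))
    }
    for (nm in names(summaries)) {
      readr::write_csv(summaries[[nm]],
                       file.path(out_dir, paste0("summary_", nm, ".csv")))
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}

#' Group mean, SEM and n for a metric
#'
#' Summarizes a per-subject table into mean +/- SEM cells. Missing values
#' are excluded and counted; single-value groups get SEM 0 with a flag so
#' tables stay rectangular.
#'
#' @param data Tibble of per-subject values.
#' @param value Value column (tidy-eval).
#' @param ... Grouping columns.
#'
#' @return Tibble with `mean`, `sem`, `n`, `n_missing`, `single_value`.
#' @export
summarize_groups <- function(data, value, ...) {
  value <- rlang::enquo(value)
  groups <- rlang::enquos(...)
  if (nrow(data) == 0L) abort("Cannot summarize an empty table.")
  data |>
    dplyr::group_by(!!!groups) |>
    dplyr::summarise(
      n_missing = sum(is.na(!!value)),
      n = sum(!is.na(!!value)),
      mean = mean(!!value, na.rm = TRUE),
      sem = if (sum(!is.na(!!value)) > 1L) {
        sd(!!value, na.rm = TRUE) / sqrt(sum(!is.na(!!value)))
      } else 0,
      single_value = sum(!is.na(!!value)) == 1L,
      .groups = "drop"
    ) |>
    dplyr::relocate("mean", "sem", "n", .before = "n_missing")
}
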