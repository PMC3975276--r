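# End-to-end orchestration: raw inputs (synthetic or on disk) through
# accelerometer reduction, journey segmentation, cohort classification and
# the comparative statistics, with reproducible stage outputs.

#' Pipeline run configuration
#'
#' Exactly one input source must be given: either a [cohort_config()] for a
#' synthetic run, or a named list of raw-input paths (`accel`, `gps`,
#' `diary` file vectors plus `demographics` and `anchors` files).
#'
#' @param synthetic A [cohort_config()], or `NULL`.
#' @param paths Raw-input path list, or `NULL`.
#' @param cut_points A [cut_point_config()].
#' @param commute_windows Commute windows for segmentation.
#' @param max_gap_s Epoch-fix merge tolerance, seconds.
#' @param max_internal_gap_min Journey internal gap tolerance, minutes.
#' @param seed Integer seed (drives synthetic generation).
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return A `run_config` object.
#' @export
run_config <- function(synthetic = NULL, paths = NULL,
                       cut_points = cut_point_config(),
                       commute_windows = default_commute_windows(),
                       max_gap_s = 5, max_internal_gap_min = 5,
                       seed = 1L, out_dir = NULL) {
  if (is.null(synthetic) == is.null(paths)) {
    abort("exactly one of `synthetic` and `paths` must be given",
          class = "commutePA_config_error")
  }
  if (!is.null(synthetic) && !inherits(synthetic, "cohort_config")) {
    abort("`synthetic` must be a cohort_config", class = "commutePA_config_error")
  }
  structure(list(synthetic = synthetic, paths = paths,
                 cut_points = cut_points, commute_windows = commute_windows,
                 max_gap_s = max_gap_s,
                 max_internal_gap_min = max_internal_gap_min,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

load_inputs <- function(config) {
  if (!is.null(config$synthetic)) {
    cohort <- generate_cohort(config$synthetic, config$seed)
    list(accel = cohort$accel, gps = cohort$gps, diary = cohort$diary,
         demographics = cohort$demographics, anchors = cohort$anchors,
         truth = cohort$truth)
  } else {
    p <- config$paths
    viol <- validate_inputs(p)
    if (nrow(viol) > 0) {
      abort(paste0("input validation failed:\n",
                   paste(sprintf("  %s: %s", viol$file, viol$message),
                         collapse = "\n")),
            class = "commutePA_input_error")
    }
    list(
      accel = purrr::map_dfr(p$accel, read_accel_csv),
      gps = if (is.null(p$gps)) NULL else purrr::map_dfr(p$gps, read_gps_csv),
      diary = purrr::map_dfr(p$diary, read_diary_csv),
      demographics = read_demographics_csv(p$demographics),
      anchors = if (is.null(p$anchors)) NULL else read_anchors_csv(p$anchors),
      truth = NULL
    )
  }
}

#' Run the full analysis pipeline
#'
#' Executes, in order: synthetic generation (or raw-input loading with
#' validation), accelerometer reduction to day summaries, accelerometer+GPS
#' merging and journey segmentation, diary-based cohort classification, and
#' the comparative statistics: group summaries by day type, paired
#' weekday-weekend tests, working-hours comparison, hourly profiles,
#' covariate-adjusted regressions of the three daily outcomes, the
#' day-level walking-days versus car-days comparison, and the commute
#' contribution to daily MVPA. With an `out_dir`, every stage result is
#' written as CSV (plus a plain-text participant-flow report and a JSON run
#' manifest); identical config and seed reproduce identical outputs.
#'
#' @param config A [run_config()].
#' @return List of stage results: `day_summaries`, `journeys` (summary
#'   columns only), `classification`, `group_summaries`, `paired_tests`,
#'   `working_hours`, `hourly`, `models`, `day_level`, `contribution`,
#'   `percent_differences`, `flow`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)), class = "commutePA_stage_error")
    })
  }
  inputs <- stage("load", load_inputs(config))
  cp <- config$cut_points

  day_summaries <- stage("reduce", summarise_days(inputs$accel, cp))

  journeys <- NULL
  if (!is.null(inputs$gps) && nrow(inputs$gps) > 0 && !is.null(inputs$anchors)) {
    journeys <- stage("segment", segment_cohort(
      inputs$accel, inputs$gps, inputs$anchors,
      commute_windows = config$commute_windows,
      max_internal_gap_min = config$max_internal_gap_min,
      config = cp, max_gap_s = config$max_gap_s))
  }

  classification <- stage("classify", build_analysis_set(
    inputs$diary, inputs$demographics, day_summaries))
  aset <- classification$analysis_set
  groups <- tibble(participant_id = aset$participant_id,
                   group = aset$usual_mode)
  included_days <- day_summaries[day_summaries$participant_id %in%
                                   aset$participant_id, ]

  results <- stage("analyse", {
    pm <- dplyr::group_by(
      included_days[included_days$valid, ],
      .data$participant_id, .data$day_type) %>%
      dplyr::summarise(mean_cpm = mean(.data$mean_cpm),
                       mvpa_minutes = mean(.data$mvpa_minutes),
                       sedentary_minutes = mean(.data$sedentary_minutes),
                       .groups = "drop") %>%
      dplyr::inner_join(groups, by = "participant_id")

    group_summaries <- purrr::map_dfr(
      c("weekday", "weekend"), function(dt) {
        purrr::map_dfr(
          c("mean_cpm", "mvpa_minutes", "sedentary_minutes"), function(oc) {
            d <- pm[pm$day_type == dt, ]
            if (length(unique(d$group)) < 2 || any(table(d$group) < 2)) {
              return(NULL)
            }
            gc <- compare_groups(d[[oc]], d$group)
            dplyr::mutate(gc$summary, day_type = dt, outcome = oc,
                          f_statistic = gc$f_statistic, p_value = gc$p_value)
          })
      })

    paired_tests <- purrr::map_dfr(
      c("mean_cpm", "mvpa_minutes", "sedentary_minutes"), function(oc) {
        wide <- tidyr::pivot_wider(pm[, c("participant_id", "day_type", oc)],
                                   names_from = "day_type",
                                   values_from = dplyr::all_of(oc))
        if (!all(c("weekday", "weekend") %in% names(wide))) return(NULL)
        pt <- paired_weekday_weekend(wide$weekday, wide$weekend)
        tibble(outcome = oc, n_pairs = pt$n_pairs,
               mean_difference = pt$mean_difference,
               t_statistic = pt$t_statistic, p_value = pt$p_value)
      })

    epochs_inc <- inputs$accel[inputs$accel$participant_id %in%
                                 aset$participant_id, ]
    working_hours <- working_hours_comparison(epochs_inc, groups, config = cp)
    hourly <- hourly_profile(epochs_inc, groups, config = cp)

    reg_data <- participant_weekday_means(day_summaries, aset)
    models <- purrr::map(
      stats::setNames(nm = c("mean_cpm", "mvpa_minutes", "sedentary_minutes")),
      function(oc) fit_adjusted_model(reg_data, oc))

    labelled <- label_days_by_mode(included_days, inputs$diary)
    day_level <- day_level_comparison(labelled, "mean_cpm")

    contribution <- NULL
    if (!is.null(journeys) && nrow(journeys) > 0) {
      walkers <- aset$participant_id[aset$usual_mode == "walk"]
      jw <- journeys[journeys$participant_id %in% walkers, ]
      if (nrow(jw) > 0) {
        contribution <- commute_contribution(jw, day_summaries)
      }
    }

    wk <- group_summaries[group_summaries$day_type == "weekday", ]
    pick <- function(oc, g) wk$mean[wk$outcome == oc & wk$group == g]
    percent_differences <- tibble(
      outcome = c("mean_cpm", "mvpa_minutes"),
      walk_mean = c(pick("mean_cpm", "walk"), pick("mvpa_minutes", "walk")),
      car_mean = c(pick("mean_cpm", "car"), pick("mvpa_minutes", "car")))
    percent_differences$percent_higher <- percent_difference(
      percent_differences$walk_mean, percent_differences$car_mean)

    list(group_summaries = group_summaries, paired_tests = paired_tests,
         working_hours = working_hours, hourly = hourly, models = models,
         day_level = day_level, contribution = contribution,
         percent_differences = percent_differences)
  })

  out <- c(list(day_summaries = day_summaries,
                journeys = if (is.null(journeys)) NULL else
                  journeys[, setdiff(names(journeys), "data")],
                classification = classification,
                flow = classification$flow,
                truth = inputs$truth),
           results)
  if (!is.null(config$out_dir)) write_run_outputs(out, config)
  invisible(out)
}

write_run_outputs <- function(out, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) {
    readr::write_csv(x, file.path(config$out_dir, paste0(name, ".csv")))
  }
  w(out$day_summaries, "day_summaries")
  if (!is.null(out$journeys)) {
    j <- out$journeys
    j$start <- fmt_ts(j$start); j$end <- fmt_ts(j$end)
    w(j, "journeys")
  }
  w(out$classification$participants, "analysis_set")
  w(out$group_summaries, "group_summaries")
  w(out$paired_tests, "paired_tests")
  w(out$hourly, "hourly_profile")
  w(out$percent_differences, "percent_differences")
  coefs <- purrr::map_dfr(out$models, function(m) {
    dplyr::mutate(m$coefficients, outcome = m$outcome, n = m$n)
  })
  w(coefs, "adjusted_models")
  if (!is.null(out$contribution)) {
    w(out$contribution$per_participant, "contribution_per_participant")
  }
  writeLines(c("participant flow",
               sprintf("  %-24s %d", names(out$flow), out$flow)),
             file.path(config$out_dir, "flow_report.txt"))
  manifest <- list(
    package = "commutePA",
    version = as.character(utils::packageVersion("commutePA")),
    seed = config$seed,
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    synthetic = !is.null(config$synthetic),
    flow = as.list(out$flow)
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(config$out_dir)
}

#' Plot the mean hourly activity profile by group
#'
#' Line plot of [hourly_profile()] output, the standard figure for locating
#' when groups' physical activity diverges during the day.
#'
#' @param hourly Output of [hourly_profile()].
#' @return A ggplot object.
#' @export
plot_hourly_profile <- function(hourly) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort("ggplot2 is required for plotting")
  }
  ggplot2::ggplot(hourly, ggplot2::aes(x = .data$hour, y = .data$mean_cpm,
                                       colour = .data$group)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "Hour of day", y = "Mean counts per minute",
                  colour = "Usual mode") +
    ggplot2::theme_minimal()
}
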