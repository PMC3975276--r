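#' Accelerometer cut-point and data-reduction configuration
#'
#' Bundles the epoch-classification thresholds and wear-time rules used by the
#' accelerometer reduction stage. Defaults are the values standard in adult
#' waist-worn accelerometry: moderate-to-vigorous physical activity (MVPA)
#' above 1952 counts per minute (cpm), sedentary below 100 cpm, non-wear as a
#' continuous run of zeros of at least 20 minutes, a valid day as at least
#' 600 minutes of wear, and an analysis window of 06:00 to midnight.
#'
#' Both threshold inequalities are strict: an epoch is MVPA only if its rate
#' exceeds `mvpa_threshold_cpm`, sedentary only if it is below
#' `sedentary_threshold_cpm`; counts exactly at either threshold are light.
#' Thresholds are expressed in counts per minute and scaled to the epoch
#' length by `epoch_s / 60` before comparison.
#'
#' @param mvpa_threshold_cpm MVPA cut-point in counts per minute (exclusive
#'   lower bound; default 1952).
#' @param sedentary_threshold_cpm Sedentary cut-point in counts per minute
#'   (exclusive upper bound; default 100).
#' @param window_start,window_end Analysis window as `"HH:MM"`; the window is
#'   half-open (`[start, end)`) and an epoch belongs to it iff its start time
#'   does. Defaults 06:00 and 24:00.
#' @param nonwear_min_minutes Minimum length, in minutes, of a continuous run
#'   of zero-count epochs classed as non-wear (default 20; the boundary is
#'   inclusive: exactly 20 minutes of zeros is non-wear).
#' @param valid_day_min_wear_minutes Minimum wear minutes inside the window
#'   for a day to be valid (default 600, inclusive).
#' @return A `cut_point_config` object (a validated list).
#' @export
#' @examples
#' cut_point_config()
#' cut_point_config(nonwear_min_minutes = 60)
cut_point_config <- function(mvpa_threshold_cpm = 1952,
                             sedentary_threshold_cpm = 100,
                             window_start = "06:00",
                             window_end = "24:00",
                             nonwear_min_minutes = 20,
                             valid_day_min_wear_minutes = 600) {
  cfg <- list(
    mvpa_threshold_cpm = mvpa_threshold_cpm,
    sedentary_threshold_cpm = sedentary_threshold_cpm,
    window_start_s = parse_tod(window_start),
    window_end_s = parse_tod(window_end),
    nonwear_min_minutes = nonwear_min_minutes,
    valid_day_min_wear_minutes = valid_day_min_wear_minutes
  )
  if (cfg$sedentary_threshold_cpm >= cfg$mvpa_threshold_cpm) {
    abort("sedentary_threshold_cpm must be below mvpa_threshold_cpm",
          class = "commutePA_config_error")
  }
  if (cfg$mvpa_threshold_cpm <= 0 || cfg$sedentary_threshold_cpm <= 0) {
    abort("thresholds must be positive", class = "commutePA_config_error")
  }
  if (cfg$window_start_s >= cfg$window_end_s) {
    abort("window_start must precede window_end", class = "commutePA_config_error")
  }
  if (cfg$nonwear_min_minutes <= 0 || cfg$valid_day_min_wear_minutes <= 0) {
    abort("nonwear_min_minutes and valid_day_min_wear_minutes must be positive",
          class = "commutePA_config_error")
  }
  structure(cfg, class = "cut_point_config")
}

#' @export
print.cut_point_config <- function(x, ...) {
  cat("<cut_point_config>\n")
  cat(sprintf("  MVPA > %g cpm; sedentary < %g cpm (strict, epoch-scaled)\n",
              x$mvpa_threshold_cpm, x$sedentary_threshold_cpm))
  cat(sprintf("  non-wear: >= %g min of continuous zeros\n", x$nonwear_min_minutes))
  cat(sprintf("  valid day: >= %g wear min in [%s, %s)\n",
              x$valid_day_min_wear_minutes,
              sprintf("%02d:%02d", x$window_start_s %/% 3600, (x$window_start_s %% 3600) %/% 60),
              sprintf("%02d:%02d", x$window_end_s %/% 3600, (x$window_end_s %% 3600) %/% 60)))
  invisible(x)
}

#' Home/work anchor pair for journey detection
#'
#' Holds the geocoded home and workplace coordinates of one participant plus
#' the geofence radius used to decide that a GPS trace has started or ended a
#' commute journey. The two anchors must be further apart than twice the
#' geofence radius, otherwise start and end fences overlap and journeys are
#' undefined.
#'
#' @param home,work Numeric `c(lat, lon)` in WGS84 decimal degrees.
#' @param geofence_radius_m Geofence radius in metres (default 100).
#' @return An `anchor_pair` object.
#' @export
#' @examples
#' anchor_pair(home = c(51.45, -2.59), work = c(51.46, -2.60))
anchor_pair <- function(home, work, geofence_radius_m = 100) {
  chk <- function(p, nm) {
    if (length(p) != 2 || !is.numeric(p)) {
      abort(sprintf("%s must be numeric c(lat, lon)", nm), class = "commutePA_config_error")
    }
    if (abs(p[1]) > 90 || abs(p[2]) > 180) {
      abort(sprintf("%s coordinates out of WGS84 range", nm), class = "commutePA_config_error")
    }
  }
  chk(home, "home"); chk(work, "work")
  if (geofence_radius_m <= 0) {
    abort("geofence_radius_m must be positive", class = "commutePA_config_error")
  }
  d <- haversine_m(home[1], home[2], work[1], work[2])
  if (d <= 2 * geofence_radius_m) {
    abort(sprintf(
      "home-work distance (%.0f m) must exceed twice the geofence radius (%g m)",
      d, geofence_radius_m), class = "commutePA_config_error")
  }
  structure(list(home = as.numeric(home), work = as.numeric(work),
                 geofence_radius_m = geofence_radius_m,
                 home_work_distance_m = d),
            class = "anchor_pair")
}

#' @export
print.anchor_pair <- function(x, ...) {
  cat(sprintf("<anchor_pair> home (%.5f, %.5f) -- work (%.5f, %.5f), %.0f m apart, fence %g m\n",
              x$home[1], x$home[2], x$work[1], x$work[2],
              x$home_work_distance_m, x$geofence_radius_m))
  invisible(x)
}

#' Synthetic commuter-cohort configuration
#'
#' Defines the study conditions a synthetic cohort is generated under:
#' cohort size and travel-mode mix, measurement days, epoch length, commute
#' durations by mode, walking intensity, the diurnal background activity
#' profile, non-wear behaviour and homeward shop detours. Defaults emulate a
#' UK workplace cohort of adults living within walking distance of work,
#' measured for five weekdays and two weekend days with waist-worn
#' accelerometers at 10-s epochs and commute-time GPS at 10-s fixes:
#' single-trip commutes average 19.7 +/- 8.3 minutes on foot and
#' 10.7 +/- 7.6 minutes by car.
#'
#' @param n_participants Cohort size.
#' @param mode_proportions Named probabilities over
#'   `c("walk", "car", "cycle", "other")`, summing to 1.
#' @param n_weekdays,n_weekend_days Measurement days of each type.
#' @param epoch_s Accelerometer epoch length in seconds; must divide 60.
#' @param walk_commute_minutes,car_commute_minutes `c(mean, sd)` of one-way
#'   commute duration in minutes.
#' @param walk_intensity_cpm `c(mean, sd)` of counts-per-minute during
#'   walking bouts (the commute itself).
#' @param background_intensity Numeric vector of 24 mean-cpm values, one per
#'   clock hour, describing non-commute waking activity on weekdays; see
#'   [default_background_profile()]. Weekends use a flattened version.
#' @param nonwear_runs_per_day Expected number of accelerometer removals per
#'   day (Poisson rate); each removal is a 25-90 min zero run.
#' @param detour_probability Probability that a homeward journey includes a
#'   mid-route stationary stop (e.g. a shop visit).
#' @param gps_jitter_sd_m Isotropic Gaussian GPS position error, metres.
#' @param gps_dropout_probability Probability any individual fix is lost.
#' @param mode_effect_cpm Optional calibration: when non-`NULL`, walkers'
#'   background wear-time counts are shifted by this constant cpm so the true
#'   travel-mode effect on daily mean cpm is known exactly (used for
#'   parameter-recovery studies). Default `NULL`: the mode effect emerges
#'   from the commute itself.
#' @param diary_missing_probability Probability a weekday diary entry is
#'   missing; a small fraction of participants return no diary at all and
#'   exercise the questionnaire fallback.
#' @return A `cohort_config` object.
#' @export
#' @examples
#' cohort_config(n_participants = 10)
cohort_config <- function(n_participants,
                          mode_proportions = c(walk = 0.55, car = 0.25,
                                               cycle = 0.13, other = 0.07),
                          n_weekdays = 5,
                          n_weekend_days = 2,
                          epoch_s = 10,
                          walk_commute_minutes = c(mean = 19.7, sd = 8.3),
                          car_commute_minutes = c(mean = 10.7, sd = 7.6),
                          walk_intensity_cpm = c(mean = 4000, sd = 600),
                          background_intensity = default_background_profile(),
                          nonwear_runs_per_day = 1.5,
                          detour_probability = 0.4,
                          gps_jitter_sd_m = 5,
                          gps_dropout_probability = 0.02,
                          mode_effect_cpm = NULL,
                          diary_missing_probability = 0.03) {
  if (length(n_participants) != 1 || n_participants < 1 ||
      n_participants != round(n_participants)) {
    abort("n_participants must be a positive integer", class = "commutePA_config_error")
  }
  if (is.null(names(mode_proportions)) ||
      !all(names(mode_proportions) %in% c("walk", "car", "cycle", "other"))) {
    abort("mode_proportions must be named with walk/car/cycle/other",
          class = "commutePA_config_error")
  }
  if (any(mode_proportions < 0) || abs(sum(mode_proportions) - 1) > 1e-9) {
    abort("mode_proportions must be non-negative and sum to 1",
          class = "commutePA_config_error")
  }
  if (60 %% epoch_s != 0) {
    abort("epoch_s must divide 60", class = "commutePA_config_error")
  }
  for (nm in c("walk_commute_minutes", "car_commute_minutes", "walk_intensity_cpm")) {
    v <- get(nm)
    if (length(v) != 2 || v[2] < 0 || v[1] <= 0) {
      abort(sprintf("%s must be c(mean, sd) with mean > 0, sd >= 0", nm),
            class = "commutePA_config_error")
    }
  }
  if (length(background_intensity) != 24 || any(background_intensity < 0)) {
    abort("background_intensity must be 24 non-negative hourly mean cpm values",
          class = "commutePA_config_error")
  }
  if (nonwear_runs_per_day < 0) {
    abort("nonwear_runs_per_day must be non-negative", class = "commutePA_config_error")
  }
  if (detour_probability < 0 || detour_probability > 1 ||
      gps_dropout_probability < 0 || gps_dropout_probability >= 1) {
    abort("probabilities must lie in [0, 1]", class = "commutePA_config_error")
  }
  structure(list(
    n_participants = as.integer(n_participants),
    mode_proportions = mode_proportions[c("walk", "car", "cycle", "other")[
      c("walk", "car", "cycle", "other") %in% names(mode_proportions)]],
    n_weekdays = as.integer(n_weekdays),
    n_weekend_days = as.integer(n_weekend_days),
    epoch_s = as.integer(epoch_s),
    walk_commute_minutes = unname(walk_commute_minutes),
    car_commute_minutes = unname(car_commute_minutes),
    walk_intensity_cpm = unname(walk_intensity_cpm),
    background_intensity = background_intensity,
    nonwear_runs_per_day = nonwear_runs_per_day,
    detour_probability = detour_probability,
    gps_jitter_sd_m = gps_jitter_sd_m,
    gps_dropout_probability = gps_dropout_probability,
    mode_effect_cpm = mode_effect_cpm,
    diary_missing_probability = diary_missing_probability
  ), class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  %d participants; modes: %s\n", x$n_participants,
              paste(sprintf("%s %.0f%%", names(x$mode_proportions),
                            100 * x$mode_proportions), collapse = ", ")))
  cat(sprintf("  %d weekdays + %d weekend days at %d-s epochs\n",
              x$n_weekdays, x$n_weekend_days, x$epoch_s))
  cat(sprintf("  commutes: walk %.1f±%.1f min, car %.1f±%.1f min; walking %g±%g cpm\n",
              x$walk_commute_minutes[1], x$walk_commute_minutes[2],
              x$car_commute_minutes[1], x$car_commute_minutes[2],
              x$walk_intensity_cpm[1], x$walk_intensity_cpm[2]))
  invisible(x)
}

#' Default weekday diurnal background-activity profile
#'
#' Hourly mean counts-per-minute of non-commute waking activity for a
#' predominantly desk-based working adult: low early morning, a plateau
#' through office hours, a modest early-evening rise (errands, chores) and a
#' decline towards bedtime. Hours outside the wake window are zero; the
#' generator only uses hours the participant is awake and wearing the device.
#'
#' @return Numeric vector of 24 mean-cpm values (hour 0 through 23).
#' @export
default_background_profile <- function() {
  c(rep(0, 6),            # 00-05: asleep
    150, 250, 300,        # 06-08: waking, breakfast
    330, 330, 330, 330, 330, 330, 330,  # 09-15: office hours
    380, 400, 420, 380,   # 16-19: early evening
    300, 250, 200, 150)   # 20-23: winding down
}
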