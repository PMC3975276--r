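# Synthetic commuter-cohort generator.
#
# Counts are generated directly at epoch level: the downstream analysis
# consumes reintegrated epochs, so simulating a raw 30 Hz signal would add
# nothing testable. Each waking minute is assigned an intensity state
# (sedentary / light / MVPA background, commute walking/riding/cycling,
# stationary detour, non-wear); a counts-per-minute level is drawn for the
# minute and epoch counts are Poisson around the per-epoch rate. States whose
# scientific role requires a definite intensity class are truncated away from
# the cut-points (continuous commuting-pace walking is moderate activity by
# definition), so the generator's injected MVPA minutes are recoverable to
# within a fraction of a minute per day.

# Per-minute cpm levels by state. MVPA-bearing states are truncated well
# above the 1952 cpm cut-point, sub-sedentary states well below 100 cpm.
.state_levels <- list(
  sedentary   = list(mean = 40,  sd = 15,  lo = 0,    hi = 90),
  light       = list(mean = 700, sd = 150, lo = 150,  hi = 1500),
  bg_mvpa     = list(mean = 2800, sd = 300, lo = 2400, hi = Inf),
  commute_ride = list(mean = 80, sd = 30,  lo = 0,    hi = 250),
  commute_cycle = list(mean = 450, sd = 100, lo = 100, hi = 1000),
  detour_stop = list(mean = 35,  sd = 15,  lo = 0,    hi = 90)
)

# States whose minutes count as generator-injected MVPA.
.mvpa_states <- c("commute_walk", "bg_mvpa")

.mode_speeds_m_min <- c(walk = 80, car = 250, cycle = 230, other = 220)

# tibble() evaluates quosures per call, which dominates tight generation
# loops; new_tibble skips that for trusted internal columns.
fast_tibble <- function(...) {
  x <- list(...)
  tibble::new_tibble(x, nrow = length(x[[1]]))
}

rnorm_trunc <- function(n, mean, sd, lo, hi) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

#' Day plan for the synthetic stream generator
#'
#' Assembles the schedule of one participant-day: the wake (wear) window,
#' zero or more commute windows with their travel mode and optional
#' stationary detour, and zero or more device-removal (non-wear) windows.
#' All times are seconds since local midnight, aligned to whole minutes.
#'
#' @param date A `Date`.
#' @param wake_start_s,wake_end_s Wake window bounds, seconds of day.
#' @param commutes Tibble with columns `start_s`, `walking_min`, `mode`
#'   (walk/car/cycle/other), `direction` (`to_work`/`from_work`),
#'   `detour_min` (0 for none) and `detour_frac` (position of the detour
#'   along the route, fraction of walking time).
#' @param nonwear Tibble with columns `start_s`, `duration_min`.
#' @param background Numeric 24-vector of hourly mean background cpm.
#' @param walk_intensity_cpm `c(mean, sd)` of minute-level cpm while walking.
#' @param activity_scale Multiplier on the background profile (between-person
#'   variation; default 1).
#' @param effect_cpm Constant added to every worn minute's cpm (calibration
#'   mode; default 0).
#' @param epoch_s Epoch length in seconds, a divisor of 60.
#' @return A `day_plan` list consumed by [generate_day_stream()].
#' @export
day_plan <- function(date, wake_start_s, wake_end_s,
                     commutes = NULL, nonwear = NULL,
                     background = default_background_profile(),
                     walk_intensity_cpm = c(4000, 600),
                     activity_scale = 1, effect_cpm = 0, epoch_s = 10) {
  empty_commutes <- tibble(start_s = numeric(), walking_min = numeric(),
                           mode = character(), direction = character(),
                           detour_min = numeric(), detour_frac = numeric())
  empty_nonwear <- tibble(start_s = numeric(), duration_min = numeric())
  structure(list(
    date = as.Date(date),
    wake_start_s = 60 * round(wake_start_s / 60),
    wake_end_s = 60 * round(wake_end_s / 60),
    commutes = if (is.null(commutes)) empty_commutes else as_tibble(commutes),
    nonwear = if (is.null(nonwear)) empty_nonwear else as_tibble(nonwear),
    background = background,
    walk_intensity_cpm = unname(walk_intensity_cpm),
    activity_scale = activity_scale,
    effect_cpm = effect_cpm,
    epoch_s = as.integer(epoch_s)
  ), class = "day_plan")
}

plan_windows <- function(plan) {
  w <- rbind(
    if (nrow(plan$commutes)) cbind(plan$commutes$start_s,
                                   plan$commutes$start_s +
                                     60 * (plan$commutes$walking_min + plan$commutes$detour_min)),
    if (nrow(plan$nonwear)) cbind(plan$nonwear$start_s,
                                  plan$nonwear$start_s + 60 * plan$nonwear$duration_min)
  )
  w
}

#' Generate one day's accelerometer epoch stream from a plan
#'
#' Emits epoch records covering the plan's wake window at `epoch_s` spacing.
#' Non-wear windows contain exactly zero counts; walking commute minutes draw
#' their counts-per-minute level from the plan's walking intensity (scaled to
#' the epoch); all other waking minutes follow the diurnal background
#' profile. Counts are non-negative integers. The returned tibble carries a
#' `state` column recording the generator's intent for every epoch — the
#' ground truth that recovery tests compare against — which callers writing
#' raw files drop.
#'
#' @param plan A [day_plan()].
#' @param seed Optional integer; when given the stream is generated under
#'   `set.seed(seed)`, otherwise the current RNG stream is used.
#' @return Tibble with columns `timestamp`, `counts`, `state`.
#' @export
generate_day_stream <- function(plan, seed = NULL) {
  stopifnot(inherits(plan, "day_plan"))
  if (!is.null(seed)) set.seed(seed)
  w <- plan_windows(plan)
  if (!is.null(w) && nrow(w) > 1) {
    o <- order(w[, 1])
    w <- w[o, , drop = FALSE]
    if (any(w[-1, 1] < w[-nrow(w), 2])) {
      abort("injected windows overlap", class = "commutePA_generation_error")
    }
  }
  epm <- 60L %/% plan$epoch_s
  minutes <- seq(plan$wake_start_s, plan$wake_end_s - 60, by = 60)
  n_min <- length(minutes)
  hour <- minutes %/% 3600

  state <- rep(NA_character_, n_min)
  # background states drawn from the hourly profile: an active fraction of
  # minutes split ~18% MVPA-intensity, 82% light, remainder sedentary
  target <- plan$activity_scale * plan$background[hour + 1]
  f <- pmin(pmax((target - 40) / 1038, 0.02), 0.95)
  u <- stats::runif(n_min)
  state[u < 0.18 * f] <- "bg_mvpa"
  state[u >= 0.18 * f & u < f] <- "light"
  state[u >= f] <- "sedentary"

  # overlay commute windows
  if (nrow(plan$commutes)) {
    for (k in seq_len(nrow(plan$commutes))) {
      cm <- plan$commutes[k, ]
      cm_state <- switch(cm$mode,
                         walk = "commute_walk",
                         car = "commute_ride",
                         cycle = "commute_cycle",
                         other = "commute_ride",
                         abort(sprintf("unknown commute mode '%s'", cm$mode),
                               class = "commutePA_generation_error"))
      idx <- minutes >= cm$start_s & minutes < cm$start_s + 60 * (cm$walking_min + cm$detour_min)
      state[idx] <- cm_state
      if (cm$detour_min > 0) {
        d0 <- cm$start_s + 60 * round(cm$detour_frac * cm$walking_min)
        state[minutes >= d0 & minutes < d0 + 60 * cm$detour_min] <- "detour_stop"
      }
    }
  }
  if (nrow(plan$nonwear)) {
    for (k in seq_len(nrow(plan$nonwear))) {
      nw <- plan$nonwear[k, ]
      state[minutes >= nw$start_s & minutes < nw$start_s + 60 * nw$duration_min] <- "nonwear"
    }
  }

  # minute-level cpm by state, then Poisson epoch counts around cpm/epm
  cpm <- numeric(n_min)
  for (st in names(.state_levels)) {
    idx <- state == st
    if (any(idx)) {
      lv <- .state_levels[[st]]
      cpm[idx] <- rnorm_trunc(sum(idx), lv$mean, lv$sd, lv$lo, lv$hi)
    }
  }
  idx <- state == "commute_walk"
  if (any(idx)) {
    cpm[idx] <- rnorm_trunc(sum(idx), plan$walk_intensity_cpm[1],
                            plan$walk_intensity_cpm[2], 2600, Inf)
  }
  worn <- state != "nonwear"
  cpm[worn] <- pmax(cpm[worn] + plan$effect_cpm, 0)
  cpm[!worn] <- 0

  lambda <- rep(cpm / epm, each = epm)
  counts <- stats::rpois(n_min * epm, lambda)
  counts[rep(!worn, each = epm)] <- 0L

  ts0 <- as.POSIXct(paste(plan$date, "00:00:00"), tz = "UTC")
  fast_tibble(
    timestamp = ts0 + rep(minutes, each = epm) + plan$epoch_s * (seq_len(epm) - 1),
    counts = as.integer(counts),
    state = rep(state, each = epm)
  )
}

#' Generate a GPS trace along a waypoint route
#'
#' Simulates a receiver logging fixes at a constant interval while moving
#' along a polyline at constant speed, with optional isotropic Gaussian
#' position jitter, random fix dropout, and a stationary mid-route detour
#' (the carrier stops at a point on the route for some minutes, e.g. a shop
#' visit). Fixes are spaced `epoch_s` seconds apart; positions past the route
#' end are clamped to the end point, so the trace always starts at the route
#' start and ends at the route end.
#'
#' @param route Two-column matrix or data frame of `lat, lon` waypoints
#'   (at least two).
#' @param start_time POSIXct of the first fix.
#' @param speed_m_s Travel speed in metres per second (> 0).
#' @param epoch_s Fix interval in seconds (default 10).
#' @param jitter_sd_m Per-axis Gaussian position error, metres (default 0).
#' @param dropout_probability Probability each fix is lost (default 0).
#' @param detour_frac Position of a stationary detour along the route as a
#'   fraction of its length, or `NULL` for none.
#' @param detour_minutes Detour stop duration in minutes.
#' @param seed Optional integer seed.
#' @return Tibble with columns `timestamp`, `lat`, `lon`.
#' @export
#' @examples
#' route <- rbind(c(51.45, -2.59), c(51.459, -2.59))  # ~1 km due north
#' tr <- generate_gps_trace(route, as.POSIXct("2012-05-07 08:20:00", tz = "UTC"),
#'                          speed_m_s = 5000 / 3600)
#' nrow(tr)  # 73 fixes over 12 minutes
generate_gps_trace <- function(route, start_time, speed_m_s, epoch_s = 10,
                               jitter_sd_m = 0, dropout_probability = 0,
                               detour_frac = NULL, detour_minutes = 0,
                               seed = NULL) {
  route <- as.matrix(route)
  if (nrow(route) < 2) abort("route needs at least 2 waypoints",
                             class = "commutePA_generation_error")
  if (speed_m_s <= 0) abort("speed must be positive",
                            class = "commutePA_generation_error")
  if (!is.null(seed)) set.seed(seed)

  seg <- haversine_m(route[-nrow(route), 1], route[-nrow(route), 2],
                     route[-1, 1], route[-1, 2])
  cum <- c(0, cumsum(seg))
  total_len <- cum[length(cum)]
  travel_s <- total_len / speed_m_s
  stop_s <- if (is.null(detour_frac)) 0 else 60 * detour_minutes
  total_s <- travel_s + stop_s
  times <- seq(0, ceiling(total_s / epoch_s) * epoch_s, by = epoch_s)

  # effective distance travelled at each fix time, frozen during the detour
  if (stop_s > 0) {
    stop_at_s <- detour_frac * total_len / speed_m_s
    moving <- pmin(times, stop_at_s) + pmax(times - stop_at_s - stop_s, 0)
  } else {
    moving <- times
  }
  dist <- pmin(moving * speed_m_s, total_len)

  i <- findInterval(dist, cum, rightmost.closed = TRUE)
  i <- pmin(i, nrow(route) - 1)
  frac <- ifelse(seg[i] > 0, (dist - cum[i]) / seg[i], 0)
  lat <- route[i, 1] + frac * (route[i + 1, 1] - route[i, 1])
  lon <- route[i, 2] + frac * (route[i + 1, 2] - route[i, 2])

  if (jitter_sd_m > 0) {
    lat <- lat + stats::rnorm(length(lat), 0, jitter_sd_m) / 111320
    lon <- lon + stats::rnorm(length(lon), 0, jitter_sd_m) /
      (111320 * cos(lat * pi / 180))
  }
  out <- tibble(timestamp = start_time + times, lat = lat, lon = lon)
  if (dropout_probability > 0) {
    out <- out[stats::runif(nrow(out)) >= dropout_probability, ]
  }
  out
}

# Study calendar: participants share measurement dates starting on a Monday.
study_dates <- function(n_weekdays, n_weekend_days, base = as.Date("2012-05-07")) {
  cal <- base + 0:27
  wk <- cal[!is_weekend(cal)][seq_len(n_weekdays)]
  we <- cal[is_weekend(cal)][seq_len(max(n_weekend_days, 0))]
  sort(c(wk, we))
}

alt_mode <- function(mode) {
  switch(mode, walk = "car", car = "walk", cycle = "car", other = "car")
}

# Build a winding waypoint polyline of roughly target_len metres from `home`
# in a random direction; returns list(route matrix, work point, length).
build_route <- function(home, target_len) {
  theta <- stats::runif(1, 0, 2 * pi)
  straight <- 0.94 * target_len
  m_per_deg_lat <- 111320
  m_per_deg_lon <- 111320 * cos(home[1] * pi / 180)
  along <- c(0, 0.33, 0.66, 1) * straight
  perp <- c(0, stats::runif(1, 0.03, 0.09), stats::runif(1, -0.09, -0.03), 0) * straight
  x <- along * cos(theta) - perp * sin(theta)
  y <- along * sin(theta) + perp * cos(theta)
  route <- cbind(lat = home[1] + y / m_per_deg_lat,
                 lon = home[2] + x / m_per_deg_lon)
  seg <- haversine_m(route[-4, 1], route[-4, 2], route[-1, 1], route[-1, 2])
  list(route = route, work = route[4, ], length_m = sum(seg))
}

sample_demographics <- function(pid) {
  tibble(
    participant_id = pid,
    age = round(pmin(pmax(stats::rnorm(1, 36.3, 11.7), 18), 65), 1),
    sex = sample(c("female", "male"), 1, prob = c(0.573, 0.427)),
    income_band = sample(c("<10k", "10-20k", "20-30k", "30-40k", "40-50k",
                           ">50k", "not_disclosed"), 1,
                         prob = c(0.030, 0.121, 0.192, 0.131, 0.131, 0.303, 0.092)),
    education_band = sample(c("no_formal", "gcse", "btec", "alevel", "hnc",
                              "degree", "postgraduate"), 1,
                            prob = c(0.020, 0.089, 0.050, 0.129, 0.020, 0.446, 0.246)),
    occupation_class = sample(c("sedentary", "standing", "manual", "heavy_manual"),
                              1, prob = c(0.802, 0.158, 0.030, 0.010)),
    employment_pattern = sample(c("full_time", "part_time"), 1,
                                prob = c(0.875, 0.125))
  )
}

generate_participant <- function(config, seed, i, dates, gps) {
  set.seed(child_seed(seed, i))
  pid <- sprintf("P%03d", i)
  mode <- sample(names(config$mode_proportions), 1,
                 prob = config$mode_proportions)
  demo <- sample_demographics(pid)
  demo$questionnaire_mode <- if (stats::runif(1) < 0.9) mode else "missing"
  no_diary <- stats::runif(1) < 0.05
  activity_scale <- pmin(pmax(exp(stats::rnorm(1, 0, 0.15)), 0.6), 1.6)

  calibration <- !is.null(config$mode_effect_cpm)
  effect <- if (calibration && mode == "walk") config$mode_effect_cpm else 0
  # In calibration mode walkers are made behaviourally identical to car
  # users (car commute durations and intensities, no detours); the whole
  # group difference is then the known constant cpm shift.
  behav_mode <- if (calibration && mode == "walk") "car" else mode

  cm <- switch(behav_mode,
               walk = pmin(pmax(stats::rnorm(1, config$walk_commute_minutes[1],
                                             config$walk_commute_minutes[2]), 8), 40),
               car = pmin(pmax(stats::rnorm(1, config$car_commute_minutes[1],
                                            config$car_commute_minutes[2]), 4), 25),
               cycle = pmin(pmax(stats::rnorm(1, 9, 3), 5), 20),
               other = pmin(pmax(stats::rnorm(1, config$car_commute_minutes[1],
                                              config$car_commute_minutes[2]), 4), 25))
  speed <- .mode_speeds_m_min[[behav_mode]]
  home <- c(51.45 + stats::runif(1, -0.02, 0.02), -2.59 + stats::runif(1, -0.03, 0.03))
  rt <- build_route(home, speed * cm)
  anchors <- anchor_pair(home, rt$work, 100)

  wake_start <- 60 * round(pmin(pmax(stats::rnorm(1, 7.2 * 60, 25), 6.2 * 60), 7.9 * 60))
  wake_end <- 60 * round(pmin(pmax(stats::rnorm(1, 22.4 * 60, 25), 21.5 * 60), 23.8 * 60))
  accel <- list(); gpsr <- list(); diary <- list()
  tdays <- list(); tjour <- list(); tnw <- list()
  weekend_bg <- flatten_profile(config$background_intensity)

  for (d in seq_along(dates)) {
    date <- dates[d]
    weekend <- is_weekend(date)
    commutes <- NULL
    day_mode <- NA_character_
    if (!weekend) {
      day_mode <- if (stats::runif(1) < 0.95) mode else alt_mode(mode)
      gen_day_mode <- if (calibration && day_mode == "walk") "car" else day_mode
      day_speed <- speed * stats::runif(1, 0.94, 1.06) *
        (.mode_speeds_m_min[[gen_day_mode]] / .mode_speeds_m_min[[behav_mode]])
      dur <- max(4, round(rt$length_m / day_speed))
      dep_to <- 60 * round(pmin(pmax(stats::rnorm(1, 8 * 60 + 20, 10),
                                     wake_start / 60 + 30), 9.4 * 60 - dur))
      detour <- gen_day_mode == "walk" && stats::runif(1) < config$detour_probability
      det_min <- if (detour) round(stats::runif(1, 4, 10)) else 0
      det_frac <- if (detour) stats::runif(1, 0.35, 0.65) else 0.5
      dep_home <- 60 * round(pmin(pmax(stats::rnorm(1, 17 * 60 + 10, 15), 16.1 * 60),
                                  19.8 * 60 - dur - det_min))
      commutes <- fast_tibble(
        start_s = c(dep_to, dep_home),
        walking_min = c(dur, dur),
        mode = rep(gen_day_mode, 2),
        direction = c("to_work", "from_work"),
        detour_min = c(0, det_min),
        detour_frac = c(0.5, det_frac)
      )
    }

    nw_start <- numeric(0); nw_dur <- numeric(0)
    k <- stats::rpois(1, config$nonwear_runs_per_day)
    if (k > 0) {
      taken <- if (is.null(commutes)) matrix(numeric(), ncol = 2) else
        cbind(commutes$start_s,
              commutes$start_s + 60 * (commutes$walking_min + commutes$detour_min))
      for (j in seq_len(k)) {
        dur_nw <- round(stats::runif(1, 25, 90))
        for (try in 1:20) {
          s0 <- 60 * round(stats::runif(1, wake_start / 60,
                                        wake_end / 60 - dur_nw))
          e0 <- s0 + 60 * dur_nw
          if (nrow(taken) == 0 || all(e0 <= taken[, 1] | s0 >= taken[, 2])) {
            nw_start <- c(nw_start, s0); nw_dur <- c(nw_dur, dur_nw)
            taken <- rbind(taken, c(s0, e0))
            break
          }
        }
      }
    }

    nonwear <- fast_tibble(start_s = nw_start, duration_min = nw_dur)
    plan <- day_plan(date, wake_start, wake_end, commutes, nonwear,
                     background = if (weekend) weekend_bg else config$background_intensity,
                     walk_intensity_cpm = config$walk_intensity_cpm,
                     activity_scale = activity_scale,
                     effect_cpm = effect, epoch_s = config$epoch_s)
    stream <- generate_day_stream(plan)

    accel[[d]] <- fast_tibble(participant_id = rep(pid, nrow(stream)),
                              timestamp = stream$timestamp,
                              counts = stream$counts)
    ts0 <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC")

    if (gps && !weekend) {
      for (j in seq_len(nrow(commutes))) {
        cj <- commutes[j, ]
        r <- if (cj$direction == "to_work") rt$route else rt$route[4:1, ]
        v <- rt$length_m / (cj$walking_min * 60)
        tr <- generate_gps_trace(
          r, ts0 + cj$start_s, v, epoch_s = 10,
          jitter_sd_m = config$gps_jitter_sd_m,
          dropout_probability = config$gps_dropout_probability,
          detour_frac = if (cj$detour_min > 0) cj$detour_frac else NULL,
          detour_minutes = cj$detour_min)
        tr$participant_id <- pid
        gpsr[[length(gpsr) + 1]] <- tr[, c("participant_id", "timestamp", "lat", "lon")]
      }
    }

    if (!weekend) {
      to_m <- from_m <- day_mode
      if (no_diary) {
        to_m <- from_m <- "missing"
      } else {
        if (stats::runif(1) < config$diary_missing_probability) to_m <- "missing"
        if (stats::runif(1) < config$diary_missing_probability) from_m <- "missing"
      }
      diary[[length(diary) + 1]] <- tibble(
        participant_id = pid, date = date,
        mode_to_work = to_m, mode_from_work = from_m)
      for (j in seq_len(nrow(commutes))) {
        cj <- commutes[j, ]
        tjour[[length(tjour) + 1]] <- tibble(
          participant_id = pid, date = date, direction = cj$direction,
          start = ts0 + cj$start_s,
          end = ts0 + cj$start_s + 60 * (cj$walking_min + cj$detour_min),
          duration_min = cj$walking_min + cj$detour_min,
          mode = day_mode,
          includes_detour = cj$detour_min > 0,
          mvpa_minutes = if (cj$mode == "walk") cj$walking_min else 0)
      }
    }
    if (nrow(nonwear)) {
      tnw[[length(tnw) + 1]] <- tibble(
        participant_id = pid, date = date,
        start = ts0 + nonwear$start_s,
        end = ts0 + nonwear$start_s + 60 * nonwear$duration_min)
    }
    tdays[[d]] <- tibble(
      participant_id = pid, date = as.Date(date),
      day_type = if (weekend) "weekend" else "weekday",
      day_mode = day_mode,
      wear_start = ts0 + wake_start, wear_end = ts0 + wake_end,
      nonwear_minutes = sum(nonwear$duration_min),
      mvpa_minutes = sum(stream$state %in% .mvpa_states) * config$epoch_s / 60)
  }

  list(
    accel = dplyr::bind_rows(accel),
    gps = dplyr::bind_rows(gpsr),
    diary = dplyr::bind_rows(diary),
    demographics = demo,
    truth_participant = tibble(
      participant_id = pid, mode = mode, no_diary = no_diary,
      commute_minutes = cm, activity_scale = activity_scale,
      home_lat = home[1], home_lon = home[2],
      work_lat = rt$work[1], work_lon = rt$work[2],
      route_length_m = rt$length_m),
    truth_days = dplyr::bind_rows(tdays),
    truth_journeys = dplyr::bind_rows(tjour),
    truth_nonwear = dplyr::bind_rows(tnw),
    anchors = anchors
  )
}

# Weekend background: same daily volume shape flattened over 08:00-21:00.
flatten_profile <- function(profile) {
  p <- rep(0, 24)
  p[9:22] <- mean(profile[7:24][profile[7:24] > 0])
  p[7:8] <- 0.6 * p[9]
  p[23:24] <- 0.6 * p[9]
  p
}

#' Generate a synthetic commuter cohort
#'
#' Generates the full raw-data bundle for a cohort defined by a
#' [cohort_config()]: per-participant accelerometer epoch streams, commute
#' GPS traces, weekday travel diaries, a demographics table with the
#' questionnaire usual-mode fallback, per-participant home/work anchors, and
#' a machine-readable ground truth recording every injected event (true
#' modes, journey windows, non-wear windows, injected MVPA minutes). One
#' global seed fans out to per-participant child seeds, so a cohort is
#' reproducible participant by participant and bit-identical under a fixed
#' seed.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @param dir Optional directory; when given, the bundle is written there as
#'   CSV files plus a JSON ground-truth sidecar (see [write_cohort()]).
#' @param gps Generate GPS traces? Disable for accelerometer-only studies
#'   (faster).
#' @return A `synthetic_cohort` list with elements `accel`, `gps`, `diary`,
#'   `demographics`, `anchors` (tibble of per-participant anchor
#'   coordinates), `truth` (list of `participants`, `days`, `journeys`,
#'   `nonwear` tibbles), `config` and `seed`.
#' @export
generate_cohort <- function(config, seed, dir = NULL, gps = TRUE) {
  if (!inherits(config, "cohort_config")) {
    abort("config must be a cohort_config object", class = "commutePA_config_error")
  }
  dates <- study_dates(config$n_weekdays, config$n_weekend_days)
  parts <- purrr::map(seq_len(config$n_participants),
                      function(i) generate_participant(config, seed, i, dates, gps))
  anchors_tbl <- purrr::map_dfr(parts, function(p) {
    tibble(participant_id = p$truth_participant$participant_id,
           home_lat = p$anchors$home[1], home_lon = p$anchors$home[2],
           work_lat = p$anchors$work[1], work_lon = p$anchors$work[2],
           geofence_radius_m = p$anchors$geofence_radius_m)
  })
  gps_tbl <- purrr::map_dfr(parts, "gps")
  if (ncol(gps_tbl) == 0) {
    gps_tbl <- tibble(participant_id = character(),
                      timestamp = as.POSIXct(character(), tz = "UTC"),
                      lat = numeric(), lon = numeric())
  }
  cohort <- structure(list(
    accel = purrr::map_dfr(parts, "accel"),
    gps = gps_tbl,
    diary = purrr::map_dfr(parts, "diary"),
    demographics = purrr::map_dfr(parts, "demographics"),
    anchors = anchors_tbl,
    truth = list(
      participants = purrr::map_dfr(parts, "truth_participant"),
      days = purrr::map_dfr(parts, "truth_days"),
      journeys = purrr::map_dfr(parts, "truth_journeys"),
      nonwear = purrr::map_dfr(parts, "truth_nonwear")
    ),
    config = config,
    seed = seed
  ), class = "synthetic_cohort")
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d participants, %d epoch records, %d GPS fixes, seed %s\n",
              x$config$n_participants, nrow(x$accel), nrow(x$gps),
              format(x$seed)))
  print(dplyr::count(x$truth$participants, .data$mode))
  invisible(x)
}
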