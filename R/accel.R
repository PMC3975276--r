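# Accelerometer data reduction: reintegration, non-wear detection,
# cut-point classification, daily and hourly summaries.

# Split row indices of an epoch table into participant-day groups. Rows of
# one participant-day must be stored contiguously (the on-disk dialects
# guarantee this); interleaved groups are an error, not silently merged.
epoch_groups <- function(epochs) {
  pid <- if ("participant_id" %in% names(epochs)) epochs$participant_id else "all"
  day <- floor(as.numeric(epochs$timestamp) / 86400)
  n <- length(day)
  if (n == 0) return(list())
  new_run <- c(TRUE, pid[-1] != pid[-n] | day[-1] != day[-n])
  starts <- which(new_run)
  ends <- c(starts[-1] - 1L, n)
  key <- paste(pid[starts], day[starts])
  if (anyDuplicated(key)) {
    abort("epochs of one participant-day are not stored contiguously",
          class = "commutePA_input_error")
  }
  stats::setNames(purrr::map2(starts, ends, seq.int), key)
}

check_contiguous <- function(ts, epoch_s) {
  d <- diff(as.numeric(ts))
  if (any(d <= 0)) abort("epochs are not sorted by timestamp",
                         class = "commutePA_input_error")
  if (any(d != epoch_s)) abort(
    sprintf("epochs are not contiguous at %gs spacing", epoch_s),
    class = "commutePA_input_error")
  invisible(TRUE)
}

#' Reintegrate accelerometer epochs to a coarser epoch length
#'
#' Sums consecutive fine epochs into coarser ones, e.g. 1-s or 10-s device
#' epochs into the 10-s or 60-s epochs used for analysis. The target length
#' must be an integer multiple of the source length; each output epoch's
#' counts are the exact sum of its constituent input epochs (total counts
#' are conserved) and output timestamps are aligned to target-epoch
#' boundaries from the first input timestamp. A trailing partial window is
#' dropped with a message. Applied per participant-day when those columns
#' are present.
#'
#' @param epochs Tibble with `timestamp` (epoch start) and `counts`, sorted
#'   and contiguous within each participant-day; optional `participant_id`.
#' @param target_epoch_s Target epoch length, seconds.
#' @param epoch_s Source epoch length; inferred from timestamps if `NULL`.
#' @return Tibble of the same shape at the target epoch length.
#' @export
#' @examples
#' x <- tibble::tibble(
#'   timestamp = as.POSIXct("2012-05-07 08:00:00", tz = "UTC") + seq(0, 50, 10),
#'   counts = c(10L, 20L, 30L, 0L, 0L, 40L))
#' reintegrate(x, 60)  # one 60-s epoch of 100 counts
reintegrate <- function(epochs, target_epoch_s, epoch_s = NULL) {
  epoch_s <- epoch_s_of(epochs, epoch_s)
  if (target_epoch_s %% epoch_s != 0) {
    abort(sprintf("target epoch (%gs) is not a multiple of the source epoch (%gs)",
                  target_epoch_s, epoch_s), class = "commutePA_input_error")
  }
  ratio <- as.integer(target_epoch_s / epoch_s)
  if (ratio == 1L) return(epochs)
  groups <- epoch_groups(epochs)
  dropped <- 0L
  out <- purrr::map(groups, function(ix) {
    g <- epochs[ix, ]
    check_contiguous(g$timestamp, epoch_s)
    n_out <- nrow(g) %/% ratio
    dropped <<- dropped + nrow(g) - n_out * ratio
    if (n_out == 0L) return(NULL)
    idx <- rep(seq_len(n_out), each = ratio)
    res <- tibble(
      timestamp = g$timestamp[1] + (seq_len(n_out) - 1L) * target_epoch_s,
      counts = as.integer(rowsum(g$counts[seq_along(idx)], idx)[, 1])
    )
    if ("participant_id" %in% names(g)) res$participant_id <- g$participant_id[1]
    res
  })
  if (dropped > 0L) {
    inform(sprintf("reintegrate: dropped %d trailing partial input epoch(s)", dropped))
  }
  res <- dplyr::bind_rows(out)
  dplyr::arrange(res, dplyr::across(dplyr::any_of(c("participant_id", "timestamp"))))
}

#' Detect non-wear time from continuous zero-count runs
#'
#' Marks an epoch as non-wear iff it belongs to a maximal run of zero-count
#' epochs whose duration is at least `nonwear_min_minutes` (default 20). A
#' single positive count terminates a run: no interruption tolerance is
#' applied. Runs are evaluated on the full per-day stream before any
#' analysis-window restriction, so a run straddling the window boundary
#' still counts its full length.
#'
#' @param epochs Epoch tibble (sorted, contiguous per participant-day).
#' @param config A [cut_point_config()].
#' @param epoch_s Epoch length; inferred if `NULL`.
#' @return Logical vector, `TRUE` where the epoch is wear time.
#' @export
detect_nonwear <- function(epochs, config = cut_point_config(), epoch_s = NULL) {
  epoch_s <- epoch_s_of(epochs, epoch_s)
  min_epochs <- config$nonwear_min_minutes * 60 / epoch_s
  wear <- rep(TRUE, nrow(epochs))
  for (ix in epoch_groups(epochs)) {
    g <- epochs[ix, ]
    check_contiguous(g$timestamp, epoch_s)
    r <- rle(g$counts == 0)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    nw <- r$values & r$lengths >= min_epochs
    for (k in which(nw)) wear[ix[starts[k]:ends[k]]] <- FALSE
  }
  wear
}

#' Classify epoch intensity with counts-per-minute cut-points
#'
#' Applies the cut-points scaled to the epoch length: counts above
#' `mvpa_threshold_cpm * epoch_s / 60` are MVPA, counts below
#' `sedentary_threshold_cpm * epoch_s / 60` are sedentary, everything else
#' (both boundaries included) is light. At 60-s epochs with the defaults,
#' 1953 counts is MVPA and 1952 is light; 99 counts is sedentary and 100 is
#' light.
#'
#' @param counts Integer vector of epoch counts (wear time).
#' @param epoch_s Epoch length in seconds.
#' @param config A [cut_point_config()].
#' @return Factor with levels `sedentary`, `light`, `mvpa`.
#' @export
classify_intensity <- function(counts, epoch_s, config = cut_point_config()) {
  scale <- epoch_s / 60
  out <- rep("light", length(counts))
  out[counts > config$mvpa_threshold_cpm * scale] <- "mvpa"
  out[counts < config$sedentary_threshold_cpm * scale] <- "sedentary"
  factor(out, levels = c("sedentary", "light", "mvpa"))
}

window_mask <- function(ts, config) {
  s <- sec_of_day(ts)
  s >= config$window_start_s & s < config$window_end_s
}

#' Summarise one participant-day of accelerometer data
#'
#' Computes the daily outcome variables inside the analysis window (default
#' 06:00 to midnight, half-open, epoch membership by start time): wear
#' minutes after non-wear removal, mean counts per minute over wear time,
#' MVPA and sedentary minutes from epoch classification, and the valid-day
#' flag (wear of at least `valid_day_min_wear_minutes`, default 600). A day
#' with zero wear gets `mean_cpm = NA` and `valid = FALSE` rather than an
#' error.
#'
#' @param epochs Epoch tibble for a single participant and calendar date.
#' @param config A [cut_point_config()].
#' @param epoch_s Epoch length; inferred if `NULL`.
#' @return One-row tibble: `participant_id`, `date`, `day_type`,
#'   `wear_minutes`, `mean_cpm`, `mvpa_minutes`, `sedentary_minutes`,
#'   `light_minutes`, `valid`.
#' @export
summarise_day <- function(epochs, config = cut_point_config(), epoch_s = NULL) {
  dates <- unique(local_date(epochs$timestamp))
  if (length(dates) != 1) {
    abort("summarise_day expects epochs from a single calendar date",
          class = "commutePA_input_error")
  }
  pid <- if ("participant_id" %in% names(epochs)) {
    u <- unique(epochs$participant_id)
    if (length(u) != 1) abort("summarise_day expects a single participant",
                              class = "commutePA_input_error")
    u
  } else NA_character_
  epoch_s <- epoch_s_of(epochs, epoch_s)
  wear <- detect_nonwear(epochs, config, epoch_s)
  keep <- wear & window_mask(epochs$timestamp, config)
  w <- epochs[keep, ]
  wear_minutes <- nrow(w) * epoch_s / 60
  cls <- classify_intensity(w$counts, epoch_s, config)
  tibble(
    participant_id = pid,
    date = dates,
    day_type = day_type_of(dates),
    wear_minutes = wear_minutes,
    mean_cpm = if (wear_minutes > 0) sum(w$counts) / wear_minutes else NA_real_,
    mvpa_minutes = sum(cls == "mvpa") * epoch_s / 60,
    sedentary_minutes = sum(cls == "sedentary") * epoch_s / 60,
    light_minutes = sum(cls == "light") * epoch_s / 60,
    valid = wear_minutes >= config$valid_day_min_wear_minutes
  )
}

#' Summarise every participant-day in an epoch table
#'
#' Vectorised equivalent of mapping [summarise_day()] over participant-days
#' (the reduction runs over millions of epochs, so the wear mask, window
#' restriction and classification are computed in one pass). Days whose
#' epochs are entirely non-wear still appear, with zero wear and
#' `valid = FALSE`.
#'
#' @param epochs Epoch tibble with `participant_id`, `timestamp`, `counts`.
#' @inheritParams summarise_day
#' @return Tibble of [summarise_day()] rows, one per participant-day.
#' @export
summarise_days <- function(epochs, config = cut_point_config(), epoch_s = NULL) {
  epoch_s <- epoch_s_of(epochs, epoch_s)
  pid <- if ("participant_id" %in% names(epochs)) epochs$participant_id else
    rep(NA_character_, nrow(epochs))
  day <- floor(as.numeric(epochs$timestamp) / 86400)
  all_days <- dplyr::distinct(tibble(participant_id = pid, day = day))
  wear <- detect_nonwear(epochs, config, epoch_s)
  keep <- wear & window_mask(epochs$timestamp, config)
  scale <- epoch_s / 60
  mvpa <- epochs$counts > config$mvpa_threshold_cpm * scale
  sed <- epochs$counts < config$sedentary_threshold_cpm * scale
  w <- tibble(participant_id = pid[keep], day = day[keep],
              counts = epochs$counts[keep], mvpa = mvpa[keep], sed = sed[keep])
  agg <- dplyr::group_by(w, .data$participant_id, .data$day) %>%
    dplyr::summarise(wear_minutes = dplyr::n() * scale,
                     mean_cpm = sum(.data$counts) / (dplyr::n() * scale),
                     mvpa_minutes = sum(.data$mvpa) * scale,
                     sedentary_minutes = sum(.data$sed) * scale,
                     .groups = "drop")
  out <- dplyr::left_join(all_days, agg, by = c("participant_id", "day"))
  out$wear_minutes[is.na(out$wear_minutes)] <- 0
  out$mvpa_minutes[is.na(out$mvpa_minutes)] <- 0
  out$sedentary_minutes[is.na(out$sedentary_minutes)] <- 0
  out$date <- as.Date(out$day, origin = "1970-01-01")
  out$day_type <- day_type_of(out$date)
  out$light_minutes <- out$wear_minutes - out$mvpa_minutes - out$sedentary_minutes
  out$valid <- out$wear_minutes >= config$valid_day_min_wear_minutes
  dplyr::arrange(
    out[, c("participant_id", "date", "day_type", "wear_minutes", "mean_cpm",
            "mvpa_minutes", "sedentary_minutes", "light_minutes", "valid")],
    .data$participant_id, .data$date)
}

#' Mean hourly physical activity by group
#'
#' For each clock hour inside the analysis window, computes each
#' participant's mean counts per minute over wear time in that hour (pooled
#' across days of the requested type), then averages over participants
#' within each group. Hours in which a participant has no wear time are
#' excluded from that participant's contribution. This is the hourly profile
#' used to locate when groups' activity diverges during the day.
#'
#' @param epochs Epoch tibble with `participant_id`.
#' @param groups Tibble with `participant_id` and `group` columns.
#' @param config A [cut_point_config()].
#' @param day_type `"weekday"`, `"weekend"` or `"all"`.
#' @param epoch_s Epoch length; inferred if `NULL`.
#' @return Tibble `group`, `hour`, `mean_cpm`, `n_participants`.
#' @export
hourly_profile <- function(epochs, groups, config = cut_point_config(),
                           day_type = "weekday", epoch_s = NULL) {
  if (nrow(groups) == 0 || any(table(groups$group) == 0)) {
    abort("each group must contain at least one participant",
          class = "commutePA_input_error")
  }
  epoch_s <- epoch_s_of(epochs, epoch_s)
  per_hour <- participant_hourly_cpm(epochs, config, day_type, epoch_s)
  dplyr::inner_join(per_hour, groups, by = "participant_id") %>%
    dplyr::group_by(.data$group, .data$hour) %>%
    dplyr::summarise(mean_cpm = mean(.data$cpm),
                     n_participants = dplyr::n(), .groups = "drop")
}

# Per-participant mean cpm for each clock hour (wear time only).
participant_hourly_cpm <- function(epochs, config, day_type, epoch_s) {
  wear <- detect_nonwear(epochs, config, epoch_s)
  keep <- wear & window_mask(epochs$timestamp, config)
  if (day_type != "all") {
    keep <- keep & day_type_of(local_date(epochs$timestamp)) == day_type
  }
  w <- epochs[keep, ]
  if (nrow(w) == 0) abort("no wear epochs in the requested window",
                          class = "commutePA_input_error")
  w$hour <- floor(sec_of_day(w$timestamp) / 3600)
  dplyr::group_by(w, .data$participant_id, .data$hour) %>%
    dplyr::summarise(cpm = sum(.data$counts) / (dplyr::n() * epoch_s / 60),
                     wear_minutes = dplyr::n() * epoch_s / 60, .groups = "drop")
}

#' Compare group activity within a time-of-day window
#'
#' Restricts wear-time epochs to a clock window (default the main working
#' hours, 09:00-16:00, on weekdays), computes each participant's mean counts
#' per minute there, and compares groups by one-way ANOVA. Used to check
#' that commute-driven differences are absent during the working day.
#'
#' @param epochs Epoch tibble with `participant_id`.
#' @param groups Tibble with `participant_id` and `group`.
#' @param window_start,window_end `"HH:MM"` bounds of the comparison window.
#' @param config A [cut_point_config()].
#' @param day_type Day type to include (default `"weekday"`).
#' @param epoch_s Epoch length; inferred if `NULL`.
#' @return A [compare_groups()] result (a `group_comparison`), with the
#'   per-participant means in `$data`.
#' @export
working_hours_comparison <- function(epochs, groups,
                                     window_start = "09:00",
                                     window_end = "16:00",
                                     config = cut_point_config(),
                                     day_type = "weekday", epoch_s = NULL) {
  s0 <- parse_tod(window_start); s1 <- parse_tod(window_end)
  if (s0 >= s1) abort("empty time-of-day window", class = "commutePA_input_error")
  epoch_s <- epoch_s_of(epochs, epoch_s)
  wear <- detect_nonwear(epochs, config, epoch_s)
  s <- sec_of_day(epochs$timestamp)
  keep <- wear & window_mask(epochs$timestamp, config) & s >= s0 & s < s1
  if (day_type != "all") {
    keep <- keep & day_type_of(local_date(epochs$timestamp)) == day_type
  }
  w <- epochs[keep, ]
  if (nrow(w) == 0) abort("no wear epochs in the requested window",
                          class = "commutePA_input_error")
  means <- dplyr::group_by(w, .data$participant_id) %>%
    dplyr::summarise(cpm = sum(.data$counts) / (dplyr::n() * epoch_s / 60),
                     .groups = "drop") %>%
    dplyr::inner_join(groups, by = "participant_id")
  res <- compare_groups(means$cpm, means$group)
  res$data <- means
  res
}
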