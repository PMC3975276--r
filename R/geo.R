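# Combined accelerometer + GPS processing: timestamp merging, automatic
# home-work journey segmentation, journey summaries and the commute
# contribution to daily MVPA.

#' Merge accelerometer epochs with GPS fixes by timestamp
#'
#' The accelerometer stream is the spine: every epoch is kept and is paired
#' with the nearest fix within `max_gap_s` seconds of the epoch start,
#' otherwise flagged position-missing. No fix ever creates an epoch; fixes
#' that match no epoch are discarded (their count is reported with a
#' message). Inputs are sorted internally, so the merge is insensitive to
#' input row order.
#'
#' @param epochs Epoch tibble (`timestamp`, `counts`, optional
#'   `participant_id`).
#' @param fixes GPS fix tibble (`timestamp`, `lat`, `lon`).
#' @param max_gap_s Maximum epoch-to-fix time difference, seconds (default 5).
#' @return The epoch tibble with `lat`, `lon` (NA when unmatched) and
#'   `fix_gap_s` columns, sorted by time.
#' @export
merge_acc_gps <- function(epochs, fixes, max_gap_s = 5) {
  epochs <- dplyr::arrange(epochs, .data$timestamp)
  out <- epochs
  out$lat <- NA_real_; out$lon <- NA_real_; out$fix_gap_s <- NA_real_
  if (nrow(fixes) > 0) {
    fixes <- dplyr::arrange(fixes, .data$timestamp)
    et <- as.numeric(epochs$timestamp)
    ft <- as.numeric(fixes$timestamp)
    lo <- pmin(pmax(findInterval(et, ft), 1L), length(ft))
    hi <- pmin(lo + 1L, length(ft))
    pick <- ifelse(abs(et - ft[lo]) <= abs(et - ft[hi]), lo, hi)
    gap <- abs(et - ft[pick])
    ok <- gap <= max_gap_s
    out$lat[ok] <- fixes$lat[pick[ok]]
    out$lon[ok] <- fixes$lon[pick[ok]]
    out$fix_gap_s[ok] <- gap[ok]
    # fixes with no epoch within the gap are discarded
    flo <- pmin(pmax(findInterval(ft, et), 1L), length(et))
    fhi <- pmin(flo + 1L, length(et))
    nearest_epoch <- pmin(abs(ft - et[flo]), abs(ft - et[fhi]))
    n_unmatched <- sum(nearest_epoch > max_gap_s)
    if (n_unmatched > 0) {
      inform(sprintf("merge_acc_gps: discarded %d fix(es) matching no epoch",
                     n_unmatched))
    }
  }
  out
}

default_commute_windows <- function() {
  list(c("06:00", "10:00"), c("16:00", "20:00"))
}

#' Segment home-work journeys from a merged accelerometer + GPS day
#'
#' Identifies commute journeys automatically: a journey is a maximal run of
#' position-bearing epochs that starts inside one anchor's geofence and ends
#' inside the other's, lies entirely within one commute window, and contains
#' no internal position gap longer than `max_internal_gap_min`. Mid-route
#' stationary stops (shop detours) are retained inside the journey.
#' Direction is inferred purely geometrically from which geofence the run
#' starts in. When several anchor-to-anchor candidates exist in one window,
#' the longest wins, ties breaking to the earlier start; a day can yield
#' zero, one or two journeys.
#'
#' @param merged One participant-day (or several days of one participant)
#'   from [merge_acc_gps()].
#' @param anchors An [anchor_pair()].
#' @param commute_windows List of `c(start, end)` `"HH:MM"` pairs (defaults
#'   06:00-10:00 and 16:00-20:00).
#' @param max_internal_gap_min Maximum tolerated internal position gap,
#'   minutes (default 5).
#' @param config A [cut_point_config()] used for journey MVPA.
#' @param epoch_s Epoch length; inferred if `NULL`.
#' @return Tibble of journeys: `participant_id`, `date`, `direction`,
#'   `start`, `end`, `duration_min`, `mean_cpm`, `mvpa_min`,
#'   `includes_detour`, plus a `data` list-column holding each journey's
#'   merged epoch rows.
#' @export
segment_journeys <- function(merged, anchors,
                             commute_windows = default_commute_windows(),
                             max_internal_gap_min = 5,
                             config = cut_point_config(), epoch_s = NULL) {
  if (!inherits(anchors, "anchor_pair")) {
    abort("anchors must be an anchor_pair", class = "commutePA_config_error")
  }
  epoch_s <- epoch_s_of(merged, epoch_s)
  merged <- dplyr::arrange(merged, .data$timestamp)
  res <- list()
  for (date in unique(format(local_date(merged$timestamp)))) {
    day <- merged[format(local_date(merged$timestamp)) == date, ]
    for (w in commute_windows) {
      s <- sec_of_day(day$timestamp)
      win <- day[s >= parse_tod(w[1]) & s < parse_tod(w[2]), ]
      j <- find_window_journey(win, anchors, max_internal_gap_min)
      if (!is.null(j)) {
        res[[length(res) + 1]] <- summarise_journey(
          j$data, anchors, direction = j$direction, config = config,
          epoch_s = epoch_s)
      }
    }
  }
  if (length(res) == 0) {
    return(tibble(participant_id = character(), date = as.Date(character()),
                  direction = character(),
                  start = as.POSIXct(character(), tz = "UTC"),
                  end = as.POSIXct(character(), tz = "UTC"),
                  duration_min = numeric(), mean_cpm = numeric(),
                  mvpa_min = numeric(), includes_detour = logical(),
                  data = list()))
  }
  dplyr::bind_rows(res)
}

# Best anchor-to-anchor candidate inside one commute window, or NULL.
find_window_journey <- function(win, anchors, max_internal_gap_min) {
  pos <- win[!is.na(win$lat), ]
  if (nrow(pos) < 2) return(NULL)
  gaps <- diff(as.numeric(pos$timestamp))
  run_id <- cumsum(c(0, gaps > max_internal_gap_min * 60))
  best <- NULL
  for (rid in unique(run_id)) {
    run <- pos[run_id == rid, ]
    dh <- haversine_m(run$lat, run$lon, anchors$home[1], anchors$home[2])
    dw <- haversine_m(run$lat, run$lon, anchors$work[1], anchors$work[2])
    H <- which(dh <= anchors$geofence_radius_m)
    W <- which(dw <= anchors$geofence_radius_m)
    cand <- list()
    if (length(H) && length(W) && min(H) < max(W)) {
      cand[[length(cand) + 1]] <- list(i = min(H), j = max(W), direction = "to_work")
    }
    if (length(H) && length(W) && min(W) < max(H)) {
      cand[[length(cand) + 1]] <- list(i = min(W), j = max(H), direction = "from_work")
    }
    for (cc in cand) {
      span <- as.numeric(run$timestamp[cc$j]) - as.numeric(run$timestamp[cc$i])
      t0 <- run$timestamp[cc$i]
      if (is.null(best) || span > best$span ||
          (span == best$span && t0 < best$t0)) {
        jd <- win[win$timestamp >= t0 & win$timestamp <= run$timestamp[cc$j], ]
        best <- list(span = span, t0 = t0, direction = cc$direction, data = jd)
      }
    }
  }
  best
}

# Stationary-cluster detour detection on the journey's fixes: displacement
# over a ~30-s lag below walking pace, outside both geofences. The decision
# is by total stationary time rather than one unbroken run, so an isolated
# noisy fix inside a stop does not hide it; while actually moving, lagged
# displacement is far above the threshold, so stationary time only
# accumulates during genuine stops.
detect_detour <- function(jd, anchors, min_minutes = 3,
                          speed_threshold_m_s = 0.6) {
  pos <- jd[!is.na(jd$lat), ]
  if (nrow(pos) < 5) return(FALSE)
  lag <- 3L
  n <- nrow(pos)
  i2 <- pmin(seq_len(n) + lag, n)
  dt <- as.numeric(pos$timestamp[i2]) - as.numeric(pos$timestamp)
  dd <- haversine_m(pos$lat, pos$lon, pos$lat[i2], pos$lon[i2])
  slow <- dt > 0 & dd / pmax(dt, 1) < speed_threshold_m_s
  dh <- haversine_m(pos$lat, pos$lon, anchors$home[1], anchors$home[2])
  dw <- haversine_m(pos$lat, pos$lon, anchors$work[1], anchors$work[2])
  mid <- dh > anchors$geofence_radius_m & dw > anchors$geofence_radius_m
  fix_interval <- stats::median(diff(as.numeric(pos$timestamp)))
  stationary_s <- sum(slow & mid) * fix_interval
  stationary_s >= min_minutes * 60
}

#' Summarise one segmented journey
#'
#' Duration in minutes (time span plus one epoch), mean counts per minute
#' over the journey's epochs, MVPA minutes from epoch classification, and
#' stationary-detour detection. Detour epochs contribute to duration and
#' mean cpm but, being stationary, add essentially no MVPA.
#'
#' @param jd Merged epoch rows of the journey (from [merge_acc_gps()]).
#' @param anchors An [anchor_pair()] (used for detour detection).
#' @param direction `"to_work"` or `"from_work"`.
#' @param config A [cut_point_config()].
#' @param epoch_s Epoch length; inferred if `NULL`.
#' @return One-row journey tibble (see [segment_journeys()]).
#' @export
summarise_journey <- function(jd, anchors, direction,
                              config = cut_point_config(), epoch_s = NULL) {
  if (nrow(jd) == 0) abort("empty journey", class = "commutePA_input_error")
  epoch_s <- epoch_s_of(jd, epoch_s)
  dur <- (as.numeric(jd$timestamp[nrow(jd)]) - as.numeric(jd$timestamp[1]) +
            epoch_s) / 60
  cls <- classify_intensity(jd$counts, epoch_s, config)
  tibble(
    participant_id = if ("participant_id" %in% names(jd)) jd$participant_id[1] else NA_character_,
    date = local_date(jd$timestamp[1]),
    direction = direction,
    start = jd$timestamp[1],
    end = jd$timestamp[nrow(jd)] + epoch_s,
    duration_min = dur,
    mean_cpm = sum(jd$counts) / dur,
    mvpa_min = sum(cls == "mvpa") * epoch_s / 60,
    includes_detour = detect_detour(jd, anchors),
    data = list(jd)
  )
}

#' Segment journeys for a whole cohort
#'
#' Maps [merge_acc_gps()] and [segment_journeys()] over every participant of
#' a cohort given per-participant anchors.
#'
#' @param epochs Cohort epoch tibble with `participant_id`.
#' @param fixes Cohort GPS tibble with `participant_id`.
#' @param anchors Tibble with `participant_id`, `home_lat`, `home_lon`,
#'   `work_lat`, `work_lon`, `geofence_radius_m`.
#' @param ... Passed to [segment_journeys()].
#' @param max_gap_s Merge tolerance, seconds.
#' @return Combined journey tibble.
#' @export
segment_cohort <- function(epochs, fixes, anchors, ..., max_gap_s = 5) {
  purrr::map_dfr(unique(fixes$participant_id), function(pid) {
    a <- anchors[anchors$participant_id == pid, ]
    if (nrow(a) != 1) abort(sprintf("no anchors for participant %s", pid),
                            class = "commutePA_input_error")
    ap <- anchor_pair(c(a$home_lat, a$home_lon), c(a$work_lat, a$work_lon),
                      a$geofence_radius_m)
    m <- merge_acc_gps(epochs[epochs$participant_id == pid, ],
                       fixes[fixes$participant_id == pid, ],
                       max_gap_s = max_gap_s)
    segment_journeys(m, ap, ...)
  })
}

#' Contribution of one quantity to another, as a fraction
#'
#' The elementary contribution arithmetic: `journey_mvpa / total_mvpa`.
#' Errors when the denominator is not positive.
#'
#' @param journey_mvpa,total_mvpa MVPA minutes (scalars or vectors).
#' @return Fraction in `[0, 1]` when journey MVPA does not exceed the total.
#' @export
#' @examples
#' contribution_fraction(38.0, 80.3)  # 0.473...
contribution_fraction <- function(journey_mvpa, total_mvpa) {
  if (any(total_mvpa <= 0)) {
    abort("total MVPA must be positive for a defined contribution",
          class = "commutePA_input_error")
  }
  journey_mvpa / total_mvpa
}

#' Commute contribution to daily MVPA
#'
#' For each participant with at least one GPS-segmented journey and at least
#' one valid day: the mean daily journey MVPA (over days with a journey)
#' divided by the mean daily total MVPA (over valid days in the analysis
#' window). The cohort-level headline figure is the ratio of cohort means
#' (mean journey MVPA over mean total MVPA across participants); the mean of
#' the per-participant ratios is also reported.
#'
#' @param journeys Journey tibble from [segment_journeys()] /
#'   [segment_cohort()].
#' @param day_summaries Day-summary tibble from [summarise_days()].
#' @param day_type Day type for the denominator (default `"weekday"`).
#' @return List with `per_participant` (tibble: `participant_id`,
#'   `journey_mvpa`, `total_mvpa`, `fraction`), `cohort_fraction`
#'   (ratio of means), `cohort_mean_journey_mvpa`, `cohort_mean_total_mvpa`
#'   and `cohort_mean_of_ratios`.
#' @export
commute_contribution <- function(journeys, day_summaries,
                                 day_type = "weekday") {
  valid <- day_summaries[day_summaries$valid &
                           day_summaries$day_type == day_type, ]
  daily_j <- dplyr::group_by(journeys, .data$participant_id, .data$date) %>%
    dplyr::summarise(journey_mvpa = sum(.data$mvpa_min), .groups = "drop")
  per <- dplyr::group_by(daily_j, .data$participant_id) %>%
    dplyr::summarise(journey_mvpa = mean(.data$journey_mvpa), .groups = "drop") %>%
    dplyr::inner_join(
      dplyr::group_by(valid, .data$participant_id) %>%
        dplyr::summarise(total_mvpa = mean(.data$mvpa_minutes), .groups = "drop"),
      by = "participant_id")
  per$fraction <- ifelse(per$total_mvpa > 0,
                         per$journey_mvpa / per$total_mvpa, NA_real_)
  if (any(is.na(per$fraction))) {
    warn(sprintf("%d participant(s) with zero total MVPA: contribution undefined",
                 sum(is.na(per$fraction))))
  }
  list(
    per_participant = per,
    cohort_mean_journey_mvpa = mean(per$journey_mvpa),
    cohort_mean_total_mvpa = mean(per$total_mvpa),
    cohort_fraction = contribution_fraction(mean(per$journey_mvpa),
                                            mean(per$total_mvpa)),
    cohort_mean_of_ratios = mean(per$fraction, na.rm = TRUE)
  )
}
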