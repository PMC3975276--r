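# File-format plumbing: the cohort CSV dialects, GPX 1.1 tracks and the
# ground-truth sidecar. All timestamps are written as ISO-8601 naive local
# time (no offset).

accel_cols <- c("participant_id", "timestamp", "counts")
gps_cols <- c("participant_id", "timestamp", "lat", "lon")
diary_cols <- c("participant_id", "date", "mode_to_work", "mode_from_work")

#' Read an accelerometer epoch CSV
#'
#' Reads the `participant_id,timestamp,counts` dialect. A device-export
#' style file with a 10-line metadata header (first line not the column
#' header) is detected and the header skipped.
#'
#' @param path CSV file path.
#' @return Epoch tibble with POSIXct `timestamp`.
#' @export
read_accel_csv <- function(path) {
  first <- readLines(path, n = 1)
  skip <- if (!grepl("participant_id", first, fixed = TRUE)) 10 else 0
  x <- readr::read_csv(path, skip = skip, col_types = readr::cols(
    participant_id = readr::col_character(),
    timestamp = readr::col_character(),
    counts = readr::col_integer()))
  x$timestamp <- parse_ts(x$timestamp)
  x
}

#' Read a GPS fix CSV
#'
#' @param path CSV with columns `participant_id,timestamp,lat,lon`.
#' @return Fix tibble with POSIXct `timestamp`.
#' @export
read_gps_csv <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    timestamp = readr::col_character(),
    lat = readr::col_double(), lon = readr::col_double()))
  x$timestamp <- parse_ts(x$timestamp)
  x
}

#' Read a travel-diary CSV
#'
#' @param path CSV with columns
#'   `participant_id,date,mode_to_work,mode_from_work`.
#' @return Diary tibble with `Date` dates.
#' @export
read_diary_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    date = readr::col_date(),
    mode_to_work = readr::col_character(),
    mode_from_work = readr::col_character()))
}

#' Read a demographics CSV
#'
#' @param path CSV with `participant_id`, demographic bands and optionally
#'   `questionnaire_mode`.
#' @return Demographics tibble.
#' @export
read_demographics_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(), .default = readr::col_guess()))
}

#' Read a home/work anchors CSV
#'
#' @param path CSV with `participant_id, home_lat, home_lon, work_lat,
#'   work_lon, geofence_radius_m`.
#' @return Anchors tibble.
#' @export
read_anchors_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(), .default = readr::col_double()))
}

#' Write a GPS trace as a GPX 1.1 track
#'
#' One track with one segment; fix times are naive local ISO-8601.
#'
#' @param fixes Tibble with `timestamp`, `lat`, `lon`.
#' @param path Output file.
#' @param name Track name.
#' @return `path`, invisibly.
#' @export
write_gpx <- function(fixes, path, name = "track") {
  doc <- xml2::xml_new_root(
    "gpx", version = "1.1", creator = "commutePA",
    xmlns = "http://www.topografix.com/GPX/1/1")
  trk <- xml2::xml_add_child(doc, "trk")
  xml2::xml_add_child(trk, "name", name)
  seg <- xml2::xml_add_child(trk, "trkseg")
  for (i in seq_len(nrow(fixes))) {
    pt <- xml2::xml_add_child(seg, "trkpt",
                              lat = sprintf("%.7f", fixes$lat[i]),
                              lon = sprintf("%.7f", fixes$lon[i]))
    xml2::xml_add_child(pt, "time", fmt_ts(fixes$timestamp[i]))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a GPX 1.1 track into a fix tibble
#'
#' @param path GPX file.
#' @return Tibble with `timestamp`, `lat`, `lon`.
#' @export
read_gpx <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  pts <- xml2::xml_find_all(doc, ".//trkpt")
  tibble(
    timestamp = parse_ts(sub("Z$", "", xml2::xml_text(
      xml2::xml_find_first(pts, "./time")))),
    lat = as.numeric(xml2::xml_attr(pts, "lat")),
    lon = as.numeric(xml2::xml_attr(pts, "lon"))
  )
}

#' Write a synthetic cohort bundle to disk
#'
#' Writes one accelerometer CSV, one GPS CSV and one diary CSV per
#' participant, the cohort demographics and anchors tables, and the
#' ground-truth JSON sidecar. Optionally also one GPX track per
#' participant-day.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @param gpx Also write per participant-day GPX tracks?
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, gpx = FALSE) {
  for (d in file.path(dir, c("accel", "gps", "diary"))) {
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  }
  iso <- function(x) { x$timestamp <- fmt_ts(x$timestamp); x }
  for (pid in unique(cohort$demographics$participant_id)) {
    readr::write_csv(iso(cohort$accel[cohort$accel$participant_id == pid, ]),
                     file.path(dir, "accel", paste0(pid, ".csv")))
    g <- cohort$gps[cohort$gps$participant_id == pid, ]
    readr::write_csv(iso(g), file.path(dir, "gps", paste0(pid, ".csv")))
    readr::write_csv(cohort$diary[cohort$diary$participant_id == pid, ],
                     file.path(dir, "diary", paste0(pid, ".csv")))
    if (gpx && nrow(g)) {
      for (dt in unique(format(local_date(g$timestamp)))) {
        gd <- g[format(local_date(g$timestamp)) == dt, ]
        write_gpx(gd, file.path(dir, "gps", paste0(pid, "_", dt, ".gpx")),
                  name = paste(pid, dt))
      }
    }
  }
  readr::write_csv(cohort$demographics, file.path(dir, "demographics.csv"))
  readr::write_csv(cohort$anchors, file.path(dir, "anchors.csv"))
  truth <- cohort$truth
  truth$days$wear_start <- fmt_ts(truth$days$wear_start)
  truth$days$wear_end <- fmt_ts(truth$days$wear_end)
  if (nrow(truth$journeys)) {
    truth$journeys$start <- fmt_ts(truth$journeys$start)
    truth$journeys$end <- fmt_ts(truth$journeys$end)
  }
  if (nrow(truth$nonwear)) {
    truth$nonwear$start <- fmt_ts(truth$nonwear$start)
    truth$nonwear$end <- fmt_ts(truth$nonwear$end)
  }
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       dataframe = "columns", digits = NA)
  invisible(dir)
}

#' Read a cohort ground-truth sidecar
#'
#' @param path `ground_truth.json` written by [write_cohort()].
#' @return List of `participants`, `days`, `journeys`, `nonwear` tibbles.
#' @export
read_ground_truth <- function(path) {
  truth <- jsonlite::read_json(path, simplifyVector = TRUE)
  truth <- purrr::map(truth, as_tibble)
  truth$days$date <- as.Date(truth$days$date)
  truth$days$wear_start <- parse_ts(truth$days$wear_start)
  truth$days$wear_end <- parse_ts(truth$days$wear_end)
  if (nrow(truth$journeys)) {
    truth$journeys$date <- as.Date(truth$journeys$date)
    truth$journeys$start <- parse_ts(truth$journeys$start)
    truth$journeys$end <- parse_ts(truth$journeys$end)
  }
  if (nrow(truth$nonwear)) {
    truth$nonwear$date <- as.Date(truth$nonwear$date)
    truth$nonwear$start <- parse_ts(truth$nonwear$start)
    truth$nonwear$end <- parse_ts(truth$nonwear$end)
  }
  truth
}

#' Validate a raw input bundle
#'
#' Schema and consistency checks over the raw files: required columns per
#' dialect, timestamp monotonicity per participant (with the offending line
#' number), coordinate ranges, diary mode vocabulary, and cross-file
#' participant-ID consistency against the demographics table. Every
#' violation is listed; nothing is silently dropped.
#'
#' @param paths Named list with any of `accel`, `gps`, `diary` (character
#'   vectors of files) and `demographics`, `anchors` (single files).
#' @return Tibble of violations (`file`, `line`, `rule`, `message`); zero
#'   rows when the bundle is clean.
#' @export
validate_inputs <- function(paths) {
  v <- list()
  add <- function(file, line, rule, msg) {
    v[[length(v) + 1]] <<- tibble(file = file, line = line, rule = rule,
                                  message = msg)
  }
  for (p in unlist(paths)) {
    if (!file.exists(p)) abort(sprintf("unreadable file: %s", p),
                               class = "commutePA_input_error")
  }
  known_ids <- NULL
  if (!is.null(paths$demographics)) {
    d <- read_demographics_csv(paths$demographics)
    known_ids <- unique(d$participant_id)
    if (anyDuplicated(d$participant_id)) {
      add(paths$demographics, NA_integer_, "unique_participants",
          "duplicated participant_id in demographics")
    }
  }
  check_ids <- function(ids, file) {
    if (is.null(known_ids)) return(invisible())
    bad <- setdiff(unique(ids), known_ids)
    for (b in bad) add(file, NA_integer_, "unknown_participant",
                       sprintf("participant '%s' not in demographics", b))
  }
  check_monotone <- function(x, file) {
    for (pid in unique(x$participant_id)) {
      ts <- x$timestamp[x$participant_id == pid]
      rows <- which(x$participant_id == pid)
      bad <- which(diff(as.numeric(ts)) <= 0)
      for (b in bad) add(file, rows[b + 1] + 1L, "monotone_timestamps",
                         sprintf("non-increasing timestamp for %s", pid))
    }
  }
  for (p in paths$accel %||% character()) {
    x <- tryCatch(read_accel_csv(p), error = function(e) NULL)
    if (is.null(x) || !all(accel_cols %in% names(x))) {
      add(p, NA_integer_, "schema", "accelerometer file missing required columns")
      next
    }
    if (any(is.na(x$counts) | x$counts < 0)) {
      add(p, which(is.na(x$counts) | x$counts < 0)[1] + 1L, "counts_nonnegative",
          "negative or missing counts")
    }
    check_monotone(x, p); check_ids(x$participant_id, p)
  }
  for (p in paths$gps %||% character()) {
    x <- tryCatch(read_gps_csv(p), error = function(e) NULL)
    if (is.null(x) || !all(gps_cols %in% names(x))) {
      add(p, NA_integer_, "schema", "GPS file missing required columns")
      next
    }
    bad <- which(abs(x$lat) > 90 | abs(x$lon) > 180)
    for (b in bad) add(p, b + 1L, "coordinate_range", "lat/lon out of WGS84 range")
    check_monotone(x, p); check_ids(x$participant_id, p)
  }
  for (p in paths$diary %||% character()) {
    x <- tryCatch(read_diary_csv(p), error = function(e) NULL)
    if (is.null(x) || !all(diary_cols %in% names(x))) {
      add(p, NA_integer_, "schema", "diary file missing required columns")
      next
    }
    bad <- which(!(x$mode_to_work %in% diary_modes) |
                   !(x$mode_from_work %in% diary_modes))
    for (b in bad) add(p, b + 1L, "mode_vocabulary",
                       "diary mode outside walk/car/cycle/other/missing")
    if (anyDuplicated(x[, c("participant_id", "date")])) {
      add(p, NA_integer_, "one_entry_per_day",
          "duplicate participant-date diary entries")
    }
    check_ids(x$participant_id, p)
  }
  if (length(v) == 0) {
    return(tibble(file = character(), line = integer(), rule = character(),
                  message = character()))
  }
  dplyr::bind_rows(v)
}
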