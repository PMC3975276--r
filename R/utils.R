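# Internal helpers shared across modules. All timestamps in this package are
# naive local datetimes carried as POSIXct in UTC; no DST arithmetic is ever
# applied.

#' @importFrom rlang abort warn inform %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>%
NULL

# Parse "HH:MM" (24:00 allowed) to seconds of day.
parse_tod <- function(x) {
  if (is.numeric(x)) return(x)
  m <- regmatches(x, regexec("^([0-9]{1,2}):([0-9]{2})$", x))[[1]]
  if (length(m) != 3) {
    abort(sprintf("time of day '%s' is not HH:MM", x), class = "commutePA_config_error")
  }
  as.numeric(m[2]) * 3600 + as.numeric(m[3]) * 60
}

# Seconds since local midnight of a POSIXct (UTC-carried naive time).
sec_of_day <- function(ts) {
  as.numeric(ts) %% 86400
}

# Fast calendar helpers on the naive-UTC contract (avoid as.Date.POSIXct /
# format, which are slow on long vectors). Unix day 0 is a Thursday, so
# day %% 7 of 2 or 3 is Saturday or Sunday.
local_date <- function(ts) {
  as.Date(floor(as.numeric(ts) / 86400), origin = "1970-01-01")
}

is_weekend <- function(date) {
  unclass(as.Date(date)) %% 7 %in% c(2, 3)
}

day_type_of <- function(date) {
  ifelse(is_weekend(date), "weekend", "weekday")
}

# Deterministic child-seed splitting: one global seed fans out to streams for
# participants (and their days) without correlated overlap in practice.
# Kept below 2^31 so the result is always a valid R integer.
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 10007) %% 2147483647)
}

# Great-circle distance in metres between (lat, lon) points; vectorised.
haversine_m <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2))
}

epoch_s_of <- function(epochs, epoch_s = NULL) {
  if (!is.null(epoch_s)) return(as.numeric(epoch_s))
  if (nrow(epochs) < 2) abort("cannot infer epoch length from fewer than 2 epochs")
  d <- diff(as.numeric(epochs$timestamp))
  d <- d[d > 0]
  if (length(d) == 0) {
    abort("cannot infer epoch length: timestamps are not increasing",
          class = "commutePA_input_error")
  }
  min(d)
}

assert_sorted_time <- function(ts, what = "epochs") {
  if (is.unsorted(as.numeric(ts))) {
    abort(sprintf("%s are not sorted by timestamp", what), class = "commutePA_input_error")
  }
  invisible(TRUE)
}

fmt_ts <- function(ts) format(ts, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

parse_ts <- function(x) as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
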