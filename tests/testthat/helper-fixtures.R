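# Shared fixtures and independent oracles, built in code at test time.

ts_at <- function(date, hms) {
  as.POSIXct(paste(date, hms), tz = "UTC")
}

# A plain epoch tibble from a counts vector.
epochs_from_counts <- function(counts, epoch_s = 10,
                               start = ts_at("2012-05-07", "06:00:00"),
                               participant_id = NULL) {
  x <- tibble::tibble(
    timestamp = start + epoch_s * (seq_along(counts) - 1),
    counts = as.integer(counts))
  if (!is.null(participant_id)) x$participant_id <- participant_id
  x
}

# Independent brute-force non-wear oracle: for every epoch, scan outward to
# find the maximal surrounding zero run and compare its length with the
# threshold. O(n^2) worst case, deliberately naive.
brute_force_nonwear <- function(counts, epoch_s, nonwear_min_minutes = 20) {
  n <- length(counts)
  min_len <- nonwear_min_minutes * 60 / epoch_s
  wear <- rep(TRUE, n)
  for (i in seq_len(n)) {
    if (counts[i] != 0) next
    a <- i
    while (a > 1 && counts[a - 1] == 0) a <- a - 1
    b <- i
    while (b < n && counts[b + 1] == 0) b <- b + 1
    if (b - a + 1 >= min_len) wear[i] <- FALSE
  }
  wear
}

# Independent exhaustive journey-search oracle: enumerate every pair of
# position-bearing epochs (i in one geofence, j > i in the other) such that
# no internal position gap exceeds the tolerance, and return the longest
# span (ties to the earlier start), or NULL.
brute_force_journey <- function(win, anchors, max_internal_gap_min = 5) {
  pos <- win[!is.na(win$lat), ]
  n <- nrow(pos)
  if (n < 2) return(NULL)
  dh <- geosphere::distHaversine(cbind(pos$lon, pos$lat),
                                 c(anchors$home[2], anchors$home[1]))
  dw <- geosphere::distHaversine(cbind(pos$lon, pos$lat),
                                 c(anchors$work[2], anchors$work[1]))
  inH <- dh <= anchors$geofence_radius_m
  inW <- dw <= anchors$geofence_radius_m
  tt <- as.numeric(pos$timestamp)
  ok_gap <- function(i, j) {
    if (j == i) return(TRUE)
    all(diff(tt[i:j]) <= max_internal_gap_min * 60)
  }
  best <- NULL
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      dir <- if (inH[i] && inW[j]) "to_work" else
        if (inW[i] && inH[j]) "from_work" else NA
      if (is.na(dir)) next
      if (!ok_gap(i, j)) next
      span <- tt[j] - tt[i]
      if (is.null(best) || span > best$span ||
          (span == best$span && tt[i] < best$t0)) {
        best <- list(span = span, t0 = tt[i], direction = dir,
                     start = pos$timestamp[i], end = pos$timestamp[j])
      }
    }
  }
  best
}

epoch_s_from <- function(m) {
  d <- diff(as.numeric(sort(m$timestamp)))
  min(d[d > 0])
}

# Cache moderately expensive shared cohorts across test files.
.fixture_env <- new.env(parent = emptyenv())

shared_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    .fixture_env$cohort <- generate_cohort(
      cohort_config(n_participants = 12), seed = 301)
  }
  .fixture_env$cohort
}

shared_day_summaries <- function() {
  if (is.null(.fixture_env$ds)) {
    .fixture_env$ds <- summarise_days(shared_cohort()$accel)
  }
  .fixture_env$ds
}

# A small random merged "day" around synthetic anchors, for the exhaustive
# segmentation cross-check: short traces that may or may not form a valid
# anchor-to-anchor journey, with random gaps and fence-miss starts.
random_mini_day <- function(seed) {
  set.seed(seed)
  home <- c(51.45, -2.59)
  work <- c(51.45 + 0.009, -2.59)  # ~1 km north
  anchors <- anchor_pair(home, work, 100)
  n <- sample(20:50, 1)
  t0 <- ts_at("2012-05-07", "08:00:00")
  ts <- t0 + cumsum(sample(c(rep(10, 19), 400), n, replace = TRUE))
  frac <- pmin(pmax(cumsum(stats::rnorm(n, 0.06, 0.04)), -0.05), 1.05)
  lat <- home[1] + frac * (work[1] - home[1]) + stats::rnorm(n, 0, 2e-5)
  lon <- home[2] + stats::rnorm(n, 0, 2e-5)
  m <- tibble::tibble(timestamp = ts,
                      counts = as.integer(stats::rpois(n, 400)),
                      lat = lat, lon = lon)
  drop <- stats::runif(n) < 0.1
  m$lat[drop] <- NA; m$lon[drop] <- NA
  list(merged = m, anchors = anchors)
}
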