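# Accelerometer reduction: reintegration, non-wear, cut-points, summaries.

test_that("reintegration sums constituent epochs and conserves counts", {
  x <- epochs_from_counts(c(10, 20, 30, 0, 0, 40))
  y <- reintegrate(x, 60)
  expect_equal(nrow(y), 1)
  expect_equal(y$counts, 100L)
  expect_equal(y$timestamp, x$timestamp[1])

  # identity at the source epoch length
  expect_identical(reintegrate(x, 10), x)

  # 13 epochs at a 6:1 ratio: 2 whole output epochs, 1 partial dropped
  z <- epochs_from_counts(rep(1, 13))
  expect_message(out <- reintegrate(z, 60), "partial")
  expect_equal(nrow(out), 2)
  expect_equal(out$counts, c(6L, 6L))

  expect_error(reintegrate(x, 25), "multiple", class = "commutePA_input_error")

  # exact integer conservation on random streams
  for (s in 1:10) {
    set.seed(s)
    n <- sample(60:600, 1)
    r <- epochs_from_counts(rpois(n, 40))
    agg <- suppressMessages(reintegrate(r, 60))
    expect_identical(sum(agg$counts), sum(r$counts[seq_len(6 * (n %/% 6))]))
  }
})

test_that("non-wear needs at least 20 continuous zero minutes", {
  cfg <- cut_point_config()
  # exactly 20 min of zeros (120 epochs at 10 s): all non-wear
  x <- epochs_from_counts(c(5, rep(0, 120), 5))
  expect_equal(detect_nonwear(x, cfg), c(TRUE, rep(FALSE, 120), TRUE))
  # 19 min 50 s: all wear
  y <- epochs_from_counts(c(5, rep(0, 119), 5))
  expect_true(all(detect_nonwear(y, cfg)))
  # one positive count terminates a run: both flanking runs removed, the
  # interrupting epoch is wear
  z <- epochs_from_counts(c(rep(0, 130), 5, rep(0, 130)))
  expect_equal(detect_nonwear(z, cfg),
               c(rep(FALSE, 130), TRUE, rep(FALSE, 130)))
  # unsorted input errors
  u <- epochs_from_counts(c(1, 2, 3)); u$timestamp <- rev(u$timestamp)
  expect_error(detect_nonwear(u, cfg), class = "commutePA_input_error")
})

test_that("non-wear detection equals the brute-force maximal-run scanner", {
  cfg <- cut_point_config()
  for (s in 1:200) {
    set.seed(s)
    counts <- ifelse(runif(400) < 0.75, 0L, rpois(400, 30))
    x <- epochs_from_counts(counts)
    expect_identical(detect_nonwear(x, cfg),
                     brute_force_nonwear(counts, 10, 20))
  }
})

test_that("intensity thresholds are strict and epoch-scaled", {
  cfg <- cut_point_config()
  cls60 <- classify_intensity(c(99L, 100L, 1952L, 1953L), 60, cfg)
  expect_equal(as.character(cls60), c("sedentary", "light", "light", "mvpa"))
  # at 10-s epochs the MVPA bound is 1952/6 = 325.33: 326 exceeds it
  cls10 <- classify_intensity(c(16L, 17L, 325L, 326L), 10, cfg)
  expect_equal(as.character(cls10), c("sedentary", "light", "light", "mvpa"))
})

test_that("classification is epoch-length invariant for minute-uniform streams", {
  set.seed(42)
  per_min <- rpois(120, 30) * 60L  # counts divisible by 60
  fine <- epochs_from_counts(rep(per_min / 6L, each = 6), epoch_s = 10)
  coarse <- reintegrate(fine, 60)
  expect_equal(as.character(rep(classify_intensity(coarse$counts, 60), each = 6)),
               as.character(classify_intensity(fine$counts, 10)))
})

test_that("day summaries apply the window, wear rules and validity boundary", {
  # exactly 600 wear minutes starting 06:00: valid
  x <- epochs_from_counts(rpois(3600, 30), start = ts_at("2012-05-07", "06:00:00"))
  d <- summarise_day(x)
  expect_equal(d$wear_minutes, 600)
  expect_true(d$valid)
  expect_equal(d$day_type, "weekday")
  expect_equal(d$mean_cpm, sum(x$counts) / 600)

  # one epoch fewer: invalid
  d2 <- summarise_day(x[-1, ])
  expect_false(d2$valid)

  # an all-zero day is one long non-wear run: zero wear, no division error
  z <- summarise_day(epochs_from_counts(rep(0, 3600)))
  expect_equal(z$wear_minutes, 0)
  expect_false(z$valid)
  expect_true(is.na(z$mean_cpm))

  # epochs before 06:00 are outside the analysis window
  early <- epochs_from_counts(rpois(720, 30),
                              start = ts_at("2012-05-07", "05:00:00"))
  expect_equal(summarise_day(early)$wear_minutes, 60)
})

test_that("a non-wear run straddling 06:00 counts its full length", {
  # 15 min of zeros before 06:00 + 10 min after: a 25-min run, so the
  # 10 post-window minutes are non-wear even though the window clips the run
  counts <- c(rep(0, 150), rep(5, 60))
  x <- epochs_from_counts(counts, start = ts_at("2012-05-07", "05:45:00"))
  d <- summarise_day(x)
  expect_equal(d$wear_minutes, 10)
})

test_that("intensity minutes partition wear time exactly", {
  for (s in 1:5) {
    set.seed(s)
    x <- epochs_from_counts(ifelse(runif(5000) < 0.3, 0L, rpois(5000, 60)))
    d <- summarise_day(x)
    expect_equal(d$mvpa_minutes + d$sedentary_minutes + d$light_minutes,
                 d$wear_minutes)
  }
})

test_that("day summaries recover generator-injected MVPA to the minute", {
  co <- shared_cohort()
  ds <- shared_day_summaries()
  m <- dplyr::inner_join(ds, co$truth$days, by = c("participant_id", "date"))
  err <- m$mvpa_minutes.x - m$mvpa_minutes.y
  expect_lte(max(abs(err)), 1)
})

test_that("the valid-day flag is monotone in wear time", {
  base <- rpois(4000, 30) + 1L
  wear <- sapply(c(3000, 3599, 3600, 4000), function(n) {
    summarise_day(epochs_from_counts(base[seq_len(n)]))$valid
  })
  expect_equal(wear, c(FALSE, FALSE, TRUE, TRUE))
})

test_that("hourly profiles reflect group structure", {
  set.seed(1)
  mk <- function(pid, counts) epochs_from_counts(counts, participant_id = pid)
  counts <- rpois(4000, 35)
  e <- dplyr::bind_rows(mk("A", counts), mk("B", counts),
                        mk("C", counts), mk("D", counts))
  g1 <- tibble::tibble(participant_id = c("A", "B", "C", "D"),
                       group = c("x", "x", "y", "y"))
  h <- hourly_profile(e, g1)
  wide <- tidyr::pivot_wider(h[, c("group", "hour", "mean_cpm")],
                             names_from = "group", values_from = "mean_cpm")
  # identical participants in both groups: identical profiles
  expect_equal(wide$x, wide$y)

  # constant stream: flat profile equal to the constant per-minute rate
  const <- mk("A", rep(60L, 4320))
  hc <- hourly_profile(const, tibble::tibble(participant_id = "A", group = "x"),
                       day_type = "all")
  expect_true(all(abs(hc$mean_cpm - 360) < 1e-9))

  expect_error(hourly_profile(e, tibble::tibble(participant_id = character(),
                                                group = character())),
               class = "commutePA_input_error")
})

test_that("working-hours comparison over the full window matches day summaries", {
  set.seed(2)
  e <- dplyr::bind_rows(lapply(c("A", "B", "C", "D"), function(p) {
    epochs_from_counts(rpois(6480, 30 + 5 * (p > "B")), participant_id = p)
  }))
  g <- tibble::tibble(participant_id = c("A", "B", "C", "D"),
                      group = c("x", "x", "y", "y"))
  full <- working_hours_comparison(e, g, "06:00", "24:00")
  ds <- summarise_days(e)
  expect_equal(sort(full$data$cpm), sort(ds$mean_cpm))
  expect_error(working_hours_comparison(e, g, "16:00", "09:00"),
               class = "commutePA_input_error")
})
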