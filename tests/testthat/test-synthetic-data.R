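# Synthetic cohort generator: determinism, validity, recoverability.

test_that("cohort configuration rejects invalid study conditions", {
  expect_error(cohort_config(0), class = "commutePA_config_error")
  expect_error(cohort_config(5, mode_proportions = c(walk = 0.6, car = 0.6)),
               "sum to 1", class = "commutePA_config_error")
  expect_error(cohort_config(5, mode_proportions = c(walk = 0.5, bus = 0.5)),
               "mode_proportions", class = "commutePA_config_error")
  expect_error(cohort_config(5, epoch_s = 7), "divide 60",
               class = "commutePA_config_error")
  expect_error(cohort_config(5, walk_intensity_cpm = c(4000, -1)),
               "walk_intensity_cpm", class = "commutePA_config_error")
  expect_error(cohort_config(5, detour_probability = 1.4),
               class = "commutePA_config_error")
})

test_that("a fixed seed reproduces the cohort bundle byte for byte", {
  cfg <- cohort_config(n_participants = 1, mode_proportions = c(walk = 1))
  a <- generate_cohort(cfg, seed = 7)
  b <- generate_cohort(cfg, seed = 7)
  expect_identical(a$accel, b$accel)
  expect_identical(a$gps, b$gps)
  expect_identical(a$diary, b$diary)
  expect_identical(a$demographics, b$demographics)
  expect_identical(a$truth, b$truth)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(a, d1); write_cohort(b, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  h <- function(d, f) unname(tools::md5sum(file.path(d, f)))
  expect_identical(h(d1, f1), h(d2, f1))
})

test_that("participants are generated from independent child seed streams", {
  cfg <- cohort_config(n_participants = 3)
  full <- generate_cohort(cfg, seed = 5)
  solo <- generate_cohort(cohort_config(n_participants = 1), seed = 5)
  expect_identical(full$accel[full$accel$participant_id == "P001", ],
                   solo$accel)
})

test_that("day streams honour plan windows, spacing and count domain", {
  plan <- day_plan(as.Date("2012-05-07"), 7 * 3600, 22 * 3600,
                   nonwear = tibble::tibble(start_s = 10 * 3600,
                                            duration_min = 25))
  s <- generate_day_stream(plan, seed = 3)
  expect_equal(as.numeric(diff(s$timestamp)), rep(10, nrow(s) - 1))
  expect_equal(nrow(s), (22 - 7) * 360)
  expect_true(all(s$counts >= 0))
  expect_true(all(s$counts == floor(s$counts)))
  # a 25-min removal is exactly 150 consecutive zero epochs at 10 s
  nw <- which(s$state == "nonwear")
  expect_length(nw, 150)
  expect_equal(nw, seq(min(nw), min(nw) + 149))
  expect_true(all(s$counts[nw] == 0))
})

test_that("overlapping injected windows are a generation error", {
  plan <- day_plan(as.Date("2012-05-07"), 7 * 3600, 22 * 3600,
                   commutes = tibble::tibble(
                     start_s = 8 * 3600, walking_min = 30, mode = "walk",
                     direction = "to_work", detour_min = 0, detour_frac = 0.5),
                   nonwear = tibble::tibble(start_s = 8 * 3600 + 600,
                                            duration_min = 30))
  expect_error(generate_day_stream(plan, seed = 1),
               class = "commutePA_generation_error")
})

test_that("commute-free days stay within the background envelope", {
  plan <- day_plan(as.Date("2012-05-12"), 8 * 3600, 21 * 3600)  # a Saturday
  s <- generate_day_stream(plan, seed = 11)
  # background minutes peak around 2800 cpm; at 10-s epochs that is a rate
  # of ~467 counts, far below commuting-pace walking
  expect_lt(max(s$counts), 900)
  expect_false(any(s$state == "commute_walk"))
})

test_that("walking epochs draw from the configured intensity", {
  cfg <- cohort_config(n_participants = 2, mode_proportions = c(walk = 1),
                       detour_probability = 0)
  co <- generate_cohort(cfg, seed = 13, gps = FALSE)
  # regenerate the streams to recover states via the per-participant truth
  jt <- co$truth$journeys
  walk_min <- sum(jt$duration_min[jt$mode == "walk"])
  expect_gt(walk_min, 50)
  in_journey <- rep(FALSE, nrow(co$accel))
  for (k in seq_len(nrow(jt))) {
    in_journey <- in_journey |
      (co$accel$participant_id == jt$participant_id[k] &
         co$accel$timestamp >= jt$start[k] & co$accel$timestamp < jt$end[k])
  }
  mean_cpm <- mean(co$accel$counts[in_journey]) * 6
  se <- 600 / sqrt(walk_min)
  expect_lt(abs(mean_cpm - 4000), 3 * se + 25)
})

test_that("walk-mode days yield more daily MVPA than car-mode days", {
  # paired replicates sharing the background profile
  wins <- function(mode) tibble::tibble(
    start_s = c(8.5 * 3600, 17.5 * 3600), walking_min = 20, mode = mode,
    direction = c("to_work", "from_work"), detour_min = 0, detour_frac = 0.5)
  more <- logical(100)
  for (r in 1:100) {
    pw <- day_plan(as.Date("2012-05-07"), 7 * 3600, 22 * 3600, wins("walk"))
    pc <- day_plan(as.Date("2012-05-07"), 7 * 3600, 22 * 3600, wins("car"))
    sw <- generate_day_stream(pw, seed = 9000 + r)
    sc <- generate_day_stream(pc, seed = 9000 + r)
    dw <- summarise_day(sw[, c("timestamp", "counts")])
    dc <- summarise_day(sc[, c("timestamp", "counts")])
    more[r] <- dw$mvpa_minutes > dc$mvpa_minutes
  }
  expect_true(all(more))
})

test_that("GPS traces have the planned spacing, span and endpoints", {
  route <- rbind(c(51.45, -2.59), c(51.45 + 1000 / 111320, -2.59))  # 1 km
  tr <- generate_gps_trace(route, ts_at("2012-05-07", "08:20:00"),
                           speed_m_s = 5000 / 3600)
  # 1 km at 5 km/h is 12 min: 73 fixes at 10-s spacing
  expect_equal(nrow(tr), 73)
  expect_equal(as.numeric(tr$timestamp[73] - tr$timestamp[1], units = "mins"), 12)
  expect_equal(c(tr$lat[1], tr$lon[1]), route[1, ], tolerance = 1e-9)
  expect_equal(c(tr$lat[73], tr$lon[73]), route[2, ], tolerance = 1e-6)
})

test_that("jitter-free fixes lie on the route polyline", {
  route <- rbind(c(51.45, -2.59), c(51.455, -2.585), c(51.46, -2.59))
  tr <- generate_gps_trace(route, ts_at("2012-05-07", "08:00:00"),
                           speed_m_s = 1.4)
  on_segment <- function(lat, lon) {
    any(vapply(1:2, function(k) {
      f <- if (route[k + 1, 1] != route[k, 1]) {
        (lat - route[k, 1]) / (route[k + 1, 1] - route[k, 1])
      } else (lon - route[k, 2]) / (route[k + 1, 2] - route[k, 2])
      f >= -1e-9 && f <= 1 + 1e-9 &&
        abs(route[k, 1] + f * (route[k + 1, 1] - route[k, 1]) - lat) < 1e-6 &&
        abs(route[k, 2] + f * (route[k + 1, 2] - route[k, 2]) - lon) < 1e-6
    }, logical(1)))
  }
  expect_true(all(mapply(on_segment, tr$lat, tr$lon)))
})

test_that("trace length scales inversely with speed", {
  route <- rbind(c(51.45, -2.59), c(51.45 + 2000 / 111320, -2.59))
  walk <- generate_gps_trace(route, ts_at("2012-05-07", "08:00:00"),
                             speed_m_s = 5 / 3.6)
  car <- generate_gps_trace(route, ts_at("2012-05-07", "08:00:00"),
                            speed_m_s = 30 / 3.6)
  expect_gt(nrow(walk) / nrow(car), 5.5)
  expect_lt(nrow(walk) / nrow(car), 6.5)
  expect_error(generate_gps_trace(route[1, , drop = FALSE],
                                  ts_at("2012-05-07", "08:00:00"), 1),
               class = "commutePA_generation_error")
})

test_that("injected non-wear minutes are recovered by the detector", {
  co <- shared_cohort()
  wear <- detect_nonwear(co$accel)
  truth_nw <- co$truth$nonwear
  skip_if(nrow(truth_nw) == 0)
  injected <- rep(FALSE, nrow(co$accel))
  for (k in seq_len(nrow(truth_nw))) {
    injected <- injected |
      (co$accel$participant_id == truth_nw$participant_id[k] &
         co$accel$timestamp >= truth_nw$start[k] &
         co$accel$timestamp < truth_nw$end[k])
  }
  # all injected runs are >= 25 min, so at least 99% of injected non-wear
  # minutes must be flagged
  expect_gte(mean(!wear[injected]), 0.99)
})

test_that("journeys are recovered from noise-free traces", {
  cfg <- cohort_config(n_participants = 6, gps_jitter_sd_m = 0,
                       gps_dropout_probability = 0, n_weekdays = 3,
                       n_weekend_days = 0)
  co <- generate_cohort(cfg, seed = 19)
  j <- segment_cohort(co$accel, co$gps, co$anchors)
  expect_gte(nrow(j) / nrow(co$truth$journeys), 0.9)
})

test_that("pipeline mode classification recovers the generating mode", {
  cfg <- cohort_config(n_participants = 50,
                       mode_proportions = c(walk = 0.7, car = 0.3))
  co <- generate_cohort(cfg, seed = 23, gps = FALSE)
  ds <- summarise_days(co$accel)
  cl <- suppressMessages(build_analysis_set(co$diary, co$demographics, ds))
  m <- dplyr::inner_join(cl$participants, co$truth$participants,
                         by = "participant_id")
  expect_gte(mean(m$usual_mode == m$mode), 0.95)
})
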