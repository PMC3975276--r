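# Comparative statistics: ANOVA, paired tests, adjusted models, percent
# differences.

test_that("two-group ANOVA is the squared equal-variance t-test", {
  for (s in 1:20) {
    set.seed(s)
    x <- rnorm(sample(5:30, 1)); y <- rnorm(sample(5:30, 1), mean = 0.5)
    gc <- compare_groups(c(x, y), rep(c("a", "b"), c(length(x), length(y))))
    tt <- t.test(x, y, var.equal = TRUE)
    expect_equal(gc$f_statistic, unname(tt$statistic)^2, tolerance = 1e-9)
    expect_equal(gc$p_value, tt$p.value, tolerance = 1e-9)
  }
})

test_that("identical groups give F = 0 and p = 1", {
  x <- c(1, 2, 3, 4)
  gc <- compare_groups(c(x, x), rep(c("a", "b"), each = 4))
  expect_equal(gc$f_statistic, 0, tolerance = 1e-12)
  expect_equal(gc$p_value, 1, tolerance = 1e-12)
  expect_error(compare_groups(c(1, 2, 3), c("a", "a", "b")),
               "degenerate", class = "commutePA_input_error")
  expect_error(compare_groups(c(1, 2, 3), c("a", "a", "a")),
               class = "commutePA_input_error")
})

test_that("three-group ANOVA matches the hand-computed decomposition", {
  g1 <- c(6, 8, 4, 5, 3, 4); g2 <- c(8, 12, 9, 11, 6, 8); g3 <- c(13, 9, 11, 8, 7, 12)
  vals <- c(g1, g2, g3)
  grp <- rep(c("a", "b", "c"), each = 6)
  # independent oracle: explicit sums of squares
  gm <- mean(vals)
  ssb <- 6 * sum((c(mean(g1), mean(g2), mean(g3)) - gm)^2)
  ssw <- sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2) + sum((g3 - mean(g3))^2)
  f_oracle <- (ssb / 2) / (ssw / 15)
  p_oracle <- pf(f_oracle, 2, 15, lower.tail = FALSE)
  gc <- compare_groups(vals, grp)
  expect_equal(gc$f_statistic, f_oracle, tolerance = 1e-12)
  expect_equal(gc$p_value, p_oracle, tolerance = 1e-12)
  expect_equal(gc$df, c(2, 15))
})

test_that("paired weekday-weekend test handles signal and degeneracy", {
  x <- c(10, 12, 9, 14, 11)
  res <- paired_weekday_weekend(x, x)
  expect_true(res$degenerate)
  expect_equal(res$t_statistic, 0)
  expect_equal(res$p_value, 1)
  # constant shift with zero noise: flagged degenerate, not an error
  res2 <- paired_weekday_weekend(x + 3, x)
  expect_true(res2$degenerate)
  expect_equal(res2$p_value, 0)
  # with noise it matches t.test
  set.seed(3)
  a <- rnorm(20, 5); b <- rnorm(20, 4)
  res3 <- paired_weekday_weekend(a, b)
  tt <- t.test(a, b, paired = TRUE)
  expect_equal(res3$t_statistic, unname(tt$statistic))
  expect_equal(res3$p_value, tt$p.value)
  expect_error(paired_weekday_weekend(1, 2), class = "commutePA_input_error")
})

test_that("paired test holds its nominal type-I error rate", {
  set.seed(77)
  p <- replicate(2000, {
    a <- rnorm(12); b <- rnorm(12)
    paired_weekday_weekend(a, b)$p_value
  })
  # binomial(2000, 0.05) 3.5-sigma band
  expect_gt(mean(p < 0.05), 0.05 - 3.5 * sqrt(0.05 * 0.95 / 2000))
  expect_lt(mean(p < 0.05), 0.05 + 3.5 * sqrt(0.05 * 0.95 / 2000))
})

fake_participants <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(
    participant_id = sprintf("P%03d", seq_len(n)),
    usual_mode = sample(c("walk", "car"), n, replace = TRUE),
    age = runif(n, 20, 60),
    sex = sample(c("male", "female"), n, replace = TRUE),
    income_band = sample(c("10-20k", "20-30k", "30-40k", ">50k"), n, replace = TRUE),
    education_band = sample(c("gcse", "degree", "postgraduate"), n, replace = TRUE),
    occupation_class = sample(c("sedentary", "standing"), n, replace = TRUE),
    employment_pattern = sample(c("full_time", "part_time"), n, replace = TRUE),
    wear_minutes = runif(n, 650, 900))
}

test_that("a noiseless linear outcome is recovered to numerical precision", {
  d <- fake_participants(80, 21)
  d$mean_cpm <- 200 + 30 * (d$sex == "female") - 2 * d$age +
    15 * (d$education_band %in% c("degree", "postgraduate")) +
    10 * (d$income_band %in% c("30-40k", ">50k")) -
    5 * (d$occupation_class != "sedentary") +
    8 * (d$employment_pattern == "full_time") +
    0.1 * d$wear_minutes + 150 * (d$usual_mode == "walk")
  # lm warns that a perfect fit makes the summary unreliable; the point
  # estimates under test are exact
  m <- suppressWarnings(fit_adjusted_model(d, "mean_cpm"))
  co <- m$coefficients
  est <- function(term) co$estimate[co$term == term]
  expect_equal(est("modewalk"), 150, tolerance = 1e-8)
  expect_equal(est("sexfemale"), 30, tolerance = 1e-8)
  expect_equal(est("age"), -2, tolerance = 1e-8)
  expect_equal(est("wear_minutes"), 0.1, tolerance = 1e-8)
  expect_equal(est("(Intercept)"), 200, tolerance = 1e-6)
  # confidence limits bracket the estimate
  expect_true(all(co$conf_low <= co$estimate & co$estimate <= co$conf_high))
})

test_that("degenerate designs are dropped or reported, never silent", {
  # a covariate with no variation is dropped with a note
  d <- fake_participants(40, 22)
  d$employment_pattern <- "full_time"
  d$mean_cpm <- rnorm(40, 400, 50)
  expect_message(m <- fit_adjusted_model(d, "mean_cpm"), "no variation")
  expect_false(any(grepl("work_status", m$coefficients$term)))

  # perfectly collinear covariates are a named error
  d2 <- fake_participants(40, 23)
  d2$income_band <- ifelse(d2$education_band == "gcse", "10-20k", ">50k")
  d2$education_band <- ifelse(d2$income_band == "10-20k", "gcse", "degree")
  d2$mean_cpm <- rnorm(40, 400, 50)
  expect_error(fit_adjusted_model(d2, "mean_cpm"), "collinear",
               class = "commutePA_input_error")

  # a single-mode cohort cannot estimate the exposure
  d3 <- fake_participants(40, 24)
  d3$usual_mode <- "walk"
  d3$mean_cpm <- rnorm(40, 400, 50)
  expect_error(fit_adjusted_model(d3, "mean_cpm"), "mode",
               class = "commutePA_input_error")
})

test_that("mode CIs cover a null and a real effect at the nominal rate", {
  covered0 <- covered1 <- logical(200)
  for (r in 1:200) {
    d <- fake_participants(60, 500 + r)
    noise <- rnorm(60, 0, 40)
    d$mean_cpm <- 400 + noise
    m0 <- fit_adjusted_model(d, "mean_cpm")
    c0 <- m0$coefficients[m0$coefficients$term == "modewalk", ]
    covered0[r] <- c0$conf_low <= 0 && 0 <= c0$conf_high
    d$mean_cpm <- 400 + 120 * (d$usual_mode == "walk") + noise
    m1 <- fit_adjusted_model(d, "mean_cpm")
    c1 <- m1$coefficients[m1$coefficients$term == "modewalk", ]
    covered1[r] <- c1$conf_low <= 120 && 120 <= c1$conf_high
  }
  # binomial(200, 0.95) three-sigma band
  expect_gt(mean(covered0), 0.95 - 3 * sqrt(0.95 * 0.05 / 200))
  expect_gt(mean(covered1), 0.95 - 3 * sqrt(0.95 * 0.05 / 200))
})

test_that("percent differences reproduce the printed group contrasts", {
  expect_equal(round(percent_difference(524.6, 364.6)), 44)
  expect_equal(round(percent_difference(78.1, 49.8)), 57)
  expect_equal(percent_difference(5, 5), 0)
  expect_error(percent_difference(5, 0), class = "commutePA_input_error")
  # antisymmetry identity: pd(a,b) = -pd(b,a) * a / b
  set.seed(8)
  a <- runif(50, 1, 100); b <- runif(50, 1, 100)
  expect_equal(percent_difference(a, b),
               -percent_difference(b, a) * a / b, tolerance = 1e-12)
})

test_that("day-level comparison contrasts walking days with car days", {
  mk_days <- function(pid, mode, cpm) tibble::tibble(
    participant_id = pid, date = as.Date("2012-05-07") + seq_along(cpm) - 1,
    day_type = "weekday", wear_minutes = 700, mean_cpm = cpm,
    mvpa_minutes = 60, sedentary_minutes = 500, light_minutes = 140,
    valid = TRUE,
    mode_to_work = mode, mode_from_work = mode)
  days <- dplyr::bind_rows(
    mk_days("A", "walk", c(520, 560, 530)),
    mk_days("B", "car", c(350, 360, 380)),
    mk_days("C", "walk", c(500, 540, 510)))
  diary <- days[, c("participant_id", "date", "mode_to_work", "mode_from_work")]
  labelled <- label_days_by_mode(days[, 1:9], diary)
  res <- day_level_comparison(labelled)
  expect_equal(sort(res$summary$group), c("car", "walk"))
  expect_gt(res$summary$mean[res$summary$group == "walk"],
            res$summary$mean[res$summary$group == "car"])
  expect_lt(res$p_value, 0.01)
  # a mode with no days is an error
  only_walk <- labelled[labelled$day_mode == "walk", ]
  expect_error(day_level_comparison(only_walk), class = "commutePA_input_error")
})
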