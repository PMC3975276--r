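# Comparative statistics: one-way ANOVA group comparisons, paired
# weekday-weekend tests, covariate-adjusted linear models, percent
# differences and the day-level mode comparison.

#' Compare groups by one-way ANOVA
#'
#' Standard fixed-effects one-way ANOVA of a continuous outcome across
#' groups, with per-group means, standard deviations and sizes. For two
#' groups the F statistic equals the square of the equal-variance two-sample
#' t statistic.
#'
#' @param values Numeric outcome vector.
#' @param group Group labels (coerced to factor).
#' @return A `group_comparison`: list with `summary` (tibble `group`, `n`,
#'   `mean`, `sd`), `f_statistic`, `df`, `p_value`.
#' @export
compare_groups <- function(values, group) {
  group <- factor(group)
  keep <- !is.na(values) & !is.na(group)
  values <- values[keep]; group <- droplevels(group[keep])
  if (nlevels(group) < 2) {
    abort("need at least two groups", class = "commutePA_input_error")
  }
  n <- table(group)
  if (any(n < 2)) {
    abort(sprintf("degenerate group(s) with n < 2: %s",
                  paste(names(n)[n < 2], collapse = ", ")),
          class = "commutePA_input_error")
  }
  fit <- stats::aov(values ~ group)
  an <- summary(fit)[[1]]
  grp_mean <- as.numeric(tapply(values, group, mean))
  grp_sd <- as.numeric(tapply(values, group, stats::sd))
  structure(list(
    summary = tibble(
      group = levels(group),
      n = as.integer(n),
      mean = grp_mean,
      sd = grp_sd
    ),
    f_statistic = an[["F value"]][1],
    df = c(an[["Df"]][1], an[["Df"]][2]),
    p_value = an[["Pr(>F)"]][1]
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison> one-way ANOVA\n")
  print(as.data.frame(x$summary), row.names = FALSE)
  cat(sprintf("  F(%d, %d) = %.3f, p = %.4g\n", x$df[1], x$df[2],
              x$f_statistic, x$p_value))
  invisible(x)
}

#' Paired weekday-weekend comparison
#'
#' Paired-samples t-test on per-participant weekday versus weekend means of
#' a daily outcome; only participants with both a weekday and a weekend
#' value contribute a pair. With zero variance in the differences the
#' degenerate result is flagged (`p` 0 or 1) rather than an error.
#'
#' @param weekday,weekend Numeric vectors aligned by participant.
#' @return List `n_pairs`, `mean_difference`, `t_statistic`, `df`,
#'   `p_value`, `degenerate`.
#' @export
paired_weekday_weekend <- function(weekday, weekend) {
  keep <- !is.na(weekday) & !is.na(weekend)
  weekday <- weekday[keep]; weekend <- weekend[keep]
  if (length(weekday) < 2) {
    abort("need at least two complete pairs", class = "commutePA_input_error")
  }
  d <- weekday - weekend
  if (stats::sd(d) == 0) {
    return(list(n_pairs = length(d), mean_difference = mean(d),
                t_statistic = if (mean(d) == 0) 0 else Inf * sign(mean(d)),
                df = length(d) - 1,
                p_value = if (mean(d) == 0) 1 else 0,
                degenerate = TRUE))
  }
  tt <- stats::t.test(weekday, weekend, paired = TRUE)
  list(n_pairs = length(d), mean_difference = unname(tt$estimate),
       t_statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, degenerate = FALSE)
}

# Dichotomised covariate coding used by the adjusted models; reference
# levels first: male, no degree, <=30k, sedentary, part time, car.
code_covariates <- function(df) {
  out <- df
  out$sex <- factor(df$sex, levels = c("male", "female"))
  out$education <- factor(
    ifelse(df$education_band %in% c("degree", "postgraduate"), "degree", "no_degree"),
    levels = c("no_degree", "degree"))
  inc <- ifelse(df$income_band %in% c("<10k", "10-20k", "20-30k"), "le30k",
                ifelse(df$income_band %in% c("30-40k", "40-50k", ">50k"),
                       "gt30k", NA))
  out$income <- factor(inc, levels = c("le30k", "gt30k"))
  out$occupation <- factor(
    ifelse(df$occupation_class == "sedentary", "sedentary", "non_sedentary"),
    levels = c("sedentary", "non_sedentary"))
  out$work_status <- factor(df$employment_pattern,
                            levels = c("part_time", "full_time"))
  out$mode <- factor(df$usual_mode, levels = c("car", "walk"))
  out
}

#' Participant-level weekday means for regression
#'
#' Averages each included participant's valid weekday summaries into one row
#' (mean cpm, MVPA minutes, sedentary minutes, wear minutes) and joins the
#' dichotomised covariates: sex (male reference), age, education (degree or
#' not), income (at or below versus above 30k), occupational activity
#' (sedentary versus not), work status (part versus full time) and travel
#' mode (car reference).
#'
#' @param day_summaries Day summaries from [summarise_days()].
#' @param analysis_set `analysis_set` tibble from [build_analysis_set()].
#' @return One row per participant, covariates coded with reference levels.
#' @export
participant_weekday_means <- function(day_summaries, analysis_set) {
  wk <- day_summaries[day_summaries$valid & day_summaries$day_type == "weekday", ]
  means <- dplyr::group_by(wk, .data$participant_id) %>%
    dplyr::summarise(mean_cpm = mean(.data$mean_cpm),
                     mvpa_minutes = mean(.data$mvpa_minutes),
                     sedentary_minutes = mean(.data$sedentary_minutes),
                     wear_minutes = mean(.data$wear_minutes),
                     .groups = "drop")
  code_covariates(dplyr::inner_join(analysis_set, means, by = "participant_id"))
}

#' Covariate-adjusted linear model of a daily activity outcome
#'
#' Ordinary least squares on one row per participant (weekday means),
#' regressing the outcome on travel mode (car reference / walk) adjusted for
#' sex, age, education, income, occupational activity, work status and
#' accelerometer wear time. Reports coefficients with 95% confidence
#' intervals and p-values.
#'
#' @param data Participant-level table from [participant_weekday_means()].
#' @param outcome One of `"mean_cpm"`, `"mvpa_minutes"`,
#'   `"sedentary_minutes"`.
#' @return An `adjusted_model`: list with `outcome`, `coefficients` tibble
#'   (`term`, `estimate`, `conf_low`, `conf_high`, `p_value`), `n` and the
#'   underlying `fit`.
#' @export
fit_adjusted_model <- function(data,
                               outcome = c("mean_cpm", "mvpa_minutes",
                                           "sedentary_minutes")) {
  outcome <- match.arg(outcome)
  if ("education_band" %in% names(data)) data <- code_covariates(data)
  rhs <- c("sex", "age", "education", "income", "occupation", "work_status",
           "wear_minutes", "mode")
  cc <- stats::complete.cases(data[, c(outcome, rhs)])
  dd <- droplevels(data[cc, ])
  # a covariate with no variation in the analysed cohort cannot be adjusted
  # for; drop it with a note (the exposure itself must vary)
  constant <- rhs[vapply(dd[rhs], function(x) length(unique(x)) < 2, logical(1))]
  if ("mode" %in% constant) {
    abort("travel mode does not vary in the analysis cohort",
          class = "commutePA_input_error")
  }
  if (length(constant)) {
    inform(sprintf("dropping covariate(s) with no variation: %s",
                   paste(constant, collapse = ", ")))
    rhs <- setdiff(rhs, constant)
  }
  f <- stats::as.formula(paste(outcome, "~", paste(rhs, collapse = " + ")))
  fit <- tryCatch(
    stats::lm(f, data = dd),
    error = function(e) abort(
      sprintf("degenerate design: %s", conditionMessage(e)),
      class = "commutePA_input_error"))
  if (any(is.na(stats::coef(fit)))) {
    abort(sprintf("rank-deficient model: collinear term(s) %s",
                  paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                        collapse = ", ")),
          class = "commutePA_input_error")
  }
  ci <- stats::confint(fit)
  sm <- summary(fit)$coefficients
  structure(list(
    outcome = outcome,
    coefficients = tibble(
      term = rownames(sm),
      estimate = unname(sm[, "Estimate"]),
      conf_low = unname(ci[, 1]),
      conf_high = unname(ci[, 2]),
      p_value = unname(sm[, "Pr(>|t|)"])
    ),
    n = sum(cc),
    fit = fit
  ), class = "adjusted_model")
}

#' @export
print.adjusted_model <- function(x, ...) {
  cat(sprintf("<adjusted_model> %s ~ mode + covariates (n = %d)\n",
              x$outcome, x$n))
  co <- x$coefficients
  co$estimate <- round(co$estimate, 2)
  co$conf_low <- round(co$conf_low, 2)
  co$conf_high <- round(co$conf_high, 2)
  co$p_value <- signif(co$p_value, 3)
  print(as.data.frame(co), row.names = FALSE)
  invisible(x)
}

#' Percent difference between two group means
#'
#' `100 * (mean_a - mean_b) / mean_b`: how much higher (or lower) group a's
#' mean is relative to group b's.
#'
#' @param mean_a,mean_b Numeric; `mean_b` must be positive.
#' @return Percent difference.
#' @export
#' @examples
#' percent_difference(524.6, 364.6)  # 43.9: walkers ~44% more active
#' percent_difference(78.1, 49.8)    # 56.8: ~57% more MVPA
percent_difference <- function(mean_a, mean_b) {
  if (any(mean_b <= 0)) {
    abort("mean_b must be positive", class = "commutePA_input_error")
  }
  100 * (mean_a - mean_b) / mean_b
}

#' Compare all walking days with all car days
#'
#' Day-level one-way ANOVA of a daily outcome across diary-labelled days
#' (every valid weekday whose diary mode was walk versus every one whose
#' mode was car), regardless of the participant's usual mode.
#'
#' @param labelled_days Output of [label_days_by_mode()].
#' @param outcome Column to compare (default `"mean_cpm"`).
#' @param modes Day modes to include (default walk and car).
#' @return A [compare_groups()] result.
#' @export
day_level_comparison <- function(labelled_days, outcome = "mean_cpm",
                                 modes = c("walk", "car")) {
  d <- labelled_days[labelled_days$valid &
                       labelled_days$day_type == "weekday" &
                       !is.na(labelled_days$day_mode) &
                       labelled_days$day_mode %in% modes, ]
  present <- unique(d$day_mode)
  if (!all(modes %in% present)) {
    abort(sprintf("no days for mode(s): %s",
                  paste(setdiff(modes, present), collapse = ", ")),
          class = "commutePA_input_error")
  }
  compare_groups(d[[outcome]], d$day_mode)
}
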