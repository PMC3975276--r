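# Travel-diary processing and participant classification into usual
# commute modes, with the standard inclusion/exclusion rules.

diary_modes <- c("walk", "car", "cycle", "other", "missing")

#' Classify one diary day's travel mode
#'
#' A day contributes a mode only when the participant reported the same
#' non-missing mode both to and from work; any disagreement or missing
#' direction excludes the day (`NA`).
#'
#' @param mode_to_work,mode_from_work Character vectors over
#'   `walk, car, cycle, other, missing`.
#' @return Character vector: the shared mode, or `NA` for excluded days.
#' @export
#' @examples
#' classify_day("walk", "walk")  # "walk"
#' classify_day("walk", "car")   # NA: mixed day, excluded
classify_day <- function(mode_to_work, mode_from_work) {
  bad <- !(mode_to_work %in% diary_modes) | !(mode_from_work %in% diary_modes)
  if (any(bad, na.rm = TRUE)) {
    abort("unknown diary mode; expected walk/car/cycle/other/missing",
          class = "commutePA_input_error")
  }
  ifelse(!is.na(mode_to_work) & !is.na(mode_from_work) &
           mode_to_work == mode_from_work & mode_to_work != "missing",
         mode_to_work, NA_character_)
}

#' Determine a participant's usual travel mode
#'
#' The mode used on the most included diary days (same mode both ways) wins.
#' With no included diary days the baseline questionnaire mode is used; with
#' neither, the participant is unclassifiable. A tie between modes has no
#' majority and maps to `mixed_other`. Days whose shared mode is neither
#' walk, car nor cycle also count towards `mixed_other`. Only usual walkers
#' and usual drivers enter the analysis; cyclists are excluded because
#' waist-worn accelerometers cannot record cycling reliably, and
#' mixed/other likewise.
#'
#' @param entries Diary tibble for one participant (`mode_to_work`,
#'   `mode_from_work`).
#' @param questionnaire_mode Optional fallback mode from the baseline
#'   questionnaire (`"missing"`/`NA` when unavailable).
#' @return One of `"walk"`, `"car"`, `"cycle"`, `"mixed_other"`,
#'   `"unclassifiable"`.
#' @export
classify_usual_mode <- function(entries, questionnaire_mode = NA_character_) {
  day_modes <- classify_day(entries$mode_to_work, entries$mode_from_work)
  day_modes <- day_modes[!is.na(day_modes)]
  if (length(day_modes) == 0) {
    q <- questionnaire_mode
    if (is.null(q) || is.na(q) || q == "missing") return("unclassifiable")
    if (q %in% c("walk", "car", "cycle")) return(q)
    return("mixed_other")
  }
  day_modes[!day_modes %in% c("walk", "car", "cycle")] <- "mixed_other"
  counts <- table(day_modes)
  winners <- names(counts)[counts == max(counts)]
  if (length(winners) > 1) {
    inform("diary mode tie: no strict majority, classified mixed_other")
    return("mixed_other")
  }
  winners
}

#' Build the analysis cohort with a participant-flow report
#'
#' Classifies every participant's usual mode from their diary (with the
#' questionnaire fallback), then retains usual walkers and usual drivers who
#' have at least one valid accelerometer day. Returns the analysis set
#' together with a flow report whose exclusion bins partition the input:
#' `classified = analysed + excluded_cycle + excluded_mixed_other +
#' excluded_unclassifiable + excluded_no_valid_days`.
#'
#' @param diary Cohort diary tibble (`participant_id`, `date`,
#'   `mode_to_work`, `mode_from_work`).
#' @param demographics Demographics tibble with `participant_id` and
#'   optionally `questionnaire_mode`.
#' @param day_summaries Day summaries from [summarise_days()].
#' @return List with `participants` (all, with `usual_mode`,
#'   `included_in_analysis`), `analysis_set` (included participants joined
#'   to demographics) and `flow` (named counts).
#' @export
build_analysis_set <- function(diary, demographics, day_summaries) {
  ids <- unique(demographics$participant_id)
  usual <- purrr::map_chr(ids, function(pid) {
    e <- diary[diary$participant_id == pid, ]
    q <- if ("questionnaire_mode" %in% names(demographics)) {
      demographics$questionnaire_mode[demographics$participant_id == pid][1]
    } else NA_character_
    classify_usual_mode(e, q)
  })
  n_valid <- purrr::map_int(ids, function(pid) {
    sum(day_summaries$valid[day_summaries$participant_id == pid])
  })
  participants <- tibble(
    participant_id = ids,
    usual_mode = usual,
    n_valid_days = n_valid,
    included_in_analysis = usual %in% c("walk", "car") & n_valid > 0
  )
  flow <- c(
    classified = length(ids),
    excluded_cycle = sum(usual == "cycle"),
    excluded_mixed_other = sum(usual == "mixed_other"),
    excluded_unclassifiable = sum(usual == "unclassifiable"),
    excluded_no_valid_days = sum(usual %in% c("walk", "car") & n_valid == 0),
    analysed = sum(participants$included_in_analysis)
  )
  if (flow[["analysed"]] == 0) {
    abort("analysis cohort is empty after exclusions",
          class = "commutePA_input_error")
  }
  list(
    participants = participants,
    analysis_set = dplyr::inner_join(
      participants[participants$included_in_analysis, ],
      demographics, by = "participant_id"),
    flow = flow
  )
}

#' Label each diary day by its travel mode
#'
#' Helper for the day-level walking-days versus car-days comparison: joins
#' day summaries to their diary day mode (same mode both ways).
#'
#' @param day_summaries Day summaries from [summarise_days()].
#' @param diary Cohort diary tibble.
#' @return Day summaries with a `day_mode` column; days without a shared
#'   diary mode get `NA`.
#' @export
label_days_by_mode <- function(day_summaries, diary) {
  d <- diary
  d$day_mode <- classify_day(d$mode_to_work, d$mode_from_work)
  dplyr::left_join(day_summaries,
                   d[, c("participant_id", "date", "day_mode")],
                   by = c("participant_id", "date"))
}
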