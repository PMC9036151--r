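#' Trial-status and completion-date distribution
#'
#' For each group (regulator, or calendar year of record entry) counts the
#' protocols in each status class and, within the completed set
#' (`Completed` or `Prematurely Ended`), how many carry the global
#' completion date that end-of-trial paperwork should have produced.
#' The completion date that appears inside a results record is ignored by
#' design: it exists only for reported trials and is not tied to the
#' official end-of-trial filing.
#'
#' Zero-protocol trial records (visible only through their results) carry
#' no status fields and do not contribute rows.
#'
#' @param x a [registry].
#' @param by grouping key: `"regulator"` or `"entry_year"` (calendar year
#'   of `date_first_entered`).
#' @return tibble with one row per group: `n_protocols`, `n_completed`,
#'   `n_completed_with_date`, `n_completed_without_date`, `n_ongoing`,
#'   `n_other`, `pct_completed`, `pct_with_date` (share of completed
#'   protocols carrying a date).
#' @export
completion_summary <- function(x, by = c("regulator", "entry_year")) {
  stopifnot(is_registry(x))
  by <- match.arg(by)
  p <- x$protocols |>
    dplyr::mutate(group = if (by == "regulator") .data$regulator_id else
      as.integer(format(.data$date_first_entered, "%Y")))
  p |>
    dplyr::group_by(group = .data$group) |>
    dplyr::summarise(
      n_protocols = dplyr::n(),
      n_completed = sum(.data$trial_status %in% completed_statuses()),
      n_completed_with_date = sum(.data$trial_status %in% completed_statuses() &
                                    !is.na(.data$global_completion_date)),
      n_ongoing = sum(.data$trial_status == "Ongoing"),
      n_other = sum(.data$trial_status == "Other"),
      .groups = "drop") |>
    dplyr::mutate(
      n_completed_without_date = .data$n_completed - .data$n_completed_with_date,
      pct_completed = format_pct(.data$n_completed, .data$n_protocols),
      pct_with_date = format_pct(.data$n_completed_with_date, .data$n_completed)) |>
    dplyr::relocate("n_completed_without_date", .after = "n_completed_with_date") |>
    dplyr::arrange(.data$group)
}

#' Cross-protocol status conflicts
#'
#' A multi-protocol trial whose country protocols simultaneously show a
#' completed-set status and an `Ongoing` status reports contradictory
#' completion information: the global end of a trial is a single event.
#' `Other` statuses never create a conflict by themselves, and two
#' completed-set statuses (`Completed` beside `Prematurely Ended`) agree
#' that the trial is over.
#'
#' @param x a [registry].
#' @return list with `findings` (tibble, one row per multi-protocol trial:
#'   `trial_id`, `n_protocols`, `statuses` — sorted, comma-joined unique
#'   statuses — `has_conflict`), `n_multi`, `n_conflicted`,
#'   `pct_conflicted`.
#' @export
status_conflicts <- function(x) {
  stopifnot(is_registry(x))
  findings <- x$protocols |>
    dplyr::group_by(trial_id = .data$trial_id) |>
    dplyr::summarise(
      n_protocols = dplyr::n(),
      statuses = paste(sort(unique(.data$trial_status)), collapse = ", "),
      has_conflict = any(.data$trial_status %in% completed_statuses()) &&
        any(.data$trial_status == "Ongoing"),
      .groups = "drop") |>
    dplyr::filter(.data$n_protocols >= 2)
  list(findings = findings,
       n_multi = nrow(findings),
       n_conflicted = sum(findings$has_conflict),
       pct_conflicted = format_pct(sum(findings$has_conflict), nrow(findings)))
}

#' Stale single-protocol trials
#'
#' Among trials with exactly one protocol entered before `cutoff_year`,
#' the count and share still marked `Ongoing` at the census. Trials that
#' genuinely run for many years exist, but at the population level an
#' `Ongoing` status on an old single-protocol record most often means the
#' completion paperwork never reached the public registry.
#'
#' @param x a [registry].
#' @param cutoff_year entry years strictly before this are counted.
#' @return list with `n_stale`, `n_eligible`, `pct_stale` (`NA` when no
#'   trial qualifies).
#' @export
stale_ongoing <- function(x, cutoff_year = 2015) {
  stopifnot(is_registry(x))
  single <- x$protocols |>
    dplyr::group_by(.data$trial_id) |>
    dplyr::filter(dplyr::n() == 1) |>
    dplyr::ungroup() |>
    dplyr::filter(as.integer(format(.data$date_first_entered, "%Y")) < cutoff_year)
  list(n_stale = sum(single$trial_status == "Ongoing"),
       n_eligible = nrow(single),
       pct_stale = format_pct(sum(single$trial_status == "Ongoing"),
                              nrow(single)))
}

#' Global completion-date consistency across protocols
#'
#' The global completion date is a property of the whole trial, so every
#' protocol of a multi-protocol trial should record the same date. Over
#' the denominator of multi-protocol trials with at least one global
#' completion date, a trial is consistent when:
#'
#' * `rule = "strict"` (default) — every protocol carries a date and all
#'   dates are equal;
#' * `rule = "lenient"` — all dates that are present agree, absences
#'   ignored.
#'
#' @param x a [registry].
#' @param rule consistency rule.
#' @return list with `findings` (tibble: `trial_id`, `n_protocols`,
#'   `n_dates`, `n_distinct_dates`, `consistent`), `n_trials`,
#'   `n_consistent`, `pct_consistent`.
#' @export
completion_date_consistency <- function(x, rule = c("strict", "lenient")) {
  stopifnot(is_registry(x))
  rule <- match.arg(rule)
  findings <- x$protocols |>
    dplyr::group_by(trial_id = .data$trial_id) |>
    dplyr::summarise(
      n_protocols = dplyr::n(),
      n_dates = sum(!is.na(.data$global_completion_date)),
      n_distinct_dates = dplyr::n_distinct(
        .data$global_completion_date[!is.na(.data$global_completion_date)]),
      .groups = "drop") |>
    dplyr::filter(.data$n_protocols >= 2, .data$n_dates >= 1) |>
    dplyr::mutate(consistent = if (rule == "strict") {
      .data$n_dates == .data$n_protocols & .data$n_distinct_dates == 1
    } else {
      .data$n_distinct_dates == 1
    })
  list(findings = findings,
       n_trials = nrow(findings),
       n_consistent = sum(findings$consistent),
       pct_consistent = format_pct(sum(findings$consistent), nrow(findings)),
       rule = rule)
}
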