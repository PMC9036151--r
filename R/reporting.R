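#' Partition trials by protocol count
#'
#' Results are posted at trial level, so for a trial registered in exactly
#' one country the follow-up duty sits with a single regulator, while
#' multi-country trials share that duty. This partition underlies all
#' reporting-rate analyses.
#'
#' Trials with zero visible protocols (reachable only through a results
#' record) belong to neither set — no regulator can be attributed — and
#' are excluded here; their count is returned for reconciliation.
#'
#' @param x a [registry].
#' @return list with `trials` (tibble: `trial_id`, `n_protocols`,
#'   `protocol_group` `"single"`/`"multi"`, `regulator_id` — the sole
#'   regulator for single-protocol trials, `NA` otherwise — `entry_year`
#'   — calendar year of the earliest protocol entry — `all_completed`,
#'   `has_results`) and `n_no_protocol`.
#' @export
partition_trials <- function(x) {
  stopifnot(is_registry(x))
  trials <- x$protocols |>
    dplyr::group_by(trial_id = .data$trial_id) |>
    dplyr::summarise(
      n_protocols = dplyr::n(),
      regulator_id = dplyr::if_else(dplyr::n() == 1,
                                    .data$regulator_id[1], NA_character_),
      entry_year = as.integer(format(min_or_na(.data$date_first_entered), "%Y")),
      all_completed = all(.data$trial_status %in% completed_statuses()),
      .groups = "drop") |>
    dplyr::mutate(
      protocol_group = dplyr::if_else(.data$n_protocols == 1, "single", "multi"),
      has_results = .data$trial_id %in% x$results$trial_id) |>
    dplyr::relocate("protocol_group", .after = "n_protocols")
  n_no_protocol <- length(setdiff(x$results$trial_id, trials$trial_id))
  list(trials = trials, n_no_protocol = n_no_protocol)
}

#' Results-reporting rates
#'
#' A trial counts as reported when it carries a results record (the
#' registry's results-link analogue), naive to whether the trial is due:
#' no completion criterion is applied unless `completed_only = TRUE`,
#' which restricts to trials whose protocols are all in the completed set.
#'
#' Grouping:
#' * `by = "overall"` — one row per protocol group (single / multi).
#' * `by = "entry_year"` — single and multi rows per trial entry year
#'   (year of the earliest protocol entry).
#' * `by = "regulator"` — single-protocol trials only, attributed to their
#'   sole regulator. Asking for a per-regulator breakdown of
#'   multi-protocol trials is an error: responsibility is shared and no
#'   single attribution exists — use the trial-level table from
#'   [partition_trials()] instead.
#'
#' @param x a [registry].
#' @param by grouping key.
#' @param subset `"both"`, `"single"` or `"multi"`.
#' @param completed_only restrict to all-completed trials.
#' @param min_group groups with fewer trials than this are flagged
#'   `small_group = TRUE` (kept in the data; suppress at presentation).
#' @return tibble with `protocol_group`, the grouping column, `n_trials`,
#'   `n_reported`, `pct_reported`, `small_group`.
#' @export
reporting_summary <- function(x, by = c("overall", "regulator", "entry_year"),
                              subset = c("both", "single", "multi"),
                              completed_only = FALSE, min_group = 20) {
  stopifnot(is_registry(x))
  by <- match.arg(by)
  subset <- match.arg(subset)
  t <- partition_trials(x)$trials
  if (subset != "both") t <- t |> dplyr::filter(.data$protocol_group == subset)
  if (by == "regulator" && any(t$protocol_group == "multi")) {
    stop(paste("per-regulator reporting rates are only defined for",
               "single-protocol trials; multi-protocol responsibility is",
               "shared across regulators. Use subset = \"single\", or the",
               "trial-level table from partition_trials()."), call. = FALSE)
  }
  if (completed_only) t <- t |> dplyr::filter(.data$all_completed)
  keys <- switch(by,
                 overall = "protocol_group",
                 regulator = c("protocol_group", "regulator_id"),
                 entry_year = c("protocol_group", "entry_year"))
  t |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(n_trials = dplyr::n(),
                     n_reported = sum(.data$has_results), .groups = "drop") |>
    dplyr::mutate(pct_reported = format_pct(.data$n_reported, .data$n_trials),
                  small_group = .data$n_trials < min_group) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(keys)))
}
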