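#' Restrict a snapshot to the analyzable study population
#'
#' Drops the protocols outside the EU/EEA regulatory system (`is_eea =
#' FALSE`, the non-EU applications attached to certain paediatric trials:
#' they have no responsible national regulator and omit completion detail
#' by design) and then drops any trial that loses all of its protocols to
#' that removal. Phase-1 healthy-volunteer trials never reach the public
#' registry, so no filter is needed for them — they must not appear in the
#' input by construction.
#'
#' A trial that already had zero protocols on ingest but carries a results
#' record is retained: its record is reachable through its results, and
#' the availability stage uses exactly those trials to detect missing
#' protocols.
#'
#' @param x a [registry].
#' @param quiet suppress the removal-count message.
#' @return the filtered [registry], with attribute `removed`, a list of
#'   `n_protocols` and `n_trials` removed.
#' @export
filter_study_population <- function(x, quiet = TRUE) {
  stopifnot(is_registry(x))
  had_protocols <- unique(x$protocols$trial_id)
  keep <- x$protocols |> dplyr::filter(.data$is_eea)
  survivors <- unique(keep$trial_id)
  dropped_trials <- setdiff(had_protocols, survivors)

  results <- x$results |>
    dplyr::filter(!.data$trial_id %in% dropped_trials)
  enrolment <- x$enrolment |>
    dplyr::filter(!.data$trial_id %in% dropped_trials)

  out <- registry(keep, results, enrolment, x$regulators, x$census_date,
                  validate = FALSE)
  removed <- list(n_protocols = nrow(x$protocols) - nrow(keep),
                  n_trials = n_trials(x) - n_trials(out))
  if (!quiet) {
    message(sprintf("study population filter: removed %d protocols, %d trials",
                    removed$n_protocols, removed$n_trials))
  }
  attr(out, "removed") <- removed
  out
}

#' Earliest record-entry date per regulator or country
#'
#' The first date each regulator ever entered a record is the evidence
#' that a working link between that regulator and the registry backend
#' existed: the expected-protocol rule only expects a protocol from a
#' country for trials starting after that date. When the reference table
#' carried by the registry supplies a date (a full-registry figure), it
#' wins over the snapshot minimum, since a partial snapshot can only
#' overestimate the true earliest date; set `use_reference = FALSE` to use
#' the snapshot alone.
#'
#' With `by = "country"` the two German regulators collapse to the earlier
#' of their dates, the granularity at which tabular results name enrolment
#' locations.
#'
#' @param x a [registry].
#' @param by aggregation unit.
#' @param use_reference prefer reference dates where available.
#' @return named `Date` vector keyed by regulator id or country code.
#'   Regulators with no protocols and no reference date are excluded with
#'   a warning.
#' @export
earliest_entry_dates <- function(x, by = c("regulator", "country"),
                                 use_reference = TRUE) {
  stopifnot(is_registry(x))
  by <- match.arg(by)
  observed <- x$protocols |>
    dplyr::group_by(.data$regulator_id) |>
    dplyr::summarise(observed = min_or_na(.data$date_first_entered),
                     .groups = "drop")
  tab <- x$regulators |>
    dplyr::select("regulator_id", "country", reference = "earliest_record_date") |>
    dplyr::full_join(observed, by = "regulator_id")
  tab$earliest <- if (use_reference) {
    pmin(tab$reference, tab$observed, na.rm = TRUE)
  } else {
    dplyr::coalesce(tab$observed, tab$reference)
  }
  empty <- tab$regulator_id[is.na(tab$earliest)]
  if (length(empty)) {
    warning("no entry date known for regulator(s), excluded: ",
            paste(empty, collapse = ", "), call. = FALSE)
    tab <- tab[!is.na(tab$earliest), ]
  }
  if (by == "regulator") {
    setNames(tab$earliest, tab$regulator_id)
  } else {
    ctab <- tab |>
      dplyr::group_by(.data$country) |>
      dplyr::summarise(earliest = min_or_na(.data$earliest), .groups = "drop")
    setNames(ctab$earliest, ctab$country)
  }
}
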