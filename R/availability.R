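#' Expected-versus-available protocol findings
#'
#' Every EU/EEA country with confirmed enrolment in a trial's tabular
#' results should hold a public country protocol for that trial. This
#' operation emits one finding per (trial, enrolment country) pair over
#' all trials with tabular results:
#'
#' * `eligibility_reason` — `"eligible"` when the trial start date (taken
#'   from the tabular results) is strictly after the country's earliest
#'   record-entry date; `"start-before-link-date"` when it is not (the
#'   country could not have entered a record yet — boundary equality
#'   counts as ineligible); `"no-link-date"` for enrolment countries
#'   absent from `link_dates` (typically non-EU/EEA locations).
#' * `expected` — `TRUE` only for eligible pairs.
#' * `available` — a protocol for that country exists on the trial
#'   (matched at country level: tabular results name countries, not
#'   regulators, so either German regulator satisfies `DE`).
#'
#' Only `expected` pairs enter any denominator downstream; ineligible
#' findings are retained for audit but never counted.
#'
#' @param x a [registry] (typically already filtered with
#'   [filter_study_population()]).
#' @param link_dates named `Date` vector keyed by country; defaults to
#'   [earliest_entry_dates()]`(x, by = "country")`.
#' @param require_enrolment if `TRUE`, countries listed with a zero
#'   participant count are ignored; by default a listed country counts as
#'   an enrolment location regardless of its count.
#' @return tibble with columns `trial_id`, `country`, `enrolment`,
#'   `eligibility_reason`, `expected`, `available`.
#' @export
expected_countries <- function(x, link_dates = NULL, require_enrolment = FALSE) {
  stopifnot(is_registry(x))
  link_dates <- link_dates %||% earliest_entry_dates(x, by = "country")
  tab <- x$results |>
    dplyr::filter(.data$format == "tabular") |>
    dplyr::select("trial_id", "trial_start_date")
  f <- x$enrolment |>
    dplyr::inner_join(tab, by = "trial_id")
  if (require_enrolment) f <- f |> dplyr::filter(.data$enrolment > 0)
  have <- x$protocols |>
    dplyr::distinct(.data$trial_id, .data$country) |>
    dplyr::mutate(available = TRUE)
  f |>
    dplyr::mutate(link_date = unname(.env$link_dates[.data$country])) |>
    dplyr::left_join(have, by = c("trial_id", "country")) |>
    dplyr::mutate(
      available = dplyr::coalesce(.data$available, FALSE),
      eligibility_reason = dplyr::case_when(
        is.na(.data$link_date) ~ "no-link-date",
        .data$trial_start_date > .data$link_date ~ "eligible",
        TRUE ~ "start-before-link-date"),
      expected = .data$eligibility_reason == "eligible") |>
    dplyr::select("trial_id", "country", "enrolment", "eligibility_reason",
                  "expected", "available") |>
    dplyr::arrange(.data$trial_id, .data$country)
}

#' Per-country protocol availability summary
#'
#' Aggregates [expected_countries()] into the audit's headline table: per
#' country, the number of protocols expected (from tabular-results
#' enrolment), available, and missing, with the availability percentage;
#' plus an overall total and the number of enrolled participants covered
#' by the missing protocols.
#'
#' @inheritParams expected_countries
#' @return object of class `availability_summary`: a list with
#'   `by_country` (tibble: `country`, `n_expected`, `n_available`,
#'   `n_missing`, `pct_available`), `total` (one-row tibble of the same
#'   shape), and `missing_participants`.
#' @export
availability_summary <- function(x, link_dates = NULL,
                                 require_enrolment = FALSE) {
  f <- expected_countries(x, link_dates, require_enrolment) |>
    dplyr::filter(.data$expected)
  by_country <- f |>
    dplyr::group_by(country = .data$country) |>
    dplyr::summarise(
      n_expected = dplyr::n(),
      n_available = sum(.data$available),
      n_missing = sum(!.data$available),
      .groups = "drop") |>
    dplyr::mutate(pct_available = format_pct(.data$n_available, .data$n_expected)) |>
    dplyr::arrange(.data$country)
  total <- tibble::tibble(
    country = "(all)",
    n_expected = nrow(f),
    n_available = sum(f$available),
    n_missing = sum(!f$available),
    pct_available = format_pct(sum(f$available), nrow(f)))
  structure(
    list(by_country = by_country, total = total,
         missing_participants = sum(f$enrolment[!f$available], na.rm = TRUE)),
    class = "availability_summary")
}

#' @export
print.availability_summary <- function(x, ...) {
  cat(sprintf("<availability_summary> %d expected, %d available (%s%%), %d missing (%s participants)\n",
              x$total$n_expected, x$total$n_available,
              format(x$total$pct_available), x$total$n_missing,
              format(x$missing_participants, big.mark = ",")))
  print(x$by_country, n = Inf)
  invisible(x)
}

#' Share of missing protocols concentrated in the top-k countries
#'
#' How concentrated is the missing-protocol problem? Returns the fraction
#' of all missing protocols attributable to the `k` countries with the
#' most missing protocols (ties broken by country code, ascending).
#'
#' @param summary an [availability_summary()].
#' @param k number of countries.
#' @return list with `countries`, `n_missing_top`, `n_missing_total`, and
#'   `share` (proportion in \[0, 1\]; `NaN` when nothing is missing).
#' @export
top_missing_share <- function(summary, k = 3) {
  stopifnot(inherits(summary, "availability_summary"))
  bc <- summary$by_country
  if (k > nrow(bc)) {
    stop(sprintf("k = %d exceeds the %d countries in the summary", k, nrow(bc)),
         call. = FALSE)
  }
  top <- bc |>
    dplyr::arrange(dplyr::desc(.data$n_missing), .data$country) |>
    head(k)
  list(countries = top$country,
       n_missing_top = sum(top$n_missing),
       n_missing_total = sum(bc$n_missing),
       share = sum(top$n_missing) / sum(bc$n_missing))
}

#' Registration trend per regulator
#'
#' Counts new protocols per regulator by the calendar year the record was
#' first entered, with the cumulative series alongside. The year grid per
#' regulator runs from its first active year to the last year seen in the
#' registry, so gap years appear with zero new protocols. Partial
#' first/last calendar years are a presentation concern: restrict with
#' `years` at the reporting layer, computation always covers everything.
#'
#' @param x a [registry].
#' @param years optional inclusive `c(first, last)` year window applied to
#'   the returned table.
#' @return tibble with `regulator_id`, `year`, `n_new`, `n_cumulative`.
#' @export
registration_trend <- function(x, years = NULL) {
  stopifnot(is_registry(x))
  if (!nrow(x$protocols)) {
    return(tibble::tibble(regulator_id = character(), year = integer(),
                          n_new = integer(), n_cumulative = integer()))
  }
  counts <- x$protocols |>
    dplyr::mutate(year = as.integer(format(.data$date_first_entered, "%Y"))) |>
    dplyr::count(.data$regulator_id, .data$year, name = "n_new")
  last_year <- max(counts$year)
  out <- counts |>
    dplyr::group_by(.data$regulator_id) |>
    tidyr::complete(year = tidyr::full_seq(c(min(.data$year), last_year), 1),
                    fill = list(n_new = 0L)) |>
    dplyr::arrange(.data$year, .by_group = TRUE) |>
    dplyr::mutate(n_cumulative = cumsum(.data$n_new)) |>
    dplyr::ungroup() |>
    dplyr::mutate(year = as.integer(.data$year))
  if (!is.null(years)) {
    out <- out |> dplyr::filter(.data$year >= years[1], .data$year <= years[2])
  }
  out
}
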