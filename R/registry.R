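#' Trial status vocabulary
#'
#' The audit collapses the registry's raw status strings to four classes.
#' `completed_statuses()` returns the "completed set": the two statuses
#' that signal a finished trial (whether it ran to term or stopped early).
#'
#' @return character vector of canonical status labels.
#' @export
trial_statuses <- function() c("Ongoing", "Completed", "Prematurely Ended", "Other")

#' @rdname trial_statuses
#' @export
completed_statuses <- function() c("Completed", "Prematurely Ended")

# Raw-string -> canonical status. Keys are lower-cased, whitespace-squeezed.
# Registry status strings vary across record vintages; anything unknown maps
# to "Other" with a warning, never an error.
.status_lookup <- c(
  "ongoing"                      = "Ongoing",
  "restarted"                    = "Ongoing",
  "completed"                    = "Completed",
  "prematurely ended"            = "Prematurely Ended",
  "premature ended"              = "Prematurely Ended",
  "temporarily halted"           = "Other",
  "suspended by ca"              = "Other",
  "not authorised"               = "Other",
  "prohibited by ca"             = "Other",
  "trial now transitioned"       = "Other",
  "gb - no longer in eu/eea"     = "Other",
  "other"                        = "Other"
)

#' Normalise raw trial-status strings
#'
#' Case-insensitive lookup into a documented vocabulary table; unknown
#' strings map to `"Other"` with one warning listing them.
#'
#' @param x character vector of raw status strings.
#' @param quiet suppress the unknown-string warning.
#' @return character vector over [trial_statuses()].
#' @export
#' @examples
#' normalize_status(c("ONGOING", "Prematurely Ended", "Temporarily Halted"))
normalize_status <- function(x, quiet = FALSE) {
  key <- tolower(trimws(gsub("\\s+", " ", as.character(x))))
  out <- unname(.status_lookup[key])
  unknown <- is.na(out) & !is.na(x)
  if (any(unknown)) {
    if (!quiet) {
      warning("unknown trial status string(s) mapped to 'Other': ",
              paste(unique(x[unknown]), collapse = ", "), call. = FALSE)
    }
    out[unknown] <- "Other"
  }
  out
}

.trial_id_pattern <- "^[0-9]{4}-[0-9]{6}-[0-9]{2}$"

empty_protocols <- function() {
  tibble::tibble(
    trial_id = character(), country = character(), regulator_id = character(),
    date_first_entered = as.Date(character()), trial_status = character(),
    global_completion_date = as.Date(character()), is_eea = logical()
  )
}

empty_results <- function() {
  tibble::tibble(
    trial_id = character(), format = character(),
    trial_start_date = as.Date(character()), has_results = logical()
  )
}

empty_enrolment <- function() {
  tibble::tibble(trial_id = character(), country = character(),
                 enrolment = integer())
}

#' Construct a registry snapshot object
#'
#' A `registry` is a census-dated snapshot held as four tidy tables:
#'
#' * `protocols` — one row per country-level clinical trial application:
#'   `trial_id` (pattern `YYYY-NNNNNN-CC`), `country`, `regulator_id`,
#'   `date_first_entered`, `trial_status`, `global_completion_date`
#'   (`NA` when absent), `is_eea` (`FALSE` marks the "Outside EU/EEA"
#'   protocols attached to certain paediatric trials).
#' * `results` — one row per trial carrying a results record: `format`
#'   (`"tabular"` or `"document-only"`), `trial_start_date`, `has_results`.
#' * `enrolment` — per-country participant counts from tabular results.
#' * `regulators` — one row per national competent authority (see
#'   [euctr_regulators()]).
#'
#' @param protocols,results,enrolment,regulators data frames as above;
#'   `results`/`enrolment` may be omitted for protocol-only snapshots.
#' @param census_date snapshot date; defaults to the latest date present.
#' @param validate run invariant checks (duplicate protocols, identifier
#'   pattern, dates not after the census).
#' @return an object of class `registry`.
#' @export
registry <- function(protocols, results = NULL, enrolment = NULL,
                     regulators = NULL, census_date = NULL, validate = TRUE) {
  protocols <- tibble::as_tibble(protocols %||% empty_protocols())
  results <- tibble::as_tibble(results %||% empty_results())
  enrolment <- tibble::as_tibble(enrolment %||% empty_enrolment())

  if (!"global_completion_date" %in% names(protocols)) {
    protocols$global_completion_date <- as.Date(NA)
  }
  if (!"is_eea" %in% names(protocols)) protocols$is_eea <- TRUE
  if (nrow(results) && !"has_results" %in% names(results)) {
    results$has_results <- TRUE
  }
  protocols$trial_status <- normalize_status(protocols$trial_status)

  if (is.null(regulators)) {
    regulators <- euctr_regulators() |>
      dplyr::filter(.data$regulator_id %in% unique(protocols$regulator_id))
    unseen <- setdiff(unique(protocols$regulator_id), regulators$regulator_id)
    if (length(unseen)) {
      extra <- protocols |>
        dplyr::filter(.data$regulator_id %in% unseen) |>
        dplyr::group_by(.data$regulator_id, .data$country) |>
        dplyr::summarise(
          earliest_record_date = min_or_na(.data$date_first_entered),
          .groups = "drop") |>
        dplyr::mutate(name = .data$regulator_id, n_protocols = NA_integer_)
      regulators <- dplyr::bind_rows(regulators, extra)
    }
  }
  regulators <- tibble::as_tibble(regulators)

  dates <- c(protocols$date_first_entered, protocols$global_completion_date,
             results$trial_start_date)
  dates <- dates[!is.na(dates)]
  if (is.null(census_date)) {
    if (!length(dates)) {
      stop("census_date must be supplied for a registry with no dates",
           call. = FALSE)
    }
    census_date <- max(dates)
  }
  census_date <- as.Date(census_date)

  x <- structure(
    list(protocols = protocols, results = results, enrolment = enrolment,
         regulators = regulators, census_date = census_date),
    class = "registry")
  if (validate) check_registry(x)
  x
}

#' @rdname registry
#' @param x object to test or print.
#' @export
is_registry <- function(x) inherits(x, "registry")

# Invariant checks; stop() with the offending records named.
check_registry <- function(x) {
  p <- x$protocols
  bad_id <- unique(c(
    p$trial_id[!grepl(.trial_id_pattern, p$trial_id)],
    x$results$trial_id[!grepl(.trial_id_pattern, x$results$trial_id)]))
  if (length(bad_id)) {
    stop("malformed trial_id (expected YYYY-NNNNNN-CC): ",
         paste(head(bad_id, 5), collapse = ", "), call. = FALSE)
  }
  dup <- p |>
    dplyr::count(.data$trial_id, .data$regulator_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    stop("duplicate protocol for (trial_id, regulator_id): ",
         paste(sprintf("%s/%s", dup$trial_id, dup$regulator_id)[1:min(5, nrow(dup))],
               collapse = ", "), call. = FALSE)
  }
  late <- p$trial_id[!is.na(p$date_first_entered) &
                       p$date_first_entered > x$census_date]
  if (length(late)) {
    stop("date_first_entered after census date for trial(s): ",
         paste(head(unique(late), 5), collapse = ", "), call. = FALSE)
  }
  if (nrow(x$enrolment) && any(x$enrolment$enrolment < 0, na.rm = TRUE)) {
    stop("negative enrolment count", call. = FALSE)
  }
  missing_reg <- setdiff(unique(p$regulator_id), x$regulators$regulator_id)
  if (length(missing_reg)) {
    stop("protocol references unknown regulator_id: ",
         paste(missing_reg, collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

#' @rdname registry
#' @export
n_trials <- function(x) {
  stopifnot(is_registry(x))
  length(union(x$protocols$trial_id, x$results$trial_id))
}

#' @param ... ignored.
#' @rdname registry
#' @export
print.registry <- function(x, ...) {
  cat(sprintf("<registry> census %s\n", format(x$census_date)))
  cat(sprintf("  %d trials, %d protocols, %d regulators, %d with results\n",
              n_trials(x), nrow(x$protocols), nrow(x$regulators),
              nrow(x$results)))
  invisible(x)
}
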