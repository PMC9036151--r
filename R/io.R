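#' Read and write registry snapshots
#'
#' Two on-disk dialects carry the same snapshot:
#'
#' * **`jsonl`** — one trial record per line:
#'   ```
#'   {"trial_id": "2010-001234-11",
#'    "protocols": [{"country": "FR", "regulator_id": "ANSM",
#'                   "date_first_entered": "2010-03-01",
#'                   "trial_status": "Ongoing",
#'                   "global_completion_date": null, "is_eea": true}],
#'    "results": {"format": "tabular", "trial_start_date": "2010-05-01",
#'                "enrolment_by_country": {"FR": 50}}}
#'   ```
#'   `results` is `null` for unreported trials; `is_eea` defaults to true;
#'   all dates are ISO-8601 strings; country codes ISO-3166-1 alpha-2.
#' * **`csv`** — a directory holding `protocols.csv` (one row per country
#'   protocol) and `results_enrolment.csv` (one row per enrolment country;
#'   document-only results carry one row with empty country/enrolment),
#'   both keyed by `trial_id`.
#'
#' Malformed lines are reported with their line number; duplicate
#' `(trial_id, regulator_id)` pairs and unparseable dates are errors.
#'
#' @param path file (`jsonl`) or directory (`csv`).
#' @param format snapshot dialect.
#' @param census_date optional override; defaults to the latest date in the
#'   snapshot.
#' @param regulators optional regulator reference table; defaults to
#'   [euctr_regulators()] restricted to the regulators seen.
#' @return [read_registry()]: a [registry]; [write_registry()]: `path`,
#'   invisibly.
#' @export
read_registry <- function(path, format = c("jsonl", "csv"),
                          census_date = NULL, regulators = NULL) {
  format <- match.arg(format)
  if (format == "jsonl") {
    read_registry_jsonl(path, census_date, regulators)
  } else {
    read_registry_csv(path, census_date, regulators)
  }
}

read_registry_jsonl <- function(path, census_date = NULL, regulators = NULL) {
  if (!file.exists(path)) stop("no such snapshot file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  errors <- character()
  prot_acc <- vector("list", length(lines))
  res_acc <- vector("list", length(lines))
  enr_acc <- vector("list", length(lines))

  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
                    error = function(e) e)
    if (inherits(rec, "error")) {
      errors <- c(errors, sprintf("line %d: invalid JSON (%s)", i,
                                  conditionMessage(rec)))
      next
    }
    tid <- rec$trial_id
    if (is.null(tid) || !nzchar(tid)) {
      errors <- c(errors, sprintf("line %d: missing field 'trial_id'", i))
      next
    }
    ps <- rec$protocols %||% list()
    if (length(ps)) {
      get_chr <- function(f, default = NA_character_) {
        vapply(ps, function(p) as.character(p[[f]] %||% default), character(1))
      }
      prot_acc[[i]] <- list(
        trial_id = rep(tid, length(ps)),
        country = get_chr("country"),
        regulator_id = get_chr("regulator_id"),
        date_first_entered = get_chr("date_first_entered"),
        trial_status = get_chr("trial_status"),
        global_completion_date = get_chr("global_completion_date"),
        is_eea = vapply(ps, function(p) isTRUE(p$is_eea %||% TRUE), logical(1)),
        line = rep(i, length(ps))
      )
      miss <- vapply(c("country", "regulator_id", "date_first_entered",
                       "trial_status"),
                     function(f) any(is.na(get_chr(f))), logical(1))
      if (any(miss)) {
        errors <- c(errors, sprintf("line %d: protocol missing field '%s'",
                                    i, names(miss)[miss][1]))
      }
    }
    rs <- rec$results
    if (!is.null(rs)) {
      res_acc[[i]] <- list(
        trial_id = tid,
        format = as.character(rs$format %||% "tabular"),
        trial_start_date = as.character(rs$trial_start_date %||% NA),
        line = i
      )
      enr <- rs$enrolment_by_country %||% list()
      if (length(enr)) {
        enr_acc[[i]] <- list(
          trial_id = rep(tid, length(enr)),
          country = names(enr),
          enrolment = as.integer(unlist(enr, use.names = FALSE))
        )
      }
    }
  }
  if (length(errors)) {
    stop("snapshot failed schema validation:\n  ",
         paste(head(errors, 10), collapse = "\n  "), call. = FALSE)
  }

  pull <- function(acc, f) unlist(lapply(acc, `[[`, f), use.names = FALSE)
  prot_acc <- prot_acc[!vapply(prot_acc, is.null, logical(1))]
  res_acc <- res_acc[!vapply(res_acc, is.null, logical(1))]
  enr_acc <- enr_acc[!vapply(enr_acc, is.null, logical(1))]

  protocols <- if (length(prot_acc)) {
    tibble::tibble(
      trial_id = pull(prot_acc, "trial_id"),
      country = pull(prot_acc, "country"),
      regulator_id = pull(prot_acc, "regulator_id"),
      date_first_entered = parse_iso_date(pull(prot_acc, "date_first_entered"),
                                          "date_first_entered",
                                          pull(prot_acc, "line")),
      trial_status = pull(prot_acc, "trial_status"),
      global_completion_date = parse_iso_date(
        pull(prot_acc, "global_completion_date"), "global_completion_date",
        pull(prot_acc, "line")),
      is_eea = pull(prot_acc, "is_eea")
    )
  } else empty_protocols()

  results <- if (length(res_acc)) {
    tibble::tibble(
      trial_id = pull(res_acc, "trial_id"),
      format = pull(res_acc, "format"),
      trial_start_date = parse_iso_date(pull(res_acc, "trial_start_date"),
                                        "trial_start_date",
                                        pull(res_acc, "line")),
      has_results = TRUE
    )
  } else empty_results()

  enrolment <- if (length(enr_acc)) {
    tibble::tibble(
      trial_id = pull(enr_acc, "trial_id"),
      country = pull(enr_acc, "country"),
      enrolment = pull(enr_acc, "enrolment")
    )
  } else empty_enrolment()

  registry(protocols, results, enrolment, regulators, census_date)
}

read_registry_csv <- function(path, census_date = NULL, regulators = NULL) {
  pfile <- file.path(path, "protocols.csv")
  rfile <- file.path(path, "results_enrolment.csv")
  if (!file.exists(pfile)) stop("no such file: ", pfile, call. = FALSE)
  protocols <- readr::read_csv(
    pfile, na = c("", "NA"), progress = FALSE,
    col_types = readr::cols(
      trial_id = readr::col_character(), country = readr::col_character(),
      regulator_id = readr::col_character(),
      date_first_entered = readr::col_date(),
      trial_status = readr::col_character(),
      global_completion_date = readr::col_date(),
      is_eea = readr::col_logical()))
  results <- empty_results()
  enrolment <- empty_enrolment()
  if (file.exists(rfile)) {
    re <- readr::read_csv(
      rfile, na = c("", "NA"), progress = FALSE,
      col_types = readr::cols(
        trial_id = readr::col_character(), format = readr::col_character(),
        trial_start_date = readr::col_date(),
        country = readr::col_character(),
        enrolment = readr::col_integer()))
    results <- re |>
      dplyr::distinct(.data$trial_id, .data$format, .data$trial_start_date) |>
      dplyr::mutate(has_results = TRUE)
    enrolment <- re |>
      dplyr::filter(!is.na(.data$country)) |>
      dplyr::select("trial_id", "country", "enrolment")
  }
  registry(protocols, results, enrolment, regulators, census_date)
}

#' @rdname read_registry
#' @param x a [registry].
#' @export
write_registry <- function(x, path, format = c("jsonl", "csv")) {
  stopifnot(is_registry(x))
  format <- match.arg(format)
  if (format == "csv") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(x$protocols, file.path(path, "protocols.csv"), na = "")
    re <- x$results |>
      dplyr::left_join(x$enrolment, by = "trial_id") |>
      dplyr::select("trial_id", "format", "trial_start_date", "country",
                    "enrolment")
    readr::write_csv(re, file.path(path, "results_enrolment.csv"), na = "")
    return(invisible(path))
  }

  ids <- sort(union(x$protocols$trial_id, x$results$trial_id))
  prot_split <- split(x$protocols, x$protocols$trial_id)
  res_split <- split(x$results, x$results$trial_id)
  enr_split <- split(x$enrolment, x$enrolment$trial_id)
  fmt_date <- function(d) if (is.na(d)) NULL else format(d, "%Y-%m-%d")
  lines <- vapply(ids, function(tid) {
    p <- prot_split[[tid]]
    protos <- if (is.null(p)) list() else lapply(seq_len(nrow(p)), function(j) {
      list(country = p$country[j], regulator_id = p$regulator_id[j],
           date_first_entered = fmt_date(p$date_first_entered[j]),
           trial_status = p$trial_status[j],
           global_completion_date = fmt_date(p$global_completion_date[j]),
           is_eea = p$is_eea[j])
    })
    r <- res_split[[tid]]
    res <- if (is.null(r)) NULL else {
      e <- enr_split[[tid]]
      list(format = r$format[1],
           trial_start_date = fmt_date(r$trial_start_date[1]),
           enrolment_by_country = if (is.null(e)) NULL else
             as.list(setNames(e$enrolment, e$country)))
    }
    jsonlite::toJSON(list(trial_id = tid, protocols = protos, results = res),
                     auto_unbox = TRUE, null = "null", na = "null", digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Validate a snapshot file without loading it into an audit
#'
#' Runs the full ingest (schema, dates, duplicate protocols) and reports
#' the outcome instead of raising.
#'
#' @inheritParams read_registry
#' @return list with `ok` (logical), `n_trials`, `n_protocols`, and
#'   `message` when invalid.
#' @export
validate_snapshot <- function(path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  out <- tryCatch(read_registry(path, format), error = function(e) e)
  if (inherits(out, "error")) {
    list(ok = FALSE, n_trials = NA_integer_, n_protocols = NA_integer_,
         message = conditionMessage(out))
  } else {
    list(ok = TRUE, n_trials = n_trials(out), n_protocols = nrow(out$protocols),
         message = "")
  }
}
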