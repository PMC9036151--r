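#' Configuration for a full audit run
#'
#' All switches of [run_audit()] with documented defaults. A config
#' round-trips through YAML or JSON via [read_audit_config()] /
#' [write_audit_config()].
#'
#' @param input path to the snapshot (JSONL file or CSV-pair directory).
#' @param format snapshot dialect, `"jsonl"` or `"csv"`.
#' @param out_dir directory receiving the report bundle.
#' @param census_date optional census override (default: latest date in
#'   the snapshot).
#' @param link_date_source `"reference"` uses the regulator reference
#'   table's earliest-record dates where they precede the snapshot
#'   minimum; `"snapshot"` uses snapshot minima only.
#' @param consistency_rule `"strict"` or `"lenient"`, see
#'   [completion_date_consistency()].
#' @param require_enrolment require enrolment > 0 for a listed country to
#'   count as an enrolment location.
#' @param completed_only restrict reporting rates to all-completed trials.
#' @param stale_cutoff_year entry-year cutoff for [stale_ongoing()].
#' @param min_group small-group flag threshold for [reporting_summary()].
#' @param top_k number of countries for the missing-concentration figure.
#' @return list of class `audit_config`.
#' @export
audit_config <- function(input, format = c("jsonl", "csv"), out_dir = "audit_out",
                         census_date = NULL,
                         link_date_source = c("reference", "snapshot"),
                         consistency_rule = c("strict", "lenient"),
                         require_enrolment = FALSE, completed_only = FALSE,
                         stale_cutoff_year = 2015L, min_group = 20L,
                         top_k = 3L) {
  format <- match.arg(format)
  link_date_source <- match.arg(link_date_source)
  consistency_rule <- match.arg(consistency_rule)
  structure(list(
    input = input, format = format, out_dir = out_dir,
    census_date = if (is.null(census_date)) NULL else as.character(census_date),
    link_date_source = link_date_source, consistency_rule = consistency_rule,
    require_enrolment = isTRUE(require_enrolment),
    completed_only = isTRUE(completed_only),
    stale_cutoff_year = as.integer(stale_cutoff_year),
    min_group = as.integer(min_group), top_k = as.integer(top_k)),
    class = "audit_config")
}

#' @rdname audit_config
#' @param path config file ending in `.yaml`, `.yml` or `.json`.
#' @export
read_audit_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(audit_config, raw)
}

#' @rdname audit_config
#' @param config an `audit_config`.
#' @export
write_audit_config <- function(config, path) {
  stopifnot(inherits(config, "audit_config"))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                         null = "null", pretty = TRUE)
  } else {
    yaml::write_yaml(unclass(config), path)
  }
  invisible(path)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("audit stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full registry audit
#'
#' Executes ingest → study-population filter → protocol availability →
#' completion quality → results reporting, then writes the report bundle
#' to `config$out_dir`:
#'
#' * `findings.csv` — one row per expected-protocol finding;
#' * `availability_summary.csv` — per-country availability plus total row;
#' * `registration_trend.csv` — yearly and cumulative new protocols per
#'   regulator;
#' * `completion_summary.csv` — status/date distribution by regulator and
#'   by entry year (stacked, `by` column);
#' * `status_conflicts.csv`, `date_consistency.csv` — per-trial findings;
#' * `reporting_summary.csv` — overall, per-regulator (single-protocol)
#'   and per-entry-year reporting rates (stacked, `by` column);
#' * `summary.json` — machine-readable headline metrics;
#' * `manifest.json` — config echo, input checksum, per-stage row counts.
#'
#' All stages are computed before anything is written, so a failing stage
#' leaves no partial bundle. Identical input and config give byte-identical
#' `summary.json`.
#'
#' @param config an [audit_config()].
#' @param quiet suppress progress messages.
#' @return (invisibly) a list with every stage result and `paths` of the
#'   written files.
#' @export
run_audit <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "audit_config"))
  say <- function(...) if (!quiet) message(sprintf(...))

  say("ingest: %s (%s)", config$input, config$format)
  raw <- run_stage("ingest", read_registry(config$input, config$format,
                                           census_date = config$census_date))
  reg <- run_stage("filter", filter_study_population(raw))
  removed <- attr(reg, "removed")
  say("filter: %d protocols in, %d removed", nrow(raw$protocols),
      removed$n_protocols)

  link_dates <- run_stage("availability", earliest_entry_dates(
    reg, by = "country",
    use_reference = config$link_date_source == "reference"))
  findings <- run_stage("availability", expected_countries(
    reg, link_dates, config$require_enrolment))
  avail <- run_stage("availability", availability_summary(
    reg, link_dates, config$require_enrolment))
  topk <- if (nrow(avail$by_country) >= config$top_k) {
    top_missing_share(avail, config$top_k)
  } else NULL
  trend <- run_stage("availability", registration_trend(reg))

  comp_reg <- run_stage("completion", completion_summary(reg, "regulator"))
  comp_year <- run_stage("completion", completion_summary(reg, "entry_year"))
  conflicts <- run_stage("completion", status_conflicts(reg))
  stale <- run_stage("completion", stale_ongoing(reg, config$stale_cutoff_year))
  consistency <- run_stage("completion", completion_date_consistency(
    reg, config$consistency_rule))

  rep_overall <- run_stage("reporting", reporting_summary(
    reg, "overall", completed_only = config$completed_only,
    min_group = config$min_group))
  rep_regulator <- run_stage("reporting", reporting_summary(
    reg, "regulator", subset = "single",
    completed_only = config$completed_only, min_group = config$min_group))
  rep_year <- run_stage("reporting", reporting_summary(
    reg, "entry_year", completed_only = config$completed_only,
    min_group = config$min_group))
  partition <- partition_trials(reg)

  grab <- function(tab, grp) {
    row <- tab[tab$protocol_group == grp, ]
    if (!nrow(row)) list(n_trials = 0L, n_reported = 0L, pct_reported = NA) else
      list(n_trials = row$n_trials, n_reported = row$n_reported,
           pct_reported = row$pct_reported)
  }
  summary <- list(
    census_date = format(reg$census_date),
    population = list(
      n_trials = n_trials(reg), n_protocols = nrow(reg$protocols),
      n_removed_protocols = removed$n_protocols,
      n_removed_trials = removed$n_trials),
    availability = list(
      n_expected = avail$total$n_expected, n_available = avail$total$n_available,
      n_missing = avail$total$n_missing,
      pct_available = avail$total$pct_available,
      missing_participants = avail$missing_participants,
      top_k = config$top_k,
      top_missing_share_pct = if (is.null(topk)) NA else
        format_pct(topk$n_missing_top, topk$n_missing_total)),
    completion = list(
      n_protocols = sum(comp_reg$n_protocols),
      n_completed = sum(comp_reg$n_completed),
      pct_completed = format_pct(sum(comp_reg$n_completed),
                                 sum(comp_reg$n_protocols)),
      pct_completed_with_date = format_pct(sum(comp_reg$n_completed_with_date),
                                           sum(comp_reg$n_completed)),
      conflicts = conflicts[c("n_multi", "n_conflicted", "pct_conflicted")],
      stale_ongoing = c(list(cutoff_year = config$stale_cutoff_year), stale),
      date_consistency = consistency[c("rule", "n_trials", "n_consistent",
                                       "pct_consistent")]),
    reporting = list(single = grab(rep_overall, "single"),
                     multi = grab(rep_overall, "multi"),
                     n_trials_no_protocol = partition$n_no_protocol))

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  avail_tab <- dplyr::bind_rows(avail$by_country, avail$total)
  comp_tab <- dplyr::bind_rows(
    comp_reg |> dplyr::mutate(by = "regulator", group = as.character(.data$group)),
    comp_year |> dplyr::mutate(by = "entry_year", group = as.character(.data$group))) |>
    dplyr::relocate("by")
  rep_tab <- dplyr::bind_rows(
    rep_overall |> dplyr::mutate(by = "overall"),
    rep_regulator |> dplyr::mutate(by = "regulator"),
    rep_year |> dplyr::mutate(by = "entry_year")) |>
    dplyr::relocate("by")

  readr::write_csv(findings, out("findings.csv"), na = "")
  readr::write_csv(avail_tab, out("availability_summary.csv"), na = "")
  readr::write_csv(trend, out("registration_trend.csv"), na = "")
  readr::write_csv(comp_tab, out("completion_summary.csv"), na = "")
  readr::write_csv(conflicts$findings, out("status_conflicts.csv"), na = "")
  readr::write_csv(consistency$findings, out("date_consistency.csv"), na = "")
  readr::write_csv(rep_tab, out("reporting_summary.csv"), na = "")
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null", pretty = TRUE)

  checksum <- if (config$format == "jsonl") unname(tools::md5sum(config$input))
    else unname(tools::md5sum(file.path(config$input, "protocols.csv")))
  manifest <- list(
    config = unclass(config), input_md5 = checksum,
    rows = list(
      protocols_in = nrow(raw$protocols), protocols_analyzed = nrow(reg$protocols),
      findings = nrow(findings), availability_countries = nrow(avail$by_country),
      trend = nrow(trend), completion_groups = nrow(comp_tab),
      conflict_trials = nrow(conflicts$findings),
      consistency_trials = nrow(consistency$findings),
      reporting_groups = nrow(rep_tab)))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  say("bundle written to %s", config$out_dir)

  invisible(list(
    registry = reg, findings = findings, availability = avail, trend = trend,
    completion_by_regulator = comp_reg, completion_by_year = comp_year,
    conflicts = conflicts, stale = stale, consistency = consistency,
    reporting = rep_tab, summary = summary,
    paths = vapply(c("findings.csv", "availability_summary.csv",
                     "registration_trend.csv", "completion_summary.csv",
                     "status_conflicts.csv", "date_consistency.csv",
                     "reporting_summary.csv", "summary.json", "manifest.json"),
                   out, character(1))))
}

#' Write a synthetic fixture to disk
#'
#' Wraps [generate_registry()] and writes `registry.jsonl`, `ledger.csv`
#' and `generator_config.json` (a config echo) to `out_dir`. Rerunning
#' with the same config produces identical files.
#'
#' @param config a [generator_config()].
#' @param out_dir output directory, created if needed.
#' @return (invisibly) named paths of the three files.
#' @export
generate_fixture <- function(config, out_dir) {
  validate_generator_config(config)
  gen <- generate_registry(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(registry = file.path(out_dir, "registry.jsonl"),
             ledger = file.path(out_dir, "ledger.csv"),
             config = file.path(out_dir, "generator_config.json"))
  write_registry(gen$registry, paths[["registry"]], "jsonl")
  write_ledger(gen$ledger, paths[["ledger"]])
  echo <- unclass(config)
  echo$census_date <- as.character(echo$census_date)
  echo$regulators <- NULL
  jsonlite::write_json(echo, paths[["config"]], auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(paths)
}
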