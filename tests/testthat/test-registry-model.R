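test_that("JSONL ingest preserves trial counts and parses the schema", {
  lines <- c(
    '{"trial_id":"2006-000001-10","protocols":[{"country":"SE","regulator_id":"MPA","date_first_entered":"2006-02-01","trial_status":"Ongoing"}],"results":null}',
    '{"trial_id":"2007-000002-11","protocols":[{"country":"DE","regulator_id":"BfArM","date_first_entered":"2007-05-10","trial_status":"Completed","global_completion_date":"2009-01-31"},{"country":"DE","regulator_id":"PEI","date_first_entered":"2007-05-12","trial_status":"Ongoing"}],"results":{"format":"tabular","trial_start_date":"2007-06-01","enrolment_by_country":{"DE":120,"FR":30}}}',
    '{"trial_id":"2010-000003-12","protocols":[{"country":"FR","regulator_id":"ANSM","date_first_entered":"2010-01-05","trial_status":"Prematurely Ended","is_eea":true}]}')
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(lines, path)
  reg <- read_registry(path)
  expect_s3_class(reg, "registry")
  expect_equal(n_trials(reg), 3)
  expect_equal(nrow(reg$protocols), 4)
  expect_equal(sum(reg$results$has_results), 1)
  expect_equal(sort(reg$enrolment$country), c("DE", "FR"))
  expect_s3_class(reg$protocols$date_first_entered, "Date")
  expect_equal(reg$census_date, as.Date("2010-01-05"))
})

test_that("malformed snapshots fail loudly with line numbers and field names", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"trial_id":"2006-000001-10","protocols":[{"country":"SE","regulator_id":"MPA","date_first_entered":"2006-02-01","trial_status":"Ongoing"}]}',
    'not json at all'), path)
  expect_error(read_registry(path), "line 2")

  writeLines('{"protocols":[]}', path)
  expect_error(read_registry(path), "trial_id")

  writeLines('{"trial_id":"2006-000001-10","protocols":[{"country":"SE","regulator_id":"MPA","date_first_entered":"February 2006","trial_status":"Ongoing"}]}',
             path)
  expect_error(read_registry(path), "date_first_entered")

  # duplicate (trial_id, regulator_id) named in the error
  writeLines('{"trial_id":"2006-000001-10","protocols":[{"country":"SE","regulator_id":"MPA","date_first_entered":"2006-02-01","trial_status":"Ongoing"},{"country":"SE","regulator_id":"MPA","date_first_entered":"2006-03-01","trial_status":"Completed"}]}',
             path)
  expect_error(read_registry(path), "2006-000001-10/MPA")

  # identifier pattern enforced
  expect_error(
    registry(proto("banana", "SE", "MPA", "2006-02-01")),
    "YYYY-NNNNNN-CC")
})

test_that("write -> load round-trips a registry in both dialects", {
  gen <- generate_registry(generator_config(seed = 21, n_trials = 10))
  reg <- gen$registry
  norm <- function(r) {
    list(p = as.data.frame(dplyr::arrange(r$protocols, trial_id, regulator_id)),
         r = as.data.frame(dplyr::arrange(r$results, trial_id)),
         e = as.data.frame(dplyr::arrange(r$enrolment, trial_id, country)),
         census = r$census_date)
  }
  jl <- withr::local_tempfile(fileext = ".jsonl")
  write_registry(reg, jl)
  back <- read_registry(jl, census_date = reg$census_date)
  expect_equal(norm(back), norm(reg), ignore_attr = TRUE)

  dir <- withr::local_tempdir()
  write_registry(reg, dir, format = "csv")
  back2 <- read_registry(dir, format = "csv", census_date = reg$census_date)
  expect_equal(norm(back2), norm(reg), ignore_attr = TRUE)
})

test_that("status strings normalise case-insensitively, unknowns to Other", {
  expect_equal(normalize_status(c("ONGOING", "completed", "Prematurely  Ended")),
               c("Ongoing", "Completed", "Prematurely Ended"))
  expect_warning(out <- normalize_status("Frozen by sponsor"), "Other")
  expect_equal(out, "Other")
  expect_equal(normalize_status("Temporarily Halted"), "Other")
})

test_that("study-population filter removes non-EEA protocols and empty trials", {
  protocols <- dplyr::bind_rows(
    proto("2010-000001-10", "DE", "BfArM", "2010-03-01"),
    proto("2010-000001-10", "XX", "XX-REG", "2010-03-02", is_eea = FALSE),
    proto("2011-000002-11", "YY", "YY-REG", "2011-01-01", is_eea = FALSE))
  reg <- registry(protocols, census_date = "2020-12-01")
  out <- filter_study_population(reg)
  expect_equal(out$protocols$country, "DE")
  expect_equal(n_trials(out), 1)
  removed <- attr(out, "removed")
  expect_equal(removed$n_protocols, 2)
  expect_equal(removed$n_trials, 1)
  # conservation: removed + retained = total
  expect_equal(removed$n_protocols + nrow(out$protocols), nrow(reg$protocols))
  expect_equal(removed$n_trials + n_trials(out), n_trials(reg))
})

test_that("earliest entry dates: minimum, reference fallback, monotonicity", {
  protocols <- dplyr::bind_rows(
    proto("2005-000001-10", "IE", "HPRA", "2005-03-01"),
    proto("2004-000002-11", "IE", "HPRA", "2004-06-18"))
  reg <- registry(protocols, census_date = "2020-12-01")
  expect_equal(unname(earliest_entry_dates(reg, use_reference = FALSE)["HPRA"]),
               as.Date("2004-06-18"))
  # Ireland's reference date coincides with the snapshot minimum
  expect_equal(unname(earliest_entry_dates(reg)["HPRA"]), as.Date("2004-06-18"))

  # reference wins when it precedes the snapshot minimum
  late <- registry(proto("2010-000003-12", "IE", "HPRA", "2010-05-01"),
                   census_date = "2020-12-01")
  expect_equal(unname(earliest_entry_dates(late)["HPRA"]), as.Date("2004-06-18"))
  expect_equal(unname(earliest_entry_dates(late, use_reference = FALSE)["HPRA"]),
               as.Date("2010-05-01"))

  # regulator with no protocols but a reference date falls back to it
  regs <- euctr_regulators()
  full <- registry(proto("2010-000003-12", "IE", "HPRA", "2010-05-01"),
                   regulators = regs, census_date = "2020-12-01")
  expect_equal(unname(suppressWarnings(earliest_entry_dates(full))["ANSM"]),
               as.Date("2005-06-21"))
  # no protocols and no reference date -> excluded with a warning
  expect_warning(ed <- earliest_entry_dates(full), "AG")
  expect_false("AG" %in% names(ed))

  # monotone: adding a protocol can only keep or lower the earliest date
  more <- registry(dplyr::bind_rows(protocols,
                                    proto("2004-000004-13", "IE", "HPRA", "2004-02-01")),
                   census_date = "2020-12-01")
  expect_lte(earliest_entry_dates(more, use_reference = FALSE)["HPRA"],
             earliest_entry_dates(reg, use_reference = FALSE)["HPRA"])
})

test_that("country-level link dates take the earlier of the German regulators", {
  ld <- reference_link_dates()
  expect_equal(unname(ld["DE"]), as.Date("2004-09-10"))
  reg <- registry(proto("2010-000001-10", "DE", "BfArM", "2010-03-01"),
                  regulators = euctr_regulators(), census_date = "2020-12-01")
  expect_equal(unname(suppressWarnings(
    earliest_entry_dates(reg, by = "country"))["DE"]), as.Date("2004-09-10"))
})

test_that("snapshot validation reports instead of raising", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines('{"trial_id":"2006-000001-10","protocols":[{"country":"SE","regulator_id":"MPA","date_first_entered":"2006-02-01","trial_status":"Ongoing"}]}',
             path)
  v <- validate_snapshot(path)
  expect_true(v$ok)
  expect_equal(v$n_trials, 1)
  writeLines("broken", path)
  v2 <- validate_snapshot(path)
  expect_false(v2$ok)
  expect_match(v2$message, "line 1")
})
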