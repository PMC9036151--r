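suppressPackageStartupMessages(library(dplyr))

# One protocol row in the canonical shape.
proto <- function(trial_id, country, regulator_id, entered,
                  status = "Ongoing", completion = NA, is_eea = TRUE) {
  tibble::tibble(
    trial_id = trial_id, country = country, regulator_id = regulator_id,
    date_first_entered = as.Date(entered), trial_status = status,
    global_completion_date = as.Date(completion), is_eea = is_eea)
}

# Registry with one trial: tabular results (start 2010-05-01, enrolment
# FR 50 / DE 80) but only a German protocol registered.
fr_de_registry <- function(start = "2010-05-01", protocols = NULL) {
  protocols <- protocols %||% proto("2010-000001-10", "DE", "BfArM", "2010-03-01")
  registry(
    protocols,
    results = tibble::tibble(trial_id = "2010-000001-10", format = "tabular",
                             trial_start_date = as.Date(start),
                             has_results = TRUE),
    enrolment = tibble::tibble(trial_id = rep("2010-000001-10", 2),
                               country = c("FR", "DE"),
                               enrolment = c(50L, 80L)),
    census_date = as.Date("2020-12-01"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Country-level link dates from the reference table alone.
reference_link_dates <- function() {
  regs <- euctr_regulators()
  regs <- regs[!is.na(regs$earliest_record_date), ]
  tapply(regs$earliest_record_date, regs$country, min) |>
    (\(v) as.Date(v, origin = "1970-01-01"))()
}

# Assign per-regulator rates by cycling values over countries (both German
# regulators get their country's rate).
rates_by_country <- function(values) {
  regs <- euctr_regulators()
  countries <- sort(unique(regs$country))
  by_country <- stats::setNames(
    values[(seq_along(countries) - 1) %% length(values) + 1], countries)
  stats::setNames(by_country[regs$country], regs$regulator_id)
}

# Generator config in which every trial is guaranteed truly completed by
# the census (early start years, short durations, census far out).
all_due_config <- function(seed, n_trials, ...) {
  generator_config(seed = seed, n_trials = n_trials,
                   year_range = c(2005L, 2012L),
                   census_date = "2020-12-01",
                   duration_median_months = 12, duration_sdlog = 0.4, ...)
}

# Defect-free study conditions: nothing suppressed, every date present and
# agreed, no stale statuses, everything reported in tabular form.
defect_free_config <- function(seed, n_trials) {
  all_due_config(seed, n_trials, p_suppress = 0, p_completion_date = 1,
                 p_stale_ongoing = 0, p_date_inconsistent = 0,
                 p_results_single = 1, p_results_multi = 1,
                 p_other = 0, p_tabular = 1, p_ineligible = 0)
}

filtered_gen <- function(config) {
  g <- generate_registry(config)
  list(registry = suppressWarnings(filter_study_population(g$registry)),
       ledger = g$ledger)
}

# 99% exact binomial CI membership check.
within_binom_ci99 <- function(p_true, x, n, conf.level = 0.99) {
  ci <- stats::binom.test(x, n, conf.level = conf.level)$conf.int
  p_true >= ci[1] & p_true <= ci[2]
}

# Joint membership check over many groups at a family-wise 99% level:
# each of the k per-group exact intervals is widened to 1 - 0.01/k
# (Bonferroni), so the probability that any unbiased group falls outside
# stays at 1% for the whole family rather than per group.
all_within_binom_ci99 <- function(p_true, x, n) {
  k <- length(x)
  mapply(within_binom_ci99, p_true, x, n,
         MoreArgs = list(conf.level = 1 - 0.01 / k))
}
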