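#' Configuration for the synthetic registry generator
#'
#' Bundles every knob of [generate_registry()] with defaults that emulate
#' a mature multi-country registry: fifteen full registration years
#' (2005–2019) censused on 2020-12-01, country weights proportional to the
#' protocol counts each regulator actually holds, 37% multi-country trials
#' whose extra-country count follows a truncated geometric distribution
#' (mean protocols per multi-country trial about 5.3), lognormal trial
#' durations with a 36-month median, and reporting probabilities of 26.5%
#' (single-protocol) and 60.6% (multi-protocol) for trials whose results
#' are due.
#'
#' Per-regulator rates (`p_completion_date`, `p_stale_ongoing`,
#' `p_suppress`) accept a scalar (applied to every regulator) or a named
#' vector covering every sampled regulator.
#'
#' @param seed integer RNG seed; the same seed and config give
#'   byte-identical output.
#' @param n_trials number of trials to generate.
#' @param year_range inclusive years over which trial start dates are
#'   uniform.
#' @param census_date snapshot date; defaults to 1 December of the year
#'   after `year_range[2]`.
#' @param regulators reference table in the [euctr_regulators()] shape;
#'   rows with no link date are never sampled.
#' @param country_weights sampling weight per regulator_id; defaults to
#'   the reference table's protocol counts.
#' @param p_multi probability a trial files in more than one country.
#' @param extra_geom_prob success probability of the truncated geometric
#'   distribution of additional countries for multi-country trials.
#' @param duration_median_months,duration_sdlog lognormal trial-duration
#'   model (median in months, log-scale dispersion).
#' @param p_completion_date probability a completed-status protocol
#'   carries its global completion date.
#' @param p_stale_ongoing probability a protocol of a truly completed
#'   trial is left marked `Ongoing`.
#' @param p_date_inconsistent probability the recorded completion dates of
#'   a multi-protocol trial are jittered apart.
#' @param date_jitter_sd jitter standard deviation, days.
#' @param p_suppress probability a protocol is omitted from the public
#'   registry despite enrolment.
#' @param p_results_single,p_results_multi probability a trial whose
#'   results are due (truly completed by the census) has a results record.
#' @param p_tabular probability a results record is tabular (with
#'   per-country enrolment) rather than document-only.
#' @param enrolment_mu,enrolment_size negative-binomial model of
#'   per-country participant counts (shifted by one so every enrolment
#'   location has at least one participant).
#' @param p_premature share of non-stale completed protocols labelled
#'   `Prematurely Ended` rather than `Completed`.
#' @param p_other probability a not-yet-completed protocol shows an
#'   `Other` status (halted, not authorised, ...).
#' @param p_ineligible probability a trial additionally enrols a country
#'   whose regulator was not yet linked at the trial start (a negative
#'   control: the expectation rule must not flag such pairs).
#' @return a validated list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             n_trials = 1000L,
                             year_range = c(2005L, 2019L),
                             census_date = NULL,
                             regulators = euctr_regulators(),
                             country_weights = NULL,
                             p_multi = 0.37,
                             extra_geom_prob = 0.23,
                             duration_median_months = 36,
                             duration_sdlog = 0.6,
                             p_completion_date = 0.756,
                             p_stale_ongoing = 0.2,
                             p_date_inconsistent = 0.3,
                             date_jitter_sd = 60,
                             p_suppress = 0.05,
                             p_results_single = 0.265,
                             p_results_multi = 0.606,
                             p_tabular = 0.9,
                             enrolment_mu = 40,
                             enrolment_size = 1.2,
                             p_premature = 0.1,
                             p_other = 0.01,
                             p_ineligible = 0.02) {
  cfg <- structure(as.list(environment()), class = "generator_config")
  if (is.null(cfg$census_date)) {
    cfg$census_date <- as.Date(sprintf("%d-12-01", year_range[2] + 1L))
  }
  cfg$census_date <- as.Date(cfg$census_date)
  if (is.null(cfg$country_weights)) {
    cfg$country_weights <- setNames(as.numeric(regulators$n_protocols),
                                    regulators$regulator_id)
  }
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  probs <- c("p_multi", "extra_geom_prob", "p_completion_date",
             "p_stale_ongoing", "p_date_inconsistent", "p_suppress",
             "p_results_single", "p_results_multi", "p_tabular",
             "p_premature", "p_other", "p_ineligible")
  for (nm in probs) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || any(is.na(v)) || any(v < 0) || any(v > 1)) {
      stop(sprintf("generator config: %s must be probabilities in [0, 1]", nm),
           call. = FALSE)
    }
  }
  if (cfg$n_trials < 1) stop("generator config: n_trials must be >= 1", call. = FALSE)
  if (length(cfg$year_range) != 2 || cfg$year_range[1] > cfg$year_range[2]) {
    stop("generator config: year_range must be an increasing pair", call. = FALSE)
  }
  if (any(cfg$country_weights < 0, na.rm = TRUE)) {
    stop("generator config: country_weights must be non-negative", call. = FALSE)
  }
  invisible(cfg)
}

# Scalar -> every regulator; named vector must cover every id.
expand_rate <- function(p, ids, what) {
  if (length(p) == 1 && is.null(names(p))) {
    return(setNames(rep(as.numeric(p), length(ids)), ids))
  }
  if (!all(ids %in% names(p))) {
    stop(sprintf("%s must be a scalar or name every sampled regulator (missing: %s)",
                 what, paste(setdiff(ids, names(p)), collapse = ", ")),
         call. = FALSE)
  }
  p[ids]
}

#' Generate a synthetic registry with a ground-truth defect ledger
#'
#' Draws trials from the model in [generator_config()] and injects the
#' defect classes the audit is built to detect, each at its configured
#' per-regulator rate, while recording the truth of every trial–country
#' pair in a ledger:
#'
#' * **suppression** — a protocol is omitted from the public snapshot,
#'   but (suppression being applied after results generation) the tabular
#'   results still list the country's enrolment: exactly the detection
#'   channel the availability audit exploits. A trial whose protocols are
#'   all suppressed stays in the registry only if it carries results;
#'   otherwise it is invisible and survives only in the ledger.
#' * **missing completion dates** — a completed-status protocol lacks its
#'   global completion date with probability `1 - p_completion_date`.
#' * **stale statuses** — a protocol of a truly completed trial remains
#'   `Ongoing`.
#' * **inconsistent completion dates** — recorded dates of a
#'   multi-protocol trial are independently jittered.
#' * **unreported results** — a due trial carries no results record with
#'   probability `1 - p_results_single` / `_multi`.
#'
#' Countries are only sampled among regulators already linked at the
#' trial's start date; `p_ineligible` injects controlled exceptions that
#' the expectation rule must leave out of every denominator.
#'
#' @param config a [generator_config()].
#' @return list with `registry` (a [registry]) and `ledger` (tibble, one
#'   row per generated trial–country pair: `trial_id`, `regulator_id`,
#'   `country`, `suppressed`, `true_completion_date`,
#'   `completion_date_recorded`, `status_stale`, `results_should_exist`,
#'   `has_results`, `ineligible_control`).
#' @export
generate_registry <- function(config = generator_config()) {
  validate_generator_config(config)
  set.seed(config$seed)

  regs <- config$regulators |>
    dplyr::filter(!is.na(.data$earliest_record_date))
  w <- expand_rate(config$country_weights[regs$regulator_id],
                   regs$regulator_id, "country_weights")
  regs <- regs[w > 0, ]
  w <- w[w > 0]
  reg_ids <- regs$regulator_id
  link <- setNames(regs$earliest_record_date, reg_ids)
  reg_country <- setNames(regs$country, reg_ids)
  p_cd <- expand_rate(config$p_completion_date, reg_ids, "p_completion_date")
  p_st <- expand_rate(config$p_stale_ongoing, reg_ids, "p_stale_ongoing")
  p_su <- expand_rate(config$p_suppress, reg_ids, "p_suppress")

  n <- config$n_trials
  census <- config$census_date
  d0 <- as.Date(sprintf("%d-01-01", config$year_range[1]))
  d1 <- as.Date(sprintf("%d-12-31", config$year_range[2]))
  starts <- d0 + floor(runif(n) * (as.numeric(d1 - d0) + 1))
  mulog <- log(config$duration_median_months * 30.44)

  led <- vector("list", n)
  pro <- vector("list", n)
  res <- vector("list", n)
  enr <- vector("list", n)

  for (i in seq_len(n)) {
    start <- starts[i]
    elig <- reg_ids[link < start]
    if (!length(elig)) {
      start <- min(link) + 1
      elig <- reg_ids[link < start]
    }
    k <- 1L
    if (length(elig) > 1 && runif(1) < config$p_multi) {
      k <- 1L + min(1L + rgeom(1, config$extra_geom_prob), length(elig) - 1L)
    }
    chosen <- if (length(elig) == 1) elig else
      sample(elig, k, prob = w[elig])
    control <- character()
    inel <- reg_ids[link >= start]
    if (length(inel) && runif(1) < config$p_ineligible) {
      control <- if (length(inel) == 1) inel else sample(inel, 1)
      chosen <- c(chosen, control)
    }
    m <- length(chosen)
    is_control <- chosen %in% control

    trial_id <- sprintf("%s-%06d-%02d", format(start, "%Y"), i, (i %% 90L) + 10L)
    entry <- start - round(runif(m, 30, 240))
    entry[is_control] <- link[control] + round(runif(sum(is_control), 30, 365))
    entry <- pmin(pmax(entry, link[chosen] + 1), census)

    duration <- round(rlnorm(1, mulog, config$duration_sdlog))
    true_completion <- start + max(duration, 1)
    due <- true_completion <= census

    stale <- due & (runif(m) < p_st[chosen])
    status <- rep("Ongoing", m)
    if (due) {
      done <- !stale
      status[done] <- ifelse(runif(sum(done)) < config$p_premature,
                             "Prematurely Ended", "Completed")
    } else {
      status[runif(m) < config$p_other] <- "Other"
    }

    recorded <- status %in% completed_statuses() &
      runif(m) < p_cd[chosen]
    cdate <- rep(as.Date(NA), m)
    cdate[recorded] <- true_completion
    if (m >= 2 && any(recorded) && runif(1) < config$p_date_inconsistent) {
      jit <- round(rnorm(sum(recorded), 0, config$date_jitter_sd))
      cdate[recorded] <- pmin(pmax(true_completion + jit, start + 1), census)
    }

    p_rep <- if (k == 1) config$p_results_single else config$p_results_multi
    has_results <- due && runif(1) < p_rep
    tabular <- has_results && runif(1) < config$p_tabular

    suppressed <- runif(m) < p_su[chosen]

    led[[i]] <- list(trial_id = rep(trial_id, m), regulator_id = chosen,
                     country = reg_country[chosen], suppressed = suppressed,
                     true_completion_date = rep(true_completion, m),
                     completion_date_recorded = recorded,
                     status_stale = stale,
                     results_should_exist = rep(due, m),
                     has_results = rep(has_results, m),
                     ineligible_control = is_control)
    if (any(!suppressed)) {
      j <- !suppressed
      pro[[i]] <- list(trial_id = rep(trial_id, sum(j)),
                       country = reg_country[chosen[j]],
                       regulator_id = chosen[j],
                       date_first_entered = entry[j],
                       trial_status = status[j],
                       global_completion_date = cdate[j],
                       is_eea = rep(TRUE, sum(j)))
    }
    visible <- any(!suppressed) || has_results
    if (has_results && visible) {
      res[[i]] <- list(trial_id = trial_id,
                       format = if (tabular) "tabular" else "document-only",
                       trial_start_date = start)
      if (tabular) {
        countries <- unique(reg_country[chosen])
        enr[[i]] <- list(
          trial_id = rep(trial_id, length(countries)), country = countries,
          enrolment = 1L + rnbinom(length(countries),
                                   size = config$enrolment_size,
                                   mu = config$enrolment_mu - 1))
      }
    }
  }

  pull <- function(acc, f, date = FALSE) {
    acc <- acc[!vapply(acc, is.null, logical(1))]
    v <- unlist(lapply(acc, `[[`, f), use.names = FALSE)
    if (date) v <- as.Date(v %||% numeric(), origin = "1970-01-01")
    v %||% vector(mode = if (date) "double" else "character")
  }
  protocols <- tibble::tibble(
    trial_id = pull(pro, "trial_id"), country = pull(pro, "country"),
    regulator_id = pull(pro, "regulator_id"),
    date_first_entered = pull(pro, "date_first_entered", date = TRUE),
    trial_status = pull(pro, "trial_status"),
    global_completion_date = pull(pro, "global_completion_date", date = TRUE),
    is_eea = as.logical(pull(pro, "is_eea")))
  results <- if (any(!vapply(res, is.null, logical(1)))) {
    tibble::tibble(trial_id = pull(res, "trial_id"),
                   format = pull(res, "format"),
                   trial_start_date = pull(res, "trial_start_date", date = TRUE),
                   has_results = TRUE)
  } else empty_results()
  enrolment <- if (any(!vapply(enr, is.null, logical(1)))) {
    tibble::tibble(trial_id = pull(enr, "trial_id"),
                   country = pull(enr, "country"),
                   enrolment = as.integer(pull(enr, "enrolment")))
  } else empty_enrolment()
  ledger <- tibble::tibble(
    trial_id = pull(led, "trial_id"), regulator_id = pull(led, "regulator_id"),
    country = pull(led, "country"),
    suppressed = as.logical(pull(led, "suppressed")),
    true_completion_date = pull(led, "true_completion_date", date = TRUE),
    completion_date_recorded = as.logical(pull(led, "completion_date_recorded")),
    status_stale = as.logical(pull(led, "status_stale")),
    results_should_exist = as.logical(pull(led, "results_should_exist")),
    has_results = as.logical(pull(led, "has_results")),
    ineligible_control = as.logical(pull(led, "ineligible_control")))

  reg <- registry(protocols, results, enrolment,
                  regulators = config$regulators, census_date = census)
  list(registry = reg, ledger = ledger)
}

#' Read and write ground-truth ledgers
#'
#' One CSV row per generated trial–country pair, losslessly
#' round-trippable.
#'
#' @param ledger ledger tibble from [generate_registry()].
#' @param path CSV file path.
#' @return `write_ledger()`: `path` invisibly; `read_ledger()`: the
#'   ledger tibble.
#' @export
write_ledger <- function(ledger, path) {
  readr::write_csv(ledger, path, na = "")
  invisible(path)
}

#' @rdname write_ledger
#' @export
read_ledger <- function(path) {
  readr::read_csv(path, na = "", progress = FALSE, col_types = readr::cols(
    trial_id = readr::col_character(), regulator_id = readr::col_character(),
    country = readr::col_character(), suppressed = readr::col_logical(),
    true_completion_date = readr::col_date(),
    completion_date_recorded = readr::col_logical(),
    status_stale = readr::col_logical(),
    results_should_exist = readr::col_logical(),
    has_results = readr::col_logical(),
    ineligible_control = readr::col_logical()))
}
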