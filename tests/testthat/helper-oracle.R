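# Independent brute-force recounts of every audit stage: plain nested
# loops over data frames, sharing no code with the pipeline. Used as the
# oracle in equivalence tests.

oracle_findings <- function(reg, link_dates) {
  res <- as.data.frame(reg$results)
  enr <- as.data.frame(reg$enrolment)
  pro <- as.data.frame(reg$protocols)
  rows <- list()
  for (i in seq_len(nrow(res))) {
    if (res$format[i] != "tabular") next
    tid <- res$trial_id[i]
    start <- res$trial_start_date[i]
    e <- enr[enr$trial_id == tid, , drop = FALSE]
    for (j in seq_len(nrow(e))) {
      ctry <- e$country[j]
      reason <- if (!ctry %in% names(link_dates)) {
        "no-link-date"
      } else if (start > link_dates[[ctry]]) {
        "eligible"
      } else {
        "start-before-link-date"
      }
      rows[[length(rows) + 1]] <- data.frame(
        trial_id = tid, country = ctry, enrolment = e$enrolment[j],
        eligibility_reason = reason, expected = reason == "eligible",
        available = any(pro$trial_id == tid & pro$country == ctry))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(trial_id = character(), country = character(),
               enrolment = integer(), eligibility_reason = character(),
               expected = logical(), available = logical())
  out[order(out$trial_id, out$country), , drop = FALSE]
}

oracle_availability <- function(reg, link_dates) {
  f <- oracle_findings(reg, link_dates)
  f <- f[f$expected, , drop = FALSE]
  out <- list()
  for (ctry in sort(unique(f$country))) {
    fc <- f[f$country == ctry, , drop = FALSE]
    out[[ctry]] <- c(n_expected = nrow(fc),
                     n_available = sum(fc$available),
                     n_missing = sum(!fc$available))
  }
  list(by_country = out,
       n_expected = nrow(f), n_available = sum(f$available),
       missing_participants = sum(f$enrolment[!f$available]))
}

oracle_completion_by_regulator <- function(reg) {
  pro <- as.data.frame(reg$protocols)
  done <- c("Completed", "Prematurely Ended")
  out <- list()
  for (r in sort(unique(pro$regulator_id))) {
    p <- pro[pro$regulator_id == r, , drop = FALSE]
    is_done <- p$trial_status %in% done
    out[[r]] <- c(
      n_protocols = nrow(p), n_completed = sum(is_done),
      n_completed_with_date = sum(is_done & !is.na(p$global_completion_date)),
      n_ongoing = sum(p$trial_status == "Ongoing"),
      n_other = sum(p$trial_status == "Other"))
  }
  out
}

oracle_conflicts <- function(reg) {
  pro <- as.data.frame(reg$protocols)
  done <- c("Completed", "Prematurely Ended")
  n_multi <- 0L
  n_conflict <- 0L
  for (tid in unique(pro$trial_id)) {
    st <- pro$trial_status[pro$trial_id == tid]
    if (length(st) < 2) next
    n_multi <- n_multi + 1L
    if (any(st %in% done) && any(st == "Ongoing")) n_conflict <- n_conflict + 1L
  }
  c(n_multi = n_multi, n_conflicted = n_conflict)
}

oracle_stale <- function(reg, cutoff_year) {
  pro <- as.data.frame(reg$protocols)
  n_eligible <- 0L
  n_stale <- 0L
  for (tid in unique(pro$trial_id)) {
    p <- pro[pro$trial_id == tid, , drop = FALSE]
    if (nrow(p) != 1) next
    if (as.integer(format(p$date_first_entered, "%Y")) >= cutoff_year) next
    n_eligible <- n_eligible + 1L
    if (p$trial_status == "Ongoing") n_stale <- n_stale + 1L
  }
  c(n_stale = n_stale, n_eligible = n_eligible)
}

oracle_consistency <- function(reg, rule = "strict") {
  pro <- as.data.frame(reg$protocols)
  n_trials <- 0L
  n_consistent <- 0L
  for (tid in unique(pro$trial_id)) {
    p <- pro[pro$trial_id == tid, , drop = FALSE]
    if (nrow(p) < 2) next
    dates <- p$global_completion_date
    if (all(is.na(dates))) next
    n_trials <- n_trials + 1L
    ok <- if (rule == "strict") {
      !anyNA(dates) && length(unique(dates)) == 1
    } else {
      length(unique(dates[!is.na(dates)])) == 1
    }
    if (ok) n_consistent <- n_consistent + 1L
  }
  c(n_trials = n_trials, n_consistent = n_consistent)
}

oracle_reporting <- function(reg) {
  pro <- as.data.frame(reg$protocols)
  reported_ids <- unique(as.data.frame(reg$results)$trial_id)
  single <- c(n = 0L, reported = 0L)
  multi <- c(n = 0L, reported = 0L)
  for (tid in unique(pro$trial_id)) {
    k <- sum(pro$trial_id == tid)
    rep <- tid %in% reported_ids
    if (k == 1) {
      single <- single + c(1L, as.integer(rep))
    } else {
      multi <- multi + c(1L, as.integer(rep))
    }
  }
  list(single = single, multi = multi)
}

oracle_trend <- function(reg) {
  pro <- as.data.frame(reg$protocols)
  out <- list()
  for (r in sort(unique(pro$regulator_id))) {
    yrs <- as.integer(format(pro$date_first_entered[pro$regulator_id == r], "%Y"))
    grid <- seq(min(yrs), max(as.integer(format(pro$date_first_entered, "%Y"))))
    n_new <- vapply(grid, function(y) sum(yrs == y), integer(1))
    out[[r]] <- data.frame(year = grid, n_new = n_new,
                           n_cumulative = cumsum(n_new))
  }
  out
}
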