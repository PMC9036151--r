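test_that("expectation rule: enrolment countries vs registered protocols", {
  link <- reference_link_dates()
  # enrolment FR 50 / DE 80, start 2010-05-01, only a DE protocol on file
  f <- expected_countries(fr_de_registry(), link)
  f <- f[order(f$country), ]
  expect_equal(f$country, c("DE", "FR"))
  expect_equal(f$eligibility_reason, c("eligible", "eligible"))
  expect_equal(f$expected, c(TRUE, TRUE))
  expect_equal(f$available, c(TRUE, FALSE))
  expect_equal(f$enrolment, c(80L, 50L))

  # a start before the country's link date is not expected
  f2 <- expected_countries(fr_de_registry(start = "2004-01-01"), link)
  expect_equal(f2$eligibility_reason[f2$country == "FR"],
               "start-before-link-date")
  expect_false(f2$expected[f2$country == "FR"])

  # boundary equality counts as ineligible ("after" is strict)
  f3 <- expected_countries(fr_de_registry(start = "2005-06-21"), link)
  expect_equal(f3$eligibility_reason[f3$country == "FR"],
               "start-before-link-date")

  # an enrolment country with no link date is excluded from denominators
  reg <- fr_de_registry()
  reg$enrolment <- dplyr::bind_rows(
    reg$enrolment,
    tibble::tibble(trial_id = "2010-000001-10", country = "US", enrolment = 10L))
  f4 <- expected_countries(reg, link)
  expect_equal(f4$eligibility_reason[f4$country == "US"], "no-link-date")
  s4 <- availability_summary(reg, link)
  expect_false("US" %in% s4$by_country$country)
  expect_equal(s4$total$n_expected, 2)
})

test_that("zero-enrolment locations count unless the strict switch is on", {
  reg <- fr_de_registry()
  reg$enrolment$enrolment[reg$enrolment$country == "FR"] <- 0L
  link <- reference_link_dates()
  expect_equal(nrow(expected_countries(reg, link)), 2)
  f <- expected_countries(reg, link, require_enrolment = TRUE)
  expect_equal(f$country, "DE")
})

test_that("availability summary aggregates findings and missing participants", {
  link <- reference_link_dates()
  s <- availability_summary(fr_de_registry(), link)
  expect_equal(s$total$n_expected, 2)
  expect_equal(s$total$n_available, 1)
  expect_equal(s$total$n_missing, 1)
  expect_equal(s$total$pct_available, 50)
  expect_equal(s$missing_participants, 50)
  expect_equal(s$by_country$n_missing[s$by_country$country == "FR"], 1)

  # per-country and overall conservation
  expect_true(all(s$by_country$n_available + s$by_country$n_missing ==
                    s$by_country$n_expected))
  expect_equal(sum(s$by_country$n_expected), s$total$n_expected)
})

test_that("no suppression means full availability", {
  fg <- filtered_gen(generator_config(seed = 31, n_trials = 300, p_suppress = 0))
  s <- availability_summary(fg$registry, reference_link_dates())
  expect_gt(s$total$n_expected, 0)
  expect_equal(s$total$pct_available, 100)
  expect_equal(s$total$n_missing, 0)
})

test_that("detected missing pairs equal the ledger's suppressed-and-eligible set", {
  fg <- filtered_gen(generator_config(seed = 32, n_trials = 500,
                                      p_suppress = 0.15))
  link <- reference_link_dates()
  f <- expected_countries(fg$registry, link)
  found_missing <- f[f$expected & !f$available, c("trial_id", "country")]

  led <- fg$ledger
  starts <- as.data.frame(fg$registry$results)
  starts <- starts[starts$format == "tabular", ]
  m <- merge(led, starts[c("trial_id", "trial_start_date")], by = "trial_id")
  m <- m[m$trial_start_date > link[m$country], ]
  # a country is missing when every one of its regulators' pairs is suppressed
  agg <- stats::aggregate(suppressed ~ trial_id + country, data = m, FUN = all)
  truth <- agg[agg$suppressed, c("trial_id", "country")]

  expect_setequal(paste(found_missing$trial_id, found_missing$country),
                  paste(truth$trial_id, truth$country))
})

test_that("top-missing concentration matches a sort-and-sum recount", {
  fg <- filtered_gen(generator_config(seed = 33, n_trials = 600,
                                      p_suppress = 0.2))
  s <- availability_summary(fg$registry, reference_link_dates())
  expect_error(top_missing_share(s, nrow(s$by_country) + 1), "exceeds")

  for (k in c(1, 3, 5)) {
    got <- top_missing_share(s, k)
    bc <- as.data.frame(s$by_country)
    bc <- bc[order(-bc$n_missing, bc$country), ]
    expect_equal(got$n_missing_top, sum(bc$n_missing[seq_len(k)]))
    expect_equal(got$share, sum(bc$n_missing[seq_len(k)]) / sum(bc$n_missing))
    expect_equal(got$countries, bc$country[seq_len(k)])
  }

  # concentration limit: one country holds all the missing protocols
  one <- fr_de_registry()
  s1 <- availability_summary(one, reference_link_dates())
  expect_equal(top_missing_share(s1, 1)$share, 1)
  expect_equal(top_missing_share(s1, 1)$countries, "FR")
})

test_that("registration trend counts, fills gap years, accumulates", {
  protocols <- dplyr::bind_rows(
    proto("2005-000001-10", "SE", "MPA", "2005-02-01"),
    proto("2005-000002-11", "SE", "MPA", "2005-07-15"),
    proto("2007-000003-12", "SE", "MPA", "2007-03-01"))
  reg <- registry(protocols, census_date = "2020-12-01")
  tr <- registration_trend(reg)
  expect_equal(tr$year, 2005:2007)
  expect_equal(tr$n_new, c(2L, 0L, 1L))
  expect_equal(tr$n_cumulative, c(2L, 2L, 3L))
  # grand total equals the registry protocol count
  expect_equal(sum(tr$n_new), nrow(reg$protocols))

  # reporting-layer year restriction
  expect_equal(registration_trend(reg, years = c(2006, 2007))$year, 2006:2007)

  # empty registry -> empty series
  empty <- registry(NULL, census_date = "2020-12-01")
  expect_equal(nrow(registration_trend(empty)), 0)

  # synthetic totals match the generator's per-regulator visible counts
  fg <- filtered_gen(generator_config(seed = 34, n_trials = 300))
  tr2 <- registration_trend(fg$registry)
  got <- tapply(tr2$n_new, tr2$regulator_id, sum)
  led <- fg$ledger[!fg$ledger$suppressed, ]
  vis <- paste(fg$registry$protocols$trial_id, fg$registry$protocols$regulator_id)
  led <- led[paste(led$trial_id, led$regulator_id) %in% vis, ]
  want <- table(led$regulator_id)
  expect_equal(as.integer(got[names(want)]), as.integer(want))
})

test_that("findings match a nested-loop recount on random registries", {
  link <- reference_link_dates()
  for (seed in 41:50) {
    fg <- filtered_gen(generator_config(
      seed = seed, n_trials = 40,
      p_suppress = (seed %% 5) / 10, p_tabular = 0.8, p_ineligible = 0.2))
    mine <- as.data.frame(expected_countries(fg$registry, link))
    orac <- oracle_findings(fg$registry, link)
    expect_equal(mine, orac, ignore_attr = TRUE)
  }
})
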