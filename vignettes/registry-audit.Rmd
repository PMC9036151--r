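---
title: "Auditing data quality in a multi-country trial registry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing data quality in a multi-country trial registry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

In the EU regulatory system a sponsor files a clinical trial application —
a standardised tabular protocol — with the national competent authority of
every country where enrolment is planned. Each approved application
becomes a public *country protocol* under a single parent trial record,
identified by a EudraCT-style number (`YYYY-NNNNNN-CC`). At the end of the
trial, end-of-trial paperwork should set the protocol's status to a
completed state and record the *global completion date*, and summary
results should be posted to the trial record within a year.

When this pipeline works, the registry is a complete public account of
regulated medicinal research. `euctraudit` measures how far a registry
snapshot deviates from that ideal, along three axes that are each tied to
a regulator's responsibilities:

1. **Protocol availability.** Tabular results contain a structured field
   listing the countries that enrolled participants. Every EU/EEA
   enrolment country should therefore hold a public protocol for that
   trial. Comparing the two sets yields, per country, the number of
   *expected*, *available* and *missing* protocols. This is deliberately a
   proxy: it can only see trials that already posted tabular results, and
   it cannot see trials whose every protocol is missing *and* that have no
   results; if unreported trials are missing protocols at a higher rate,
   the audit underestimates the problem.
2. **Completion quality.** The distribution of protocol statuses
   (`Ongoing`, `Completed`, `Prematurely Ended`, `Other`; the *completed
   set* is the latter two excluding `Ongoing`/`Other`), the share of
   completed protocols carrying a global completion date, cross-protocol
   *status conflicts* (a completed-set status beside an `Ongoing` one on
   the same trial), *stale* single-protocol trials (entered long ago,
   still `Ongoing`), and whether multi-protocol trials record the *same*
   global completion date everywhere — it is a property of the whole
   trial, so disagreement is an error by construction.
3. **Results availability.** Results are posted at trial level, so for a
   trial registered in exactly one country the reporting follow-up duty
   falls to a single regulator. The audit partitions trials into
   single-protocol and multi-protocol sets and reports the share with a
   results record — naive to due dates by design, because due-date logic
   itself depends on the completion fields whose quality is in question.

## The expectation rule

A country is only *expected* to hold a protocol for a trial if the trial
could have been registered there at all: the trial start date (taken from
the tabular results) must be **strictly after** the earliest record-entry
date of that country's regulator, the first evidence of a working link
between the regulator and the registry backend. We read "after" as a
strict inequality; a start date exactly equal to the link date is treated
as ineligible and surfaced in the findings table with reason
`start-before-link-date`. Ineligible pairs are excluded from both the
numerator and the denominator of every availability figure (the
alternative — counting an available-but-ineligible protocol in both — is
noted but not used). Enrolment countries with no known link date
(non-EU/EEA locations) are likewise excluded, with reason `no-link-date`.

Tabular results name countries, not regulators, so availability is
matched at country level: either German regulator (BfArM or PEI, the one
country with two authorities) satisfies an expected `DE` protocol.
Everywhere else the audit unit is the regulator, and country-level views
are roll-ups.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `link_date_source` | `"reference"` | Reference link dates win over snapshot minima when earlier (a partial snapshot can only overestimate the earliest date). |
| `require_enrolment` | `FALSE` | A listed enrolment country counts even with a zero participant count; the rule keys on listed locations, not counts. |
| `consistency_rule` | `"strict"` | A multi-protocol trial is date-consistent only if *every* protocol carries the same date. `"lenient"` ignores absent dates. Both are defensible operationalizations; strict is the default and the difference is worth inspecting on real data. |
| `stale_cutoff_year` | `2015` | Entry years strictly before this define "old" single-protocol trials. |
| `completed_only` | `FALSE` | Restrict reporting rates to trials whose protocols are all in the completed set. |
| `min_group` | `20` | Groups with fewer trials are flagged `small_group` rather than dropped, mirroring the practice of suppressing very small regulators (a handful of protocols) from trend displays. |
| `top_k` | `3` | Number of countries in the missing-protocol concentration figure; ties are broken by country code, ascending, so the statistic is deterministic. |

Report percentages are rounded **half away from zero to one decimal**
(`format_pct()`), matching the precision registry audits conventionally
print; shares printed as integers use `digits = 0`.

## The synthetic registry generator

Because the real registry's truth is unknowable, every metric is
validated against a seeded generator (`generate_registry()`) that draws
registries with the statistical structure the audit assumes and records
the truth of every trial–country pair in a ledger. The defaults are the
study conditions used throughout the test suite:

* start dates uniform over 2005–2019, census 2020-12-01;
* country weights proportional to each regulator's actual protocol
  holdings, so big and small regulators appear in realistic proportion;
* 37% of trials are multi-country; the number of additional countries is
  1 + a truncated geometric draw (`extra_geom_prob = 0.23`), giving
  multi-country trials about 5.3 protocols on average;
* trial durations are lognormal with a 36-month median (`sdlog = 0.6`);
  a trial is *due* when its true completion date is on or before the
  census;
* completed-status protocols carry their date with probability 0.756;
  due trials report results with probability 0.265 (single) / 0.606
  (multi); 90% of results records are tabular;
* per-country enrolment is 1 + negative binomial (`mu = 39`,
  `size = 1.2`), right-skewed counts with occasional large sites;
* defect rates the source data cannot pin down are set once at realistic
  levels: `p_suppress = 0.05`, `p_stale_ongoing = 0.2`,
  `p_date_inconsistent = 0.3` with 60-day jitter, and `p_ineligible =
  0.02` start-before-link negative controls.

Two generator choices matter for verification. Suppression is applied
*after* results generation, so tabular results faithfully retain the
enrolment of suppressed countries — precisely the channel the audit uses
to detect them. And a trial whose protocols are *all* suppressed is kept
in the registry when it carries results (its record is reachable through
the results) but dropped entirely when it does not; the invisible trial
survives only in the ledger. Retaining results-bearing zero-protocol
trials keeps the per-country missingness estimator unbiased — discarding
them would make visible single-protocol pairs never missing and bias the
estimate downward at high suppression rates. Zero-protocol trials carry
no status or regulator information, so they are excluded from the
completion and reporting stages, whose partition invariant holds over
trials with at least one visible protocol.

What the generator does **not** emulate: free-text protocol fields,
sponsors and therapeutic areas, due-date bookkeeping, country-specific
registration waves or policy shocks, and correlation of defects within
sponsors or years (defects are independent given the regulator). Passing
recovery tests therefore show the estimators are correct *under the
model*, not that real registries obey it.

## Numerical and testing choices

* **Determinism.** All generation flows from one `set.seed()` call per
  `generate_registry()`; identical config and seed give byte-identical
  files, and `run_audit()` writes a byte-identical `summary.json` for
  identical input and config.
* **Degenerate inputs.** Empty registries flow through every stage as
  well-formed zero tables; zero denominators yield `NA` percentages
  rather than errors; document-only results contribute no availability
  findings.
* **Status vocabulary.** Raw status strings are normalised
  case-insensitively through a documented lookup; unknown strings map to
  `Other` with a warning, never an error, since status wording varies
  across record vintages. `Other` never creates a status conflict.
* **Recovery testing.** Per-country estimates are compared to injected
  rates with exact (Clopper–Pearson) binomial intervals. When a single
  assertion spans ~20 countries at once, each interval is widened by
  Bonferroni (`conf.level = 1 − 0.01/k`) so the *family-wise* error stays
  at 1%; otherwise an unbiased estimator would fail about one seed in
  five by chance alone.
* **Problem sizes.** The suite exercises suppression recovery at 5,000
  trials, date/status/reporting recovery at 2,000–4,000, oracle
  equivalence on 200 registries of up to 80 trials against plain
  nested-loop recounts, and the eligibility property across 50 seeds —
  sizes chosen so binomial intervals are tight enough to detect
  percent-level bias while the whole suite stays comfortably fast.

## Limitations

The availability measure is a lower bound conditioned on reported,
tabular results; the completion and reporting measures take registry
fields at face value and cannot distinguish a sponsor's failure to file
from a regulator's failure to act on a filing. Findings across the three
axes are not independent — a country missing many protocols has fewer
records whose completion quality can be judged — and should be read
together.
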