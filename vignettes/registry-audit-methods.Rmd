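---
title: "Auditing recruitment and reporting in trial-registry snapshots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing recruitment and reporting in trial-registry snapshots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctriaudit)
```

## The problem

Trials that recruit in India must be registered with the Clinical Trials
Registry-India (CTRI). For a multinational trial — one recruiting in India
and at least one other country — an unusually large fraction of participants
drawn from India raises an ethical concern: the risk of the trial
concentrates on one population while the eventual benefit is global.
Separately, many registry records that describe trials as "not completed"
are simply stale: given the trial's start date and its registered estimated
duration, the study must long since have ended, but the record was never
updated.

`ctriaudit` turns both audits into a reproducible pipeline over a registry
snapshot (SQLite or CSV, one row per trial). It is aimed at meta-researchers
and registry auditors, and at anyone who wants to re-run or vary the audit
rules — every rule is an explicit, documented parameter.

## The record model and its sentinels

CTRI fields use fixed sentinel strings rather than empty cells: a date field
can hold a real date in the `dd/mm/yyyy` dialect, the string `"Date
Missing"`, `"Not Applicable"`, or — for completion dates of unfinished
trials — `"Applicable only for Completed/Terminated trials"`. The reader
(`read_records()`) keeps these distinctions: every raw value maps to exactly
one tag (`DATE`, `DATE_MISSING`, `NOT_APPLICABLE`, `COMPLETED_SENTINEL`,
`EMPTY`), real dates are normalised to ISO on output, sentinels survive
verbatim, and an empty cell is never conflated with `"Date Missing"`. Rows
that cannot be represented (an unparseable registration date, a non-numeric
sample size, a date string that is neither a date nor a known sentinel) are
collected into a rejects table with reasons instead of being silently
dropped. Date parsing is strict: a string must round-trip through its
matched format, so `31/02/2016` is rejected rather than rolled over, and
single-digit day/month strings without zero-padding are treated as
unparseable rather than guessed at.

Source snapshots rarely use tidy column names; a `col_map` argument maps any
scrape dialect onto the canonical snake_case schema, so the audit logic
never depends on the scrape.

## The cohort cascade

The audit cohort is: records registered in a window (default 2013-01-01 to
2020-12-31, both inclusive), interventional type, phase 2 or 3. Phase
strings in the registry are free text, so which labels count as "phase 2 or
3" is an explicit allow-list (`default_phase_tokens()`): `Phase 2`, `Phase
3`, combined `Phase 2/Phase 3` labels and roman-numeral variants, matched
case-insensitively at token boundaries. Whether combined 2/3 labels belong
in the cohort is genuinely open; we include them, since such a trial has a
phase-2 or phase-3 arm by definition, and the list is editable for anyone
who disagrees. Each filter tallies what it dropped and why, so the cascade
counts are reconstructible; the filters commute and are idempotent
(properties the test suite checks).

## Scope classification

Three field pairs carry scope information:

1. *Recruitment Status (India)* vs *(Global)* — a multinational trial needs
   both applicable; `"Not Applicable"` on the global side is consistent only
   with a domestic trial, on the India side only with a trial that has no
   Indian arm. `Terminated` or `Suspended` in either field outranks scope.
2. *Date of First Enrollment (India)* vs *(Global)* — a multinational trial
   needs real dates in both.
3. *Total Sample Size* vs *Sample Size from India* — a multinational trial
   needs the total to exceed the India size (with a non-empty Indian arm);
   equality marks a domestic trial.

A record is classified `INDIAN` or `MULTINATIONAL` only when **all three**
pairs agree — registry records carry enough internal contradictions that any
single pair is unreliable. Everything else falls through a fixed precedence:
terminated/suspended, then `FOREIGN_ONLY` (no Indian arm: India sample size
zero, or an inapplicable India status while the global fields are
populated), then the ambiguous categories, then `OTHER_DISCREPANCY`.

The leaning of an ambiguous record is anchored on the sample-size pair:
equal sizes *imply* a domestic trial, a larger total *implies* a
multinational one, and the contradiction lies in the other fields. We chose
this anchoring (rather than a simple majority vote across the three pairs)
because it is how the documented worked examples reason — a record with
equal sizes but a `Completed` global status and a populated global date is
an apparently-domestic trial with contradictory global fields, even though
two of its three pairs "look multinational". A majority vote would invert
that reading. When the size pair itself is uninformative (missing or
contradictory sizes), agreement of the two remaining pairs decides the
leaning, and records with no coherent leaning land in
`OTHER_DISCREPANCY`. Every verdict carries a `rule_fired` code naming the
sub-verdicts, so any classification can be audited after the fact.

## Completion partition and the recruitment audit

Multinational records split on the two completion-date fields: both real
dates → completed; both the `"Applicable only for Completed/Terminated
trials"` sentinel → not completed; anything else → an explicit `mixed`
bucket. The mixed residue is reported rather than dropped so the partition
always covers the input.

For the completed set the audit computes the planned fraction of
recruitment from India (*Sample Size from India* / *Total Sample Size*) and
the actual fraction (*Final Enrollment (India)* / *(Total)*). Invalid data
— India enrollment exceeding the total, a zero total, missing values — is
tagged, never clipped or imputed: these are audit findings in their own
right. The high-recruitment flag is an inclusive threshold (default 60%,
"60% or more"), swept by default over 50–70% in 5-point steps as a
sensitivity analysis; flagged sets are nested, so counts are monotone in
the cutoff.

The ratio of actual to planned percent recruitment is rounded half-up to
two decimals — the bin edges 1.01–1.15 / 1.16–1.60 / ≥1.61 presume
two-decimal granularity, and half-up matches the edges' reading — and
binned, with an explicit `AT_OR_BELOW_1` bucket for completeness and
`INCORRECT_DATA` whenever either fraction is invalid (invalidity is
contagious). Whether to round the percentages before forming the ratio is
undocumented; we form the ratio on the raw fractions and round once, which
avoids double rounding.

## Overdue detection

For not-completed records the pipeline estimates when the registry record
ought to have been updated:

1. the overall first-enrollment date is the **later** of the India and
   global dates;
2. the registered duration (years, months, days) is normalised to months —
   years contribute 12 each, a non-zero day component contributes one extra
   month;
3. a duration-dependent delay margin inflates the months: doubled for
   durations up to two years, ×1.5 (rounded up) for two to five years, no
   margin beyond five years;
4. calendar-month addition of the adjusted months to the anchor gives the
   estimated completion date;
5. a further six months of filing grace gives the filing-due date.

A record is overdue when its filing-due date is on or before the reference
date (default 2022-01-27), inclusive. Boundary choices: a duration of
exactly 24 months falls in the doubled class and exactly 60 months in the
×1.5 class — at each overlap the more generous margin applies, and the ×1.5
fraction rounds up — both chosen to minimise false "overdue" labels; flip
them via `apply_margin()` if you prefer the stricter reading.
Calendar-month addition clamps the day of month (Jan 31 + 1 month = Feb
28/29), the standard convention; the test suite checks it against an
independent day-counting oracle. All-zero durations are degenerate: such
records are excluded from the overdue denominator and reported separately,
as are records missing an enrollment date.

## The synthetic registry

`generate_registry()` produces seeded snapshots with ground truth stored
*beside* (never inside) the records, so every pipeline stage can be
validated end to end without access to the live registry. The defaults are
the composition observed in the real 2013–2020 snapshot this audit design
was developed against: ~67.5% of records in-window, ~72% of those
interventional, ~33% of those phase 2/3; a scope mix of roughly 86.7%
domestic, 7.3% multinational, with small terminated / suspended / no-Indian-
arm / ambiguous / discrepant fractions; a 62 : 362 : 49
completed : not-completed : mixed split of multinational records; planned
India-fractions drawn from Beta(2, 4), which places 8.7% of multinational
trials at or above the 60% cutoff, matching the observed ~8% rate; an
actual-to-planned ratio mixture populating every reporting bin; and
final-enrollment error rates of 2/62 each for the two documented
invalid-data modes. Ambiguous records replicate one of the three documented
contradiction patterns exactly.

What the generator does **not** emulate: free-text fields (titles,
conditions, eligibility), sponsor-nationality structure (sponsor strings
are arbitrary labels — the real audit's foreign/domestic attribution is a
manual step outside this package's scope), correlations between duration
and phase, or registration-volume trends over time. Passing tests therefore
show that the pipeline implements its rules exactly and recovers known
structure under realistic composition and error rates — not that the rules
themselves capture every pathology of real registry data.

## Numerical and degenerate-input choices

* Fractions are never clipped to \[0, 1\]; out-of-range data is tagged.
* Half-up rounding is implemented with an epsilon guard against binary
  floating-point representation (so 1.005 rounds to 1.01).
* Empty datasets flow through every stage and yield an all-zero report.
* Every record receives exactly one scope category; the report constructor
  verifies that sub-counts sum to their parents before anything is written.

## Problem sizes in the test suite

The suite validates ground-truth recovery on generated snapshots of
1,000–39,821 records (the larger matching a full registry download),
exercises the month-addition oracle on 1,000 random date/offset pairs, and
runs the cutoff sensitivity sweep on a 20,000-record snapshot; the whole
suite completes in well under a minute.

## Limitations

Labels are taken at face value: a mislabelled trial type or phase excludes
a record from the cohort, exactly as it would in the registry. Ambiguous
records are surfaced, never repaired; no attempt is made to infer true
scope from sponsor text. "Overdue" means the registry record was not
updated by the estimated filing date — it is a statement about the record,
not about the trial, and the margins guarantee false positives and
negatives in unknown proportion when durations are themselves misregistered.
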