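# ctriaudit

Audits of recruitment and reporting compliance in snapshots of the Clinical
Trials Registry-India (CTRI), for meta-researchers and registry auditors.

Trials recruiting in India register with CTRI. Two questions about
multinational phase 2/3 interventional trials motivate this package:

1. **Over-recruitment.** In a trial run across several countries, is the
   planned or actual fraction of participants recruited from India too
   high? With *s*ᵢ the registered *Sample Size from India*, *s* the *Total
   Sample Size*, and *f*ᵢ, *f* the final enrollment numbers achieved, the
   audit computes the planned fraction *p* = *s*ᵢ/*s* and the actual
   fraction *a* = *f*ᵢ/*f*, flags trials with *p* ≥ *c* or *a* ≥ *c* for an
   inclusive cutoff *c* (default 0.60, swept over 0.50–0.70), and bins the
   ratio *a*/*p* (rounded half-up to 2 decimals) into
   ≤1.00 / 1.01–1.15 / 1.16–1.60 / ≥1.61 / incorrect-data categories.
2. **Stale records.** Which "not completed" records ought to have been
   updated? For each, the estimated completion date is
   *anchor* + *m*·*g*(*m*) calendar months, where *anchor* is the later of
   the India and global first-enrollment dates, *m* the registered duration
   in months (days > 0 count as one month), and the margin factor *g* is 2
   for *m* ≤ 24, 1.5 (rounded up) for 25 ≤ *m* ≤ 60, and 1 beyond. Six
   further months of filing grace give the filing-due date; a record is
   overdue when that date is on or before the reference date (default
   2022-01-27, inclusive).

Upstream of both audits, records are filtered to a registration window /
interventional type / phase 2–3 cohort, and classified as `INDIAN` or
`MULTINATIONAL` only when three field pairs (recruitment statuses,
first-enrollment dates, sample sizes) are **unanimously** consistent with
that scope; contradictory records land in explicit ambiguous categories
with a `rule_fired` audit trail.

## Worked example

The package ships a seeded synthetic-registry generator that emulates the
registry's field dialects (dd/mm/yyyy dates, sentinel strings such as
`"Date Missing"` and `"Applicable only for Completed/Terminated trials"`),
its cohort composition, and its documented error modes, with ground truth
kept alongside the records:

```r
library(ctriaudit)
g <- generate_registry(registry_config(n_records = 10000, seed = 7))
a <- ctri_audit(g$records)
print(a)
```

```
Registry recruitment and reporting audit
  window 2013-01-01 .. 2020-12-31, cutoff 60%, reference date 2022-01-27

  records read:        10000
  in window:           6731
  interventional:      4911
  phase 2/3:           1635

  scope:
    INDIAN                        1461
    MULTINATIONAL                 88
    FOREIGN_ONLY                  7
    TERMINATED                    23
    SUSPENDED                     0
    AMBIGUOUS_INDIAN_LIKE         55
    AMBIGUOUS_MULTINATIONAL_LIKE  1
    OTHER_DISCREPANCY             0

  multinational completion:  9 completed / 67 not completed / 12 mixed

  completed set: 2 planned-high (22% of 9), 1 actual-high (11% of 9), 1 invalid
  ratio of actual to planned percent recruitment:
    AT_OR_BELOW_1   5
    R_101_115       0
    R_116_160       2
    R_161_PLUS      1
    INCORRECT_DATA  1

  not-completed set: 11 planned-high (16% of 67)
  overdue at 2022-01-27: 28 (42% of 67) (67 estimable)
```

Reading the output: of 10,000 records, 1,635 survive the window /
interventional / phase-2-3 cascade; 88 are unambiguously multinational, of
which 9 carry completion dates on both the India and global side. Among
those completed trials, 2 planned and 1 actually recruited 60% or more of
participants from India, and 1 has unusable enrollment data (here, a zero
final total — a finding, not a parsing failure). Of the 67 not-completed
multinational trials, 28 have an estimated filing-due date on or before
27 Jan 2022: their registry records are overdue for an update.

Per-trial tables (`a$verdicts`, `a$completed_audit`, `a$overdue$table`) back
every count; `write_audit(a, dir)` exports them as CSV plus a JSON summary.
`summary(a)` returns the counts as a plain list. A real snapshot is audited
the same way: `ctri_audit("snapshot.sqlite", table_name = "trials")`, with a
`col_map` argument to translate the snapshot's column labels.

A thin command-line wrapper is installed under `exec/`:

```sh
ctri-audit simulate --n 5000 --seed 7 --out snapshot.sqlite
ctri-audit audit --db snapshot.sqlite --out audit-out
```

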