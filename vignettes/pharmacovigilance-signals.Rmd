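---
title: "Disproportionality signal detection: models, simulation and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection: models, simulation and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
```

# The model

Spontaneous reporting systems collect adverse-event (AE) reports without a
denominator of exposed patients, so incidence cannot be estimated. What can
be estimated is *disproportionality*: whether an event is reported more
often for a drug than for everything else in the same collection. For an
index drug and event, deduplicated reports are cross-classified into the
2×2 table `(DE, De, dE, de)`; the exposed margin is the set of reports
naming the drug as **primary suspect**, and the background is every other
report in the store.

Three statistics are computed per drug–event pair:

* the reporting odds ratio `ROR = (DE/De)/(dE/de)` with the Wald interval
  `exp(ln ROR ± z·√(1/DE + 1/De + 1/dE + 1/de))`, `z = 1.96`;
* the proportional reporting ratio `PRR = (DE/D)/(dE/d)`;
* the Yates-corrected chi-squared
  `χ² = N(|DE·de − dE·De| − N/2)²/(D·d·E·e)`.

A pair is a **significant signal** when `DE ≥ 3`, `ROR ≥ 2`, the CI lower
bound exceeds 1, `PRR ≥ 2` and `χ² ≥ 4` (`signal_criteria()`). Two
strictness conventions circulate for these thresholds — inclusive (`≥`) and
strict (`>`); the package defaults to the inclusive form, with
`strict = TRUE` switching the DE/ROR/PRR/χ² comparisons to `>`. The CI
bound is strict either way. All thresholds and `z` are ordinary arguments.

Assumptions worth keeping in mind: each deduplicated report is treated as an
independent draw; disproportionality is a reporting association, not risk;
and the background is everything else in the collection, **including any
comparator drug's reports** — the honest analogue of using a whole database
as comparator. This last choice has a visible consequence discussed under
*Masking* below.

# The reconstruction oracle

Published signal tables usually print, per pair, only `DE`, the drug total
`D`, the ROR (with CI lower bound) and the PRR (with χ²) — not the
background cells. Two identities make such tables verifiable anyway:

1. ROR and PRR share the single unknown background odds `r = dE/de =
   (DE/De)/ROR`, so `PRR = (DE/D)·(1+r)/r` is determined by the printed
   triple (`implied_prr()`).
2. With `r` fixed, the Yates χ² is an increasing function of the background
   scale `s` (cells `(DE, D−DE, r·s, s)`) with the finite asymptote
   `(|DE − r·De| − (1+r)/2)²/(D·r)`; `reconstruct_table()` recovers `s` by
   bracketed bisection on a log grid (relative tolerance `1e-9` on the χ²
   match, 200 iterations maximum), then the whole table and its CI follow.
   A χ² at or above the asymptote is rejected with an error naming the
   asymptote — no table exists.

`verify_printed_stats()` applies both checks to the bundled table of 20
published rows for the two study drugs; all rows reproduce with relative
errors around `1e-4`, i.e. at the precision limit of the 3-decimal printed
inputs. The default pass tolerances (`1e-3` for PRR, `2e-3` for the CI
bound) were set from that input rounding, an order of magnitude above the
observed errors.

# The synthetic world

`sim_config()` / `generate_reports()` state a scaled-down spontaneous
reporting world with known ground truth. Defaults encode the conditions of
the antiresorptive two-drug setting the package was built around:

* **Drug shares.** Two study drugs (default 0.35 / 0.15) plus a catch-all
  `"background"` pseudo-drug absorbing the rest, so the non-exposed margin
  is well populated. Real databases have much smaller index-drug shares
  (~1%); the inflation is a deliberate desk-scale compromise and is why
  tests that need a clean background use small index shares explicitly.
* **Planted associations.** A planted pair draws the event in the index
  drug's reports with `p1 = planted_event_prob(target_ror, p0) =
  target_ror·p0/(1 − p0 + target_ror·p0)`, i.e. `odds(p1) =
  target_ror·odds(p0)`; every other arm draws at the background `p0`. For
  an event planted for a single drug, the population ROR equals the target
  exactly (`expected_table()` returns the expectation of each cell and the
  identity is tested to machine precision).
* **Duplicates.** A fraction `duplicate_rate` (default 0.6, the magnitude
  by which case-level deduplication shrinks real FAERS extracts) of emitted
  reports are exact-payload re-submissions with incremented version
  numbers. Deduplication keeps the highest `(version, isr_id)` per case —
  a documented stand-in, since real duplicate detection keys are not
  standardized. Duplicates are exact copies because the rule under test is
  key-based; conflicting-field duplicates are out of scope.
* **Demographics, years, outcomes.** Sex 76/12/12 female/male/unknown, ages
  ~N(68, 13²) rounded and clamped to [0, 110] with 44% unknown, mostly-US
  countries, report years 2004–2022 with linearly increasing weights, and
  independent per-category serious-outcome flags dominated by death (0.18)
  and hospitalization (0.13) — the orders of magnitude seen in published
  characteristics tables for these drugs.
* **Reproducibility.** Every component (drugs, events, indications,
  demographics, outcomes, years, duplicates, concomitants) draws from its
  own seed derived from the config seed, so enlarging one vocabulary does
  not shift unrelated draws.

What the generator does **not** emulate: event–event correlation (terms are
independent Bernoulli draws per report), dose and therapy dates,
polypharmacy structure, secular reporting effects beyond the year-weight
vector, and conflicting duplicate versions. A green pipeline test therefore
establishes correctness of the counting and statistics, not realism of any
clinical claim.

## Masking: planted targets vs population RORs

When two drugs plant the *same* event, each drug's elevated rate sits in
the other's background, so the measured (population) ROR of each is pulled
below its target. This is a real phenomenon in disproportionality work
(competition/masking by the comparator), and it follows necessarily from
the generative scheme plus the whole-store background: for a drug planted
at target 2, `odds(p1) = 2·odds(p0)` is fixed while the background rate
strictly exceeds `p0` whenever a stronger co-planted drug is present —
hence a true ROR strictly below 2, by any margin the share structure
dictates. One end-to-end acceptance test documents this deliberately: a
shared event planted at targets (8 vs 2) is detectable for the stronger
drug only, so the weaker side never enters the significant overlap and the
test records the masked outcome rather than papering over it. Tests that
need a weak shared signal to stay detectable give the stronger drug a small
share so the contamination is negligible.

# Numerical and tie-break choices

* **Yates clamp.** The literal χ² formula is positive at exact
  independence; when `|DE·de − dE·De| < N/2` the statistic is set to 0,
  matching `stats::chisq.test(correct = TRUE)`, which serves as the
  independent oracle in the tests.
* **Zero cells.** Any zero denominator cell makes ROR/PRR non-evaluable
  (reason-coded `NA`, never an error); no Haldane–Anscombe 0.5 correction
  is applied by default because the `DE ≥ 3` criterion already excludes the
  index-cell zero and corrections would break printed-value checks.
  Non-evaluable statistics fail their criterion.
* **Ranking and ties.** Signal tables order significant rows first, by `DE`
  descending, ties broken lexicographically by event term. Overlap records
  order by `|ROR difference|` descending. Equal RORs in a comparison give
  `direction = "tie"` and no tier.
* **Quartiles.** Linear-interpolation (type 7) quantiles over known ages;
  unknowns form an explicit category and are never dropped.
* **Age bins.** `<18`, `[18, 40]`, `(40, 65]`, `>65` — published bin labels
  ("18–40", "41–65") leave the real-valued edges implicit; these closures
  cover the line and reproduce integer-age tables.
* **Rounding.** Printed percentages use round-half-away-from-zero (base R
  rounds half to even): 2 decimals for demographic and off-label shares, 1
  for within-indication profiles; configurable per call via `digits`.
* **Term matching.** Exact equality of normalized terms (trimmed,
  case-folded, whitespace-collapsed) everywhere — no fuzzy or ontology
  matching. Umbrella aggregation is available only through an explicit
  grouping map (`load_grouping()`), where a report counts once per group.

# Other design decisions

* Unresolved drug names are retained in reports — they matter as background
  exposure — but can never serve as an index drug.
* Events and indications are sets per report: a term occurring twice in one
  report counts once, preventing double-counting in `DE`.
* Off-label percentages use the drug's full primary-suspect total as
  denominator (reports with no recorded indication stay in it);
  within-indication AE profiles use the indication subgroup size. Both
  choices reproduce published tables built the same way.
* Signal comparison uses point RORs only, with independent asymmetric tier
  thresholds per direction, because that is how published comparisons are
  made; no CI-overlap test is performed, and a tier is a descriptive label,
  not an inference.
* The reconstruction oracle solves each printed row independently; the
  implied backgrounds of different rows need not be mutually consistent and
  are not asserted to be.

# Limitations

No true MedDRA hierarchy (a flat term vocabulary stands in), no Bayesian
disproportionality (BCPNN/EBGM), no multiple-testing adjustment, no
live-database querying. The bundled drug labels are synthetic stand-ins
assembled for testing, not full FDA label text. And everything a
spontaneous-report analysis cannot do — incidence, causality, clinical
appropriateness of off-label use — this package cannot do either.
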