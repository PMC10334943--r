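---
title: "Defining, characterizing and validating phenotype algorithms with phenoforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Defining, characterizing and validating phenotype algorithms with phenoforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoforge)
```

## The problem

A phenotype algorithm (PA) turns a clinical case definition into
executable logic over observational data: a set of diagnosis codes
plus temporal criteria.  For hidradenitis suppurativa (HS) — a
chronic, under-diagnosed inflammatory skin disease — four PAs are in
standard use, crossed between *incident* vs *prevalent* entry and a
*one-code* vs *two-code* requirement.  Because no gold-standard label
exists in claims data, a PA's sensitivity, specificity, PPV and NPV
must themselves be estimated, classically by chart review and here by
a probabilistic reference standard.

`phenoforge` implements the whole chain — data model, cohort engine,
cohort diagnostics, probabilistic validation — plus a synthetic-data
generator with known ground truth, so that every stage can be checked
against an exact oracle.

## The data model

Five flat tables mirror the OMOP Common Data Model's core:
`person (person_id, sex, year_of_birth)`,
`observation_period (start, end)` — the continuous-enrollment
substrate — `visit_occurrence`, `condition_occurrence`,
`drug_exposure`.  Dates are calendar dates; all intervals are counted
in whole days.  Design choices a user should know:

* Events dated outside every observation period of their person are
  *flagged* by `validate_dataset()` but retained; cohort logic ignores
  them.  This mirrors payer data, where stray claims occur, and keeps
  validation side-effect-free.
* Multiple observation periods per person are treated independently;
  no gap-merging rule is applied, since none is standard.
* Concept identifiers are opaque integers; the shipped HS concept set
  is {4241223 ("hidradenitis suppurativa", ICD-10 L73.2), 434119
  ("hidradenitis", ICD-9 705.83)} with no vocabulary expansion.

## Cohort-engine semantics

A `cohort_definition()` holds: the concept set; `incident` (entry code
must be the person's first ever); `washout_days` of continuous
observation required before entry *within the same observation
period* (an enrollment boundary breaks continuity); `min_code_count`,
with codes 2..N confined to the inclusive `confirmation_window`
(default [31, 365] days after entry) and to the entry code's
observation period (a disenrolled patient contributes no claims); and
`index_at`.

Decisions where published descriptions are ambiguous:

* **Index date of two-code algorithms.**  The index is the *first*
  qualifying code, with the confirmation code acting as an inclusion
  criterion — the reading under which "second diagnosis 31 to 365
  days after index date" is coherent.  The alternative (index when all
  criteria are met) is available as `index_at = "confirmation"`; it
  changes index dates, never membership.
* **Window endpoints** are inclusive on both sides: a confirmation on
  day 31 or day 365 qualifies.
* **Incident exclusivity.**  If a person's first-ever code fails
  washout or confirmation, the person is excluded outright; deferring
  to a later code would make the cohort non-incident.  Prevalent
  definitions defer: the entry event is the earliest code satisfying
  all criteria.
* **Same-day codes collapse** to a single event: one encounter cannot
  confirm itself, and two different vocabularies coding one visit
  count once.

These semantics are enforced by an independent brute-force interpreter
in the test suite, which re-derives membership and index dates
literally for hundreds of randomized persons and definitions.

## Cohort diagnostics

* **Incidence rates**: numerator = index dates in the window;
  denominator = eligible person-time of *all* persons — observation
  time after the first `washout_days` of each period (one cannot
  index during washout, so that time is not at risk), censored at the
  person's own index.  Person-years use 365.25 days.  Strata: calendar
  year, 10-year age bands (age = year − year of birth, the only
  resolution the model carries), sex.
* **Standardized difference** of binary proportions defaults to the
  *unpooled* form `(p1 − p2)/sqrt(p1(1−p1) + p2(1−p2))` because it
  reproduces the published HS comparison values from their printed
  proportions ((0.50, 0.11) → 0.66; (0.32, 0.14) → 0.3), which the
  more common pooled form does not; the pooled variant is selectable.
  Imbalance is flagged at strictly |d| > 0.1.
* **Characterization** covariates are any-occurrence indicators per
  condition/drug concept in a day window relative to index (default
  [31, 365]), hence invariant to duplicated events.

## The probabilistic reference standard

`evaluate_algorithm()` estimates PA performance without chart review:

1. **xSpec cohort** — persons with ≥ 5 qualifying codes on distinct
   days (noisy positives; the 5-code choice echoes the finding that
   PPV rises steeply at five or more codes).  **Noisy negatives** — a
   seeded random sample of code-free persons, 10 per xSpec member.
2. **Features** — binary indicators for every condition/drug concept
   observed within ±365 days of the anchor (first qualifying code, or
   a random in-observation date for code-free persons), with the
   phenotype's own codes excluded so the model cannot see the labels.
3. **Model** — elastic-net logistic regression (`glmnet`, α = 0.5).
   The penalty is chosen at the minimum of the deviance curve averaged
   over three class-stratified 5-fold cross-validations, with the
   path extended far below glmnet's default floor: with few, highly
   informative binary features the calibration-optimal penalty is
   nearly unpenalized.
4. **Positive-unlabeled filtering** — the code-free pool is unlabeled,
   not clean: it contains undiagnosed true cases.  Mislabeling the
   ones the model itself recognizes biases every profile's probability
   downward, so negatives scoring above `pu_threshold` (default 0.1,
   an order of magnitude above the negative-pool base score) are
   dropped and the model refitted until the kept set stabilizes.
5. **Evaluation cohort** — a seeded sample (default 25,000) of
   non-xSpec persons, model-scored; xSpec members re-enter with
   probability 1, the published method's convention.  They are
   positives by construction, and dropping them would leave a sample
   that over-represents hard-to-classify cases, systematically
   deflating expected-count PPV.
6. **Expected-count confusion matrix** — `tp = Σ p` over cohort
   members, `fp = Σ (1−p)`, `fn`/`tn` likewise over non-members;
   sensitivity, specificity, PPV, NPV follow, with 95% percentile
   bootstrap intervals (default 500 resamples) over the evaluation
   cohort.  With degenerate 0/1 probabilities the matrix reduces
   exactly to classical counts.

**Known limitations.**  (i) A case with no disease-correlated events
in its record is invisible to any model built on such features; since
the exact oracle still counts these persons, estimated sensitivity
sits above truth by roughly the footprint-free case share (about
+0.05 to +0.10 under the simulator's defaults).  (ii) Probabilities
inherit the training design's case–control mix; the PU filter and
near-unpenalized fit keep high-evidence profiles well calibrated, but
genuinely ambiguous profiles (one weak marker) remain uncertain.
(iii) Bootstrap intervals quantify evaluation-sample noise only, not
model-specification error.

## The synthetic-data generator

`simulate_population()` emulates a commercial-claims database; the
defaults are the `ccae_like` preset:

| parameter | default | why |
|---|---|---|
| enrollment | exponential, mean 2.25 y, uniform start in 2015–2020 | median ≈ 1.56 y, matching large US commercial claims |
| visit rate | 4 /person-year (Poisson), ×2 after disease onset | typical outpatient contact rates; care intensifies with disease |
| true incidence | 12 /100,000 person-years, flat hazard | the rate reported for US commercial databases |
| baseline prevalence | 1% | population HS prevalence estimates ≈ 1% |
| coding sensitivity | 0.35 per disease-related visit, pre-diagnosis | diagnosis is missed far more often than made for HS |
| disease-related visit fraction | 0.25 pre-diagnosis, 0.5 after | encodes HS's long diagnostic delay; after first coding the chronic diagnosis is re-recorded (p = 0.85) at disease-related visits, producing realistic code accumulation |
| false-positive coding | 2×10⁻⁵ per visit of a disease-free person | rare stray codes |
| female fraction | 0.51 | commercial-claims demography |
| comorbidity panel | 14 concepts: clindamycin- and doxycycline-like antibiotics, skin abscess, folliculitis/acne, soft-tissue infection, incision & drainage, intertriginous dermatitis, pilonidal cyst, adalimumab-like biologic, plus weak diabetes / depression / obesity / hyperlipidemia / nicotine signals | collectively identifies cases while no single code is decisive — standing in for the thousands of weakly informative codes real claims data offer a diagnostic model |

One global seed drives a deterministic substream per table, so
identical parameters and seed reproduce identical files.

What the generator does *not* emulate — and hence what passing tests
do and do not show: no disease-course structure (severity stages,
flares), no care-seeking heterogeneity beyond the single post-onset
multiplier, no coding-practice drift over calendar time, no
cross-database heterogeneity.  Results on synthetic data validate the
*machinery* (engine correctness, estimator calibration against known
truth); they do not transfer numerically to any real database.  Two
realism notes follow directly from the defaults: simulated sensitivity
of the one-code algorithms is governed by the first-coding intensity
(≈ 0.7/person-year), which lands the four algorithms in plausible
published ranges; and simulated incident-algorithm incidence rates
exceed the true onset rate because diagnostic delay funnels prevalent
disease into first codes — a caveat the diagnostics are designed to
surface, not a bug.

## Numerical and testing choices

* Tests validate the engine against a literal brute-force interpreter
  on randomized persons (two-period enrollments, out-of-observation
  codes, same-day duplicates) and randomized definitions.
* The evaluator is validated on a 50,000-person simulation in a
  well-coded regime (per-visit coding sensitivity 0.9, the top of the
  grid used for ordering checks): the expected-count PPV and
  sensitivity of all four algorithms are required to track the exact
  oracle within ±0.10 on the shared evaluation cohort, and the
  published qualitative ordering (two-code: lower sensitivity, higher
  mean PPV) must reproduce.  Under heavy under-coding the structural
  sensitivity overestimate described above can exceed that band —
  documented here rather than hidden.
* Simulation-based checks use closed-form Poisson intervals (99%)
  around expected event counts, never re-derived from the code under
  test.
* Problem sizes in the suite: 50,000 persons for the recovery check,
  4,000–8,000 for structural invariants, 1,200 for oracle
  equivalence — chosen as the smallest sizes at which the checked
  quantities are statistically stable.
* Rounding of published-style percentages is half-away-from-zero
  (`as_percent()`); base `round()`'s half-to-even cannot reproduce
  conventionally rounded published summaries.  Two published
  cross-database means (prevalent one-code PPV and sensitivity) are
  not arithmetically reachable from the printed per-database cells
  under any standard rounding (59.76% → 60 vs printed 59; 58.9% → 59
  vs printed 58), presumably because they were computed on unrounded
  values; the packaged table documents, and the tests do not assert,
  those two.

## Reference metrics table

`hs_reference_metrics()` returns the packaged published per-database
estimates for the four algorithms across five large US databases.
`mean_across_databases()` reproduces the quoted cross-database means
(e.g. two-code incident PPV 88%, one-code incident PPV 62%), and
`ppv_ladder_report()` formats code-count ladders, flagging whether PPV
rises with the required code count as reported (59% at 2 codes to 84%
at 5 or more).
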