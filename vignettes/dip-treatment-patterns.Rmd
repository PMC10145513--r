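---
title: "Classifying treatment changes and prognoses after incident drug-induced parkinsonism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying treatment changes and prognoses after incident drug-induced parkinsonism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Drug-induced parkinsonism (DIP) is a parkinsonian syndrome caused by
dopamine-blocking or dopamine-depleting drugs — antipsychotics,
gastrointestinal (GI) motility drugs such as metoclopramide and
levosulpiride, and the calcium-channel blocker flunarizine. After a patient
develops DIP, the prescriber faces a choice: stop the offending drug, lower
its dose, switch within the class, or continue. What clinicians actually do,
and how the syndrome then evolves (remits, recurs, or persists), can be read
off longitudinal healthcare claims — but only through a stack of carefully
specified day-level rules: incident-case selection with a washout, drug-era
construction under a permissible-gap rule, a mutually exclusive first-change
taxonomy, and a diagnosis-episode algorithm.

`dipcohort` implements that stack as a tested pipeline over a documented
plain-text claims schema, together with a synthetic-claims generator that
plants *labelled* treatment-change and prognosis archetypes, so every
classifier in the chain can be validated by label recovery rather than by
eyeballing real data that cannot be redistributed.

## Study design encoded in the configuration

`study_config()` carries every design parameter, in days:

* **Accrual window** 2004-01-01 – 2013-12-31 inside a **data window**
  2002-01-01 – 2015-12-31; the two leading years provide washout lookback,
  the two trailing years follow-up.
* **Index date** — the earliest DIP diagnosis (ICD-10 `G21.1` "other
  drug-induced secondary parkinsonism" or `G25.1` "drug-induced tremor",
  primary or secondary position) in the accrual window.
* **Washout** 730 days: any DIP code in `[index − 730, index − 1]` makes the
  case prevalent, not incident. A DIP code on the index date itself *is* the
  index event. We use 730 days rather than "two calendar years" so the rule
  is deterministic across month lengths; the same convention (365/730 days)
  applies to every other window.
* **Overlap rule** — at least one *outpatient* prescription for an offending
  drug whose supply interval covers the index date. Supply intervals are
  half-open, `[start, start + days_supply)`, which fixes every off-by-one
  question downstream: a 30-day supply starting on day 0 covers days 0–29
  and "ends" on day 30, the first uncovered day.
* **Era gap** 60 days: consecutive prescriptions with at most 60 uncovered
  days between them form one continuous drug era.
* **Episode gap** 120 days (4 months): DIP diagnoses at most 120 days apart
  belong to one episode; a 120-day diagnosis-free run confirms remittance.
* **Follow-up** 730 days from the index date, fixed. Claims data carry no
  reliable death or disenrollment signal in this schema, so the window is
  not censored by them; the one censoring rule we do apply is described
  below.

ICD-10 codes are normalized (uppercase, dot stripped) and matched by exact
prefix, so sub-coded records such as `G2110` are captured by `G211`. Drug
identity is the normalized substance name: the offending lists are the 13
antipsychotics, 6 GI motility drugs and flunarizine marketed in South Korea
during the study period; anything else (nizatidine, proton-pump inhibitors,
…) is invisible to the exposure logic.

## The first-change taxonomy

Within the patient's **index class only** (patients are counted once, under
the class of the drug that overlapped their index date), prescriptions are
merged into eras and each era into segments of constant regimen — the
mapping substance → total daily dose active on a day. Boundary events are
scanned in date order and the first one decides the category:

| Category | Trigger | Event date |
|---|---|---|
| switching | substance set changes between consecutive segments of one era | new segment start |
| dose adjustment | same substances, a total daily dose changes | new segment start |
| reinitiation | era ends, a later era starts inside follow-up | restart date |
| discontinuation | era ends, no restart, > 60 days of window remain | era end |
| persistent use | no boundary event at all | — |

Three deliberately documented choices fill gaps the day-level rules leave
open:

* **Augmentation counts as switching.** Adding a second in-class substance
  while the first continues changes the regimen's composition; we treat any
  change of the substance *set* as a switch, and a simultaneous substance
  and dose change resolves to switching (substance identity dominates).
* **Censored trailing gaps.** If an era ends later than day 670 of the
  730-day window, the remaining window cannot contain the > 60-day gap that
  defines discontinuation; no modification is observable, so the patient is
  classified as a persistent user.
* **Resuming unchanged after a permissible gap is not an event.** The
  regimens on either side of a ≤ 60-day gap are compared directly: same
  drug at the same dose means continued use.

Reinitiation is subtyped by comparing the regimen before the gap with the
regimen at restart: a different substance set is a within-class switch after
temporary discontinuation; the same set at a different total dose is
same-drug-dose-adjusted; otherwise same-drug-same-dose. Dose equality uses
a relative tolerance of 1e-6 — claims doses are exact rationals, and the
tolerance only guards text round-trips.

## Prognosis

DIP diagnosis dates inside the follow-up window (the prescription-overlap
rule applies at the index only) are clustered by single linkage at 120 days.
The index episode decides the category: if it never achieves a confirmed
120-day diagnosis-free run inside the window, the DIP is *persisting*; if it
remits and a later episode occurs, the patient is a *recurrence* (time to
recurrence = first diagnosis of the second episode − index); otherwise
*remittance*. Time to remittance is anchored at the **last diagnosis of the
index episode**, which makes a patient whose only DIP claim is the index
visit remit at day 0 — consistent with the many single-visit patients such
cohorts contain. An episode whose last diagnosis falls after day 610 cannot
confirm remittance within the window and is right-censored into persisting.
Only the first prognosis cycle is classified.

## What the generator emulates — and what it does not

`generate_cohort()` plants, per patient, one of six treatment-change
archetypes and one of three prognosis archetypes, built from 30-day refill
chains with jittered gaps. Every planted gap keeps a **margin of at least
14 days** from every decision threshold (60-day era gap, 120-day episode
gap, and the end-of-window censoring bounds), so the intended label is
provably unambiguous — any recovery below 100% is a bug, not noise. Class
shares default to the study population (53.7% antipsychotics, 41.5% GI
motility, 4.8% flunarizine), as do the demographic marginals (62.5% female,
7.4% Medical Aid, 15.4% Parkinson's disease, the age-band and income-decile
weights). Flunarizine is a single-member class, so archetypes that need a
second substance fall back to their dose/same-drug counterparts there; the
ground truth records what was actually planted, keeping the class mix
faithful. Per-patient randomness comes from streams hashed from (root seed,
patient index), so patient *i*'s records do not depend on cohort size, and
identical seeds reproduce identical files byte for byte.

`generate_decoys()` adds what the pipeline must ignore or exclude:
non-offending prescriptions, unrelated and comorbidity diagnoses (varying
the Charlson index), prevalent-DIP patients caught by the washout, and
patients whose supply ends before the index date.

The generator is deliberately *not* a realistic claims simulator: it models
no prescribing volumes, costs, adherence, death or disenrollment, no
multi-class polypharmacy by default, and its planted gaps avoid exactly the
threshold-straddling ambiguity that real refill behaviour produces. Passing
the recovery tests therefore shows the classifiers implement the stated
rules exactly; it does not show how often real-world refill noise lands on
the thresholds where those rules bite.

## Baseline covariates

Age is index year minus birth year (the schema carries birth year only),
banded as 0–19 and decades to 80+. The Charlson comorbidity index maps
ICD-10 codes in `[index − 365, index − 1]` to the 17 original categories via
the Quan coding, with the classical weights and the three hierarchy rules
(complicated diabetes over uncomplicated, metastatic tumour over localized
malignancy, severe over mild liver disease); no installed package provides
this mapping, so it is implemented and tested here. Parkinson's disease is
any `G20`-prefixed code in `[index − 730, index]` — the index day included,
since a same-day G20 code is still pre-existing disease being recorded.
When several offending classes cover the index date the fixed priority
antipsychotic > GI motility > flunarizine assigns the class (the rarer,
higher-risk psychiatric exposure should not be masked by a co-prescribed
prokinetic); ties are flagged in the cohort table.

## Reporting conventions

Percentages are `100·n/N` rounded **half away from zero** to one decimal,
the convention of printed clinical tables (banker's rounding would turn
6.25% into 6.2%). Medians and quartiles interpolate linearly between order
statistics (`quantile` type 7). The pooled time to "any discontinuation,
temporary or permanent" summarizes the first era end for patients whose
first change was discontinuation *or* reinitiation. By-sex and by-class
proportions use within-stratum denominators.

## Verification strategy and problem sizes

Every algorithmic step has an independent brute-force oracle in the test
suite: a day-grid merge oracle for eras, a day-by-day state machine for the
first-change classifier, a gap scan for episodes, a three-criteria replay
for eligibility, and sort-and-interpolate quartiles. The suite checks exact
agreement on randomized inputs (100 era fuzz cases × 3 gap settings, 200
random prescription streams, 10,000 random diagnosis sets, and a 1,000 +
decoys end-to-end cohort), label recovery on 500 patients per clean
archetype, threshold monotonicity at era gaps 30/60/90 and episode gaps
60/120/180, and byte-level determinism of two full runs. These sizes keep
the whole suite within a few minutes on one CPU while leaving each property
thousands of independent chances to fail.

## Known limitations

* Calendar-year age (not birth-date age) can differ by one year from true
  age and is not invariant under small date shifts across New Year.
* Overlapping refills are taken at face value; no stockpiling adjustment is
  applied, and the era-gap computation uses the cumulative maximum supply
  end. Claims with heavy early refills would need a stockpiling convention
  this package does not implement.
* Only the index class is analysed per patient; cross-class replacement
  (e.g. metoclopramide → nizatidine) is, by design, temporary
  discontinuation, and multi-change sequences beyond the first change are
  not classified.
* The empirical outcome proportions of the source cohort (a non-public
  national claims sample) are data-dependent and are not reproduced here;
  the package reproduces the *method*, verified on synthetic data, plus the
  printed baseline proportions that are arithmetic facts of the published
  counts.
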