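---
title: "Measuring concordance between antidepressant treatment patterns and the CANMAT algorithm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring concordance between antidepressant treatment patterns and the CANMAT algorithm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adconcord)
library(data.table)
```

## The problem

Sequential pharmacotherapy for major depressive disorder (MDD) is usually
described as a ladder: a first-line antidepressant, then — if the response
is inadequate — a *switch* to another drug or an *add-on* (augmentation or
combination). The CANMAT 2016 guidelines make the ladder operational by
assigning every drug a line of treatment, for monotherapy and for adjunctive
use separately. Whether everyday prescribing actually follows that ladder is
an empirical question that can be answered from dispensing records, provided
the records are reduced to treatment *levels* by explicit, reproducible
rules. This package implements one such reduction and its concordance
scoring, together with a synthetic EMR generator so the whole chain is
testable without access to clinical data.

## From dispensings to treatment levels

All date handling is day-granular and closed-interval: a d-day supply
starting on day s covers [s, s + d − 1], and
overlap([a,b],[c,d]) = max(0, min(b,d) − max(a,c) + 1).

**Exposure intervals.** Within one drug, supply runs that overlap or are
separated by at most `grace_days` (default 14) drug-free days are merged;
the merged interval spans from the first to the last covered day, and its
`supplied_days` is that span (internal grace gaps count toward it).

**Classification.** Scanning a patient's merged intervals in date order,
every interval of a drug outside the current regimen is a candidate:

* supplied < `supply_min_days` (30) ⇒ **attempt** — the level is unchanged
  and that use of the drug never enters a regimen;
* otherwise, qualifying candidates whose intervals start within
  `event_window_days` (14) of each other form one transition event
  (`multi_drug` when two or more qualify). The event is an **add-on** when
  the new drug(s) overlap *every* continuing regimen drug by at least
  `overlap_min_days` (30); otherwise a **switch**, which drops exactly the
  regimen drugs with overlap below the threshold.

Each switch or add-on increments the level by one; level k runs from its
entry date to the day before level k+1 starts, and the last level ends at
the end of follow-up, so per-patient level durations partition the follow-up
window exactly — a structural invariant the tests assert.

**Boundary conventions** (the source rules leave these open; each is fixed
once and covered by a test):

* "at least 30 days" is inclusive on both thresholds: supplied = 30
  qualifies, overlap = 30 is an add-on;
* a same-drug gap of exactly 14 days still merges; 15 splits;
* week bins for durations partition the integers: <2w = 1–13, 2–4w = 14–27,
  4–6w = 28–41, 6–8w = 42–55, >8w = 56+ days (chosen so the bins partition
  ℕ; with the 30-day supply floor they also reproduce the observation that
  no level ≥ 2 has mass below 4 weeks);
* the multi-drug grouping window reuses the 14-day grace constant — the only
  within-patient tolerance the source rules contain — and is configurable;
* a regimen drug's supply run starting exactly on an event date counts as
  continuation (membership is evaluated at the start of the day), and a
  qualifying candidate starting exactly on the current level's start date is
  absorbed into the regimen without an event. Both corners are unreachable
  for cohorts with single-drug index dates but must be deterministic for
  arbitrary inputs;
* once entered, a level persists until the next qualifying event, even if an
  added drug is later stopped early.

The engine is verified against an independent day-by-day simulator (explicit
day sets instead of interval arithmetic) on hundreds of random timelines;
agreement is required in 100% of cases.

## Cohort definition

The index date is the first antidepressant dispense inside the accrual
window (2015-01-01 to 2017-12-31 by default) preceded by 365
antidepressant-free days. Follow-up runs to the earlier of the treatment
episode's end and the study end (2018-12-31); an episode ends when more than
120 drug-free days separate the end of one supply run from the next
antidepressant dispense. Eligibility is applied in a fixed precedence order
(prior ECT → bipolar/schizophrenia → CNS disease → age 18–64 → MDD code
during baseline → multi-drug index), so exclusion counts are reproducible;
the source flowchart implies sequential filtering but does not state the
order, and any fixed order leaves the final cohort unchanged. An MDD code
dated exactly on the index date counts as a baseline diagnosis (diagnosis
and first prescription typically co-occur at the index visit); age is
calendar age at index, inclusive at both bounds.

## Concordance scoring

The drug knowledge lives in two editable TSV files: a catalog (drug, class,
antidepressant flag) and a tier table (monotherapy lines 1–3 with a
superior-efficacy flag; adjunct lines 1–3). The shipped tier table
transcribes the CANMAT 2016 recommendations; because the exact source
formulary is not reproducible from the published text, the file is
documented as editable and every constraint the text does fix is asserted in
tests (buspirone absent from the adjunct list, mirtazapine a second-line and
trazodone a third-line adjunct, quetiapine an adjunct, and exactly 12 of the
17 observed initiator antidepressants first-line).

Level 1 is concordant iff the index drug is first-line monotherapy. A switch
is concordant iff it introduces a single drug from the switch-eligible set —
by default the superior-efficacy drugs plus second- and third-line
antidepressants, following the guideline wording literally. Whether a plain
first-line drug without the superior-efficacy label is an acceptable switch
target is genuinely ambiguous (the wording excludes it; the discussion of
observed switch choices treats first-line targets approvingly), so it is a
configuration flag (`switch_allow_any_first_line`, default off) and neither
behavior is asserted as the source's intent. An add-on is concordant iff it
adds a single drug whose adjunct line is in `adjunct_eligible_lines`
(default: all three lines — "in the recommendation list" read as the whole
list; restrictable to first or first+second). Multi-drug switches and
add-ons are always discordant. A patient is concordant overall iff every
realized level up to 3 is concordant; levels beyond 3 are recorded but not
scored; treatment duration never affects the flag.

Two conventions deserve emphasis:

* **Attempts are neutral.** Short-supply drugs do not change the level and
  do not change the concordance flag. The published cohort's arithmetic
  suggests its ~150 attempt-only first-line patients were counted
  discordant; the contract implemented here makes attempt neutrality an
  invariant instead, and the reporting layer exposes both denominators —
  patients who moved to level 2 (the 2,829-style count) and patients with
  any medication change including attempt-only (the 2,977-style count) — so
  either analysis can be reproduced.
* **Evaluation is over realized levels.** A patient whose follow-up ends in
  level 1 with a first-line drug is concordant; concordance is not
  penalized for hypothetical future levels.

## The trend test

`cochran_armitage()` implements the standard trend statistic
T = Σ sᵢ(xᵢ − nᵢp̄), Var T = p̄(1−p̄)[Σ nᵢsᵢ² − (Σ nᵢsᵢ)²/N], Z = T/√Var T,
with a two-sided normal p-value and no continuity correction (a correction
flag exists but defaults off — the reproduced published Z/p pairs match the
uncorrected form). Z is invariant to affine rescaling of the scores; the
reported sign follows ascending year scores, and comparisons against the
published values use |Z| because the original sign convention follows an
undocumented internal coding of the statistics package used there. The
implementation is cross-checked in tests against `stats::prop.trend.test`
and a Monte-Carlo permutation oracle (mid-p convention for the discrete
tie mass).

The published yearly table reproduces exactly from its printed (n, %)
pairs, reconstructing per-year denominators as round(100·n/%):

```{r trend}
trend_worked_example()
```

## The synthetic generator: what it emulates, and what it does not

`sim_config()` encodes the stated world of the source cohort: accrual
2015–2017 with follow-up through 2018; age mix (39.9 / 26.2 / 14.3 / 19.6%
over 18–30 / 31–40 / 41–50 / 51–64) and 66.25% female; escitalopram the
modal initiator with the five published top initiators at their published
shares and the remaining mass spread over the other 12 observed initiators
so that ~96.4% of initiations are first-line; 15.57% of eligible patients
moving beyond level 1, 54.2% of level-2 entries being switches, the
published continuation and kind-split probabilities into levels 3 and 4, and
the published multi-drug event rates (23.5% of switches, 4.4% of add-ons).
Level durations are log-normal with medians 28 / 64.5 / 70.5 days for levels
1–3 and dispersions fitted to the published quartiles, with a 30-day floor
at levels ≥ 2. `n_patients` counts *screened* patients; the sequential
exclusion probabilities derive from the published screening funnel (40,856
screened → 19,955 eligible), with two rates the funnel does not contain —
washout violations (0.02) and missing MDD codes (0.01) — set once to small
plausible values. Dispensing uses a 28-day refill quantum; the source never
states supply lengths, so this is a modeling choice, not a reported fact.

Switch-target and adjunct drug pools mix recommended and non-recommended
agents so that single-drug discordance rates at the level-1→2 step match the
published flow (≈7.5% of single switches, ≈27% of single add-ons
discordant). **Not emulated:** per-step discordance at level 3 and beyond is
not separately calibrated (the source reports none), so the *cumulative*
optimized-treatment concordance in synthetic cohorts (~60%) is higher than
the published 27.24%; that figure is reproduced in the worked example from
its printed pair instead. Also not emulated: comorbidity structure,
dose changes, psychotherapy/rTMS co-treatment, care-seeking behavior, and
loss to follow-up beyond the episode rule.

Clean mode realizes the intended structure exactly: regimen drugs are
dispensed continuously across the levels they belong to, switches start the
day after the previous regimen's supply ends, add-ons overlap every
continuing drug for the full (≥ 30-day) level, attempts (14-day supplies)
are placed just after the level-1 start when the level can contain them, and
planned levels that would not fit before the study end are dropped or
truncated with the ground truth updated accordingly. Running the full
pipeline on clean-mode output must recover 100% of exclusion reasons, level
sequences (regimens, entry patterns, durations) and concordance labels — the
acceptance suite asserts this at n = 10,000. Noisy mode adds late/early
refill jitter, occasional long same-drug gaps and stray short supplies;
there only the structural invariants are asserted (durations partition
follow-up; bins, exclusion reasons and subsequent-pattern counts partition
their totals).

A green recovery test therefore establishes that the pipeline inverts the
generator's realization of the rules — not that either matches the source
EMR, which is not available.

## Numerical and degenerate-input choices

* Dates are integer days internally; no time-of-day exists anywhere.
* Person-years use 365.25-day years; visit counts are distinct visit dates.
* An all-success or all-failure trend table is an error (Z undefined), as is
  a non-positive supply or duration; an empty stratum yields a flagged
  undefined percentage rather than NaN propagation.
* Ties in candidate processing are broken by drug name after start date;
  with the grouping window this affects only the labeling, not membership.

## Known limitations

* The tier table is a transcription; institution-specific formularies should
  replace it (the loader validates any user table against the catalog).
* Concordance is assessed on drug identity only — dose escalation, which the
  source explicitly set aside, is out of scope, so concordance is likely
  overestimated in the same way.
* Only the first treatment episode per patient is analyzed.
* The generator's excluded patients carry exactly one exclusion trigger
  each, so it cannot probe the (order-dependent) attribution of patients who
  satisfy several exclusion criteria at once; the precedence order is fixed
  and documented instead.
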