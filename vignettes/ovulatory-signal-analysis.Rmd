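---
title: "Analysing noisy ovulatory signals in bonobo swelling cycles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing noisy ovulatory signals in bonobo swelling cycles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyclescope)
```

## The scientific problem

Female bonobos advertise their ovarian cycle with an exaggerated anogenital
swelling, scored in the field on a three-point ordinal scale (1
non-swelling, 2 intermediate, 3 maximal). The *maximal swelling phase*
(MSP) runs from the first score-3 day to the last score-3 day before
*detumescence*, the day the swelling visibly shrinks back to score 2.
Unlike chimpanzees, bonobo ovulation is poorly predicted by the *onset* of
the MSP: day-specific ovulation probability computed from onset is spread
over weeks. Two very different biologies can produce that spread:

1. ovulation really is placed (near-)randomly within the phase, or
2. ovulation is tightly locked a short lag before detumescence, and the
   spread is an artefact of large between- and within-female variation in
   MSP length.

`cyclescope` implements the full analysis chain needed to distinguish
these: phase segmentation from daily scores, hormone-based ovulation
dating, day-specific ovulation/fertility probability estimation under both
alignments, landmark-aligned male-behaviour tables, dominance indices, and
a seeded synthetic-data generator that can produce either biology on
demand. Every quantity the package reports is recomputed from data at run
time; the generator provides ground truth for recovery testing.

## Phase segmentation

`segment_phases()` scans each female's ordered daily scores. A phase is
the interval from the first to the last score-3 day, and stays continuous
across a dip to sub-maximal scores provided the score returns to 3 no
later than the 4th calendar day after the last score-3 day (at most 3
intervening sub-3 days). The same window (`missing_gap_max_days`) is
applied when the intervening days are unobserved, because field gaps
should not split a phase that resumes promptly. Both windows are exposed
as parameters: the continuity rule's phrase "within 4 days" could also be
read as permitting 4 intervening days, and users can set
`merge_gap_max_days = 5` to get that reading.

Phase length is the calendar length of the interval (merged gap days
count), because the phase is defined by its first and last days, not by a
count of score-3 days. Phases abutting the first or last observed day are
flagged censored; when the day after the last score-3 day was not
observed, the first later observed sub-3 day is used as the detumescence
date and flagged `detum_uncertain`.

Two alignment conventions are used everywhere downstream: onset-aligned
day indices start at 1 on the onset day; detumescence-aligned indices are
0 on the detumescence day, negative before.

## Ovulation detection from urinary PdG

Ovulation is dated from the urinary progesterone metabolite
pregnanediol-3-glucuronide (PdG). Samples below assay sensitivity (6.6
pg/ml for estrone conjugates E1C, 2.1 ng/ml for PdG; values exactly at the
limit are kept) are excluded up front, and duplicate same-day samples are
averaged after creatinine correction.

For a given day, the *baseline* is the mean and sample SD of PdG over the
10 calendar days strictly preceding it. A rise starts at the earliest
sampled day whose PdG exceeds the baseline mean by more than 2 baseline
SDs, and is *sustained* when three successive sampled days — urine cannot
be collected daily, so calendar-consecutive days would make detection
impossible on real schedules — stay above the rise-start day's threshold
and fall within a 7-calendar-day span. The ovulation date is the day
before the first elevated day. The threshold is deliberately fixed at the
rise-start day's baseline: later days' own trailing windows would contain
the rise itself, and the 2-SD envelope would chase the very signal being
detected.

The baseline includes whatever sampled values fall in its window, with no
iterative exclusion of already-elevated days (available as
`exclude_elevated = TRUE` for sensitivity analyses). A consequence worth
knowing: when two cycles follow each other so closely that the previous
luteal elevation intrudes into the next rise's 10-day baseline window, the
inflated threshold can shift the detected date by a few days. At realistic
bonobo cycle lengths (about 42 days) this is rare, but users segmenting
irregular or post-conception cycles should inspect the per-candidate
skip log attached to each call.

Cycles are scanned from 5 days before MSP onset to 10 days after
detumescence (ovulation can fall outside the phase); samples from the 10
days before the scan window still feed the baselines, otherwise the first
scanned days would have their baselines truncated. With no confirmed rise
the cycle is *anovulatory* when at least `min_coverage_n = 5` samples
covered the scan span, else *undetermined* — the distinction is a coverage
judgement the underlying field method leaves open, so the threshold is
configurable.

The *fertile window* is the 4 days ending on the ovulation day (sperm
survive about 3 days, the egg about 24 h). The ovulation-to-detumescence
lag is `detumescence_date - ovulation_date`, positive when detumescence
follows ovulation.

## Day-specific probabilities

With `n` ovulatory cycles of which `n_t` ovulated on aligned day `t`, the
day-specific ovulation probability is `P(T = t) = n_t / n`, and the
day-specific fertility probability is the forward window sum
`P(X(f) = 1) = sum_{t = f}^{f + 3} P(T = t)`. Probabilities are stored
with their integer counts so normalization is exact by construction (no
floating-point drift at the small `n` typical of field studies); two
identities are tested: the ovulation vector sums to 1, and when all mass
is interior the fertility vector sums to exactly 4 (each ovulation day
lands in exactly 4 windows). Peak days are reported with an explicit tie
flag, ties broken toward the earliest day.

`compare_msp_lengths()` reproduces the cross-study contrast of per-study
average MSP lengths bundled in `inst/extdata/msp_lengths.csv` (8 bonobo
and 7 chimpanzee study means, with SE-reported dispersions flagged). The
rank-sum statistic W is computed by mid-ranks; the p-value uses exact
enumeration when the pooled sample is tie-free and small, else the
tie-corrected normal approximation with continuity correction — the
bundled table contains a tie (10.9 twice), so it takes the approximate
path, and the method label always records which path was used.

## Behaviour tables and dominance

The behaviour module builds model-ready tables rather than fitting models:
the bespoke content of this analysis is the data construction, while
negative-binomial/binomial mixed-model fits are routine in any statistics
environment.

* *Intensive following* — a male within 10 m of a target female for more
  than 5 minutes — is counted as distinct qualifying males per female-day.
* The dyad-day table has one row per male x female x day with the day's
  offset from the female's ovulation restricted to `[-14, 0]` (a 15-day
  span matching the 13.5 ± 1.8 day mean MSP length), shared party hours as
  the exposure offset, per-dyad counts of copulations, solicitations and
  interventions (interventions directed at females are excluded; the
  intervened-over female attributes the event to the dyad), configurable
  dyad exclusions (e.g., a mother-son pair), and a dyad-within-cycle
  random-effect key.
* The daily male-male aggression rate divides the day's aggression count
  by total follow hours and is square-root transformed; a per-male
  denominator is a documented alternative reading and can be had by
  passing per-male hours.
* Hurdle-style subsets mirror the two-stage analysis design: all
  female-days; maximal-swelling days only; and days with at least 2
  females with maximal swelling (`fms_min` configurable, since "more than
  2" is readable as either at least 2 simultaneous targets or at least 3).
* Infant age is coded ordinally in half-year bins from -1 (conceptive
  detumescence) through -0.5 (final 6 months of pregnancy), 0 (newborn) up
  to a cap of 5; predictors are standardized to mean 0, SD 1.

Dominance hierarchies come from decided (non-tied) dyadic agonistic bouts.
David's score uses win proportions `P_ij` (unknown dyads contribute 0, the
standard convention; the sample-size-corrected `D_ij` variant is
available), normalized as `(DS + N(N-1)/2)/N`; steepness is the absolute
OLS slope of normalized scores against rank. Linearity uses Landau's `h`
generalized to h′: unknown and tied dyads are randomly directed in each of
10,000 seeded iterations (configurable) and `h` is averaged; the
right-tail p compares each completion against a fully random tournament.
These indices are implemented from their definitions and verified against
independent brute-force oracles (a four-sum David's score and exhaustive
enumeration of all completions for small matrices).

## The synthetic-data generator

`simulate_dataset()` emits a complete, internally consistent dataset —
daily swelling scores, urine samples, behaviour events, hourly party
records, metadata — as a deterministic function of a `sim_config()`.
Defaults encode the study conditions; each was chosen once, with the
following reasoning, and is a parameter rather than a constant:

* **MSP length**: mean 13.5 days with an explicit variance split —
  between-female SD 2.5 days (female-specific means) and within-female SD
  5 days (cycle draws), truncated at 5 days. The biology attributes the
  onset-aligned spread to both components without quantifying the split,
  so both are exposed.
* **Ovulation placement**: `lag_locked` draws the
  detumescence-minus-ovulation lag from a normal(1.9, 2.4) truncated at -3
  days (ovulation at most 3 days after detumescence, keeping fertile
  windows near the phase); `random_within_msp` places ovulation uniformly
  over the phase days. The truncated normal is a modelling choice — only
  the mean and SD of the lag are empirically anchored.
* **Cycle spacing**: 28 days from detumescence to the next onset, giving a
  total cycle of about 42 days as observed in wild bonobos. This also
  guarantees the luteal PdG elevation (12 days, log-linear ramp to an
  8-fold plateau over 4 days) has cleared the next cycle's 10-day baseline
  window, as it does physiologically.
* **Hormones**: multiplicative log-normal noise (sdlog 0.15, a realistic
  urinary assay + physiology CV) on piecewise level curves; an E1C peak 1
  day before ovulation. The curves are deliberately *not*
  pharmacokinetic — they carry exactly the structure the threshold
  detector consumes, no more.
* **Sampling**: each day yields a urine sample with probability 0.8,
  near-daily targeted sampling of cycling females with misses, matching
  intensive field protocols. Because the detected date is the day before
  the first *sampled* elevated day, recovery within ±1 day is bounded by
  `1 - (1 - p)^2`; at `p = 0.8` the expected ceiling is about 96%, and the
  package's recovery experiments run at about 90%. At sparse sampling
  (`p = 0.6`) the same bound caps recovery near 84% — no detector honouring
  the day-before-first-rise definition can beat it, which is worth
  remembering when comparing sparse-schedule studies.
* **Behaviour**: a male's daily probability of intensively following a
  cycling female is logistic in days-to-detumescence and the female's
  infant-age code, and following stops at detumescence (the stop-signal
  finding the pipeline is designed to expose); copulations/solicitations
  are Poisson in shared hours rising log-linearly toward ovulation;
  interventions come from the top three ranks; daily male-male aggression
  is log-linear in male count, FMS count and their interaction, with
  higher-ranking males winning 80% of bouts.

Short score-2 dips (probability 0.2 per cycle, length at most 2 days, kept
clear of phase edges) exercise the segmentation merge rule; the emitted
scores re-segment to the true phases with or without dips. A configurable
fraction of samples is pushed below assay sensitivity to exercise
filtering.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: observer error in swelling scores, postconception
swelling and early pregnancy loss, seasonal variation in party attendance,
female dominance effects on male behaviour, and hormone pharmacokinetics.
Recovery rates measured here characterize the detector under the stated
noise model, not field performance.

## The scenario contrast

`scenario_contrast()` is the computational heart of the package's
discrimination argument. It takes *detected* (not true) ovulations with
their phase landmarks and compares the spread (SD and IQR) of the
ovulation-day distribution under onset versus detumescence alignment.
Under lag-locked ovulation with variable phase lengths, the onset-aligned
spread strictly exceeds the detumescence-aligned spread (at the defaults,
roughly twofold). Under uniform placement the two are comparable: if `U`
is uniform on the `L` phase days, the onset index `U` and the
detumescence index `-(L - U)` are equal in distribution, so the SD ratio
converges to 1 and any departure is Monte-Carlo noise (about ±0.05 SD at
200 cycles). A wide onset-aligned distribution together with a narrow
detumescence-aligned one therefore identifies the variable-phase-length
biology; wide distributions under both alignments identify random
placement. It refuses to run on fewer than 5 detected cycles.

## Numerical choices and degenerate inputs

* All dates are calendar days (`Date` or plain integers), all intervals
  closed, all indices integer; no fractional-day arithmetic anywhere.
* Probability vectors carry integer counts; equality tests on them are
  exact, not tolerance-based.
* Tie-breaks are always deterministic and flagged (peak days to the
  earliest day; dominance ranks by score, then normalized score, then
  identifier).
* Degenerate inputs fail loudly with named diagnostics: unsorted or
  duplicated swelling rows, negative concentrations, constant vectors
  passed to `standardize()`, single-individual dominance matrices, empty
  ovulatory-cycle sets.
* Detection at zero baseline SD still works (any exceedance of the mean
  triggers a candidate), so the noiseless limit is well defined.
* The h′ randomization restores the caller's RNG state, so embedding it in
  a larger seeded workflow does not perturb downstream draws.

The problem sizes used throughout the test-suite experiments — 200
simulated cycles for recovery and scenario-contrast runs, 15 cycles for
end-to-end pipeline checks, 2,000-4,000 randomizations for h′ — were
chosen so that Monte-Carlo error is comfortably below the effect sizes
being asserted.

## Interface

The exported functions are the interface, composable in scripts and
pipelines: `simulate_dataset()` → `run_pipeline()` → `pipeline_report()`
covers the end-to-end path, and each stage (`segment_phases()`,
`filter_samples()`, `detect_cycles()`, `day_probabilities()`,
`assemble_dyad_day()`, `davids_score()`, `h_prime()`, ...) is usable on
its own with plain data frames read from CSV. `run_pipeline()` returns a
manifest with config and table hashes plus per-stage kept/excluded counts,
so identical inputs and seeds are verifiably reproducible and every filter
is auditable (kept + excluded = input at each stage).

## Known limitations

* The detector implements the day-before-first-sustained-rise definition
  exactly; its timing error under sparse sampling is an information limit,
  not an implementation artefact.
* Baseline contamination by a preceding luteal phase can shift detections
  when cycles are unusually close together (see above).
* The MSP-length comparison table stores per-study *means*; the rank-sum
  test treats studies, not cycles, as units, exactly as in the original
  cross-study comparison.
* Day-probability estimates are raw empirical fractions; no smoothing or
  shrinkage is applied, so they are as granular as the number of cycles
  allows.
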