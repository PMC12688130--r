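# cyclescope

Ovulatory-signal analysis for primates with exaggerated sexual swellings,
built for field datasets of daily categorical swelling scores, urinary
hormone assays and behavioural observations — the data a long-term bonobo
study produces.

## The problem

Female bonobos display a conspicuous anogenital swelling scored daily on
an ordinal scale (1 non-swelling, 2 intermediate, 3 maximal). The
**maximal swelling phase** (MSP) runs from the first to the last score-3
day; **detumescence** is the first day the score drops back to 2.
Ovulation is dated from urine: the day before the first sustained rise of
pregnanediol-3-glucuronide (PdG) more than 2 SD above its trailing 10-day
baseline, sustained over three successive sampled days within a week. The
**fertile window** is the 4 days ending on the ovulation day.

With *n* ovulatory cycles, of which *n<sub>t</sub>* ovulated on aligned
day *t*, the day-specific ovulation probability is

> P(T = t) = n<sub>t</sub> / n

and the day-specific fertility (fertilization) probability is the 4-day
forward window sum

> P(X(f) = 1) = Σ<sub>t = f</sub><sup>f + 3</sup> P(T = t).

Computed from MSP *onset*, this distribution is spread over weeks in
bonobos — ovulation looks unpredictable. The package's central analysis
asks *why*: because ovulation is placed randomly within the phase, or
because ovulation is locked a short lag (about 1.9 ± 2.4 days) before
*detumescence* while MSP length varies widely between and within females.
The two biologies are distinguished by comparing the spread of the
ovulation-day distribution under onset versus detumescence alignment — on
detected ovulations, exactly as a field study would have to.

The package covers the full chain: phase segmentation with a 4-day
continuity rule, hormone filtering and PdG-rise ovulation detection,
day-specific probability estimation under both alignments, model-ready
behavioural tables (intensive following, dyad-day mating effort with
exposure offsets, aggression rates, hurdle-style subsets), David's-score
dominance hierarchies with steepness and the h′ linearity index, and a
fully seeded synthetic-data generator with ground truth for all of it.

## Worked example

Simulate a detumescence-locked cohort (5 females, 3 cycles each), run the
pipeline, and ask which biology the data show:

```r
library(cyclescope)

cfg <- sim_config(seed = 11, scenario = "lag_locked")
ds  <- simulate_dataset(cfg)
out <- run_pipeline(ds)

out$cycles[out$cycles$status == "ovulatory",
           c("female_id", "onset_date", "detumescence_date",
             "ovulation_date", "lag_days", "length_days")]
#> # A tibble: 15 × 6
#>    female_id onset_date detumescence_date ovulation_date lag_days length_days
#>  1 F01       2014-02-04 2014-02-16        2014-02-17           -1          12
#>  2 F01       2014-03-16 2014-03-24        2014-03-23            1           8
#>  3 F01       2014-04-21 2014-04-26        2014-04-25            1           5
#>  4 F02       2014-02-02 2014-02-11        2014-02-08            3           9
#>  ...
#> 15 F05       2014-05-01 2014-05-17        2014-05-17            0          16
```

All 15 cycles are detected as ovulatory; the ovulation-to-detumescence
lags cluster near +2 days while MSP lengths range 5–16 days. The
day-specific ovulation probability peaks just before detumescence:

```r
dp <- out$day_probs
peak_day(dp[dp$alignment == "detumescence" & dp$kind == "ovulation", ])
#> # A tibble: 1 × 3
#>     day probability tie
#> 1    -1       0.333 FALSE
```

The scenario contrast quantifies the asymmetry — onset-aligned spread
almost twice the detumescence-aligned spread, the signature of variable
phase lengths with detumescence-locked ovulation:

```r
scenario_contrast(out$cycles)$by_alignment
#> # A tibble: 2 × 4
#>   alignment        n    sd   iqr
#> 1 onset           15  3.40   3.5
#> 2 detumescence    15  1.80   2
# SD ratio: 1.88
```

The bundled cross-study table of published MSP lengths reproduces the
species contrast:

```r
cmp <- compare_msp_lengths()
#> bonobo 13.5 +/- 1.8 d (n=8) vs chimpanzee 11.3 +/- 1.1 d (n=7):
#> W = 48, p = 0.024
```

Field data in the same CSV schemas (swelling scores, urine samples,
events, hourly party records) drop into the same functions; see the
vignette in `vignettes/ovulatory-signal-analysis.Rmd` for the model,
every tunable parameter, and the generator's assumptions.

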