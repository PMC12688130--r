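Package: cyclescope
Title: Ovulatory-Signal Analysis for Primate Sexual-Swelling Cycles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing ovulatory signalling in primates with
    exaggerated sexual swellings, built around daily categorical swelling
    scores and urinary hormone profiles. Segments maximal swelling phases
    (MSPs) from ordinal swelling series with a gap-merging continuity rule,
    detects ovulation from sustained rises of urinary pregnanediol
    glucuronide (PdG) above a trailing baseline, derives 4-day fertile
    windows, and estimates day-specific ovulation and fertility
    probabilities aligned either to MSP onset or to detumescence. Also
    assembles model-ready behavioural tables (intensive following,
    dyad-day mating effort with exposure offsets, male-male aggression
    rates), computes David's score dominance hierarchies with steepness and
    the h' linearity index, and ships a seeded synthetic-data generator
    that discriminates random-within-phase ovulation from
    detumescence-locked ovulation with variable phase lengths.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
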