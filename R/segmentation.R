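# Segmentation of maximal swelling phases (MSPs) from daily ordinal
# swelling scores.
#
# Scores are 1 (non-swelling), 2 (intermediate), 3 (maximal). An MSP runs
# from the first score-3 day to the last score-3 day before detumescence;
# detumescence is the first day the score falls from 3 to 2. A phase stays
# continuous across a short dip below 3 when the score returns to 3 within
# the continuity window (default: on or before the 4th day after the last
# score-3 day, i.e. at most 3 intervening sub-3 days).

#' Segment maximal swelling phases from daily swelling scores
#'
#' Converts per-female daily swelling-score series into maximal swelling
#' phases (MSPs). Runs of score 3 separated by short dips to sub-maximal
#' scores are merged into a single phase when the score returns to 3 no
#' later than `merge_gap_max_days` calendar days after the last score-3
#' day. Days on which the female was not observed do not break a phase if
#' the run resumes within `missing_gap_max_days`.
#'
#' @param swelling A data frame with columns `female_id`, `date` (`Date` or
#'   integer day number), `score` (1, 2 or 3) and optionally `observed`
#'   (logical; defaults to `TRUE`). Rows must be sorted by date within each
#'   female, with at most one row per female-day.
#' @param merge_gap_max_days Maximum calendar gap (days) between successive
#'   score-3 days across an *observed* sub-3 dip for the phase to remain
#'   continuous. Default 4: the score must return to 3 on or before the 4th
#'   day after the last score-3 day.
#' @param missing_gap_max_days Same bound applied when the intervening days
#'   are unobserved. Default 4.
#'
#' @return A tibble with one row per phase: `female_id`, `phase_id`,
#'   `onset_date` (first score-3 day), `last_max_date` (final score-3 day),
#'   `detumescence_date` (first sub-3 day after the phase; `NA` when the
#'   phase is right-censored), `length_days` (`last_max_date - onset_date +
#'   1`, counting merged gap days), `gap_days` (merged sub-3 or unobserved
#'   days inside the phase), `censored_start`, `censored_end` (phase abuts
#'   the first/last observed day) and `detum_uncertain` (`TRUE` when the
#'   true detumescence day fell on an unobserved day and the first later
#'   observed sub-3 day was used instead).
#'
#' @examples
#' x <- tibble::tibble(
#'   female_id = "F1", date = 1:7,
#'   score = c(3, 3, 2, 2, 3, 3, 2)
#' )
#' segment_phases(x)
#' @export
segment_phases <- function(swelling, merge_gap_max_days = 4,
                           missing_gap_max_days = 4) {
  check_columns(swelling, c("female_id", "date", "score"), "swelling")
  if (!"observed" %in% names(swelling)) swelling$observed <- TRUE
  if (merge_gap_max_days < 1 || missing_gap_max_days < 1) {
    abort("Gap parameters must be >= 1 day.")
  }
  obs <- swelling[swelling$observed, , drop = FALSE]
  bad <- !obs$score %in% c(1, 2, 3)
  if (any(bad)) {
    abort("`score` must be 1, 2 or 3 on observed days.")
  }
  check_sorted_unique(swelling, "female_id", "date", "swelling")

  out <- lapply(split(obs, obs$female_id), function(fem) {
    segment_one_female(fem, merge_gap_max_days, missing_gap_max_days)
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0L) {
    return(tibble(
      female_id = character(), phase_id = integer(),
      onset_date = swelling$date[0], last_max_date = swelling$date[0],
      detumescence_date = swelling$date[0], length_days = integer(),
      gap_days = integer(), censored_start = logical(),
      censored_end = logical(), detum_uncertain = logical()
    ))
  }
  dplyr::arrange(out, .data$female_id, .data$onset_date)
}

# Core run-merge scan for a single female's observed rows (sorted).
segment_one_female <- function(fem, merge_gap_max_days, missing_gap_max_days) {
  d3 <- fem$date[fem$score == 3]
  if (length(d3) == 0L) return(NULL)
  obs_dates <- as.numeric(fem$date)
  sub3_dates <- as.numeric(fem$date[fem$score < 3])
  d3n <- as.numeric(d3)

  # Decide, for each consecutive pair of score-3 days, whether they belong
  # to the same phase. The allowance depends on whether the gap contains an
  # observed sub-3 day (an actual dip) or only unobserved days.
  grp <- integer(length(d3n))
  grp[1] <- 1L
  if (length(d3n) > 1L) {
    for (i in 2:length(d3n)) {
      gap <- d3n[i] - d3n[i - 1]
      between <- sub3_dates[sub3_dates > d3n[i - 1] & sub3_dates < d3n[i]]
      allowance <- if (gap <= 1) {
        Inf # consecutive days: always the same run
      } else if (length(between) > 0L) {
        merge_gap_max_days
      } else {
        missing_gap_max_days
      }
      grp[i] <- if (gap <= allowance) grp[i - 1] else grp[i - 1] + 1L
    }
  }

  first_obs <- min(obs_dates)
  last_obs <- max(obs_dates)
  phases <- lapply(unique(grp), function(g) {
    run <- d3[grp == g]
    onset <- run[1]
    last_max <- run[length(run)]
    n_max_days <- length(run)
    length_days <- day_diff(last_max, onset) + 1L
    censored_start <- as.numeric(onset) == first_obs
    censored_end <- as.numeric(last_max) == last_obs

    # Next phase's onset bounds the search for this phase's detumescence.
    later3 <- d3n[d3n > as.numeric(last_max)]
    upper <- if (length(later3) > 0L) min(later3) else Inf
    if (censored_end) {
      detum <- onset; detum[1] <- NA
      uncertain <- NA
    } else {
      cand <- sub3_dates[sub3_dates > as.numeric(last_max) & sub3_dates < upper]
      if (length(cand) == 0L) {
        detum <- onset; detum[1] <- NA
        uncertain <- TRUE
      } else {
        detum <- onset + (min(cand) - as.numeric(onset))
        uncertain <- min(cand) != as.numeric(last_max) + 1
      }
    }
    tibble(
      female_id = fem$female_id[1],
      onset_date = onset,
      last_max_date = last_max,
      detumescence_date = detum,
      length_days = length_days,
      gap_days = length_days - n_max_days,
      censored_start = censored_start,
      censored_end = censored_end,
      detum_uncertain = uncertain
    )
  })
  res <- dplyr::bind_rows(phases)
  res$phase_id <- seq_len(nrow(res))
  res[, c(
    "female_id", "phase_id", "onset_date", "last_max_date",
    "detumescence_date", "length_days", "gap_days", "censored_start",
    "censored_end", "detum_uncertain"
  )]
}

#' Index a calendar day relative to a phase landmark
#'
#' Converts calendar days to integer day indices under one of the two
#' alignments used throughout the package: `"onset"` maps the MSP onset to
#' day 1, counting up; `"detumescence"` maps the detumescence day to day 0,
#' with earlier days negative.
#'
#' @param date Calendar day(s) (`Date` or integer), vectorized.
#' @param phase A single phase: one row of [segment_phases()] output, or any
#'   list with `onset_date` and `detumescence_date`.
#' @param alignment `"onset"` or `"detumescence"`.
#' @return Integer day index (defined for any date, inside the phase or not).
#' @examples
#' ph <- list(onset_date = 10, detumescence_date = 20)
#' align_day_index(10, ph, "onset")         # 1
#' align_day_index(20, ph, "detumescence")  # 0
#' @export
align_day_index <- function(date, phase, alignment = c("onset", "detumescence")) {
  alignment <- match.arg(alignment)
  if (alignment == "onset") {
    day_diff(date, phase$onset_date) + 1L
  } else {
    if (is.na(phase$detumescence_date[1])) {
      abort("Phase has no detumescence date; cannot align to detumescence.")
    }
    day_diff(date, phase$detumescence_date)
  }
}
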