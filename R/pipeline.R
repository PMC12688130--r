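# End-to-end orchestration: segment -> detect -> classify -> probabilities
# -> behaviour tables -> dominance, with a reproducibility manifest.

#' Detect and classify ovulation for every segmented phase
#'
#' For each maximal swelling phase, scans the female's filtered hormone
#' samples from `scan_before` days before onset to `scan_after` days after
#' detumescence (ovulation can fall outside the phase itself), runs
#' [detect_ovulation()], and merges the call with the phase via
#' [classify_cycle()].
#'
#' @param phases Output of [segment_phases()].
#' @param samples Filtered urine samples ([filter_samples()]).
#' @param scan_before,scan_after Scan-window margins in days (defaults 5
#'   and 10).
#' @param ... Passed to [detect_ovulation()].
#' @return A tibble of cycle records, one per phase (see
#'   [classify_cycle()]).
#' @export
detect_cycles <- function(phases, samples, scan_before = 5, scan_after = 10,
                          ...) {
  check_columns(phases, c("female_id", "phase_id", "onset_date",
                          "detumescence_date"), "phases")
  check_columns(samples, c("female_id", "date", "pdg"), "samples")
  rows <- lapply(seq_len(nrow(phases)), function(i) {
    ph <- phases[i, ]
    end_ref <- if (is.na(ph$detumescence_date)) ph$last_max_date else
      ph$detumescence_date
    lo <- ph$onset_date - scan_before
    hi <- end_ref + scan_after
    # Include the 10 days before the scan start so that trailing baselines
    # are never truncated at the window edge; rises may only start at
    # or after `lo`.
    sub <- samples[samples$female_id == ph$female_id &
                     as.numeric(samples$date) >= as.numeric(lo) - 10 &
                     as.numeric(samples$date) <= as.numeric(hi), ,
                   drop = FALSE]
    call <- detect_ovulation(sub, scan_from = lo,
                             cycle_id = sprintf("%s-p%d", ph$female_id,
                                                ph$phase_id), ...)
    if (nrow(sub) == 0L) call$female_id <- ph$female_id
    classify_cycle(ph, call)
  })
  dplyr::bind_rows(rows)
}

#' Day-specific probabilities from cycle records, both alignments
#'
#' Aligns each detected ovulation to the MSP onset (day 1) and to
#' detumescence (day 0) and computes the day-specific ovulation and
#' fertility probability vectors under each alignment.
#'
#' @param cycle_records Output of [detect_cycles()].
#' @param window Fertile-window width (default 4 days).
#' @return A tibble stacking the four vectors (columns of
#'   [ovulation_probability()]).
#' @export
day_probabilities <- function(cycle_records, window = 4) {
  ov <- cycle_records[cycle_records$status == "ovulatory", , drop = FALSE]
  if (nrow(ov) == 0L) abort("No ovulatory cycles in `cycle_records`.")
  onset_idx <- day_diff(ov$ovulation_date, ov$onset_date) + 1L
  keep <- !is.na(ov$detumescence_date)
  detum_idx <- day_diff(ov$ovulation_date[keep], ov$detumescence_date[keep])
  res <- list(
    ovulation_probability(onset_idx, "onset"),
    fertility_probability(ovulation_probability(onset_idx, "onset"), window)
  )
  if (sum(keep) > 0) {
    res <- c(res, list(
      ovulation_probability(detum_idx, "detumescence"),
      fertility_probability(ovulation_probability(detum_idx, "detumescence"),
                            window)
    ))
  }
  dplyr::bind_rows(res)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order on an in-memory dataset (the
#' list of tables produced by [simulate_dataset()], or equivalently shaped
#' field data): sample filtering, phase segmentation, ovulation detection
#' and classification, day-specific probabilities under both alignments,
#' intensive-following counts, the dyad-day mating-effort table, daily
#' aggression rates, and the male dominance hierarchy. Each stage validates
#' its input schema and aborts with a stage-tagged, named-column diagnostic
#' on violation. No stage mutates its inputs.
#'
#' @param data A named list with `swelling`, `hormones`, and optionally
#'   `events`, `party`, `metadata`.
#' @param merge_gap_max_days Phase-continuity window (default 4 days).
#' @param window Dyad-day ovulation-offset window (default `c(-14, 0)`).
#' @param excluded_dyads Optional data frame `male_id`, `female_id`.
#' @param h_prime_iterations Randomizations for the linearity index
#'   (default 2000).
#' @param seed Seed for the h' randomization (default 1).
#' @param ... Further arguments to [detect_cycles()].
#' @return A list: `phases`, `cycles`, `day_probs`, `following`,
#'   `dyad_day`, `aggression`, `dominance` (scores, steepness, linearity)
#'   and `manifest`.
#' @export
run_pipeline <- function(data, merge_gap_max_days = 4, window = c(-14, 0),
                         excluded_dyads = NULL, h_prime_iterations = 2000,
                         seed = 1L, ...) {
  if (!is.list(data)) abort("`data` must be a named list of tables.")
  for (nm in c("swelling", "hormones")) {
    if (is.null(data[[nm]])) abort(sprintf("`data$%s` is required.", nm))
  }
  counts <- list()

  samples <- filter_samples(data$hormones)
  counts$hormone_samples_in <- nrow(data$hormones)
  counts$hormone_samples_kept <- nrow(samples)
  counts$hormone_samples_excluded <- nrow(attr(samples, "exclusions"))

  phases <- segment_phases(data$swelling, merge_gap_max_days)
  counts$swelling_rows <- nrow(data$swelling)
  counts$phases <- nrow(phases)

  cycles <- detect_cycles(phases, samples, ...)
  counts$cycles_ovulatory <- sum(cycles$status == "ovulatory")
  counts$cycles_anovulatory <- sum(cycles$status == "anovulatory")
  counts$cycles_undetermined <- sum(cycles$status == "undetermined")

  day_probs <- if (any(cycles$status == "ovulatory")) {
    day_probabilities(cycles)
  } else {
    NULL
  }

  following <- dyad_day <- aggression <- dominance <- NULL
  if (!is.null(data$events)) {
    following <- count_intensive_following(data$events)
    if (!is.null(data$party) && any(cycles$status == "ovulatory")) {
      dyad_day <- assemble_dyad_day(
        data$events, data$party, cycles, metadata = data$metadata,
        window = window, excluded_dyads = excluded_dyads
      )
      counts$dyad_day_rows <- nrow(dyad_day)
    }
    aggr_events <- data$events[data$events$event_type == "aggression", ,
                               drop = FALSE]
    if (nrow(aggr_events) > 0 && !is.null(data$party)) {
      daily_hours <- data$party |>
        dplyr::distinct(.data$date, .data$hour) |>
        dplyr::count(.data$date, name = "hours")
      daily_aggr <- aggr_events |>
        dplyr::count(.data$date, name = "n_aggression") |>
        dplyr::right_join(daily_hours, by = "date") |>
        dplyr::mutate(n_aggression = dplyr::coalesce(.data$n_aggression, 0L))
      aggression <- aggression_rate(daily_aggr)
      bouts <- tibble(
        winner_id = aggr_events$actor_id,
        loser_id = aggr_events$target_id,
        tied = aggr_events$tied
      )
      male_ids <- if (!is.null(data$metadata)) {
        data$metadata$id[data$metadata$sex == "M"]
      } else {
        NULL
      }
      wl <- build_winloss_matrix(bouts, individuals = male_ids)
      scores <- davids_score(wl)
      dominance <- list(
        matrix = wl,
        scores = scores,
        steepness = hierarchy_steepness(scores),
        linearity = if (nrow(wl) >= 3) {
          h_prime(wl, n_randomizations = h_prime_iterations, seed = seed)
        } else {
          NULL
        }
      )
      counts$agonistic_bouts <- sum(wl)
    }
  }

  manifest <- list(
    timestamp = format(Sys.time(), tz = "UTC"),
    package_version = as.character(utils::packageVersion("cyclescope")),
    config_hash = rlang::hash(list(merge_gap_max_days, window,
                                   excluded_dyads, h_prime_iterations, seed)),
    input_hashes = lapply(
      data[intersect(names(data),
                     c("swelling", "hormones", "events", "party",
                       "metadata"))],
      table_hash
    ),
    output_hashes = list(
      phases = table_hash(phases),
      cycles = table_hash(cycles),
      day_probs = if (!is.null(day_probs)) table_hash(day_probs)
    ),
    counts = counts
  )
  list(
    phases = phases, cycles = cycles, day_probs = day_probs,
    following = following, dyad_day = dyad_day, aggression = aggression,
    dominance = dominance, manifest = manifest
  )
}

#' Summary report of pipeline outputs
#'
#' Assembles the tabular analogues of the study's headline displays:
#' day-probability tables under both alignments, intensive-following
#' counts by aligned day, the top-k copulation share, a dominance summary,
#' the cross-study MSP-length comparison, and (when ground truth is
#' available) the scenario-contrast block. Sections without data are
#' marked `"no data"`.
#'
#' @param outputs Result of [run_pipeline()].
#' @param truth Optional ground-truth table (enables the scenario
#'   contrast).
#' @param top_k Ranks counted in the copulation-share block (default 3).
#' @return A named list of report sections.
#' @export
pipeline_report <- function(outputs, truth = NULL, top_k = 3) {
  sections <- list()
  sections$day_probabilities <- outputs$day_probs %||% "no data"
  sections$lag_summary <- {
    ov <- outputs$cycles[outputs$cycles$status == "ovulatory" &
                           !is.na(outputs$cycles$lag_days), , drop = FALSE]
    if (nrow(ov)) summary_mean_sd(ov$lag_days) else "no data"
  }
  sections$following_by_day <- if (!is.null(outputs$following) &&
                                   !is.null(outputs$cycles)) {
    fol <- outputs$following
    cyc <- outputs$cycles[outputs$cycles$status == "ovulatory", ,
                          drop = FALSE]
    if (nrow(fol) && nrow(cyc)) {
      joined <- dplyr::inner_join(fol, cyc, by = "female_id",
                                  relationship = "many-to-many")
      joined <- joined[!is.na(joined$detumescence_date), , drop = FALSE]
      joined$day_from_detum <- day_diff(joined$date,
                                        joined$detumescence_date)
      keep <- joined$day_from_detum >= -25 & joined$day_from_detum <= 5
      dplyr::summarise(
        dplyr::group_by(joined[keep, ], .data$day_from_detum),
        n_following_males = sum(.data$n_following_males), .groups = "drop"
      )
    } else {
      "no data"
    }
  } else {
    "no data"
  }
  sections$copulation_share <- if (!is.null(outputs$dyad_day) &&
                                   "male_rank" %in% names(outputs$dyad_day)) {
    by_male <- outputs$dyad_day |>
      dplyr::group_by(male_id = .data$male_id, rank = .data$male_rank) |>
      dplyr::summarise(n_copulation = sum(.data$n_copulation),
                       .groups = "drop")
    if (sum(by_male$n_copulation) > 0) {
      top_k_copulation_share(by_male, k = min(top_k, nrow(by_male)))
    } else {
      "no data"
    }
  } else {
    "no data"
  }
  sections$dominance <- outputs$dominance %||% "no data"
  sections$msp_comparison <- compare_msp_lengths()
  sections$scenario_contrast <- if (!is.null(truth)) {
    tryCatch(scenario_contrast(outputs$cycles), error = function(e) "no data")
  } else {
    "no data"
  }
  sections
}
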