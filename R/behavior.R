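# Behaviour-side data constructions: intensive-following counts, dyad-day
# mating-effort tables with exposure offsets, male-male aggression rates,
# predictor codings and hurdle-style subsets. Model fitting itself is out
# of scope: this module emits model-ready tables (response, offset,
# standardized predictors, grouping keys) for any statistics environment.

#' Ordinal infant-age code
#'
#' Codes female reproductive state on an ordinal half-year scale: `-1` from
#' the conceptive detumescence day until 6 months before parturition,
#' `-0.5` during the final 6 months of pregnancy, `0` for a newborn, then
#' the infant's age floored to 0.5-year bins and capped at 5. Days before
#' the conceptive detumescence are uncoded (`NA`).
#'
#' @param obs_date Observation day(s); vectorized.
#' @param parturition_date Parturition day (scalar or same length).
#' @param conception_date Conceptive detumescence day; when `NA` it is
#'   imputed as `parturition_date - gestation_days`.
#' @param gestation_days Gestation length used for imputation (default 240,
#'   about 8 months).
#' @param cap Maximum code (default 5).
#' @return Numeric code in `{-1, -0.5, 0, 0.5, ..., cap}` or `NA`.
#' @examples
#' infant_age_code(100, parturition_date = 190)  # 3 months pre-partum: -0.5
#' infant_age_code(190, parturition_date = 190)  # newborn: 0
#' @export
infant_age_code <- function(obs_date, parturition_date,
                            conception_date = NA, gestation_days = 240,
                            cap = 5) {
  k <- max(length(obs_date), length(parturition_date), length(conception_date))
  obs <- rep_len(as.numeric(obs_date), k)
  part <- rep_len(as.numeric(parturition_date), k)
  conc <- rep_len(as.numeric(conception_date), k)
  conc <- ifelse(is.na(conc), part - gestation_days, conc)
  half_year <- 365.25 / 2

  age_years <- (obs - part) / 365.25
  code <- pmin(floor(age_years * 2) / 2, cap)
  code[obs < part] <- -0.5
  code[obs < part - half_year] <- -1
  code[obs < conc] <- NA_real_
  code
}

#' Standardize predictor values to z-scores
#'
#' `(x - mean) / sd` with the n-1 sample standard deviation, so that every
#' predictor enters a model with mean 0 and standard deviation 1.
#'
#' @param x Numeric vector with at least 2 non-missing, non-constant values.
#' @return Numeric vector of z-scores (`NA`s preserved).
#' @export
standardize <- function(x) {
  v <- x[!is.na(x)]
  if (length(v) < 2) abort("`x` needs at least 2 non-missing values.")
  s <- sd(v)
  if (s == 0) abort("`x` is constant; cannot standardize.")
  (x - mean(v)) / s
}

#' Count males intensively following each female per day
#'
#' Intensive following is a male keeping within 10 m of a target female for
#' more than `min_duration` minutes (default 5). Counts the number of
#' *distinct* males with at least one qualifying event per female-day.
#'
#' @param events Event table with columns `event_type`, `actor_id`,
#'   `target_id`, `date` and `duration_min`; rows with
#'   `event_type == "intensive_follow"` are used.
#' @param states Optional female-day table (columns `female_id`, `date`);
#'   when given, the result covers every state row, with zero counts filled
#'   in.
#' @param min_duration Qualification threshold in minutes, strict (default 5).
#' @return A tibble `female_id`, `date`, `n_following_males`.
#' @export
count_intensive_following <- function(events, states = NULL, min_duration = 5) {
  check_columns(events, c("event_type", "actor_id", "target_id", "date"),
                "events")
  fol <- events[events$event_type == "intensive_follow", , drop = FALSE]
  if (!"duration_min" %in% names(fol)) {
    abort("intensive_follow events need a `duration_min` column.")
  }
  fol <- fol[!is.na(fol$duration_min) & fol$duration_min > min_duration, ,
             drop = FALSE]
  counts <- fol |>
    dplyr::distinct(.data$target_id, .data$date, .data$actor_id) |>
    dplyr::count(female_id = .data$target_id, .data$date,
                 name = "n_following_males")
  if (is.null(states)) return(counts)
  check_columns(states, c("female_id", "date"), "states")
  states |>
    dplyr::distinct(.data$female_id, .data$date) |>
    dplyr::left_join(counts, by = c("female_id", "date")) |>
    dplyr::mutate(n_following_males = dplyr::coalesce(.data$n_following_males, 0L))
}

#' Assemble the dyad-day mating-effort table
#'
#' Builds one row per male x female x day with the day's offset from the
#' female's ovulation restricted to `window` (default `[-14, 0]`, a 15-day
#' span matching the published mean MSP length of 13.5 +/- 1.8 days),
#' shared observation hours from hourly party records (the model offset),
#' and per-dyad daily counts of copulations, interventions and
#' solicitations. Dyads listed in `excluded_dyads` (e.g., a mother-son
#' pair) are dropped; rows with zero shared hours are dropped; days with no
#' party record are dropped and logged.
#'
#' Interventions whose target is female are excluded from intervention
#' counts when `metadata` identifies sexes; intervention events are
#' attributed to the dyad via their `context_female_id` column (the female
#' whose copulation was contested) when present, else via `target_id`.
#'
#' @param events Event table (`event_type`, `actor_id`, `target_id`,
#'   `date`, optionally `context_female_id`).
#' @param party Hourly party records: `date`, `hour`, `id` (one row per
#'   individual per observation hour).
#' @param cycles Cycle table with `female_id`, `cycle_id`,
#'   `ovulation_date` (non-ovulatory rows are ignored).
#' @param metadata Optional individual table `id`, `sex` (`"M"`/`"F"`), and
#'   optionally `age`, `rank`; male list and male covariates come from it.
#' @param window Integer bounds of the ovulation-day offset, inclusive.
#' @param excluded_dyads Optional data frame `male_id`, `female_id`.
#' @return A tibble with keys (`male_id`, `female_id`, `cycle_id`, `date`,
#'   `day_from_ovulation`), the exposure `hours_together`, counts
#'   (`n_copulation`, `n_intervention`, `n_solicitation`), male covariates
#'   when available, and the random-effect key `dyad_cycle`. A `log`
#'   attribute records rows dropped at each filter.
#' @export
assemble_dyad_day <- function(events, party, cycles, metadata = NULL,
                              window = c(-14, 0), excluded_dyads = NULL) {
  check_columns(events, c("event_type", "actor_id", "target_id", "date"),
                "events")
  check_columns(party, c("date", "hour", "id"), "party")
  check_columns(cycles, c("female_id", "cycle_id", "ovulation_date"), "cycles")

  cyc <- cycles[!is.na(cycles$ovulation_date), , drop = FALSE]
  if (nrow(cyc) == 0L) abort("`cycles` contains no ovulation dates.")
  males <- if (!is.null(metadata)) {
    check_columns(metadata, c("id", "sex"), "metadata")
    metadata$id[metadata$sex == "M"]
  } else {
    setdiff(unique(c(events$actor_id, party$id)), cyc$female_id)
  }

  # Candidate grid: every male x cycle x in-window day.
  grid <- tidyr::crossing(
    male_id = males,
    cyc[, c("female_id", "cycle_id", "ovulation_date")]
  ) |>
    tidyr::crossing(day_from_ovulation = seq(window[1], window[2])) |>
    dplyr::mutate(date = .data$ovulation_date + .data$day_from_ovulation)
  n_grid <- nrow(grid)

  if (!is.null(excluded_dyads) && nrow(excluded_dyads) > 0L) {
    grid <- dplyr::anti_join(grid, excluded_dyads,
                             by = c("male_id", "female_id"))
  }
  n_after_dyads <- nrow(grid)

  # Shared hours: number of observation hours both members were in party.
  party_key <- party |>
    dplyr::distinct(.data$date, .data$hour, .data$id)
  shared <- dplyr::inner_join(
    party_key, party_key,
    by = c("date", "hour"), suffix = c("_m", "_f"),
    relationship = "many-to-many"
  ) |>
    dplyr::count(male_id = .data$id_m, female_id = .data$id_f, .data$date,
                 name = "hours_together")
  party_dates <- unique(as.numeric(party$date))
  no_party <- !(as.numeric(grid$date) %in% party_dates)
  grid <- grid[!no_party, , drop = FALSE]
  grid <- dplyr::left_join(grid, shared,
                           by = c("male_id", "female_id", "date")) |>
    dplyr::mutate(hours_together = dplyr::coalesce(.data$hours_together, 0L))
  n_zero_hours <- sum(grid$hours_together <= 0)
  grid <- grid[grid$hours_together > 0, , drop = FALSE]

  # Event counts per dyad-day.
  count_type <- function(type, actor, target) {
    ev <- events[events$event_type == type, , drop = FALSE]
    if (nrow(ev) == 0L) {
      return(tibble(male_id = character(), female_id = character(),
                    date = events$date[0], nn = integer()))
    }
    dplyr::count(ev, male_id = ev[[actor]], female_id = ev[[target]],
                 .data$date, name = "nn")
  }
  ev_int <- events[events$event_type == "intervention", , drop = FALSE]
  if (!is.null(metadata) && nrow(ev_int) > 0L) {
    female_ids <- metadata$id[metadata$sex == "F"]
    drop_female_target <- ev_int$target_id %in% female_ids
    ev_int <- ev_int[!drop_female_target, , drop = FALSE]
  }
  int_target <- if ("context_female_id" %in% names(ev_int) &&
                    any(!is.na(ev_int$context_female_id))) {
    "context_female_id"
  } else {
    "target_id"
  }
  cop <- count_type("copulation", "actor_id", "target_id")
  sol <- count_type("solicitation", "actor_id", "target_id")
  intv <- if (nrow(ev_int) > 0L) {
    dplyr::count(ev_int, male_id = ev_int$actor_id,
                 female_id = ev_int[[int_target]], .data$date, name = "nn")
  } else {
    cop[0, ]
  }

  add_count <- function(g, cnt, col) {
    names(cnt)[names(cnt) == "nn"] <- col
    g <- dplyr::left_join(g, cnt, by = c("male_id", "female_id", "date"))
    g[[col]] <- dplyr::coalesce(g[[col]], 0L)
    g
  }
  grid <- add_count(grid, cop, "n_copulation")
  grid <- add_count(grid, intv, "n_intervention")
  grid <- add_count(grid, sol, "n_solicitation")

  if (!is.null(metadata)) {
    cov_cols <- intersect(c("rank", "age"), names(metadata))
    if (length(cov_cols) > 0L) {
      mcov <- metadata[metadata$sex == "M", c("id", cov_cols), drop = FALSE]
      names(mcov) <- c("male_id", paste0("male_", cov_cols))
      grid <- dplyr::left_join(grid, mcov, by = "male_id")
    }
  }
  grid$dyad_cycle <- paste(grid$male_id, grid$female_id, grid$cycle_id,
                           sep = ":")
  grid <- dplyr::arrange(grid, .data$cycle_id, .data$date, .data$male_id)
  attr(grid, "log") <- tibble(
    stage = c("grid", "dyad_exclusion", "no_party_record", "zero_shared_hours",
              "kept"),
    n = c(n_grid, n_grid - n_after_dyads, sum(no_party), n_zero_hours,
          nrow(grid))
  )
  grid
}

#' Daily male-male aggression rate
#'
#' Divides the day's total male-male aggression count by the day's total
#' following hours, then square-root transforms the rate (the transform
#' under which the published daily rates satisfy linear-model normality).
#' Rows with non-positive hours are dropped and logged.
#'
#' @param daily Data frame with columns `date`, `n_aggression`, `hours`.
#' @return `daily` with `rate` (= count/hours) and `rate_sqrt` columns and
#'   a `log` attribute counting dropped rows.
#' @export
aggression_rate <- function(daily) {
  check_columns(daily, c("date", "n_aggression", "hours"), "daily")
  bad <- !(daily$hours > 0) | is.na(daily$hours)
  out <- daily[!bad, , drop = FALSE]
  out <- dplyr::mutate(
    out,
    rate = .data$n_aggression / .data$hours,
    rate_sqrt = sqrt(.data$rate)
  )
  attr(out, "log") <- tibble(stage = c("dropped_nonpositive_hours", "kept"),
                             n = c(sum(bad), nrow(out)))
  out
}

#' Copulation share of the top-ranked males
#'
#' Proportion (as a percentage) of all copulations performed by the `k`
#' highest-ranking males.
#'
#' @param counts Data frame with `male_id`, `n_copulation`, `rank` (1 =
#'   highest).
#' @param k Number of top ranks.
#' @return A list with `share_pct`, `top_count`, `total`.
#' @export
top_k_copulation_share <- function(counts, k = 3) {
  check_columns(counts, c("male_id", "n_copulation", "rank"), "counts")
  if (k > nrow(counts)) abort("`k` exceeds the number of males.")
  total <- sum(counts$n_copulation)
  if (total <= 0) abort("No copulations in `counts`.")
  ord <- counts[order(counts$rank), , drop = FALSE]
  top <- sum(ord$n_copulation[seq_len(k)])
  list(share_pct = 100 * top / total, top_count = top, total = total)
}

#' Hurdle-style subsets of the female-day table
#'
#' Mirrors a hurdle model's two stages plus the simultaneous-choice subset:
#' the full female-day table; only days on which the female had maximal
#' swelling (score 3); and only days on which at least `fms_min` females
#' had maximal swelling in the party.
#'
#' @param states Female-day table with `swelling_score` and `n_fms`
#'   (females with maximal swelling present that day).
#' @param fms_min Threshold for the multi-FMS subset (default 2, i.e. a
#'   choice between at least two maximally swollen females).
#' @return A list of tibbles `full`, `msp_only`, `multi_fms`, with an
#'   attached `counts` element.
#' @export
hurdle_subsets <- function(states, fms_min = 2) {
  check_columns(states, c("swelling_score", "n_fms"), "states")
  full <- as_tibble(states)
  msp_only <- full[full$swelling_score == 3, , drop = FALSE]
  multi <- full[full$n_fms >= fms_min, , drop = FALSE]
  list(
    full = full, msp_only = msp_only, multi_fms = multi,
    counts = c(full = nrow(full), msp_only = nrow(msp_only),
               multi_fms = nrow(multi))
  )
}
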