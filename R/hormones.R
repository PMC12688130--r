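# Urinary hormone filtering and PdG-based ovulation detection.
#
# Ovulation is dated from a sustained rise of urinary pregnanediol
# glucuronide (PdG) above a trailing baseline: the baseline for a given day
# is the mean PdG of the 10 preceding days; when PdG exceeds the baseline
# mean by more than `sd_multiplier` standard deviations on three successive
# sampled days falling within a 7-calendar-day span, the day before the
# first elevated day is the ovulation date. The fertile window is the 4
# days ending on the ovulation day (sperm survive ~3 days, the egg ~24 h).

#' Filter urine samples against assay sensitivity
#'
#' Removes samples whose creatinine-corrected concentrations fall below the
#' enzyme-immunoassay sensitivity limits (defaults: 6.6 pg/ml for estrone
#' conjugates E1C, 2.1 ng/ml for PdG). Values exactly at the limit are
#' retained. When a female has several samples on one day they are averaged
#' to a single record after filtering.
#'
#' @param samples Data frame with columns `female_id`, `date`, `e1c`, `pdg`
#'   and optionally `creatinine`.
#' @param e1c_min,pdg_min Sensitivity thresholds; samples strictly below
#'   either are excluded.
#' @param aggregate Average duplicate (female, day) records after filtering
#'   (default `TRUE`).
#' @return The retained samples, with an `exclusions` attribute: a tibble
#'   logging one row per excluded sample with its reason.
#' @export
filter_samples <- function(samples, e1c_min = 6.6, pdg_min = 2.1,
                           aggregate = TRUE) {
  check_columns(samples, c("female_id", "date", "e1c", "pdg"), "samples")
  if (any(samples$e1c < 0, na.rm = TRUE) || any(samples$pdg < 0, na.rm = TRUE)) {
    abort("Hormone concentrations must be non-negative.")
  }
  low_e1c <- !is.na(samples$e1c) & samples$e1c < e1c_min
  low_pdg <- !is.na(samples$pdg) & samples$pdg < pdg_min
  drop <- low_e1c | low_pdg
  reason <- dplyr::case_when(
    low_e1c & low_pdg ~ "e1c and pdg below sensitivity",
    low_e1c ~ "e1c below sensitivity",
    low_pdg ~ "pdg below sensitivity",
    TRUE ~ NA_character_
  )
  excl <- as_tibble(samples[drop, , drop = FALSE])
  excl$reason <- reason[drop]
  kept <- as_tibble(samples[!drop, , drop = FALSE])
  if (aggregate && nrow(kept) > 0L) {
    kept <- kept |>
      dplyr::group_by(.data$female_id, .data$date) |>
      dplyr::summarise(
        dplyr::across(dplyr::where(is.numeric), mean),
        .groups = "drop"
      )
  }
  attr(kept, "exclusions") <- excl
  kept
}

#' Trailing PdG baseline for a given day
#'
#' Mean and sample standard deviation of PdG over the samples dated in the
#' `window_days` calendar days strictly preceding `at_date`
#' (`[at_date - window_days, at_date - 1]`).
#'
#' @param samples Filtered samples for one female (columns `date`, `pdg`).
#' @param at_date The day whose baseline is wanted.
#' @param window_days Length of the trailing window (default 10 days).
#' @param min_samples Minimum number of samples for a usable baseline.
#' @return A list with `mean`, `sd`, `n` and `sufficient` (`n >= min_samples`).
#'   With a single sample `sd` is `NA`.
#' @export
pdg_baseline <- function(samples, at_date, window_days = 10, min_samples = 3) {
  check_columns(samples, c("date", "pdg"), "samples")
  off <- day_diff(samples$date, at_date)
  inwin <- off >= -window_days & off <= -1
  vals <- samples$pdg[inwin]
  list(
    mean = if (length(vals)) mean(vals) else NA_real_,
    sd = if (length(vals) >= 2) sd(vals) else NA_real_,
    n = length(vals),
    sufficient = length(vals) >= min_samples
  )
}

#' Detect ovulation from a sustained PdG rise
#'
#' Scans one cycle's filtered PdG series in date order. A candidate rise
#' starts at the earliest sampled day whose PdG exceeds its trailing
#' baseline mean by more than `sd_multiplier` baseline standard deviations;
#' the rise is confirmed when `n_sustained` successive *sampled* days
#' (starting at the candidate) all stay above that day's threshold and fall
#' within a `span_days`-calendar-day span. The ovulation date is
#' the day before the first elevated day. Because urine is not collected
#' daily, "consecutive days" is read as successive sampled days; this is
#' the only workable reading on sparse field sampling schedules.
#'
#' @param samples Filtered samples for one female's cycle window (columns
#'   `female_id`, `date`, `pdg`), sorted by date.
#' @param sd_multiplier Baseline SD multiple a day must exceed (default 2).
#' @param n_sustained Number of successive elevated sampled days (default 3).
#' @param span_days Calendar span the elevated days must fit in (default 7).
#' @param window_days Trailing baseline window (default 10).
#' @param min_baseline_n Minimum baseline samples; candidates with an
#'   insufficient baseline are skipped and logged (default 3).
#' @param min_coverage_n With no confirmed rise, the cycle is called
#'   `"anovulatory"` when at least this many samples were available, else
#'   `"undetermined"` (default 5).
#' @param exclude_elevated If `TRUE`, days already above the running
#'   threshold are excluded from later baselines (default `FALSE`).
#' @param scan_from Optional earliest date at which a rise may start;
#'   earlier samples still feed the trailing baselines.
#' @param cycle_id Optional label carried into the result.
#'
#' @return A one-row tibble (an ovulation call): `female_id`, `cycle_id`,
#'   `status` (`"ovulatory"`, `"anovulatory"` or `"undetermined"`),
#'   `ovulation_date`, `rise_start_date`, `baseline_mean`, `baseline_sd`,
#'   `n_baseline`, `n_samples`, plus an `elevated_dates` attribute and a
#'   `skipped` attribute logging candidates skipped for insufficient
#'   baselines.
#' @export
detect_ovulation <- function(samples, sd_multiplier = 2, n_sustained = 3,
                             span_days = 7, window_days = 10,
                             min_baseline_n = 3, min_coverage_n = 5,
                             exclude_elevated = FALSE, scan_from = NULL,
                             cycle_id = NA_character_) {
  check_columns(samples, c("female_id", "date", "pdg"), "samples")
  if (length(unique(samples$female_id)) > 1L) {
    abort("`detect_ovulation()` expects samples from a single female.")
  }
  samples <- samples[order(as.numeric(samples$date)), , drop = FALSE]
  n <- nrow(samples)
  # Coverage is judged over the scanned span only, not baseline history.
  n_scan <- if (is.null(scan_from)) n else
    sum(as.numeric(samples$date) >= as.numeric(scan_from))
  no_call <- function(status) {
    out <- tibble(
      female_id = if (n) samples$female_id[1] else NA_character_,
      cycle_id = cycle_id, status = status,
      ovulation_date = samples$date[NA_integer_][1],
      rise_start_date = samples$date[NA_integer_][1],
      baseline_mean = NA_real_, baseline_sd = NA_real_,
      n_baseline = NA_integer_, n_samples = n_scan
    )
    attr(out, "elevated_dates") <- samples$date[0]
    attr(out, "skipped") <- skipped_log
    out
  }
  skipped_log <- tibble(date = samples$date[0], reason = character())
  if (n == 0L) return(no_call("undetermined"))

  # Per-day elevation flags against each day's own trailing baseline.
  elevated <- logical(n)
  base_mean <- base_sd <- rep(NA_real_, n)
  base_n <- integer(n)
  base_ok <- logical(n)
  excluded_dates <- numeric(0)
  for (i in seq_len(n)) {
    hist <- samples[!(as.numeric(samples$date) %in% excluded_dates), , drop = FALSE]
    b <- pdg_baseline(hist, samples$date[i], window_days, min_baseline_n)
    base_mean[i] <- b$mean; base_sd[i] <- b$sd
    base_n[i] <- b$n; base_ok[i] <- b$sufficient
    if (b$sufficient && !is.na(b$sd)) {
      elevated[i] <- samples$pdg[i] > b$mean + sd_multiplier * b$sd
      if (exclude_elevated && elevated[i]) {
        excluded_dates <- c(excluded_dates, as.numeric(samples$date[i]))
      }
    }
  }

  # Earliest confirmed candidate wins. Days that look like a rise (PdG
  # above the series median) but lack a usable baseline are logged.
  med <- stats::median(samples$pdg)
  for (i in seq_len(n)) {
    if (!is.null(scan_from) &&
        as.numeric(samples$date[i]) < as.numeric(scan_from)) next
    if (!base_ok[i] && samples$pdg[i] > med) {
      skipped_log <- dplyr::bind_rows(skipped_log, tibble(
        date = samples$date[i], reason = "insufficient baseline"
      ))
      next
    }
    if (!elevated[i]) next
    idx <- i:min(n, i + n_sustained - 1L)
    if (length(idx) < n_sustained) next
    span <- day_diff(samples$date[idx[n_sustained]], samples$date[i])
    # The rise is sustained when PdG stays above the threshold set by the
    # rise-start day's baseline (the baseline of "a given day"); later
    # days' own trailing baselines would absorb the rise itself.
    thr <- base_mean[i] + sd_multiplier * base_sd[i]
    if (all(samples$pdg[idx] > thr) && span <= span_days - 1L) {
      out <- tibble(
        female_id = samples$female_id[1], cycle_id = cycle_id,
        status = "ovulatory",
        ovulation_date = samples$date[i] - 1L,
        rise_start_date = samples$date[i],
        baseline_mean = base_mean[i], baseline_sd = base_sd[i],
        n_baseline = base_n[i], n_samples = n_scan
      )
      attr(out, "elevated_dates") <- samples$date[idx]
      attr(out, "skipped") <- skipped_log
      return(out)
    }
  }
  no_call(if (n_scan >= min_coverage_n) "anovulatory" else "undetermined")
}

#' The 4-day fertile window for an ovulation date
#'
#' The fertile (periovulatory) window comprises the 3 days before ovulation
#' plus the ovulation day itself.
#'
#' @param ovulation_date Calendar day of ovulation.
#' @return A list with `start_date` (`ovulation_date - 3`), `end_date`
#'   (`ovulation_date`) and `day_offsets` (`-3:0`).
#' @examples
#' fertile_window(20)
#' @export
fertile_window <- function(ovulation_date) {
  if (length(ovulation_date) != 1L || is.na(ovulation_date)) {
    abort("`ovulation_date` must be a single non-missing day.")
  }
  list(
    start_date = ovulation_date - 3L,
    end_date = ovulation_date,
    day_offsets = -3:0
  )
}

#' Combine a phase and an ovulation call into a cycle record
#'
#' Computes the signed ovulation-to-detumescence lag
#' (`detumescence_date - ovulation_date`; positive when detumescence
#' follows ovulation) and flags ovulations falling outside the maximal
#' swelling phase.
#'
#' @param phase One row of [segment_phases()] output.
#' @param call One row of [detect_ovulation()] output for the same female.
#' @return A one-row tibble: ids, landmark dates, `status`, `lag_days`,
#'   `fertile_start`, `fertile_end` and `ovulation_outside_msp` (ovulation
#'   before onset or after detumescence).
#' @export
classify_cycle <- function(phase, call) {
  if (!identical(as.character(phase$female_id[1]), as.character(call$female_id[1]))) {
    abort("`phase` and `call` refer to different females.")
  }
  ovulatory <- identical(call$status[1], "ovulatory")
  lag <- if (ovulatory && !is.na(phase$detumescence_date[1])) {
    day_diff(phase$detumescence_date[1], call$ovulation_date[1])
  } else {
    NA_integer_
  }
  outside <- if (ovulatory) {
    ov <- call$ovulation_date[1]
    isTRUE(day_diff(ov, phase$onset_date[1]) < 0) ||
      (!is.na(phase$detumescence_date[1]) &&
         isTRUE(day_diff(ov, phase$detumescence_date[1]) > 0))
  } else {
    NA
  }
  fw <- if (ovulatory) fertile_window(call$ovulation_date[1]) else NULL
  tibble(
    female_id = phase$female_id[1],
    cycle_id = call$cycle_id[1],
    phase_id = phase$phase_id[1],
    onset_date = phase$onset_date[1],
    last_max_date = phase$last_max_date[1],
    detumescence_date = phase$detumescence_date[1],
    length_days = phase$length_days[1],
    status = call$status[1],
    ovulation_date = call$ovulation_date[1],
    lag_days = lag,
    fertile_start = if (ovulatory) fw$start_date else call$ovulation_date[1],
    fertile_end = if (ovulatory) fw$end_date else call$ovulation_date[1],
    ovulation_outside_msp = outside
  )
}
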