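# Day-specific ovulation and fertility probabilities, and the cross-study
# comparison of maximal-swelling-phase lengths.
#
# With n ovulatory cycles and n_t of them ovulating on aligned day t, the
# day-specific ovulation probability is P(T = t) = n_t / n. The
# day-specific fertility probability is the 4-term forward window sum
# P(X(f) = 1) = sum_{t = f}^{f + 3} P(T = t): a day is fertile when
# ovulation falls on it or on one of the next 3 days.

#' Day-specific ovulation probability
#'
#' Empirical distribution of aligned ovulation day indices over ovulatory
#' cycles: `P(T = t) = n_t / n`. Probabilities are stored with their exact
#' integer counts (`n_t`, `n`) so normalization is exact by construction.
#'
#' @param day_indices Integer day indices, one per ovulatory cycle, under a
#'   single alignment (see [align_day_index()]).
#' @param alignment Label recorded in the output (`"onset"`,
#'   `"detumescence"` or `"ovulation"`).
#' @return A tibble with columns `alignment`, `kind` (`"ovulation"`),
#'   `day`, `n_t`, `n` and `probability`, one row per day with positive
#'   mass, sorted by day.
#' @examples
#' ovulation_probability(c(5, 5, 7, 9))
#' @export
ovulation_probability <- function(day_indices,
                                  alignment = c("onset", "detumescence", "ovulation")) {
  alignment <- match.arg(alignment)
  day_indices <- day_indices[!is.na(day_indices)]
  if (length(day_indices) == 0L) {
    abort("At least one ovulatory cycle is required.")
  }
  tab <- table(day_indices)
  n <- length(day_indices)
  tibble(
    alignment = alignment,
    kind = "ovulation",
    day = as.integer(names(tab)),
    n_t = as.integer(tab),
    n = n,
    probability = as.integer(tab) / n
  )
}

#' Day-specific fertility probability
#'
#' Converts an ovulation-day distribution into the day-specific probability
#' of fertility via the forward window sum over the 4-day fertile window:
#' `P(X(f) = 1) = sum_{t = f}^{f + window - 1} P(T = t)`.
#'
#' @param ov Output of [ovulation_probability()].
#' @param window Fertile-window width in days (default 4).
#' @return A tibble like `ov` with `kind = "fertility"`, one row per day
#'   with positive fertility probability.
#' @examples
#' fertility_probability(ovulation_probability(c(5, 5, 7, 9)))
#' @export
fertility_probability <- function(ov, window = 4) {
  check_columns(ov, c("alignment", "kind", "day", "n_t", "n", "probability"), "ov")
  if (!all(ov$kind == "ovulation")) {
    abort("`ov` must be an ovulation-probability vector.")
  }
  n <- ov$n[1]
  support <- seq(min(ov$day) - window + 1L, max(ov$day))
  counts <- vapply(support, function(f) {
    sum(ov$n_t[ov$day >= f & ov$day <= f + window - 1L])
  }, integer(1))
  keep <- counts > 0L
  tibble(
    alignment = ov$alignment[1],
    kind = "fertility",
    day = as.integer(support[keep]),
    n_t = counts[keep],
    n = n,
    probability = counts[keep] / n
  )
}

#' Peak day of a day-probability vector
#'
#' Argmax over the stored days; ties are broken toward the earliest day and
#' flagged.
#'
#' @param vec A tibble from [ovulation_probability()] or
#'   [fertility_probability()].
#' @return One-row tibble with `day`, `probability` and `tie`.
#' @export
peak_day <- function(vec) {
  check_columns(vec, c("day", "probability"), "vec")
  if (nrow(vec) == 0L) abort("Empty probability vector.")
  pmax_ <- max(vec$probability)
  at <- vec$day[vec$probability == pmax_]
  tibble(day = min(at), probability = pmax_, tie = length(at) > 1L)
}

#' Mean and sample standard deviation of phase lengths
#'
#' @param lengths Numeric vector (e.g., study-average MSP lengths).
#' @return A list with `mean`, `sd` (n-1 denominator; `NA` when fewer than
#'   2 values) and `n`.
#' @export
summary_mean_sd <- function(lengths) {
  lengths <- lengths[!is.na(lengths)]
  list(
    mean = if (length(lengths)) mean(lengths) else NA_real_,
    sd = if (length(lengths) >= 2) sd(lengths) else NA_real_,
    n = length(lengths)
  )
}

#' Two-sample rank-sum (Mann-Whitney) test
#'
#' Computes the Mann-Whitney W statistic by mid-ranks
#' (`W = rank-sum of group a - n_a (n_a + 1) / 2`) and obtains the p-value
#' by exact enumeration when the pooled sample is tie-free and small, or by
#' the tie-corrected normal approximation with continuity correction
#' otherwise (delegated to [stats::wilcox.test()], which implements both
#' paths). The returned `method` label records which path was used.
#'
#' @param a,b Numeric vectors (non-empty).
#' @param alternative Passed through; default two-sided.
#' @param exact Force (`TRUE`)/suppress (`FALSE`) the exact path; default
#'   `NULL` = automatic (exact when tie-free and `n_a`, `n_b` < 50).
#' @return A list with `statistic` (W), `p_value`, `method` and the group
#'   sizes.
#' @export
rank_sum_test <- function(a, b, alternative = "two.sided", exact = NULL) {
  if (length(a) == 0L || length(b) == 0L) {
    abort("Both groups must be non-empty.")
  }
  r <- rank(c(a, b))
  w <- sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  ties <- anyDuplicated(c(a, b)) > 0L
  use_exact <- exact %||% (!ties && length(a) < 50 && length(b) < 50)
  ht <- suppressWarnings(
    wilcox.test(a, b, alternative = alternative, exact = use_exact,
                correct = TRUE)
  )
  stopifnot(isTRUE(all.equal(unname(ht$statistic), w)))
  list(
    statistic = w,
    p_value = ht$p.value,
    method = if (use_exact && !ties) {
      "exact enumeration"
    } else {
      "normal approximation, tie-corrected, continuity-corrected"
    },
    n_a = length(a), n_b = length(b)
  )
}

#' Cross-study maximal-swelling-phase length table
#'
#' Published per-study average MSP lengths for bonobos and chimpanzees
#' (captive and wild), bundled as a plain-text fixture. Bonobos average
#' 13.5 +/- 1.8 days over 8 studies; chimpanzees 11.3 +/- 1.1 days over 7.
#'
#' @return A tibble with columns `species`, `condition` (`C` captive, `W`
#'   wild), `n_cycles`, `n_id`, `avg_length_days`, `dispersion` (SD, or SE
#'   where `dispersion_is_se` is `TRUE`) and `site`.
#' @export
msp_length_table <- function() {
  path <- system.file("extdata", "msp_lengths.csv", package = "cyclescope",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_tibble(tab)
}

#' Compare MSP lengths between two species
#'
#' Runs [summary_mean_sd()] per species and [rank_sum_test()] on the
#' per-study average MSP lengths.
#'
#' @param tab A table like [msp_length_table()].
#' @param species_a,species_b Species labels to compare.
#' @return A list with `summary_a`, `summary_b` and `test`.
#' @export
compare_msp_lengths <- function(tab = msp_length_table(),
                                species_a = "bonobo", species_b = "chimpanzee") {
  check_columns(tab, c("species", "avg_length_days"), "tab")
  a <- tab$avg_length_days[tab$species == species_a]
  b <- tab$avg_length_days[tab$species == species_b]
  list(
    summary_a = summary_mean_sd(a),
    summary_b = summary_mean_sd(b),
    test = rank_sum_test(a, b)
  )
}
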