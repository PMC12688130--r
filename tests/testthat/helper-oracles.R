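# Independent brute-force oracles and tiny fixture builders. These stay
# deliberately naive: exhaustive scans and enumerations that are obviously
# correct at small n, against which the package implementations are checked.

# Build a one-female swelling table on integer days 1..length(scores).
make_swelling <- function(scores, female_id = "F1", observed = NULL) {
  tibble::tibble(
    female_id = female_id,
    date = seq_along(scores),
    score = scores,
    observed = observed %||% rep(TRUE, length(scores))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exhaustive run-scanner: enumerate score-3 runs on fully observed integer
# days, then merge neighbouring runs while the next run starts within
# `merge_gap` days of the previous run's last day.
oracle_segment <- function(scores, merge_gap = 4) {
  d3 <- which(scores == 3)
  if (length(d3) == 0) {
    return(data.frame(onset = integer(), last_max = integer()))
  }
  onsets <- d3[1]
  lasts <- d3[1]
  for (d in d3[-1]) {
    if (d - lasts[length(lasts)] <= merge_gap) {
      lasts[length(lasts)] <- d
    } else {
      onsets <- c(onsets, d)
      lasts <- c(lasts, d)
    }
  }
  data.frame(onset = onsets, last_max = lasts)
}

# Exhaustive two-sided rank-sum p-value over all C(n_a + n_b, n_a)
# labelings (tie-free inputs only).
oracle_rank_sum_p <- function(a, b) {
  pooled <- c(a, b)
  n_a <- length(a)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  mu <- n_a * length(b) / 2
  combos <- utils::combn(length(pooled), n_a)
  ws <- apply(combos, 2, function(idx) sum(r[idx]) - n_a * (n_a + 1) / 2)
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-12)
}

# Direct four-sum David's score computation with explicit loops.
oracle_davids <- function(m) {
  n <- nrow(m)
  p <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      tot <- m[i, j] + m[j, i]
      if (i != j && tot > 0) p[i, j] <- m[i, j] / tot
    }
  }
  w <- rowSums(p)
  l <- colSums(p)
  w2 <- numeric(n); l2 <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      w2[i] <- w2[i] + p[i, j] * w[j]
      l2[i] <- l2[i] + p[j, i] * l[j]
    }
  }
  w + w2 - l - l2
}

# Landau's h for a completed dominance matrix given as a logical
# "i dominates j" matrix.
oracle_landau <- function(dom) {
  v <- rowSums(dom)
  n <- nrow(dom)
  12 / (n^3 - n) * sum((v - (n - 1) / 2)^2)
}

# Exact h' by enumerating all 2^u completions of unknown dyads.
oracle_h_enumerate <- function(m) {
  n <- nrow(m)
  upper <- which(upper.tri(m), arr.ind = TRUE)
  dir <- m[upper] - t(m)[upper]
  unknown <- which(dir == 0)
  base <- matrix(FALSE, n, n)
  for (k in seq_len(nrow(upper))) {
    if (dir[k] > 0) base[upper[k, 1], upper[k, 2]] <- TRUE
    if (dir[k] < 0) base[upper[k, 2], upper[k, 1]] <- TRUE
  }
  if (length(unknown) == 0) return(oracle_landau(base))
  hs <- numeric(0)
  for (mask in 0:(2^length(unknown) - 1)) {
    dom <- base
    for (b in seq_along(unknown)) {
      k <- unknown[b]
      if (bitwAnd(mask, bitwShiftL(1L, b - 1L)) > 0) {
        dom[upper[k, 1], upper[k, 2]] <- TRUE
        dom[upper[k, 2], upper[k, 1]] <- FALSE
      } else {
        dom[upper[k, 1], upper[k, 2]] <- FALSE
        dom[upper[k, 2], upper[k, 1]] <- TRUE
      }
    }
    hs <- c(hs, oracle_landau(dom))
  }
  mean(hs)
}

# Step PdG series: flat baseline then a sustained plateau, daily samples.
make_step_series <- function(n_days = 30, step_day = 16, baseline = 10,
                             step_value = 30, noise_sd = 0, seed = 1,
                             female_id = "F1") {
  set.seed(seed)
  pdg <- rep(baseline, n_days) + rnorm(n_days, 0, noise_sd)
  pdg[seq(step_day, n_days)] <- step_value
  tibble::tibble(
    female_id = female_id, date = seq_len(n_days),
    e1c = 50, pdg = pdg, creatinine = 1
  )
}

# Match detected cycles to ground truth by female and onset date.
match_truth <- function(cycles, truth) {
  det <- cycles[cycles$status == "ovulatory", , drop = FALSE]
  m <- merge(as.data.frame(det), as.data.frame(truth),
             by = c("female_id", "onset_date"), suffixes = c(".det", ".true"))
  m$error <- as.integer(m$ovulation_date.det) -
    as.integer(m$ovulation_date.true)
  m
}
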