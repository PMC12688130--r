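# Dominance hierarchies from dyadic agonistic interactions: win-loss
# matrices, David's scores with normalization and ranks, hierarchy
# steepness, and the h' linearity index (Landau's h generalized to
# matrices with unknown or tied relationships via randomized completion).

#' Build a win-loss matrix from agonistic bouts
#'
#' Accumulates decided (non-tied) dyadic bouts into a square count matrix
#' with wins of the row individual over the column individual.
#'
#' @param bouts Data frame with `winner_id`, `loser_id`, optionally `tied`
#'   (logical; tied bouts are excluded) and `study_period`.
#' @param periods Optional vector of `study_period` labels to keep.
#' @param individuals Optional vector fixing the matrix order (defaults to
#'   the sorted union of winners and losers).
#' @return An integer matrix with zero diagonal and dimnames; total equals
#'   the number of retained bouts.
#' @export
build_winloss_matrix <- function(bouts, periods = NULL, individuals = NULL) {
  check_columns(bouts, c("winner_id", "loser_id"), "bouts")
  if (!is.null(periods)) {
    check_columns(bouts, "study_period", "bouts")
    bouts <- bouts[bouts$study_period %in% periods, , drop = FALSE]
  }
  if ("tied" %in% names(bouts)) {
    bouts <- bouts[!isTRUE_vec(bouts$tied), , drop = FALSE]
  }
  if (any(bouts$winner_id == bouts$loser_id)) {
    abort("Bouts cannot have winner == loser.")
  }
  ids <- individuals %||% sort(unique(c(bouts$winner_id, bouts$loser_id)))
  m <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(bouts) > 0L) {
    tab <- table(factor(bouts$winner_id, ids), factor(bouts$loser_id, ids))
    m <- m + unclass(tab)
  }
  storage.mode(m) <- "integer"
  m
}

isTRUE_vec <- function(x) !is.na(x) & x

#' David's scores, normalized scores and ranks
#'
#' For each dyad let `P_ij` be the proportion of i's wins over j (0 for
#' unobserved dyads). With `w_i = sum_j P_ij`, `l_i = sum_j P_ji`,
#' `w2_i = sum_j P_ij w_j` and `l2_i = sum_j P_ji l_j`, David's score is
#' `DS_i = w_i + w2_i - l_i - l2_i`; the normalized score is
#' `(DS_i + N(N-1)/2) / N`. The `"Dij"` variant replaces `P_ij` with the
#' sample-size-corrected proportion
#' `D_ij = P_ij - (P_ij - 0.5) / (n_ij + 1)`.
#'
#' @param m Win-loss matrix from [build_winloss_matrix()].
#' @param dyadic_index `"Pij"` (simple proportion, default) or `"Dij"`.
#' @return A tibble `id`, `ds`, `norm_ds`, `rank` (descending DS; ties
#'   broken by id), sorted by rank.
#' @export
davids_score <- function(m, dyadic_index = c("Pij", "Dij")) {
  dyadic_index <- match.arg(dyadic_index)
  n <- nrow(m)
  if (n < 2) abort("At least 2 individuals are required.")
  tot <- m + t(m)
  p <- ifelse(tot > 0, m / tot, 0)
  if (dyadic_index == "Dij") {
    p <- ifelse(tot > 0, p - (p - 0.5) / (tot + 1), 0)
  }
  diag(p) <- 0
  w <- rowSums(p)
  l <- colSums(p)
  w2 <- as.vector(p %*% w)
  l2 <- as.vector(t(p) %*% l)
  ds <- w + w2 - l - l2
  norm_ds <- (ds + n * (n - 1) / 2) / n
  ord <- order(-ds, -norm_ds, rownames(m))
  out <- tibble(
    id = rownames(m), ds = unname(ds), norm_ds = unname(norm_ds),
    rank = NA_integer_
  )
  out$rank[ord] <- seq_len(n)
  dplyr::arrange(out, .data$rank)
}

#' Steepness of the dominance hierarchy
#'
#' Absolute slope of the ordinary least-squares fit of normalized David's
#' scores against rank order 1..N. 0 for a flat hierarchy; steeper
#' hierarchies give larger values.
#'
#' @param scores Output of [davids_score()] (or any data frame with
#'   `norm_ds` and `rank`).
#' @return Absolute OLS slope (non-negative scalar).
#' @export
hierarchy_steepness <- function(scores) {
  check_columns(scores, c("norm_ds", "rank"), "scores")
  if (nrow(scores) < 2) abort("At least 2 individuals are required.")
  abs(unname(coef(lm(norm_ds ~ rank, data = scores))[2]))
}

# Landau's linearity index h for a fully decided dominance structure,
# from the vector of individuals each individual dominates.
landau_h <- function(v) {
  n <- length(v)
  12 / (n^3 - n) * sum((v - (n - 1) / 2)^2)
}

#' h' linearity index with randomization test
#'
#' Landau's h measures how linear a dominance hierarchy is (1 = perfectly
#' transitive). The h' modification handles unknown and tied dyads by
#' assigning them a random direction in each of `n_randomizations`
#' iterations and averaging h over iterations. Decided dyads keep the
#' direction of the majority of wins; dyads with equal wins both ways (or
#' never observed together) are treated as unknown. The right-tail p-value
#' compares, per iteration, the completed matrix's h with the h of a fully
#' random dominance structure on the same individuals.
#'
#' @param m Win-loss matrix (at least 3 individuals).
#' @param n_randomizations Iterations (default 10000).
#' @param seed Integer seed; required for reproducibility.
#' @return A list: `h_prime`, `p_value`, `n_unknown_dyads`, `n_individuals`,
#'   `n_randomizations`.
#' @export
h_prime <- function(m, n_randomizations = 10000, seed = 1L) {
  n <- nrow(m)
  if (n < 3) abort("At least 3 individuals are required.")
  if (n_randomizations < 1) abort("`n_randomizations` must be >= 1.")
  withr_seed <- function(expr) { # local RNG scope without extra deps
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  upper <- which(upper.tri(m), arr.ind = TRUE)
  wins_ij <- m[upper]
  wins_ji <- t(m)[upper]
  known_i_beats_j <- wins_ij > wins_ji
  known_j_beats_i <- wins_ji > wins_ij
  unknown <- !(known_i_beats_j | known_j_beats_i)
  n_unknown <- sum(unknown)

  base_dom <- matrix(FALSE, n, n)
  base_dom[upper[known_i_beats_j, , drop = FALSE]] <- TRUE
  base_dom[upper[known_j_beats_i, , drop = FALSE][, c(2, 1), drop = FALSE]] <- TRUE

  withr_seed({
    h_obs <- h_rand <- numeric(n_randomizations)
    unk_idx <- upper[unknown, , drop = FALSE]
    n_dyads <- nrow(upper)
    for (k in seq_len(n_randomizations)) {
      dom <- base_dom
      if (n_unknown > 0) {
        flip <- runif(n_unknown) < 0.5
        dom[unk_idx[flip, , drop = FALSE]] <- TRUE
        dom[unk_idx[!flip, , drop = FALSE][, c(2, 1), drop = FALSE]] <- TRUE
      }
      h_obs[k] <- landau_h(rowSums(dom))
      rdom <- matrix(FALSE, n, n)
      rflip <- runif(n_dyads) < 0.5
      rdom[upper[rflip, , drop = FALSE]] <- TRUE
      rdom[upper[!rflip, , drop = FALSE][, c(2, 1), drop = FALSE]] <- TRUE
      h_rand[k] <- landau_h(rowSums(rdom))
    }
    list(
      h_prime = mean(h_obs),
      p_value = mean(h_rand >= h_obs),
      n_unknown_dyads = n_unknown,
      n_individuals = n,
      n_randomizations = n_randomizations
    )
  })
}
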