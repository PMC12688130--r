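# Shared validators and small helpers.
#
# Dates are calendar days throughout: either `Date` or plain integers.
# All day arithmetic is integer-day arithmetic on closed intervals.

#' Difference between two calendar days, in whole days
#'
#' Works for `Date` and for integer day numbers; always returns an integer.
#' @param a,b dates (`Date` or numeric day numbers).
#' @return integer vector `a - b` in days.
#' @keywords internal
#' @noRd
day_diff <- function(a, b) {
  as.integer(as.numeric(a) - as.numeric(b))
}

#' Check a data frame for required columns
#'
#' Aborts with a named-column diagnostic when a required column is missing,
#' so that schema violations surface at the stage boundary rather than as
#' obscure downstream errors.
#' @param df a data frame.
#' @param required character vector of column names.
#' @param what label used in the error message.
#' @keywords internal
#' @noRd
check_columns <- function(df, required, what = "input") {
  if (!is.data.frame(df)) {
    abort(sprintf("`%s` must be a data frame.", what))
  }
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste0("`", missing, "`", collapse = ", ")
    ))
  }
  invisible(df)
}

#' Assert that a per-female series is sorted and duplicate-free
#' @keywords internal
#' @noRd
check_sorted_unique <- function(df, id_col, date_col, what = "series") {
  split_idx <- split(seq_len(nrow(df)), df[[id_col]])
  for (idx in split_idx) {
    d <- df[[date_col]][idx]
    if (anyDuplicated(d)) {
      abort(sprintf("%s has duplicate (%s, %s) records.", what, id_col, date_col))
    }
    if (is.unsorted(as.numeric(d), strictly = TRUE)) {
      abort(sprintf("%s must be sorted by %s within each %s.", what, date_col, id_col))
    }
  }
  invisible(df)
}

#' Stable content hash of a data frame (order-sensitive)
#'
#' Used by the run manifest to prove byte-level reproducibility of outputs.
#' @keywords internal
#' @noRd
table_hash <- function(df) {
  rlang::hash(lapply(df, function(x) {
    if (inherits(x, "Date")) as.integer(x) else x
  }))
}
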