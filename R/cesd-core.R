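#' CES-D item column names
#'
#' The package stores the 20 CES-D items in columns `item_01` .. `item_20`
#' of a data frame, each an integer in 0--3 (0--60 total score scale) or
#' `NA` for a missing response.
#'
#' @return Character vector of the 20 item column names.
#' @export
item_cols <- function() sprintf("item_%02d", 1:20)

#' Default positions of the positively worded items
#'
#' Sixteen CES-D items are negatively worded and four positively worded;
#' the positive ones are reverse-scored before summing. The canonical
#' instrument places the positive items at positions 4, 8, 12 and 16.
#'
#' @return Integer vector of length 4.
#' @export
positive_items_default <- function() c(4L, 8L, 12L, 16L)

# Extract the n x 20 item matrix from a cohort data frame (or pass a matrix
# through), validating the response range.
item_matrix <- function(data) {
  if (is.data.frame(data)) {
    missing_cols <- setdiff(item_cols(), names(data))
    if (length(missing_cols) > 0) {
      stop("cohort is missing item columns: ", paste(missing_cols, collapse = ", "))
    }
    m <- as.matrix(data[item_cols()])
  } else {
    m <- as.matrix(data)
    if (ncol(m) != 20L) stop("item matrix must have exactly 20 columns")
    colnames(m) <- item_cols()
  }
  storage.mode(m) <- "double"
  v <- m[!is.na(m)]
  if (length(v) > 0 && (any(v < 0) || any(v > 3))) {
    stop("item responses must lie in [0, 3]")
  }
  m
}

#' Reverse-code the positively worded items
#'
#' Maps responses of the positively worded items x -> 3 - x so that higher
#' values mean more depressive symptomatology on every item; negatively
#' worded items and missing cells are left untouched. Applying the function
#' twice restores the input.
#'
#' @param data Data frame with columns `item_01`..`item_20`, or an n x 20
#'   matrix, holding raw responses in 0--3 (NA allowed).
#' @param positive_items Integer positions (1--20) of the positively worded
#'   items; defaults to the canonical 4, 8, 12, 16.
#' @return Object of the same shape with positive items reverse-scored.
#' @export
#' @examples
#' raw <- matrix(0:3, nrow = 1, ncol = 20)[, rep(1:4, 5), drop = FALSE]
#' scored <- reverse_code(raw)
reverse_code <- function(data, positive_items = positive_items_default()) {
  positive_items <- as.integer(positive_items)
  if (any(is.na(positive_items)) || any(positive_items < 1L) ||
      any(positive_items > 20L) || anyDuplicated(positive_items) > 0) {
    stop("positive_items must be distinct item positions in 1..20")
  }
  m <- item_matrix(data)
  m[, positive_items] <- 3 - m[, positive_items]
  if (is.data.frame(data)) {
    data[item_cols()] <- as.data.frame(m)
    data
  } else {
    m
  }
}

#' Total CES-D score of complete rows
#'
#' Sums the 20 scored items of each row. Rows with any missing item are a
#' precondition violation: partially observed responders are handled by
#' [classify_partial()] or by an imputation method, never silently dropped.
#'
#' @param data Cohort data frame or item matrix with no missing cells.
#' @return Numeric vector of totals in \[0, 60\] (fractional totals arise
#'   only after person-mean imputation).
#' @export
score_total <- function(data) {
  m <- item_matrix(data)
  if (anyNA(m)) {
    stop("score_total requires complete rows; use classify_partial or an ",
         "imputation method for rows with missing items")
  }
  unname(rowSums(m))
}

# Row totals with NA for incomplete rows; internal convenience.
score_if_complete <- function(data) {
  m <- item_matrix(data)
  s <- rowSums(m)
  unname(s)
}

#' Classify a CES-D score against the high-depressive-symptoms cut-off
#'
#' A total score at or above the cut-off (16 by convention) indicates high
#' depressive symptoms (hDS).
#'
#' @param score Numeric vector of totals in \[0, 60\].
#' @param cutoff Classification threshold; scores `>= cutoff` are hDS.
#' @return Character vector with values `"hDS"` / `"NhDS"` (`NA` propagated).
#' @export
classify_hds <- function(score, cutoff = 16) {
  if (any(score < 0 | score > 60, na.rm = TRUE)) {
    stop("scores must lie in [0, 60]")
  }
  ifelse(score >= cutoff, "hDS", "NhDS")
}

#' Bound-based classification of partially observed responders
#'
#' Even with missing items, a responder's hDS status can be determined when
#' every possible completion of the missing items falls on the same side of
#' the cut-off: the minimum completion (all missing set to 0) already reaches
#' the cut-off, or the maximum completion (all missing set to 3) still falls
#' short. Otherwise the status is undetermined.
#'
#' @param data Cohort data frame or item matrix; missing cells allowed.
#' @param cutoff Classification threshold (default 16).
#' @return Character vector with values `"hDS"`, `"NhDS"`, `"undetermined"`.
#'   Complete rows agree with `classify_hds(score_total(row))`.
#' @export
classify_partial <- function(data, cutoff = 16) {
  m <- item_matrix(data)
  observed_sum <- rowSums(m, na.rm = TRUE)
  n_missing <- rowSums(is.na(m))
  ifelse(observed_sum >= cutoff, "hDS",
    ifelse(observed_sum + 3 * n_missing < cutoff, "NhDS", "undetermined")
  )
}

#' Prevalence bounds from determined / undetermined counts
#'
#' Given counts of responders classified hDS, NhDS and undetermined by
#' [classify_partial()], the hDS prevalence is bracketed by imputing every
#' missing value to 0 (only the determined hDS remain above the cut-off) and
#' to 3 (all undetermined cross it).
#'
#' @param n_hds,n_nhds,n_undetermined Non-negative counts.
#' @return Object of class `prevalence_bounds`: list with `low_pct`,
#'   `high_pct` (exact percentages) and `denominator`.
#' @export
#' @examples
#' # incomplete responders of a small interview study
#' prevalence_bounds(n_hds = 14, n_nhds = 12, n_undetermined = 8)
prevalence_bounds <- function(n_hds, n_nhds, n_undetermined) {
  counts <- c(n_hds, n_nhds, n_undetermined)
  if (any(counts < 0)) stop("counts must be non-negative")
  denominator <- sum(counts)
  if (denominator == 0) stop("empty denominator: no subjects to classify")
  structure(
    list(
      low_pct = 100 * n_hds / denominator,
      high_pct = 100 * (n_hds + n_undetermined) / denominator,
      denominator = denominator
    ),
    class = "prevalence_bounds"
  )
}

#' @export
print.prevalence_bounds <- function(x, ...) {
  cat(sprintf(
    "hDS prevalence between %.1f%% and %.1f%% (N = %d)\n",
    round_half_up(x$low_pct), round_half_up(x$high_pct), x$denominator
  ))
  invisible(x)
}

#' Prevalence bounds computed directly from an item table
#'
#' Convenience wrapper: classifies each row with [classify_partial()] and
#' passes the counts to [prevalence_bounds()].
#'
#' @inheritParams classify_partial
#' @return See [prevalence_bounds()].
#' @export
prevalence_bounds_from_items <- function(data, cutoff = 16) {
  s <- classify_partial(data, cutoff = cutoff)
  prevalence_bounds(sum(s == "hDS"), sum(s == "NhDS"), sum(s == "undetermined"))
}

#' Add derived score and status columns to a cohort
#'
#' Appends `cesd_score` (total score, `NA` unless all 20 items observed) and
#' `hds` (0/1 indicator; determined for partially observed rows whenever the
#' bound classification is decisive, `NA` when undetermined).
#'
#' @param cohort Cohort data frame with item columns.
#' @param cutoff Classification threshold (default 16).
#' @return The cohort with `cesd_score` and `hds` columns appended/replaced.
#' @export
add_derived <- function(cohort, cutoff = 16) {
  m <- item_matrix(cohort)
  s <- rowSums(m)                      # NA where any item missing
  status <- classify_partial(m, cutoff = cutoff)
  cohort$cesd_score <- s
  cohort$hds <- ifelse(status == "undetermined", NA_integer_,
                       as.integer(status == "hDS"))
  cohort
}
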