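#' Deterministic single-imputation comparators
#'
#' Three classical ways of completing a partially answered CES-D
#' questionnaire, used as comparators for multiple imputation:
#' `impute_min()` sets every missing item to 0, `impute_max()` to 3, and
#' `impute_person_mean()` to the mean of the subject's own observed items
#' (fractional values are kept unrounded, so the completed total equals
#' `observed_sum * 20 / n_observed`).
#'
#' @param data Cohort data frame with `item_01`..`item_20` columns, or an
#'   n x 20 item matrix; missing cells allowed. Observed cells are never
#'   altered.
#' @return Object of the same shape with every missing item cell filled in.
#'   `impute_person_mean()` errors on rows with all 20 items missing; such
#'   subjects have no observed information and must be excluded upstream.
#' @name single_imputation
#' @examples
#' row <- matrix(c(rep(1, 15), rep(NA, 5)), nrow = 1)
#' sum(impute_min(row))          # 15
#' sum(impute_max(row))          # 30
#' sum(impute_person_mean(row))  # 20 = 15 * 20/15
NULL

fill_items <- function(data, fill) {
  m <- item_matrix(data)
  idx <- is.na(m)
  m[idx] <- fill(m)[idx]
  if (is.data.frame(data)) {
    data[item_cols()] <- as.data.frame(m)
    data
  } else {
    m
  }
}

#' @rdname single_imputation
#' @export
impute_min <- function(data) fill_items(data, function(m) array(0, dim(m)))

#' @rdname single_imputation
#' @export
impute_max <- function(data) fill_items(data, function(m) array(3, dim(m)))

#' @rdname single_imputation
#' @export
impute_person_mean <- function(data) {
  m <- item_matrix(data)
  if (any(rowSums(!is.na(m)) == 0)) {
    stop("person-mean imputation is undefined for rows with all 20 items ",
         "missing; exclude those subjects first")
  }
  fill_items(data, function(m) {
    pm <- rowMeans(m, na.rm = TRUE)
    matrix(pm, nrow = nrow(m), ncol = ncol(m))
  })
}

#' Descriptive summary of completed CES-D scores
#'
#' The summary layout used throughout the package's comparison tables:
#' number of subjects, mean and standard deviation of the total score,
#' standard error of the mean, and percentage at or above the cut-off.
#'
#' @param scores Numeric vector of total scores (no missing values).
#' @param cutoff Classification threshold (default 16).
#' @return One-row data frame with columns `n`, `mean`, `sd`, `sem`,
#'   `pct_hds`.
#' @export
score_summary <- function(scores, cutoff = 16) {
  if (anyNA(scores)) stop("scores must be complete")
  n <- length(scores)
  data.frame(
    n = n,
    mean = mean(scores),
    sd = stats::sd(scores),
    sem = stats::sd(scores) / sqrt(n),
    pct_hds = 100 * mean(scores >= cutoff)
  )
}
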