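#' Combine completed-data estimates by Rubin's rules
#'
#' Pools `m` point estimates and their complete-data variances into a single
#' estimate whose variance has a within-imputation component `W` (mean of
#' the complete-data variances) and a between-imputation component `B`
#' (sample variance of the estimates): total variance `W + (1 + 1/m) B`.
#'
#' @param estimates Numeric vector of the `m` completed-data estimates.
#' @param variances Numeric vector of their complete-data variances.
#' @return Object of class `pooled_estimate`: list with `estimate`,
#'   `within_var`, `between_var`, `total_var`, `se`, `m`.
#' @export
#' @examples
#' pool_rubin(c(10, 11, 12, 13, 14), rep(1, 5))  # estimate 12, se 2
pool_rubin <- function(estimates, variances) {
  m <- length(estimates)
  if (m < 2) stop("Rubin pooling needs at least 2 imputations")
  if (length(variances) != m) stop("estimates and variances differ in length")
  W <- mean(variances)
  B <- stats::var(estimates)
  total <- W + (1 + 1 / m) * B
  structure(
    list(estimate = mean(estimates), within_var = W, between_var = B,
         total_var = total, se = sqrt(total), m = m),
    class = "pooled_estimate"
  )
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf(
    "pooled estimate %.4f (se %.4f; W %.4f, B %.4f, m %d)\n",
    x$estimate, x$se, x$within_var, x$between_var, x$m
  ))
  invisible(x)
}

# Completed-data CES-D scores for one dataset of a cesd_sets object:
# item-level models rebuild the total from the items; the score-level model
# reads the imputed total; the status-level model has no score.
completed_scores <- function(dataset, spec) {
  targets <- rownames(spec$predictors)
  if (any(targets %in% item_cols())) {
    score_total(dataset)
  } else if ("cesd_score" %in% targets) {
    dataset$cesd_score
  } else {
    NULL
  }
}

completed_hds <- function(dataset, spec, cutoff = 16) {
  s <- completed_scores(dataset, spec)
  if (!is.null(s)) as.integer(s >= cutoff) else dataset$hds
}

#' Pooled hDS prevalence across completed datasets
#'
#' Computes the prevalence of high depressive symptoms in each completed
#' dataset (with binomial variance `p (1 - p) / n`) and combines them with
#' [pool_rubin()]. Works for item-, score- and status-level models.
#'
#' @param sets A `cesd_sets` object from [mice_run()].
#' @param cutoff Classification threshold (default 16).
#' @param subset Optional logical/integer row subset (e.g. a missing-count
#'   stratum) evaluated within each completed dataset.
#' @return A `pooled_estimate` on the proportion scale.
#' @export
pooled_prevalence <- function(sets, cutoff = 16, subset = NULL) {
  stopifnot(inherits(sets, "cesd_sets"))
  per_set <- vapply(sets$datasets, function(d) {
    h <- completed_hds(d, sets$spec, cutoff)
    if (!is.null(subset)) h <- h[subset]
    p <- mean(h)
    c(p, p * (1 - p) / length(h))
  }, numeric(2))
  pool_rubin(per_set[1, ], per_set[2, ])
}

#' Pooled summary of score and prevalence across completed datasets
#'
#' The layout used in the package's comparison tables: pooled mean score
#' (Rubin-pooled, SEM from the total variance), SD averaged across the
#' completed datasets, and pooled hDS prevalence as a percentage.
#'
#' @inheritParams pooled_prevalence
#' @return One-row data frame with `n`, `mean`, `sd`, `sem`, `pct_hds`,
#'   `pct_hds_se` (columns `mean`, `sd`, `sem` are `NA` for the status-level
#'   model, which carries no score).
#' @export
pooled_summary <- function(sets, cutoff = 16, subset = NULL) {
  stopifnot(inherits(sets, "cesd_sets"))
  prev <- pooled_prevalence(sets, cutoff, subset)
  scores <- lapply(sets$datasets, completed_scores, spec = sets$spec)
  if (is.null(scores[[1]])) {
    n <- if (is.null(subset)) nrow(sets$datasets[[1]]) else {
      length(completed_hds(sets$datasets[[1]], sets$spec, cutoff)[subset])
    }
    return(data.frame(n = n, mean = NA_real_, sd = NA_real_, sem = NA_real_,
                      pct_hds = 100 * prev$estimate,
                      pct_hds_se = 100 * prev$se))
  }
  if (!is.null(subset)) scores <- lapply(scores, `[`, subset)
  n <- length(scores[[1]])
  per_set <- vapply(scores, function(s) {
    c(mean(s), stats::var(s) / length(s), stats::sd(s))
  }, numeric(3))
  mn <- pool_rubin(per_set[1, ], per_set[2, ])
  data.frame(
    n = n,
    mean = mn$estimate,
    sd = mean(per_set[3, ]),
    sem = mn$se,
    pct_hds = 100 * prev$estimate,
    pct_hds_se = 100 * prev$se
  )
}
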