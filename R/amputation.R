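#' Delete item responses completely at random
#'
#' Benchmarking device: from a fully observed cohort, a uniformly chosen
#' subset of subjects (`round(fraction * n)` of them) each loses exactly `k`
#' uniformly chosen items. Deletions are independent of every data value
#' (MCAR by construction) and reproducible under the seed.
#'
#' The default fraction, 0.448, is the incomplete-responder rate implied by
#' the reference cohort's printed totals (see [e3n_printed_counts()]).
#'
#' @param cohort Fully observed cohort data frame (no missing item cells).
#' @param k Number of items deleted per amputated subject, 1--19.
#' @param fraction Proportion of subjects amputated.
#' @param seed Integer seed.
#' @return The cohort with `NA` holes in the item columns.
#' @export
ampute_mcar <- function(cohort, k, fraction = amputation_fraction_default(),
                        seed) {
  m <- item_matrix(cohort)
  if (anyNA(m)) stop("ampute_mcar requires a fully observed cohort")
  k <- as.integer(k)
  if (k < 1L || k > 19L) stop("k must lie in 1..19")
  if (fraction < 0 || fraction > 1) stop("fraction must lie in [0, 1]")
  n <- nrow(m)
  with_seed(seed, {
    subjects <- sample.int(n, round(fraction * n))
    for (i in subjects) {
      m[i, sample.int(20L, k)] <- NA
    }
  })
  cohort[item_cols()] <- as.data.frame(m)
  cohort
}

#' Printed totals of the reference cohort
#'
#' The mailed / returned / complete-responder counts of the cohort the
#' package's defaults are calibrated against: 94,503 questionnaires mailed,
#' 71,412 returned, 39,393 complete on all 20 items.
#'
#' @return Named list `mailed`, `returned`, `complete`.
#' @export
e3n_printed_counts <- function() {
  list(mailed = 94503L, returned = 71412L, complete = 39393L)
}

#' @rdname e3n_printed_counts
#' @export
amputation_fraction_default <- function() {
  with(e3n_printed_counts(), (returned - complete) / returned)
}

#' Accuracy study of imputation methods under MCAR amputation
#'
#' For each number of deleted items `k` and each method, repeatedly amputes
#' the complete cohort, re-imputes it, and records the accuracy indicators:
#' mean and variance of the total score, standard error of the mean, and
#' hDS prevalence. Multiple-imputation rows are Rubin-pooled; indicators are
#' averaged over `reps` independent amputation replicates. A `truth` row
#' holds the pre-amputation values.
#'
#' @param cohort Fully observed cohort data frame.
#' @param k_range Integer vector of missing-count conditions (1--19).
#' @param methods Subset of `"person_mean"`, `"mi_pmm"`, `"mi_polyreg"`.
#' @param reps Amputation replicates per condition (default 10).
#' @param seed Integer seed.
#' @param fraction Proportion of subjects amputated per replicate.
#' @param m,n_iter,donor_k Multiple-imputation run parameters (items-only
#'   parsimonious model).
#' @param cutoff Classification threshold.
#' @return Data frame keyed by (`k`, `method`) with columns `mean`,
#'   `variance`, `sem`, `pct_hds`, plus a leading row `k = NA, method =
#'   "truth"`.
#' @export
run_accuracy_study <- function(cohort, k_range = c(1, 5, 10),
                               methods = c("person_mean", "mi_pmm", "mi_polyreg"),
                               reps = 10L, seed = 1L,
                               fraction = amputation_fraction_default(),
                               m = 5L, n_iter = 10L, donor_k = 5L,
                               cutoff = 16) {
  if (length(methods) == 0) stop("at least one method is required")
  methods <- match.arg(methods, c("person_mean", "mi_pmm", "mi_polyreg"),
                       several.ok = TRUE)
  truth_scores <- score_total(cohort)
  truth <- data.frame(
    k = NA_integer_, method = "truth", rep = NA_integer_,
    mean = mean(truth_scores), variance = stats::var(truth_scores),
    sem = stats::sd(truth_scores) / sqrt(length(truth_scores)),
    pct_hds = 100 * mean(truth_scores >= cutoff)
  )
  rows <- list(truth)
  for (k in k_range) {
    for (r in seq_len(reps)) {
      rep_seed <- seed + 1000L * k + r
      amputed <- ampute_mcar(cohort, k = k, fraction = fraction,
                             seed = rep_seed)
      for (method in methods) {
        if (method == "person_mean") {
          s <- score_total(impute_person_mean(amputed))
          rows[[length(rows) + 1]] <- data.frame(
            k = k, method = method, rep = r,
            mean = mean(s), variance = stats::var(s),
            sem = stats::sd(s) / sqrt(length(s)),
            pct_hds = 100 * mean(s >= cutoff)
          )
        } else {
          fam <- if (method == "mi_pmm") "pmm" else "polyreg"
          spec <- build_model("items_parsimonious", method = fam, m = m,
                              n_iter = n_iter, donor_k = donor_k)
          sets <- mice_run(amputed, spec, seed = rep_seed)
          per_set <- vapply(sets$datasets, function(d) {
            s <- score_total(d)
            c(mean(s), stats::var(s) / length(s), stats::var(s),
              mean(s >= cutoff))
          }, numeric(4))
          mn <- pool_rubin(per_set[1, ], per_set[2, ])
          rows[[length(rows) + 1]] <- data.frame(
            k = k, method = method, rep = r,
            mean = mn$estimate, variance = mean(per_set[3, ]),
            sem = mn$se, pct_hds = 100 * mean(per_set[4, ])
          )
        }
      }
    }
  }
  all_rows <- do.call(rbind, rows)
  # average the replicates; keep the truth row as-is
  reps_part <- all_rows[all_rows$method != "truth", ]
  agg <- stats::aggregate(
    reps_part[c("mean", "variance", "sem", "pct_hds")],
    by = reps_part[c("k", "method")], FUN = mean
  )
  truth$rep <- NULL
  out <- rbind(truth[c("k", "method", "mean", "variance", "sem", "pct_hds")],
               agg[order(agg$k, agg$method), ])
  rownames(out) <- NULL
  out
}
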