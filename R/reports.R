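# Report builders and CSV plumbing tying the stages into reproducible runs.

#' Read a cohort CSV
#'
#' Expects columns `item_01`..`item_20` plus any covariates; missing item
#' responses are empty cells or the `sentinel` string. When `raw = TRUE`
#' the items are raw instrument responses and are reverse-coded on ingestion.
#'
#' @param path CSV file.
#' @param raw Are items on the raw (pre reverse-coding) scale?
#' @param positive_items Positions of the positively worded items.
#' @param sentinel Extra string treated as missing (besides empty cells).
#' @return Cohort data frame with items on the scored scale.
#' @export
read_cohort <- function(path, raw = FALSE,
                        positive_items = positive_items_default(),
                        sentinel = "NA") {
  data <- utils::read.csv(path, na.strings = c("", "NA", sentinel),
                          stringsAsFactors = TRUE)
  invisible(item_matrix(data))    # validates presence and range
  if (raw) data <- reverse_code(data, positive_items)
  data
}

#' Write a cohort (or any report table) as CSV with a config stamp
#'
#' @param x Data frame.
#' @param path Output file.
#' @param config Optional configuration object; its hash and the seed are
#'   written as `#`-prefixed header comments so a rerun is recognizable.
#' @export
write_report_csv <- function(x, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config)) {
    writeLines(sprintf("# config_hash: %s", config_hash(config)), con)
    if (!is.null(config$seed)) {
      writeLines(sprintf("# seed: %s", config$seed), con)
    }
  }
  utils::write.csv(x, con, row.names = FALSE)
}

#' Read back a report CSV written by [write_report_csv()]
#' @param path CSV file.
#' @return Data frame (header comments skipped).
#' @export
read_report_csv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Comparative table of missing-data methods (score and prevalence)
#'
#' The package's central comparison: for a cohort with missing item cells,
#' reports the mean score, SD, SEM and hDS prevalence under every method —
#' complete cases, bound-classifiable cases, the three single imputations,
#' score-level and status-level multiple imputation, and item-level multiple
#' imputation (parsimonious and full structure, pmm and polyreg family) —
#' stratified by missing-count ceilings. Multiple imputation runs once on
#' the full cohort; strata are evaluated as subject subsets of the completed
#' datasets.
#'
#' @param cohort Cohort data frame with missing item cells and the covariate
#'   block.
#' @param covariates Covariate column names (default [covariate_cols()]).
#' @param strata Missing-count ceilings (default `c(4, 10, 20)`).
#' @param m,n_iter,donor_k Multiple-imputation parameters.
#' @param seed Integer seed.
#' @param cutoff Classification threshold.
#' @param mi_structures Which multiple-imputation rows to include; any of
#'   `"score"`, `"status"`, `"items_parsimonious"`, `"items_full"`.
#' @param item_methods Regression families for the item-level rows.
#' @return Data frame with columns `method`, `max_mv`, `n`, `mean`, `sd`,
#'   `sem`, `pct_hds`.
#' @export
cesd_table3 <- function(cohort, covariates = covariate_cols(),
                        strata = c(4, 10, 20), m = 5L, n_iter = 10L,
                        donor_k = 5L, seed = 1L, cutoff = 16,
                        mi_structures = c("score", "status",
                                          "items_parsimonious", "items_full"),
                        item_methods = c("pmm", "polyreg")) {
  items <- item_matrix(cohort)
  n_missing <- rowSums(is.na(items))
  rows <- list()
  push <- function(method, max_mv, summ) {
    rows[[length(rows) + 1]] <<- cbind(
      data.frame(method = method, max_mv = max_mv), summ
    )
  }
  blank_pct <- function(n, pct) {
    data.frame(n = n, mean = NA_real_, sd = NA_real_, sem = NA_real_,
               pct_hds = pct)
  }

  # complete cases and bound-classifiable cases (no stratification: the
  # complete-case row ignores incomplete subjects, the classifiable row
  # uses every determined status)
  cc <- items[n_missing == 0, , drop = FALSE]
  push("complete_cases", 20, cbind(score_summary(score_total(cc), cutoff)))
  status <- classify_partial(items, cutoff)
  det <- status != "undetermined"
  push("classifiable_cases", 20,
       blank_pct(sum(det), 100 * mean(status[det] == "hDS")))

  single <- list(minimum = impute_min, maximum = impute_max,
                 person_mean = impute_person_mean)
  for (nm in names(single)) {
    usable <- if (nm == "person_mean") rowSums(!is.na(items)) > 0 else
      rep(TRUE, nrow(items))
    completed <- single[[nm]](items[usable, , drop = FALSE])
    s <- score_total(completed)
    for (k in strata) {
      keep <- n_missing[usable] <= k
      push(paste0("single_", nm), k, score_summary(s[keep], cutoff))
    }
  }

  data2 <- add_derived(cohort, cutoff)
  mi_grid <- list()
  if ("score" %in% mi_structures) {
    mi_grid[["mi_score_pmm"]] <- build_model("score_pmm", covariates = covariates,
                                             m = m, n_iter = n_iter,
                                             donor_k = donor_k)
  }
  if ("status" %in% mi_structures) {
    mi_grid[["mi_status_logreg"]] <- build_model("status_logreg",
                                                 covariates = covariates,
                                                 m = m, n_iter = n_iter,
                                                 donor_k = donor_k)
  }
  for (st in intersect(mi_structures, c("items_parsimonious", "items_full"))) {
    for (fam in item_methods) {
      mi_grid[[paste0("mi_", st, "_", fam)]] <-
        build_model(st, method = fam, covariates = covariates, m = m,
                    n_iter = n_iter, donor_k = donor_k)
    }
  }
  for (nm in names(mi_grid)) {
    sets <- mice_run(data2, mi_grid[[nm]], seed = seed)
    for (k in strata) {
      summ <- pooled_summary(sets, cutoff = cutoff, subset = n_missing <= k)
      summ$pct_hds_se <- NULL
      push(nm, k, summ)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Psychometric report block
#'
#' @param data Complete cohort or item matrix.
#' @return List with `alpha` and the first five eigenvalues.
#' @export
psychometric_report <- function(data) {
  ev <- pca_spectrum(data)
  list(alpha = cronbach_alpha(data), eigenvalues = ev[1:5],
       eigen_ratio_12 = ev[1] / ev[2])
}
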