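#' Construct an imputation specification
#'
#' Bundles everything the chained-equations engine needs: the per-variable
#' imputation method, the predictor matrix, and the run parameters.
#'
#' @param methods Named character vector mapping variable names to one of
#'   `"pmm"`, `"logreg"`, `"polyreg"`, `"none"`.
#' @param predictors Logical matrix; `predictors[v, p]` is `TRUE` when
#'   variable `p` predicts target `v`. Row and column names are variable
#'   names. A variable never predicts itself.
#' @param m Number of imputations (default 5, the number used throughout the
#'   package's comparison tables). Must be at least 2 so a between-imputation
#'   variance exists.
#' @param n_iter Chained-equation cycles per imputation (default 10).
#' @param donor_k pmm donor-pool size (default 5).
#' @param seed Default seed for [mice_run()]; may be overridden there.
#' @return Object of class `imputation_spec`.
#' @export
imputation_spec <- function(methods, predictors, m = 5L, n_iter = 10L,
                            donor_k = 5L, seed = NULL) {
  stopifnot(is.character(methods), !is.null(names(methods)))
  bad <- setdiff(methods, c("pmm", "logreg", "polyreg", "none"))
  if (length(bad) > 0) stop("unknown imputation method(s): ", paste(bad, collapse = ", "))
  if (m < 2) stop("m must be at least 2 (between-imputation variance needs replicates)")
  predictors <- as.matrix(predictors)
  if (is.null(rownames(predictors)) || is.null(colnames(predictors))) {
    stop("predictor matrix must carry row and column names")
  }
  self <- intersect(rownames(predictors), colnames(predictors))
  if (any(predictors[cbind(self, self)])) stop("a variable may not predict itself")
  structure(
    list(methods = methods, predictors = predictors, m = as.integer(m),
         n_iter = as.integer(n_iter), donor_k = as.integer(donor_k),
         seed = seed),
    class = "imputation_spec"
  )
}

#' Build one of the four standard imputation model structures
#'
#' The package compares four ways of framing the imputation problem:
#' item-level models (each of the 20 items imputed from the other 19, the
#' *parsimonious* structure, or from the other 19 plus the covariate block,
#' the *full* structure), a score-level model (the total score imputed by
#' pmm from the covariates), and a status-level model (the hDS indicator
#' imputed by logistic regression from the covariates).
#'
#' @param structure One of `"items_parsimonious"`, `"items_full"`,
#'   `"score_pmm"`, `"status_logreg"`.
#' @param method Item-level regression family, `"pmm"` or `"polyreg"`;
#'   ignored by the score- and status-level structures.
#' @param covariates Character vector of covariate column names (the
#'   risk-factor block); required by every structure except
#'   `items_parsimonious`.
#' @inheritParams imputation_spec
#' @return An [imputation_spec()].
#' @export
build_model <- function(structure = c("items_parsimonious", "items_full",
                                      "score_pmm", "status_logreg"),
                        method = c("pmm", "polyreg"),
                        covariates = NULL,
                        m = 5L, n_iter = 10L, donor_k = 5L, seed = NULL) {
  structure <- match.arg(structure)
  method <- match.arg(method)
  items <- item_cols()
  needs_cov <- structure != "items_parsimonious"
  if (needs_cov && is.null(covariates)) {
    stop("structure '", structure, "' requires the covariate block")
  }
  if (structure %in% c("items_parsimonious", "items_full")) {
    preds <- if (structure == "items_full") c(items, covariates) else items
    pm <- matrix(TRUE, nrow = 20, ncol = length(preds),
                 dimnames = list(items, preds))
    pm[cbind(items, items)] <- FALSE
    methods <- stats::setNames(rep(method, 20), items)
  } else if (structure == "score_pmm") {
    pm <- matrix(TRUE, nrow = 1, ncol = length(covariates),
                 dimnames = list("cesd_score", covariates))
    methods <- c(cesd_score = "pmm")
  } else {
    pm <- matrix(TRUE, nrow = 1, ncol = length(covariates),
                 dimnames = list("hds", covariates))
    methods <- c(hds = "logreg")
  }
  imputation_spec(methods, pm, m = m, n_iter = n_iter, donor_k = donor_k,
                  seed = seed)
}

# Design matrix (with intercept) for the given predictor columns of `data`,
# expanding factors/characters through model.matrix. Numeric-only blocks
# skip model.matrix for speed (the item-level models hit this path 20 times
# per cycle).
design_matrix <- function(data, cols) {
  block <- data[cols]
  if (all(vapply(block, is.numeric, logical(1)))) {
    cbind(`(Intercept)` = 1, as.matrix(block))
  } else {
    stats::model.matrix(~ ., data = block)
  }
}

#' Multiple imputation by chained equations
#'
#' Imputes every variable that has missing cells and a declared method, by
#' iterated conditional modeling: missing cells are initialized by uniform
#' draws from the variable's observed values, then `n_iter` cycles visit the
#' targets in order of increasing missing count, re-imputing each from the
#' current completions of its predictors. The whole procedure is repeated
#' independently `m` times. Observed cells are never altered.
#'
#' An optional [mnar_scenario()] tilts the predictive distribution of the
#' item targets (and, through `delta`, of continuous targets) for the missing
#' rows only, turning the ignorable model into a pattern-mixture
#' nonignorable model. The identity scenario reproduces the ignorable run
#' bit-for-bit under the same seed.
#'
#' @param data Cohort data frame containing every target and predictor
#'   variable.
#' @param spec An [imputation_spec()].
#' @param scenario `NULL` (ignorable) or an [mnar_scenario()].
#' @param seed Integer seed; defaults to `spec$seed`. Identical seeds give
#'   identical results.
#' @param positive_items Positions of the positively worded items, used only
#'   to route a scenario's positive-item odds ratios.
#' @return Object of class `cesd_sets`: list with `datasets` (list of `m`
#'   completed data frames), `spec`, `scenario`, `seed` and `trace`
#'   (per-chain, per-iteration mean and SD of the imputed values of each
#'   target).
#' @export
mice_run <- function(data, spec, scenario = NULL, seed = spec$seed,
                     positive_items = positive_items_default()) {
  stopifnot(inherits(spec, "imputation_spec"))
  if (is.null(seed)) stop("a seed is required (set it in the spec or pass it)")
  if (!is.null(scenario) && !inherits(scenario, "mnar_scenario")) {
    stop("scenario must be built with mnar_scenario()")
  }
  targets_all <- rownames(spec$predictors)
  missing_vars <- setdiff(targets_all, names(data))
  if (length(missing_vars) > 0) {
    stop("data lacks variables: ", paste(missing_vars, collapse = ", "))
  }
  nmis <- vapply(targets_all, function(v) sum(is.na(data[[v]])), integer(1))
  full_miss <- targets_all[nmis == nrow(data)]
  if (length(full_miss) > 0) {
    stop("variable(s) with no observed values cannot be imputed: ",
         paste(full_miss, collapse = ", "))
  }
  no_method <- targets_all[nmis > 0 & spec$methods[targets_all] == "none"]
  if (length(no_method) > 0) {
    stop("variables with missing cells but method 'none': ",
         paste(no_method, collapse = ", "))
  }
  targets <- targets_all[nmis > 0]
  targets <- targets[order(nmis[targets])]   # visit order: fewest missing first

  pos_names <- item_cols()[positive_items]
  item_theta <- function(v) {
    if (is.null(scenario)) return(NULL)
    if (!(v %in% item_cols())) return(NULL)
    if (v %in% pos_names) scenario$theta_positive else scenario$theta_negative
  }
  item_delta <- function(v) {
    if (is.null(scenario)) return(0)
    d <- scenario$delta
    if (length(d) == 1) return(d)
    if (v %in% item_cols()) return(d[match(v, item_cols())])
    0
  }

  masks <- lapply(targets, function(v) is.na(data[[v]]))
  names(masks) <- targets

  datasets <- vector("list", spec$m)
  trace <- vector("list", spec$m)
  with_seed(seed, {
    for (imp in seq_len(spec$m)) {
      cur <- data
      # initialization: uniform draws from the observed values
      for (v in targets) {
        wy <- masks[[v]]
        obs <- cur[[v]][!wy]
        cur[[v]][wy] <- sample(obs, sum(wy), replace = TRUE)
      }
      tr <- array(NA_real_, dim = c(spec$n_iter, length(targets), 2),
                  dimnames = list(NULL, targets, c("mean", "sd")))
      for (it in seq_len(spec$n_iter)) {
        for (v in targets) {
          wy <- masks[[v]]
          pred_cols <- colnames(spec$predictors)[spec$predictors[v, ]]
          X <- design_matrix(cur, pred_cols)
          y <- cur[[v]]
          y[wy] <- NA
          method <- spec$methods[[v]]
          y_new <- switch(method,
            pmm = pmm_impute_variable(y, X, donor_k = spec$donor_k,
                                      delta = item_delta(v)),
            polyreg = polyreg_impute_variable(y, X, levels = 0:3,
                                              theta = item_theta(v)),
            logreg = logreg_impute_variable(y, X, levels = 0:1,
                                            theta = scenario$theta_status %||% NULL)
          )
          cur[[v]] <- y_new
          tr[it, v, "mean"] <- mean(y_new[wy])
          tr[it, v, "sd"] <- stats::sd(y_new[wy])
        }
      }
      datasets[[imp]] <- cur
      trace[[imp]] <- tr
    }
  })
  structure(
    list(datasets = datasets, spec = spec, scenario = scenario, seed = seed,
         trace = trace),
    class = "cesd_sets"
  )
}

#' @export
print.cesd_sets <- function(x, ...) {
  cat(sprintf(
    "Multiply imputed CES-D data: m = %d completed datasets, %d subjects\n",
    length(x$datasets), nrow(x$datasets[[1]])
  ))
  cat(sprintf("targets: %s\n",
              paste(dimnames(x$trace[[1]])[[2]], collapse = ", ")))
  if (!is.null(x$scenario)) cat("nonignorable scenario:", x$scenario$name, "\n")
  invisible(x)
}
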