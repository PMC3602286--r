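#' Default generator calibration
#'
#' Item discriminations (loadings on the single latent depressive-symptom
#' trait) and per-item ordered thresholds of the synthetic cohort generator.
#' The defaults are calibrated by simulation so that a generated cohort
#' reproduces the aggregate psychometric profile of the instrument in a
#' large female cohort: Cronbach's alpha near 0.89, a dominant first
#' principal component, and a high-depressive-symptoms prevalence near one
#' quarter. Item-level response distributions are an invention of the
#' generator, not an estimate.
#'
#' @return `default_loadings()`: numeric vector of 20 positive loadings.
#'   `default_thresholds()`: 20 x 3 matrix of strictly increasing cut-points
#'   on the latent-propensity scale.
#' @export
default_loadings <- function() {
  # mild spread in discrimination; positions follow no special pattern
  rep(c(0.875, 0.735, 1.015, 0.665, 0.805), 4)
}

#' @rdname default_loadings
#' @export
default_thresholds <- function() {
  base <- c(0.50, 1.35, 2.05)
  offset <- rep(c(-0.20, 0.12, 0, -0.08, 0.16), 4)
  t(vapply(offset, function(o) base + o, numeric(3)))
}

#' Generate a synthetic CES-D cohort
#'
#' Draws a standard-normal latent depressive-symptom trait per subject and
#' produces the 20 ordinal items by a graded-response-style mechanism: item
#' j's response is the count of its thresholds lying below
#' `loading_j * trait + noise`. Items are therefore positively correlated
#' through the single trait (unidimensional, high internal consistency); a
#' 17-column covariate block of depression risk-factor analogues (age-like
#' continuous, treatment-history binaries, chronic-disease count, ...) is
#' drawn with mild associations to the same trait. Items are returned on the
#' *scored* scale (already reverse-coded).
#'
#' @param n Number of subjects.
#' @param loadings 20 positive item discriminations.
#' @param thresholds 20 x 3 matrix of strictly increasing cut-points.
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @return Data frame with `id`, `item_01`..`item_20` and 17 covariates;
#'   the latent trait is attached as attribute `"trait"`.
#' @export
generate_cohort <- function(n, loadings = default_loadings(),
                            thresholds = default_thresholds(), seed = 1L) {
  if (length(loadings) != 20 || any(loadings <= 0)) {
    stop("loadings must be 20 positive values")
  }
  thresholds <- as.matrix(thresholds)
  if (!all(dim(thresholds) == c(20, 3))) stop("thresholds must be 20 x 3")
  if (any(apply(thresholds, 1, diff) <= 0)) {
    stop("thresholds must be strictly increasing within each item")
  }
  with_seed(seed, {
    z <- stats::rnorm(n)
    items <- matrix(0, n, 20, dimnames = list(NULL, item_cols()))
    for (j in 1:20) {
      prop <- loadings[j] * z + stats::rnorm(n)
      items[, j] <- (prop > thresholds[j, 1]) + (prop > thresholds[j, 2]) +
        (prop > thresholds[j, 3])
    }
    bern <- function(base_logit, beta) {
      stats::rbinom(n, 1L, stats::plogis(base_logit + beta * z))
    }
    covs <- data.frame(
      age = round(60 + 0.6 * z + 6 * stats::rnorm(n), 1),
      marital_status = factor(
        sample(c("married", "single", "widowed"), n, TRUE, c(0.70, 0.12, 0.18))
      ),
      employed = bern(stats::qlogis(0.35), -0.15),
      education = as.integer(cut(stats::rnorm(n), c(-Inf, -1, 0, 1, Inf))),
      pregnancy_history = bern(stats::qlogis(0.85), 0),
      menopausal = bern(stats::qlogis(0.90), 0.1),
      needs_help_questionnaire = bern(stats::qlogis(0.04), 0.4),
      history_depression = bern(stats::qlogis(0.18), 0.9),
      current_depression_treatment = bern(stats::qlogis(0.07), 1.1),
      psychotropic_drug_use = bern(stats::qlogis(0.12), 0.8),
      menopause_mood_symptoms = bern(stats::qlogis(0.28), 0.6),
      alcohol_gday = round(exp(1.2 + 0.8 * stats::rnorm(n)), 1),
      smoking_status = factor(
        sample(c("never", "former", "current"), n, TRUE, c(0.55, 0.33, 0.12))
      ),
      sleep_duration = round(7.2 - 0.25 * z + 0.9 * stats::rnorm(n), 1),
      recent_hospitalization = bern(stats::qlogis(0.10), 0.3),
      psychiatric_hospitalization = bern(stats::qlogis(0.01), 1.2),
      chronic_disease_count = pmin(stats::rpois(n, exp(-0.4 + 0.18 * z)), 6L)
    )
    cohort <- cbind(data.frame(id = seq_len(n)), as.data.frame(items), covs)
    attr(cohort, "trait") <- z
    cohort
  })
}

#' The 17 covariate column names of a generated cohort
#' @return Character vector.
#' @export
covariate_cols <- function() {
  c("age", "marital_status", "employed", "education", "pregnancy_history",
    "menopausal", "needs_help_questionnaire", "history_depression",
    "current_depression_treatment", "psychotropic_drug_use",
    "menopause_mood_symptoms", "alcohol_gday", "smoking_status",
    "sleep_duration", "recent_hospitalization", "psychiatric_hospitalization",
    "chronic_disease_count")
}

#' Specify a missingness mechanism for the generator
#'
#' @param mechanism `"MCAR"`, `"MAR"` or `"MNAR"`.
#' @param overall_fraction Expected proportion of subjects with at least one
#'   missing item (default 0.448, the incomplete-responder rate implied by
#'   the reference cohort's printed totals).
#' @param item_rate Baseline per-item missingness probability within an
#'   affected subject (default 0.25).
#' @param mar_drivers Covariate names whose (standardized) values raise the
#'   odds of being an incomplete responder under MAR.
#' @param mar_strength Log-odds slope per standardized driver unit.
#' @param mnar_theta Category odds-ratio triplet: under MNAR an item's own
#'   scored category c multiplies the odds of that item going missing by
#'   `mnar_theta[c]` (categories 1, 2, 3 vs 0).
#' @return Object of class `missingness_spec`.
#' @export
missingness_spec <- function(mechanism = c("MCAR", "MAR", "MNAR"),
                             overall_fraction = amputation_fraction_default(),
                             item_rate = 0.25,
                             mar_drivers = "age", mar_strength = 1,
                             mnar_theta = c(2, 3, 5)) {
  mechanism <- match.arg(mechanism)
  if (overall_fraction < 0 || overall_fraction > 1) {
    stop("overall_fraction must lie in [0, 1]")
  }
  if (mechanism == "MNAR" &&
      (length(mnar_theta) != 3 || any(mnar_theta <= 0))) {
    stop("mnar_theta must be 3 positive odds ratios")
  }
  structure(
    list(mechanism = mechanism, overall_fraction = overall_fraction,
         item_rate = item_rate, mar_drivers = mar_drivers,
         mar_strength = mar_strength, mnar_theta = mnar_theta),
    class = "missingness_spec"
  )
}

#' Delete item responses under a configurable mechanism
#'
#' Selects incomplete responders and deletes item cells per the mechanism:
#' MCAR ignores every value; MAR raises a subject's selection odds with the
#' driver covariates (fully observed, so the mechanism stays ignorable);
#' MNAR makes each item's deletion odds depend on its own (unobserved)
#' scored category through the `mnar_theta` odds ratios — the pattern the
#' sensitivity analysis is designed to invert. The pre-deletion values and
#' mask are returned for oracle testing.
#'
#' @param cohort Fully observed cohort data frame.
#' @param spec A [missingness_spec()].
#' @param seed Integer seed.
#' @return List with `cohort` (item cells deleted), `mask` (logical n x 20,
#'   `TRUE` = deleted) and `truth` (the original item matrix).
#' @export
generate_missingness <- function(cohort, spec, seed) {
  stopifnot(inherits(spec, "missingness_spec"))
  m <- item_matrix(cohort)
  if (anyNA(m)) stop("cohort must be fully observed")
  n <- nrow(m)
  with_seed(seed, {
    if (spec$mechanism == "MAR") {
      drv <- sapply(spec$mar_drivers, function(v) {
        x <- cohort[[v]]
        if (is.null(x)) stop("unknown MAR driver: ", v)
        as.numeric(scale(as.numeric(x)))
      })
      lp <- spec$mar_strength * rowMeans(as.matrix(drv))
      # intercept solved so the mean selection probability hits the target
      alpha <- stats::uniroot(
        function(a) mean(stats::plogis(a + lp)) - spec$overall_fraction,
        c(-20, 20)
      )$root
      selected <- stats::runif(n) < stats::plogis(alpha + lp)
    } else {
      selected <- rep(FALSE, n)
      selected[sample.int(n, round(spec$overall_fraction * n))] <- TRUE
    }
    mask <- matrix(FALSE, n, 20)
    idx <- which(selected)
    if (spec$mechanism == "MNAR") {
      offs <- c(0, log(spec$mnar_theta))        # log-odds offset per category
      base <- stats::qlogis(spec$item_rate)
      p <- matrix(0, length(idx), 20)
      p[] <- stats::plogis(base + offs[m[idx, , drop = FALSE] + 1])
      mask[idx, ] <- matrix(stats::runif(length(idx) * 20), length(idx)) < p
    } else if (length(idx) > 0) {
      sub <- matrix(stats::runif(length(idx) * 20), length(idx)) < spec$item_rate
      none <- rowSums(sub) == 0
      if (any(none)) {             # an incomplete responder misses >= 1 item
        sub[cbind(which(none), sample.int(20L, sum(none), replace = TRUE))] <- TRUE
      }
      mask[idx, ] <- sub
    }
    out <- m
    out[mask] <- NA
    cohort[item_cols()] <- as.data.frame(out)
    list(cohort = cohort, mask = mask, truth = m)
  })
}

#' Counts of the small interview (qualitative) study
#'
#' The packaged fixture of the interview-study cross-tabulations: 183
#' returned questionnaires, of which 34 had at least one missing item;
#' bound-based status counts (104/45 NhDS/hDS among complete responders;
#' 12/14/8 NhDS/hDS/undetermined among incomplete ones) and the two
#' cross-tabulations against the earlier mailed questionnaire.
#'
#' @return List with `status` (data frame of NhDS/hDS/undetermined counts by
#'   completeness), `q8_by_mv` and `q8_by_status` (2 x 2 count matrices),
#'   and `n_invited` (204 questionnaires mailed).
#' @export
fixture_table1 <- function() {
  status <- data.frame(
    response = c("complete", "incomplete"),
    NhDS = c(104L, 12L),
    hDS = c(45L, 14L),
    undetermined = c(0L, 8L)
  )
  list(
    status = status,
    q8_by_mv = matrix(c(91L, 19L, 57L, 15L), 2, 2, byrow = TRUE,
                      dimnames = list(q8 = c("no_mv", "mv"),
                                      qs = c("no_mv", "mv"))),
    q8_by_status = matrix(c(79L, 23L, 19L, 25L), 2, 2, byrow = TRUE,
                          dimnames = list(q8 = c("NhDS", "hDS"),
                                          qs = c("NhDS", "hDS"))),
    n_invited = 204L
  )
}
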