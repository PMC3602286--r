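# Per-variable imputation methods used inside the chained-equations cycles.
# Each takes the full response vector (NA where missing), a design matrix
# X (n x p, intercept included) aligned with it, and returns the vector with
# missing entries imputed. Observed entries are returned bit-for-bit.

#' Impute a numeric variable by predictive mean matching
#'
#' Fits a Bayesian linear regression on the observed rows, predicts the
#' observed rows with the fitted coefficients and the missing rows with a
#' posterior coefficient draw, then copies for each missing row the observed
#' value of one of the `donor_k` observed rows with the closest prediction
#' (ties broken uniformly at random). Imputed values are therefore always
#' members of the observed support. `delta` shifts the missing-row
#' predictions before matching and is the continuous-variable path of the
#' nonignorable sensitivity analysis; under `delta = 0` the method is the
#' ordinary ignorable pmm.
#'
#' @param y Numeric vector with `NA` for missing entries.
#' @param X Design matrix (rows aligned with `y`, intercept included).
#' @param donor_k Donor pool size (default 5).
#' @param delta Additive shift applied to missing-row predictions (default 0).
#' @return `y` with missing entries imputed.
#' @export
pmm_impute_variable <- function(y, X, donor_k = 5L, delta = 0) {
  wy <- is.na(y)
  if (!any(wy)) return(y)
  if (all(wy)) stop("cannot impute a variable with no observed values")
  X <- as.matrix(X)
  fit <- norm_draw(X[!wy, , drop = FALSE], y[!wy])
  yhat_obs <- drop(X[!wy, , drop = FALSE] %*% fit$beta_hat)
  yhat_mis <- drop(X[wy, , drop = FALSE] %*% fit$beta_draw) + delta
  y[wy] <- match_donors(yhat_obs, y[!wy], yhat_mis, donor_k = donor_k)
  y
}

#' Impute a categorical variable by polytomous (multinomial) regression
#'
#' Fits a ridge-penalized multinomial logistic model on the observed rows
#' (with a light per-level pseudo-observation so levels absent from the
#' observed rows retain a small nonzero probability), draws coefficients
#' from the asymptotic normal at the fit, computes category probabilities
#' for the missing rows, optionally tilts them by per-category odds ratios
#' (the categorical path of the nonignorable sensitivity analysis), and
#' samples each imputed category from the resulting distribution.
#'
#' @param y Vector with `NA` for missing entries; values must be members of
#'   `levels`.
#' @param X Design matrix (rows aligned with `y`, intercept included).
#' @param levels Full ordered level set of the variable (default `0:3`, the
#'   scored CES-D item categories).
#' @param theta Odds-ratio vector of length `length(levels) - 1` applied to
#'   levels 2..K against the reference level 1; `NULL` or all-ones leaves the
#'   model untilted (ignorable).
#' @param lambda Ridge penalty on the multinomial coefficients.
#' @return `y` with missing entries imputed (values drawn from `levels`).
#' @export
polyreg_impute_variable <- function(y, X, levels = 0:3, theta = NULL,
                                    lambda = 1e-4) {
  wy <- is.na(y)
  if (!any(wy)) return(y)
  if (all(wy)) stop("cannot impute a variable with no observed values")
  K <- length(levels)
  yi <- match(y, levels)
  if (anyNA(yi[!wy])) stop("observed values outside the declared level set")
  X <- as.matrix(X)
  X_obs <- X[!wy, , drop = FALSE]
  # per-level pseudo-observation at the predictor centroid, small weight:
  # keeps every level estimable without materially moving a well-populated fit
  centroid <- matrix(colMeans(X_obs), nrow = K, ncol = ncol(X), byrow = TRUE)
  fit <- fit_multinom_ridge(
    X = rbind(X_obs, centroid),
    y = c(yi[!wy], seq_len(K)),
    K = K,
    w = c(rep(1, nrow(X_obs)), rep(0.01, K)),
    lambda = lambda
  )
  B_draw <- draw_multinom(fit)
  P <- predict_multinom(B_draw, X[wy, , drop = FALSE])
  P <- shift_category_probs(P, theta)
  y[wy] <- levels[sample_categories(P)]
  y
}

#' Impute a binary variable by logistic regression
#'
#' The two-level case of [polyreg_impute_variable()]: a ridge-penalized
#' logistic fit with a posterior-style coefficient draw; `theta` is a single
#' odds ratio tilting the probability of the second level for nonresponders.
#'
#' @inheritParams polyreg_impute_variable
#' @param levels Two-level set, default `0:1`.
#' @param theta Single odds ratio (default `NULL`, ignorable).
#' @return `y` with missing entries imputed.
#' @export
logreg_impute_variable <- function(y, X, levels = 0:1, theta = NULL,
                                   lambda = 1e-4) {
  if (length(levels) != 2L) stop("logreg requires a two-level variable")
  if (!is.null(theta) && length(theta) != 1L) {
    stop("logreg takes a single odds ratio")
  }
  polyreg_impute_variable(y, X, levels = levels, theta = theta, lambda = lambda)
}

# Draw one category index per row of a probability matrix (rows sum to 1).
# Consumes exactly one uniform per row, so tilting the probabilities never
# changes the random-number stream alignment.
sample_categories <- function(P) {
  K <- ncol(P)
  u <- stats::runif(nrow(P))
  idx <- rep(1L, nrow(P))
  acc <- P[, 1]
  for (k in seq_len(K - 1)) {
    idx <- idx + (u > acc)
    acc <- acc + P[, k + 1]
  }
  pmin(idx, K)
}
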