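#' Cronbach's alpha of the item set
#'
#' Internal-consistency coefficient
#' `alpha = k/(k-1) * (1 - sum(item variances) / variance(total))`,
#' computed with sample variances throughout.
#'
#' @param data Complete cohort data frame or item matrix (no missing cells);
#'   at least 2 items and 2 subjects.
#' @return Scalar alpha.
#' @export
cronbach_alpha <- function(data) {
  m <- if (is.data.frame(data)) item_matrix(data) else as.matrix(data)
  if (anyNA(m)) stop("cronbach_alpha requires complete data")
  k <- ncol(m)
  if (k < 2 || nrow(m) < 2) stop("need at least 2 items and 2 subjects")
  total_var <- stats::var(rowSums(m))
  if (total_var == 0) stop("total score has zero variance; alpha undefined")
  k / (k - 1) * (1 - sum(apply(m, 2, stats::var)) / total_var)
}

#' Principal-component eigenvalue spectrum of the items
#'
#' Eigenvalues of the item correlation matrix, in decreasing order. A
#' dominant first eigenvalue (relative to the second) indicates an
#' essentially unidimensional scale. The correlation scale is used because
#' the items share a response format but differ in variance; the
#' eigenvalues then sum to the number of items.
#'
#' @param data Complete cohort data frame or item matrix (no missing cells,
#'   no constant item column).
#' @return Numeric vector of eigenvalues (length = number of items).
#' @export
pca_spectrum <- function(data) {
  m <- if (is.data.frame(data)) item_matrix(data) else as.matrix(data)
  if (anyNA(m)) stop("pca_spectrum requires complete data")
  v <- apply(m, 2, stats::var)
  if (any(v == 0)) {
    stop("constant item column(s): ", paste(which(v == 0), collapse = ", "))
  }
  ev <- eigen(stats::cor(m), symmetric = TRUE, only.values = TRUE)$values
  pmax(ev, 0)
}
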