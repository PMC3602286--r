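# Low-level regression engines backing the imputation methods.
#
# Both engines implement "proper" imputation: the parameters used to impute
# are a draw from the asymptotic posterior at the (penalized) fit, not the
# point estimate, so that between-imputation variance reflects parameter
# uncertainty.

# Bayesian linear regression draw.
# X: n x p design (including intercept), y: n response vector.
# A small scale-free ridge keeps rank-deficient or n < p designs workable
# (the limiting case degenerates to an intercept-plus-shrinkage fit).
# Returns beta_hat (the ML-ish fit used for the observed-side predictions)
# and beta_draw / sigma_draw (the posterior draw used for the missing side).
norm_draw <- function(X, y, ridge = 1e-5) {
  p <- ncol(X)
  n <- nrow(X)
  S <- crossprod(X)
  S <- S + diag(ridge * pmax(diag(S), 1), p)
  R <- chol(S)
  beta_hat <- backsolve(R, forwardsolve(t(R), crossprod(X, y)))
  resid <- y - X %*% beta_hat
  df <- max(n - p, 1)
  sigma2 <- sum(resid^2) / stats::rchisq(1, df)
  beta_draw <- beta_hat + backsolve(R, stats::rnorm(p)) * sqrt(sigma2)
  list(beta_hat = beta_hat, beta_draw = beta_draw, sigma = sqrt(sigma2))
}

# Ridge-penalized multinomial logistic regression by Newton-Raphson.
# X: n x p design (including intercept); y: integer class index in 1..K
# (class 1 is the reference); w: observation weights. lambda penalizes all
# coefficients, which bounds the fit when a class is rare or separable.
# Returns the p x (K-1) coefficient matrix and the Cholesky factor of the
# penalized Hessian (for posterior draws).
fit_multinom_ridge <- function(X, y, K, w = NULL, lambda = 1e-4,
                               maxit = 30, tol = 1e-7) {
  n <- nrow(X)
  p <- ncol(X)
  if (is.null(w)) w <- rep(1, n)
  Y <- matrix(0, n, K)
  Y[cbind(seq_len(n), y)] <- 1

  B <- matrix(0, p, K - 1)
  probs <- function(B) {
    eta <- X %*% B
    eta <- pmin(pmax(eta, -30), 30)
    E <- cbind(1, exp(eta))
    E / rowSums(E)
  }
  pen_ll <- function(B, P) {
    sum(w * log(pmax(P[cbind(seq_len(n), y)], 1e-12))) - 0.5 * lambda * sum(B^2)
  }

  P <- probs(B)
  ll <- pen_ll(B, P)
  d <- p * (K - 1)
  H <- matrix(0, d, d)
  for (iter in seq_len(maxit)) {
    # gradient and Hessian of the penalized log-likelihood
    G <- crossprod(X, w * (Y[, -1, drop = FALSE] - P[, -1, drop = FALSE])) -
      lambda * B
    for (a in seq_len(K - 1)) {
      for (b in a:(K - 1)) {
        wab <- w * (P[, a + 1] * ((a == b) - P[, b + 1]))
        block <- crossprod(X, X * wab)
        ra <- (a - 1) * p + seq_len(p)
        rb <- (b - 1) * p + seq_len(p)
        H[ra, rb] <- block
        if (a != b) H[rb, ra] <- block
      }
    }
    diag(H) <- diag(H) + lambda
    step <- tryCatch(solve(H, as.vector(G)), error = function(e) {
      solve(H + diag(1e-6 * max(diag(H)), d), as.vector(G))
    })
    # damped Newton: halve until the penalized log-likelihood improves
    alpha <- 1
    repeat {
      B_new <- B + alpha * matrix(step, p, K - 1)
      P_new <- probs(B_new)
      ll_new <- pen_ll(B_new, P_new)
      if (ll_new >= ll - 1e-10 || alpha < 1e-4) break
      alpha <- alpha / 2
    }
    converged <- abs(ll_new - ll) < tol * (abs(ll) + 1)
    B <- B_new
    P <- P_new
    ll <- ll_new
    if (converged) break
  }
  # final Hessian at the optimum, for the asymptotic-normal parameter draw
  for (a in seq_len(K - 1)) {
    for (b in a:(K - 1)) {
      wab <- w * (P[, a + 1] * ((a == b) - P[, b + 1]))
      block <- crossprod(X, X * wab)
      ra <- (a - 1) * p + seq_len(p)
      rb <- (b - 1) * p + seq_len(p)
      H[ra, rb] <- block
      if (a != b) H[rb, ra] <- block
    }
  }
  diag(H) <- diag(H) + lambda
  R <- tryCatch(chol(H), error = function(e) {
    chol(H + diag(1e-6 * max(diag(H)), d))
  })
  list(coef = B, chol_hessian = R, K = K)
}

# Draw coefficients from the asymptotic normal N(B_hat, H^-1).
draw_multinom <- function(fit) {
  d <- length(fit$coef)
  z <- stats::rnorm(d)
  fit$coef + matrix(backsolve(fit$chol_hessian, z), nrow(fit$coef))
}

# Class probabilities for new rows under coefficient matrix B.
predict_multinom <- function(B, X_new) {
  eta <- X_new %*% B
  eta <- pmin(pmax(eta, -30), 30)
  E <- cbind(1, exp(eta))
  E / rowSums(E)
}

# Predictive-mean-matching donor selection.
# For each missing-row prediction, find the donor_k observed rows with the
# closest predictions (distance ties broken uniformly at random) and copy
# the observed value of one donor chosen uniformly among them.
#
# The k nearest donors in |prediction - target| always lie within donor_k
# sorted positions of the target's insertion point, so a window search is
# exact — except that donors tied in distance with the k-th nearest deserve
# an equal chance. The tie set is the contiguous value interval
# [target - r, target + r] (r = k-th smallest distance); when it is large
# (e.g. constant predictions, where every donor ties) selection degenerates
# to a uniform draw over the tie set, which is the correct limit.
match_donors <- function(yhat_obs, y_obs, yhat_mis, donor_k = 5L) {
  n_obs <- length(yhat_obs)
  donor_k <- min(donor_k, n_obs)
  ord <- order(yhat_obs)
  ys <- yhat_obs[ord]
  vals <- y_obs[ord]
  tol <- 1e-7 * max(diff(range(c(yhat_obs, yhat_mis))), 1)
  out <- numeric(length(yhat_mis))
  pos <- findInterval(yhat_mis, ys)
  for (j in seq_along(yhat_mis)) {
    x <- yhat_mis[j]
    cand <- max(1L, pos[j] - donor_k):min(n_obs, pos[j] + donor_k)
    d <- abs(ys[cand] - x)
    r <- sort(d, partial = donor_k)[donor_k]
    # all observed rows within distance r (+ tolerance) of the target
    lo <- findInterval(x - r - tol, ys) + 1L
    hi <- findInterval(x + r + tol, ys)
    if (hi - lo + 1L <= 4L * donor_k) {
      cand2 <- lo:hi
      d2 <- abs(ys[cand2] - x)
      keep <- cand2[order(d2, stats::runif(length(d2)))][seq_len(donor_k)]
      out[j] <- vals[keep[sample.int(donor_k, 1L)]]
    } else {
      # huge tie set: strictly-closer donors are a vanishing fraction and a
      # uniform draw over the tie interval is the exact tie-break limit
      out[j] <- vals[lo + sample.int(hi - lo + 1L, 1L) - 1L]
    }
  }
  out
}
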