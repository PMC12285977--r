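#' Gaussian mixture parameters
#'
#' Container for a K-component multivariate Gaussian mixture: the mixture
#' density is `sum_k c_k N(x | mu_k, Sigma_k)` with non-negative weights
#' `c_k` summing to 1.
#'
#' @param weights Numeric vector of K mixture coefficients.
#' @param means K x d matrix of component means (rows).
#' @param covariances List of K d x d covariance matrices.
#' @return An object of class `gmm_params`.
#' @export
gmm_params <- function(weights, means, covariances) {
  means <- as.matrix(means)
  K <- length(weights)
  if (nrow(means) != K || length(covariances) != K)
    stop("weights, means and covariances must describe the same K components")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9)
    stop("mixture weights must be non-negative and sum to 1")
  for (S in covariances) {
    S <- as.matrix(S)
    if (nrow(S) != ncol(means) || max(abs(S - t(S))) > 1e-8)
      stop("each covariance must be a symmetric d x d matrix")
  }
  structure(list(weights = as.numeric(weights), means = means,
                 covariances = lapply(covariances, as.matrix)),
            class = "gmm_params")
}

# log density of N(x | mu, Sigma) for rows of X, via Cholesky
log_dmvn <- function(X, mu, Sigma) {
  X <- as.matrix(X)
  d <- ncol(X)
  L <- chol(Sigma)
  z <- forwardsolve(t(L), t(X) - mu)
  -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(L))) + colSums(z^2))
}

# T x K matrix of per-component log densities (+ log weight)
gmm_component_logdens <- function(X, params) {
  X <- as.matrix(X)
  K <- length(params$weights)
  out <- matrix(-Inf, nrow(X), K)
  for (k in seq_len(K)) {
    if (params$weights[k] > 0)
      out[, k] <- log(params$weights[k]) +
        log_dmvn(X, params$means[k, ], params$covariances[[k]])
  }
  out
}

logsumexp_rows <- function(M) {
  mx <- apply(M, 1, max)
  fin <- is.finite(mx)
  out <- mx
  out[fin] <- mx[fin] + log(rowSums(exp(M[fin, , drop = FALSE] - mx[fin])))
  out
}

#' Gaussian mixture density
#'
#' Evaluates `sum_k c_k N(x | mu_k, Sigma_k)` at one or more observations.
#'
#' @param x Numeric vector (one observation) or matrix (rows = observations)
#'   whose dimension matches the mixture means.
#' @param params A [gmm_params()] object.
#' @return Numeric vector of densities, strictly positive for finite input.
#' @export
gmm_pdf <- function(x, params) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != ncol(params$means))
    stop("observation dimension (", ncol(x), ") does not match mixture (",
         ncol(params$means), ")")
  exp(logsumexp_rows(gmm_component_logdens(x, params)))
}

#' Log mixture density (internal scale of the HMM recursions)
#' @inheritParams gmm_pdf
#' @return Numeric vector of log densities.
#' @export
gmm_log_pdf <- function(x, params) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  logsumexp_rows(gmm_component_logdens(x, params))
}

# moment estimates for one weighted component, with diagonal floor eps
weighted_moments <- function(X, w, eps) {
  W <- sum(w)
  mu <- colSums(X * w) / W
  Xc <- sweep(X, 2, mu)
  S <- crossprod(Xc * w, Xc) / W
  S <- (S + t(S)) / 2
  diag(S) <- diag(S) + eps
  list(mean = mu, cov = S)
}

#' Fit a Gaussian mixture by EM with k-means initialisation
#'
#' Components are initialised from seeded-restart k-means on the data
#' (falling back to quantile splits in one dimension when k-means degenerates)
#' and refined by expectation-maximisation. The mean log-likelihood is
#' non-decreasing across iterations; covariance diagonals are floored by a
#' regularisation constant so degenerate (repeated) data stay well-posed.
#'
#' @param data Numeric vector (1-D) or matrix (rows = observations).
#' @param K Number of mixture components; at least K observations required.
#' @param seed Integer seed for the k-means initialisation.
#' @param tol Stop when the mean log-likelihood improves by less than this
#'   (default 1e-6).
#' @param max_iter Maximum EM iterations (default 200).
#' @param eps Covariance diagonal floor (default 1e-6).
#' @return A [gmm_params()] object with attribute `log_likelihood`.
#' @export
fit_gmm <- function(data, K, seed = 1, tol = 1e-6, max_iter = 200,
                    eps = 1e-6) {
  X <- if (is.null(dim(data))) matrix(as.numeric(data), ncol = 1)
       else as.matrix(data)
  n <- nrow(X); d <- ncol(X)
  if (n < K) stop("need at least K observations (n=", n, ", K=", K, ")")
  params <- gmm_init_kmeans(X, K, seed, eps)
  if (K == 1L) {
    # single component: one closed-form M-step
    m <- weighted_moments(X, rep(1, n), eps)
    params <- gmm_params(1, matrix(m$mean, 1), list(m$cov))
    attr(params, "log_likelihood") <- sum(gmm_log_pdf(X, params))
    return(params)
  }
  ll_prev <- -Inf
  for (it in seq_len(max_iter)) {
    ld <- gmm_component_logdens(X, params)
    tot <- logsumexp_rows(ld)
    ll <- sum(tot)
    R <- exp(ld - tot)  # responsibilities
    Wk <- colSums(R)
    Wk <- pmax(Wk, 1e-12)
    weights <- Wk / sum(Wk)
    means <- matrix(0, K, d)
    covs <- vector("list", K)
    for (k in seq_len(K)) {
      m <- weighted_moments(X, R[, k], eps)
      means[k, ] <- m$mean
      covs[[k]] <- m$cov
    }
    params <- gmm_params(weights, means, covs)
    if (is.finite(ll_prev) && (ll - ll_prev) / n < tol) break
    ll_prev <- ll
  }
  attr(params, "log_likelihood") <- sum(gmm_log_pdf(X, params))
  params
}

# k-means-based initial mixture parameters
gmm_init_kmeans <- function(X, K, seed, eps) {
  n <- nrow(X); d <- ncol(X)
  assign <- gaze_kmeans(X, K, seed = seed, n_restarts = 5)$assignment
  weights <- numeric(K); means <- matrix(0, K, d); covs <- vector("list", K)
  for (k in seq_len(K)) {
    idx <- which(assign == k)
    if (!length(idx)) idx <- sample.int(n, 1)
    weights[k] <- length(idx) / n
    m <- weighted_moments(X[idx, , drop = FALSE], rep(1, length(idx)), eps)
    means[k, ] <- m$mean
    covs[[k]] <- m$cov
  }
  gmm_params(weights / sum(weights), means, covs)
}
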