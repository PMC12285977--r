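# Shared fixtures and independent oracles for the test suite.
# Oracles are deliberately naive (enumeration / direct formulas) and share no
# code with the implementation paths they check.

# random valid HMM with GMM emissions (d-dimensional, K components per state)
random_hmm <- function(N, d = 1, K = 1, seed = 1) {
  set.seed(seed)
  pi <- runif(N); pi <- pi / sum(pi)
  A <- matrix(runif(N * N), N, N); A <- A / rowSums(A)
  B <- lapply(seq_len(N), function(i) {
    w <- runif(K); w <- w / sum(w)
    mu <- matrix(rnorm(K * d, sd = 3), K, d)
    covs <- lapply(seq_len(K), function(k) {
      M <- matrix(rnorm(d * d), d, d)
      S <- crossprod(M) + diag(d) * 0.5
      (S + t(S)) / 2
    })
    gmm_params(w, mu, covs)
  })
  hmm_model(pi, A, B)
}

# brute-force log P(obs | model): explicit sum over all N^T paths
brute_force_loglik <- function(obs, model) {
  obs <- if (is.null(dim(obs))) matrix(obs, ncol = 1) else as.matrix(obs)
  T_ <- nrow(obs); N <- length(model$pi)
  logb <- sapply(seq_len(N), function(i) gmm_log_pdf(obs, model$B[[i]]))
  logb <- matrix(logb, nrow = T_)
  paths <- as.matrix(expand.grid(rep(list(seq_len(N)), T_)))
  lp <- apply(paths, 1, function(s) {
    val <- log(model$pi[s[1]]) + logb[1, s[1]]
    if (T_ > 1) for (t in 2:T_)
      val <- val + log(model$A[s[t - 1], s[t]]) + logb[t, s[t]]
    val
  })
  m <- max(lp)
  m + log(sum(exp(lp - m)))
}

# brute-force best path and its joint log-probability
brute_force_viterbi <- function(obs, model) {
  obs <- if (is.null(dim(obs))) matrix(obs, ncol = 1) else as.matrix(obs)
  T_ <- nrow(obs); N <- length(model$pi)
  logb <- sapply(seq_len(N), function(i) gmm_log_pdf(obs, model$B[[i]]))
  logb <- matrix(logb, nrow = T_)
  paths <- as.matrix(expand.grid(rep(list(seq_len(N)), T_)))
  lp <- apply(paths, 1, function(s) {
    val <- log(model$pi[s[1]]) + logb[1, s[1]]
    if (T_ > 1) for (t in 2:T_)
      val <- val + log(model$A[s[t - 1], s[t]]) + logb[t, s[t]]
    val
  })
  list(states = as.integer(paths[which.max(lp), ]), log_likelihood = max(lp))
}

# well-separated planar blobs for clustering tests
make_blobs <- function(centers, n_per, sd = 1, seed = 1) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    cbind(rnorm(n_per, centers[i, 1], sd), rnorm(n_per, centers[i, 2], sd))))
  list(X = X, membership = rep(seq_len(nrow(centers)), each = n_per))
}

# random proper rotation matrix
random_rotation <- function(seed = 1) {
  set.seed(seed)
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
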