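#' Hidden Markov model with Gaussian-mixture emissions
#'
#' @param pi Initial state distribution over N states (sums to 1).
#' @param A N x N state transition matrix (rows sum to 1).
#' @param B List of N [gmm_params()] emission models, one per state.
#' @return An object of class `hmm_model`.
#' @export
hmm_model <- function(pi, A, B) {
  A <- as.matrix(A)
  N <- length(pi)
  if (N < 1L) stop("at least one state is required")
  if (!all(dim(A) == c(N, N)) || length(B) != N)
    stop("pi, A and B must describe the same number of states")
  if (any(pi < 0) || abs(sum(pi) - 1) > 1e-9)
    stop("pi must be a probability distribution")
  if (any(A < 0) || any(abs(rowSums(A) - 1) > 1e-9))
    stop("rows of A must be probability distributions")
  if (!all(vapply(B, inherits, logical(1), "gmm_params")))
    stop("B must be a list of gmm_params")
  structure(list(pi = as.numeric(pi), A = A, B = B), class = "hmm_model")
}

#' @export
print.hmm_model <- function(x, ...) {
  cat(sprintf("<hmm_model> %d states, %d-D emissions\n",
              length(x$pi), ncol(x$B[[1]]$means)))
  invisible(x)
}

# T x N matrix of per-state emission log densities
emission_logdens <- function(obs, model) {
  obs <- obs_matrix(obs)
  vapply(model$B, function(p) gmm_log_pdf(obs, p), numeric(nrow(obs)))
}

obs_matrix <- function(obs) {
  if (is.null(dim(obs))) matrix(as.numeric(obs), ncol = 1) else as.matrix(obs)
}

logsumexp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}

# log-space forward pass; returns T x N matrix of log alpha
forward_pass <- function(logB, log_pi, log_A) {
  T_ <- nrow(logB); N <- ncol(logB)
  la <- matrix(-Inf, T_, N)
  la[1, ] <- log_pi + logB[1, ]
  if (T_ > 1) for (t in 2:T_) {
    for (j in seq_len(N))
      la[t, j] <- logsumexp(la[t - 1, ] + log_A[, j]) + logB[t, j]
  }
  la
}

backward_pass <- function(logB, log_A) {
  T_ <- nrow(logB); N <- ncol(logB)
  lb <- matrix(0, T_, N)
  if (T_ > 1) for (t in (T_ - 1):1) {
    for (i in seq_len(N))
      lb[t, i] <- logsumexp(log_A[i, ] + logB[t + 1, ] + lb[t + 1, ])
  }
  lb
}

#' Log-likelihood of an observation sequence under an HMM
#'
#' Computes `log P(obs | model)` with the log-space forward recursion
#' (immune to underflow on long sequences).
#'
#' @param obs Numeric vector (1-D observations) or matrix with one
#'   observation per row.
#' @param model An [hmm_model()].
#' @return The log-likelihood (scalar).
#' @export
forward_log_likelihood <- function(obs, model) {
  logB <- emission_logdens(obs, model)
  la <- forward_pass(logB, log(model$pi), log(model$A))
  logsumexp(la[nrow(la), ])
}

#' Viterbi decoding
#'
#' Returns the most probable hidden-state path in log space; ties at any
#' backtrack step break toward the lower state index, making decoding
#' deterministic.
#'
#' @inheritParams forward_log_likelihood
#' @return A list of class `decode_result` with `states` (integer path,
#'   1-based) and `log_likelihood` (joint log-probability of the path).
#' @export
viterbi <- function(obs, model) {
  logB <- emission_logdens(obs, model)
  T_ <- nrow(logB); N <- ncol(logB)
  log_pi <- log(model$pi); log_A <- log(model$A)
  delta <- matrix(-Inf, T_, N)
  psi <- matrix(1L, T_, N)
  delta[1, ] <- log_pi + logB[1, ]
  if (T_ > 1) for (t in 2:T_) {
    for (j in seq_len(N)) {
      cand <- delta[t - 1, ] + log_A[, j]
      psi[t, j] <- which.max(cand)   # first max = lowest state index
      delta[t, j] <- cand[psi[t, j]] + logB[t, j]
    }
  }
  states <- integer(T_)
  states[T_] <- which.max(delta[T_, ])
  if (T_ > 1) for (t in (T_ - 1):1) states[t] <- psi[t + 1, states[t + 1]]
  structure(list(states = states, log_likelihood = max(delta[T_, ])),
            class = "decode_result")
}

# E-step sufficient statistics for one sequence
hmm_estep <- function(obs, model, logB = NULL) {
  obs <- obs_matrix(obs)
  if (is.null(logB)) logB <- emission_logdens(obs, model)
  T_ <- nrow(logB); N <- ncol(logB)
  log_pi <- log(model$pi); log_A <- log(model$A)
  la <- forward_pass(logB, log_pi, log_A)
  lb <- backward_pass(logB, log_A)
  ll <- logsumexp(la[T_, ])
  lgamma_ <- la + lb - ll
  gamma_ <- exp(lgamma_)
  xi <- matrix(0, N, N)
  if (T_ > 1) for (t in 1:(T_ - 1)) {
    lx <- outer(la[t, ], logB[t + 1, ] + lb[t + 1, ], "+") + log_A - ll
    xi <- xi + exp(lx)
  }
  list(gamma = gamma_, xi = xi, log_likelihood = ll)
}

#' Baum-Welch re-estimation for a GMM-emission HMM
#'
#' Expectation-maximisation over hidden state paths: the E-step runs the
#' log-space forward-backward recursions (with per-component responsibilities
#' inside each state's mixture), the M-step re-estimates the initial
#' distribution, transition matrix and every state's mixture weights, means
#' and covariances (diagonals floored by `eps`). The forward log-likelihood
#' is non-decreasing across iterations up to numerical slack. Multiple
#' observation sequences are trained by summing sufficient statistics.
#'
#' @param obs Numeric vector/matrix, or a list of such sequences.
#' @param init An [hmm_model()] starting point.
#' @param n_iter Maximum iterations (default 100); `0` returns `init`.
#' @param tol Stop when the mean per-observation log-likelihood improves by
#'   less than `tol` (default 1e-4).
#' @param eps Covariance diagonal floor (default 1e-6).
#' @param viterbi_training If `TRUE`, state responsibilities are replaced by
#'   the hard Viterbi path at each iteration (segmental/hard EM).
#' @return An `hmm_model` with attribute `log_likelihood` (final forward
#'   log-likelihood, summed over sequences) and `n_iter_used`.
#' @export
baum_welch <- function(obs, init, n_iter = 100, tol = 1e-4, eps = 1e-6,
                       viterbi_training = FALSE) {
  seqs <- if (is.list(obs) && !is.data.frame(obs)) lapply(obs, obs_matrix)
          else list(obs_matrix(obs))
  model <- init
  if (n_iter == 0L) return(model)
  N <- length(model$pi)
  total_T <- sum(vapply(seqs, nrow, integer(1)))
  ll_prev <- -Inf
  iters <- 0L
  for (it in seq_len(n_iter)) {
    iters <- it
    pi_acc <- numeric(N)
    xi_acc <- matrix(0, N, N)
    gamma_all <- vector("list", length(seqs))
    ll <- 0
    for (s in seq_along(seqs)) {
      logB <- emission_logdens(seqs[[s]], model)
      if (viterbi_training) {
        dec <- viterbi(seqs[[s]], model)
        T_ <- length(dec$states)
        g <- matrix(0, T_, N)
        g[cbind(seq_len(T_), dec$states)] <- 1
        xi <- matrix(0, N, N)
        if (T_ > 1) for (t in 1:(T_ - 1))
          xi[dec$states[t], dec$states[t + 1]] <-
            xi[dec$states[t], dec$states[t + 1]] + 1
        es <- list(gamma = g, xi = xi,
                   log_likelihood = forward_log_likelihood(seqs[[s]], model))
      } else {
        es <- hmm_estep(seqs[[s]], model, logB)
      }
      pi_acc <- pi_acc + es$gamma[1, ]
      xi_acc <- xi_acc + es$xi
      gamma_all[[s]] <- es$gamma
      ll <- ll + es$log_likelihood
    }
    # M-step
    new_pi <- pi_acc / sum(pi_acc)
    row_tot <- rowSums(xi_acc)
    new_A <- model$A
    for (i in seq_len(N)) {
      if (row_tot[i] > 0) new_A[i, ] <- xi_acc[i, ] / row_tot[i]
    }
    new_B <- vector("list", N)
    X_all <- do.call(rbind, seqs)
    for (i in seq_len(N)) {
      g_i <- unlist(lapply(gamma_all, function(g) g[, i]))
      if (sum(g_i) < 1e-8) {
        warning("state ", i, " starved of responsibility; reinitialising ",
                "its emission from a random observation")
        new_B[[i]] <- reinit_emission(X_all, length(model$B[[i]]$weights), eps)
        next
      }
      new_B[[i]] <- mstep_emission(X_all, g_i, model$B[[i]], eps)
    }
    model <- hmm_model(new_pi, new_A, new_B)
    if (is.finite(ll_prev) && (ll - ll_prev) / total_T < tol) break
    ll_prev <- ll
  }
  attr(model, "log_likelihood") <- sum(vapply(
    seqs, forward_log_likelihood, numeric(1), model = model))
  attr(model, "n_iter_used") <- iters
  model
}

# re-estimate one state's GMM given state responsibilities g (length T)
mstep_emission <- function(X, g, old, eps) {
  K <- length(old$weights)
  ld <- gmm_component_logdens(X, old)       # T x K, includes log weights
  tot <- logsumexp_rows(ld)
  R <- exp(ld - tot) * g                    # joint state-component resp.
  Wk <- colSums(R)
  if (any(Wk < 1e-12)) {
    # collapse unused components onto used ones
    Wk <- pmax(Wk, 1e-12)
  }
  weights <- Wk / sum(Wk)
  d <- ncol(X)
  means <- matrix(0, K, d); covs <- vector("list", K)
  for (k in seq_len(K)) {
    m <- weighted_moments(X, R[, k] + 1e-300, eps)
    means[k, ] <- m$mean
    covs[[k]] <- m$cov
  }
  gmm_params(weights, means, covs)
}

reinit_emission <- function(X, K, eps) {
  d <- ncol(X)
  idx <- sample.int(nrow(X), K, replace = nrow(X) < K)
  S <- stats::cov(X) * 0.1
  if (any(!is.finite(S))) S <- diag(d)
  S <- (S + t(S)) / 2
  diag(S) <- diag(S) + eps
  gmm_params(rep(1 / K, K), X[idx, , drop = FALSE],
             replicate(K, S, simplify = FALSE))
}

# diagonal-dominant initial model: k-means emissions, 0.9 self-transition
init_hmm <- function(obs, N, gmm_K = 2, seed = 1, self_trans = 0.9,
                     eps = 1e-6) {
  X <- obs_matrix(obs)
  n <- nrow(X)
  pi <- rep(1 / N, N)
  A <- matrix(if (N > 1) (1 - self_trans) / (N - 1) else 0, N, N)
  diag(A) <- if (N > 1) self_trans else 1
  assign <- gaze_kmeans(X, N, seed = seed, n_restarts = 5)$assignment
  B <- vector("list", N)
  for (i in seq_len(N)) {
    Xi <- X[assign == i, , drop = FALSE]
    Ki <- max(1L, min(gmm_K, nrow(Xi)))
    B[[i]] <- if (nrow(Xi) == 0) reinit_emission(X, gmm_K, eps)
              else fit_gmm(Xi, Ki, seed = seed + i, eps = eps)
  }
  hmm_model(pi, A, B)
}

#' Write an HMM model to a structured text (YAML) file
#'
#' Values are written with 15 significant digits so a read/write round trip
#' reproduces the model to that precision.
#'
#' @param model An [hmm_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hmm_model <- function(model, path) {
  lst <- list(
    pi = model$pi,
    A = apply(model$A, 1, as.numeric, simplify = FALSE),
    B = lapply(model$B, function(p) list(
      weights = p$weights,
      means = apply(p$means, 1, as.numeric, simplify = FALSE),
      covariances = lapply(p$covariances, function(S)
        apply(S, 1, as.numeric, simplify = FALSE)))))
  writeLines(yaml::as.yaml(lst, precision = 15), path)
  invisible(path)
}

#' Read an HMM model written by [write_hmm_model()]
#' @param path Path to the YAML file.
#' @return An [hmm_model()].
#' @export
read_hmm_model <- function(path) {
  lst <- yaml::read_yaml(path)
  A <- do.call(rbind, lapply(lst$A, as.numeric))
  B <- lapply(lst$B, function(p) gmm_params(
    as.numeric(p$weights),
    do.call(rbind, lapply(p$means, as.numeric)),
    lapply(p$covariances, function(S)
      do.call(rbind, lapply(S, as.numeric)))))
  hmm_model(as.numeric(lst$pi), A, B)
}
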