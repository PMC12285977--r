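test_that("single-state likelihood is the summed emission log-density", {
  m <- random_hmm(N = 1, d = 1, K = 2, seed = 3)
  obs <- rnorm(20)
  expect_equal(forward_log_likelihood(obs, m),
               sum(gmm_log_pdf(matrix(obs), m$B[[1]])))
  dec <- viterbi(obs, m)
  expect_equal(dec$states, rep(1L, 20))
})

test_that("forward likelihood equals exhaustive path enumeration", {
  for (trial in 1:25) {
    N <- sample(2:3, 1)
    T_ <- sample(2:6, 1)
    m <- random_hmm(N, d = 1, K = sample(1:2, 1), seed = trial)
    set.seed(trial + 500)
    obs <- rnorm(T_, sd = 3)
    expect_equal(forward_log_likelihood(obs, m),
                 brute_force_loglik(obs, m), tolerance = 1e-10)
  }
})

test_that("viterbi attains the enumerated maximum path probability", {
  for (trial in 1:25) {
    N <- sample(2:3, 1)
    T_ <- sample(2:5, 1)
    m <- random_hmm(N, d = 1, seed = trial + 40)
    set.seed(trial + 900)
    obs <- rnorm(T_, sd = 3)
    dec <- viterbi(obs, m)
    bf <- brute_force_viterbi(obs, m)
    expect_equal(dec$log_likelihood, bf$log_likelihood, tolerance = 1e-10)
    expect_equal(dec$states, bf$states)
  }
})

test_that("ties break toward the lower state index", {
  em <- gmm_params(1, matrix(0), list(matrix(1)))
  m <- hmm_model(rep(1 / 3, 3), matrix(1 / 3, 3, 3), list(em, em, em))
  dec <- viterbi(rnorm(10), m)
  expect_equal(dec$states, rep(1L, 10))
})

test_that("jointly permuting state labels preserves likelihood and path", {
  m <- random_hmm(3, d = 2, K = 2, seed = 8)
  set.seed(77)
  obs <- matrix(rnorm(24, sd = 2), ncol = 2)
  perm <- c(3, 1, 2)
  mp <- hmm_model(m$pi[perm], m$A[perm, perm], m$B[perm])
  expect_equal(forward_log_likelihood(obs, mp),
               forward_log_likelihood(obs, m), tolerance = 1e-10)
  d1 <- viterbi(obs, m); d2 <- viterbi(obs, mp)
  expect_equal(d2$log_likelihood, d1$log_likelihood, tolerance = 1e-10)
  # path maps through the inverse permutation
  expect_equal(perm[d2$states], d1$states)
})

test_that("baum_welch honours its degenerate contracts", {
  m <- random_hmm(2, d = 1, seed = 5)
  obs <- rnorm(30)
  expect_identical(baum_welch(obs, m, n_iter = 0), m)

  m1 <- random_hmm(1, d = 1, K = 2, seed = 6)
  fit <- baum_welch(obs, m1, n_iter = 20)
  expect_equal(fit$A, matrix(1, 1, 1), ignore_attr = TRUE)
  expect_equal(fit$pi, 1)
})

test_that("baum_welch log-likelihood is non-decreasing and keeps invariants", {
  for (trial in 1:10) {
    m <- random_hmm(2, d = 1, K = 2, seed = trial + 200)
    set.seed(trial + 300)
    obs <- c(rnorm(30, -2), rnorm(30, 2))[sample(60)]
    model <- m
    ll_prev <- -Inf
    for (it in 1:6) {
      model <- baum_welch(obs, model, n_iter = 1, tol = 0)
      ll <- forward_log_likelihood(obs, model)
      expect_gte(ll, ll_prev - 1e-8)
      expect_equal(sum(model$pi), 1, tolerance = 1e-9)
      expect_equal(rowSums(model$A), rep(1, 2), tolerance = 1e-9,
                   ignore_attr = TRUE)
      for (B in model$B) {
        expect_equal(sum(B$weights), 1, tolerance = 1e-9)
        for (S in B$covariances) expect_gte(min(eigen(S)$values), 1e-7)
      }
      ll_prev <- ll
    }
  }
})

test_that("baum_welch recovers transition structure from simulated data", {
  # 2-state chain with well-separated 1-D Gaussian emissions
  A_true <- rbind(c(0.95, 0.05), c(0.10, 0.90))
  set.seed(123)
  T_ <- 3000
  states <- integer(T_); states[1] <- 1
  for (t in 2:T_)
    states[t] <- sample(1:2, 1, prob = A_true[states[t - 1], ])
  obs <- rnorm(T_, mean = c(-5, 5)[states], sd = 1)
  init <- hmm_model(c(0.5, 0.5), rbind(c(0.8, 0.2), c(0.2, 0.8)),
                    list(gmm_params(1, matrix(-2), list(matrix(4))),
                         gmm_params(1, matrix(2), list(matrix(4)))))
  fit <- baum_welch(obs, init, n_iter = 50)
  # state matching by emission mean sign
  ord <- order(vapply(fit$B, function(p) sum(p$weights * p$means), 1))
  A_hat <- fit$A[ord, ord]
  expect_lt(max(abs(A_hat - A_true)), 0.05)
})

test_that("multiple sequences train via summed sufficient statistics", {
  set.seed(31)
  seqs <- list(c(rnorm(40, -3), rnorm(40, 3)), c(rnorm(40, 3), rnorm(40, -3)))
  init <- hmm_model(c(0.5, 0.5), rbind(c(0.9, 0.1), c(0.1, 0.9)),
                    list(gmm_params(1, matrix(-1), list(matrix(4))),
                         gmm_params(1, matrix(1), list(matrix(4)))))
  fit <- baum_welch(seqs, init, n_iter = 30)
  mus <- sort(vapply(fit$B, function(p) sum(p$weights * p$means), 1))
  expect_lt(abs(mus[1] - -3), 0.5)
  expect_lt(abs(mus[2] - 3), 0.5)
})

test_that("model serialization round-trips to 15 significant digits", {
  m <- random_hmm(3, d = 2, K = 2, seed = 14)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_hmm_model(m, f)
  m2 <- read_hmm_model(f)
  expect_equal(m2$pi, m$pi, tolerance = 1e-14)
  expect_equal(m2$A, m$A, tolerance = 1e-14)
  for (i in 1:3) {
    expect_equal(m2$B[[i]]$weights, m$B[[i]]$weights, tolerance = 1e-14)
    expect_equal(m2$B[[i]]$means, m$B[[i]]$means, tolerance = 1e-14)
    expect_equal(m2$B[[i]]$covariances, m$B[[i]]$covariances,
                 tolerance = 1e-14)
  }
})

test_that("hmm_model validates its stochastic constraints", {
  em <- gmm_params(1, matrix(0), list(matrix(1)))
  expect_error(hmm_model(c(0.5, 0.6), diag(2), list(em, em)), "probability")
  expect_error(hmm_model(c(0.5, 0.5), rbind(c(0.5, 0.4), c(0.5, 0.5)),
                         list(em, em)), "rows of A")
})
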