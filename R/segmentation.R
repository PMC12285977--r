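#' K-means clustering of gaze coordinates (Lloyd iterations, seeded restarts)
#'
#' Clusters the spatial coordinates (x, y) of a gaze sequence with Lloyd's
#' algorithm. Centers are initialised by sampling k distinct points; the best
#' (lowest-cost) result over `n_restarts` seeded restarts is returned, making
#' the result deterministic for a fixed seed. Empty clusters are re-seeded at
#' the sample farthest from its current center.
#'
#' @param seq A `gaze_sequence` (clustered on its x, y columns) or a numeric
#'   matrix with one observation per row.
#' @param k Number of cluster centers, `1 <= k <= n`.
#' @param max_iter Maximum Lloyd iterations per restart (default 100).
#' @param seed Integer seed; restart r uses `seed + r - 1`.
#' @param n_restarts Number of seeded restarts (default 10).
#' @return A list of class `gaze_kmeans` with components `centers` (k x d
#'   matrix), `assignment` (per-sample center index), and `cost` (the k-means
#'   objective: total squared distance of samples to assigned centers).
#' @export
gaze_kmeans <- function(seq, k, max_iter = 100, seed = 1, n_restarts = 10) {
  X <- kmeans_coords(seq)
  n <- nrow(X)
  if (k < 1L || k > n) stop("k must satisfy 1 <= k <= n (k=", k, ", n=", n, ")")
  if (max_iter < 1L) stop("max_iter must be >= 1")
  best <- NULL
  for (r in seq_len(n_restarts)) {
    res <- lloyd_once(X, k, max_iter, seed + r - 1L)
    if (is.null(best) || res$cost < best$cost) best <- res
  }
  class(best) <- "gaze_kmeans"
  best
}

kmeans_coords <- function(seq) {
  if (is.matrix(seq)) {
    storage.mode(seq) <- "double"
    return(seq)
  }
  seq <- as_gaze_sequence(seq)
  cbind(x = seq$x, y = seq$y)
}

# squared distances from every row of X to every center: n x k matrix
sqdist_to_centers <- function(X, centers) {
  n <- nrow(X); k <- nrow(centers)
  D <- matrix(0, n, k)
  for (j in seq_len(k))
    D[, j] <- rowSums(sweep(X, 2, centers[j, ])^2)
  D
}

lloyd_once <- function(X, k, max_iter, seed) {
  n <- nrow(X)
  set.seed(seed)
  centers <- X[sample.int(n, k), , drop = FALSE]
  assign_prev <- integer(0)
  for (it in seq_len(max_iter)) {
    D <- sqdist_to_centers(X, centers)
    assignment <- max.col(-D, ties.method = "first")
    # empty clusters: re-seed at the sample farthest from its assigned center
    dmin <- D[cbind(seq_len(n), assignment)]
    for (j in seq_len(k)) {
      if (!any(assignment == j)) {
        far <- which.max(dmin)
        centers[j, ] <- X[far, ]
        assignment[far] <- j
        dmin[far] <- 0
      }
    }
    for (j in seq_len(k))
      centers[j, ] <- colMeans(X[assignment == j, , drop = FALSE])
    if (identical(assignment, assign_prev)) break
    assign_prev <- assignment
  }
  D <- sqdist_to_centers(X, centers)
  assignment <- max.col(-D, ties.method = "first")
  cost <- sum(D[cbind(seq_len(n), assignment)])
  list(centers = centers, assignment = assignment, cost = cost)
}

#' SSE curve over candidate cluster counts
#'
#' Runs seeded-restart k-means for every cluster count `k = 1..K_m` and
#' records the sum of squared errors (SSE, px^2) of the best run; the curve
#' drives elbow-based selection of the number of gaze-path segments.
#'
#' @inheritParams gaze_kmeans
#' @param K_m Maximum cluster count (clipped to the number of samples).
#' @return An object of class `sse_curve`: data.frame with columns `k`, `sse`.
#' @export
sse_curve <- function(seq, K_m = 10, max_iter = 100, seed = 1,
                      n_restarts = 10) {
  X <- kmeans_coords(seq)
  if (K_m > nrow(X)) stop("K_m must not exceed the number of samples")
  sse <- vapply(seq_len(K_m), function(k) {
    gaze_kmeans(X, k, max_iter = max_iter, seed = seed,
                n_restarts = n_restarts)$cost
  }, numeric(1))
  out <- data.frame(k = seq_len(K_m), sse = sse)
  class(out) <- c("sse_curve", "data.frame")
  out
}

#' Elbow selection of the cluster count
#'
#' Picks the k whose point (k, SSE_k) has maximal perpendicular distance to
#' the chord joining the curve's endpoints (a "kneedle"-style rule); ties
#' break toward the smallest k. The choice is invariant to uniform scaling of
#' all SSE values.
#'
#' @param curve An `sse_curve` (or data.frame with columns `k`, `sse`)
#'   covering at least 3 values of k.
#' @return The selected integer k.
#' @export
select_k_elbow <- function(curve) {
  k <- curve$k; s <- curve$sse
  m <- length(k)
  if (m < 3L) stop("elbow selection needs at least 3 SSE entries")
  # |cross product| of (chord) x (point - first); chord length is common to
  # all k, so it can be dropped from the argmax
  dk <- k[m] - k[1]; ds <- s[m] - s[1]
  num <- abs(dk * (s - s[1]) - ds * (k - k[1]))
  # endpoints lie on the chord (distance 0) and are never candidates
  interior <- 2:(m - 1L)
  k[interior][which.max(num[interior])]  # first maximum = smallest k on ties
}
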