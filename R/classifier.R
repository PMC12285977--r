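#' Configuration for the hierarchical classifier
#'
#' @param K_m Maximum cluster count scanned by the SSE elbow rule
#'   (default 10, clipped to the sequence length).
#' @param kmeans_max_iter Lloyd iterations per k-means restart (default 100).
#' @param n_restarts Seeded k-means restarts (default 10).
#' @param n_iter_round1,n_iter_round2 Maximum Baum-Welch iterations for the
#'   coarse (spatial) and fine (velocity) rounds (default 100 each;
#'   convergence tolerance usually stops much earlier).
#' @param tol Baum-Welch convergence tolerance on the mean per-observation
#'   log-likelihood change (default 1e-4).
#' @param gmm_k_round1,gmm_k_round2 Gaussian-mixture components per HMM
#'   state in each round (default 2, valid 1-5).
#' @param min_run_length Minimum first-round run length in samples; shorter
#'   runs are merged into their longer temporal neighbour (default 3,
#'   about 33 ms at 90 Hz, suppressing single-sample Viterbi flicker).
#' @param degenerate_velocity_spread Velocity spread (max - min, px/s) below
#'   which a segment (or the whole recording) is treated as single-behaviour
#'   and labelled without HMM fitting (default 30). A 3-state HMM on a
#'   one-behaviour velocity trace is unidentifiable; this keeps such inputs
#'   well-defined.
#' @param features_round1 Coarse-round features: `"xy"` (default) or
#'   `"xyv"`.
#' @param features_round2 Fine-round features: `"v"` (default) or `"xyv"`.
#' @param log_velocity Model the fine-round velocity trace as
#'   `log(v + degenerate_velocity_spread)` (default `TRUE`). Gaze speeds
#'   span four decades; the monotone offset-log transform keeps Gaussian
#'   mixtures well-conditioned without changing the velocity ordering used
#'   for labelling, and the offset stops sub-resolution differences among
#'   near-zero speeds from being magnified.
#' @param state_mapping `"global"` (default): each fine-round HMM state is
#'   labelled by the nearest of the recording-level velocity regimes
#'   (fixation/pursuit/saccade levels found by seeded 3-means on the whole
#'   recording's velocity trace). `"rank"`: states are labelled by ascending
#'   learned mean velocity within each segment.
#' @param viterbi_training Use hard (Viterbi) state assignments inside
#'   Baum-Welch instead of soft responsibilities (default `FALSE`).
#' @param smooth_window Optional centered moving-average window (samples,
#'   odd) applied to the velocity trace; 0 disables (default).
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(K_m = 10, kmeans_max_iter = 100,
                              n_restarts = 10,
                              n_iter_round1 = 100, n_iter_round2 = 100,
                              tol = 1e-4,
                              gmm_k_round1 = 2, gmm_k_round2 = 2,
                              min_run_length = 3,
                              degenerate_velocity_spread = 30,
                              features_round1 = c("xy", "xyv"),
                              features_round2 = c("v", "xyv"),
                              log_velocity = TRUE,
                              state_mapping = c("global", "rank"),
                              viterbi_training = FALSE,
                              smooth_window = 0) {
  cfg <- list(K_m = K_m, kmeans_max_iter = kmeans_max_iter,
              n_restarts = n_restarts,
              n_iter_round1 = n_iter_round1, n_iter_round2 = n_iter_round2,
              tol = tol,
              gmm_k_round1 = gmm_k_round1, gmm_k_round2 = gmm_k_round2,
              min_run_length = min_run_length,
              degenerate_velocity_spread = degenerate_velocity_spread,
              features_round1 = match.arg(features_round1),
              features_round2 = match.arg(features_round2),
              log_velocity = isTRUE(log_velocity),
              state_mapping = match.arg(state_mapping),
              viterbi_training = isTRUE(viterbi_training),
              smooth_window = smooth_window)
  counts <- c(cfg$K_m, cfg$kmeans_max_iter, cfg$n_restarts,
              cfg$n_iter_round1, cfg$n_iter_round2, cfg$gmm_k_round1,
              cfg$gmm_k_round2, cfg$min_run_length)
  if (any(counts < 1)) stop("all count parameters must be >= 1")
  if (cfg$gmm_k_round1 > 5 || cfg$gmm_k_round2 > 5)
    stop("gmm components per state must be between 1 and 5")
  class(cfg) <- "classifier_config"
  cfg
}

#' Load a classifier configuration from a YAML file
#'
#' Keys mirror the arguments of [classifier_config()]; unlisted keys keep
#' their defaults.
#'
#' @param path Path to a YAML file.
#' @return A `classifier_config`.
#' @export
read_classifier_config <- function(path) {
  lst <- yaml::read_yaml(path)
  known <- names(formals(classifier_config))
  bad <- setdiff(names(lst), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(classifier_config, lst)
}

# fine-round velocity feature: offset-log transform. The offset (the
# velocity-indistinguishability scale) keeps sub-resolution differences
# among near-zero speeds from being magnified, while speeds spanning four
# decades are compressed to comparable scales.
vel_feature <- function(v, cfg) {
  if (cfg$log_velocity) log(v + cfg$degenerate_velocity_spread) else v
}

# recording-level velocity regimes: seeded 3-means on the velocity feature;
# regimes sorted by velocity map ascending onto fixation < pursuit < saccade
global_velocity_regimes <- function(v, cfg, seed) {
  spread <- max(v) - min(v)
  if (spread < cfg$degenerate_velocity_spread)
    return(list(all_fixation = TRUE,
                fix_med = stats::median(v), pur_med = NA_real_))
  z <- vel_feature(v, cfg)
  km <- gaze_kmeans(matrix(z, ncol = 1), 3, seed = seed,
                    n_restarts = cfg$n_restarts)
  ord <- order(km$centers[, 1])
  centers_z <- km$centers[ord, 1]
  med_raw <- vapply(ord, function(j)
    stats::median(v[km$assignment == j]), numeric(1))
  if (med_raw[3] - med_raw[1] < cfg$degenerate_velocity_spread)
    return(list(all_fixation = TRUE,
                fix_med = stats::median(v), pur_med = NA_real_))
  labels <- event_levels()
  run_med <- function(level_idx) {
    assign_lvl <- apply(abs(outer(z, centers_z, "-")), 1, which.min)
    runs <- label_runs(assign_lvl == level_idx)
    stats::median(runs$end[runs$value] - runs$start[runs$value] + 1L)
  }
  if (med_raw[2] - med_raw[1] < cfg$degenerate_velocity_spread) {
    # lower two regimes indistinguishable: both fixation; top regime is a
    # saccade if its occupancy runs are ballistic-brief, else pursuit
    top <- if (run_med(3) <= 13) "saccade" else "pursuit"
    labels <- c("fixation", "fixation", top)
  } else if (med_raw[3] - med_raw[2] < cfg$degenerate_velocity_spread) {
    top <- if (run_med(3) <= 13) "saccade" else "pursuit"
    labels <- c("fixation", top, top)
  }
  list(all_fixation = FALSE, centers_z = centers_z, labels = labels,
       fix_med = med_raw[1],
       pur_med = if (labels[2] == "pursuit") med_raw[2] else NA_real_)
}

#' First-round coarse segmentation
#'
#' Fits a k-state GMM-HMM on the spatial coordinates, decodes the most
#' probable state path with Viterbi, converts the path to maximal runs and
#' merges runs shorter than `min_run_length` into their longer temporal
#' neighbour. The result is a contiguous partition of the samples.
#'
#' @param seq A `gaze_sequence`.
#' @param k Number of coarse states (from the SSE elbow rule).
#' @param cfg A [classifier_config()].
#' @param seed Integer seed.
#' @return A data.frame of class `segmentation_result` with columns
#'   `start`, `end` (1-based, inclusive) and `state`.
#' @export
first_round_segment <- function(seq, k, cfg = classifier_config(),
                                seed = 1) {
  seq <- as_gaze_sequence(seq)
  n <- nrow(seq)
  if (k < 1L || n < k) stop("need 1 <= k <= sequence length")
  X <- round1_features(seq, cfg)
  n_distinct <- nrow(unique(X))
  if (k > n_distinct) {
    warning("k exceeds the number of distinct positions; falling back to k = 1")
    k <- 1L
  }
  if (k == 1L) {
    path <- rep(1L, n)
  } else {
    model0 <- init_hmm(X, k, gmm_K = cfg$gmm_k_round1, seed = seed)
    model <- baum_welch(X, model0, n_iter = cfg$n_iter_round1,
                        tol = cfg$tol,
                        viterbi_training = cfg$viterbi_training)
    path <- viterbi(X, model)$states
  }
  runs <- merge_short_runs(label_runs(path), cfg$min_run_length)
  out <- data.frame(start = runs$start, end = runs$end, state = runs$value)
  class(out) <- c("segmentation_result", "data.frame")
  out
}

round1_features <- function(seq, cfg) {
  X <- cbind(seq$x, seq$y)
  if (cfg$features_round1 == "xyv")
    X <- cbind(X, compute_velocity(seq, cfg$smooth_window))
  X
}

# merge runs shorter than min_len into their longer temporal neighbour
merge_short_runs <- function(runs, min_len) {
  repeat {
    len <- runs$end - runs$start + 1L
    if (nrow(runs) <= 1L || all(len >= min_len)) return(runs)
    i <- which(len < min_len)[which.min(len[len < min_len])]
    if (i == 1L) j <- 2L
    else if (i == nrow(runs)) j <- nrow(runs) - 1L
    else j <- if (len[i - 1L] >= len[i + 1L]) i - 1L else i + 1L
    runs$value[i] <- runs$value[j]
    # recombine adjacent equal-valued runs
    keep <- c(TRUE, runs$value[-1] != runs$value[-nrow(runs)])
    grp <- cumsum(keep)
    runs <- data.frame(start = tapply(runs$start, grp, min),
                       end = tapply(runs$end, grp, max),
                       value = runs$value[keep])
  }
}

#' Second-round fine classification of one segment
#'
#' Fits a 3-state GMM-HMM on the segment's velocity trace (modelled on a
#' log scale by default), decodes with Viterbi, and maps states to event
#' labels (see `state_mapping` in [classifier_config()]). Segments whose
#' velocity spread falls below `degenerate_velocity_spread` skip HMM fitting
#' and take a single label from comparing the segment's median velocity to
#' the recording-level fixation/pursuit medians.
#'
#' @param seq A `gaze_sequence`.
#' @param range Integer vector `c(start, end)` (1-based, inclusive) of the
#'   segment; at least 2 samples.
#' @param cfg A [classifier_config()].
#' @param seed Integer seed.
#' @param velocity Optional precomputed full-sequence velocity trace.
#' @param regimes Optional precomputed recording-level velocity regimes;
#'   computed from the whole sequence when missing.
#' @return Factor of event labels, one per segment sample.
#' @export
second_round_classify <- function(seq, range, cfg = classifier_config(),
                                  seed = 1, velocity = NULL,
                                  regimes = NULL) {
  seq <- as_gaze_sequence(seq)
  if (is.null(velocity)) velocity <- compute_velocity(seq, cfg$smooth_window)
  if (is.null(regimes))
    regimes <- global_velocity_regimes(velocity, cfg, seed)
  idx <- range[1]:range[2]
  if (length(idx) < 2L) stop("segment must contain at least 2 samples")
  v <- velocity[idx]
  lev <- event_levels()
  if (isTRUE(regimes$all_fixation))
    return(factor(rep("fixation", length(idx)), levels = lev))
  if (max(v) - min(v) < cfg$degenerate_velocity_spread) {
    med <- stats::median(v)
    lab <- if (is.na(regimes$pur_med) ||
               abs(med - regimes$fix_med) <= abs(med - regimes$pur_med))
      "fixation" else "pursuit"
    return(factor(rep(lab, length(idx)), levels = lev))
  }
  z <- vel_feature(v, cfg)
  obs <- if (cfg$features_round2 == "xyv")
    cbind(seq$x[idx], seq$y[idx], z) else matrix(z, ncol = 1)
  N <- min(3L, nrow(unique(obs)))
  gmm_K <- max(1L, min(cfg$gmm_k_round2, floor(length(idx) / (2L * N))))
  model0 <- init_hmm(obs, N, gmm_K = gmm_K, seed = seed)
  model <- baum_welch(obs, model0, n_iter = cfg$n_iter_round2,
                      tol = cfg$tol,
                      viterbi_training = cfg$viterbi_training)
  path <- viterbi(obs, model)$states
  vcol <- ncol(obs)  # velocity feature is the last column
  state_means <- vapply(model$B, function(p)
    sum(p$weights * p$means[, vcol]), numeric(1))
  state_lab <- map_states(state_means, regimes, cfg, N)
  factor(state_lab[path], levels = lev)
}

map_states <- function(state_means, regimes, cfg, N) {
  lev <- event_levels()
  if (cfg$state_mapping == "rank") {
    ranks <- rank(state_means, ties.method = "first")
    if (N == 3L) return(lev[ranks])
    if (N == 2L) return(c("fixation", "saccade")[ranks])
    return(rep("fixation", N))
  }
  # global mapping: nearest recording-level regime by learned mean velocity
  # (state means and regime centers live on the same feature scale)
  nearest <- apply(abs(outer(state_means, regimes$centers_z, "-")), 1,
                   which.min)
  regimes$labels[nearest]
}

#' Hierarchical GMM-HMM ternary classification
#'
#' The full pipeline: (0) an SSE curve over candidate cluster counts and the
#' elbow rule choose the number of coarse segments k; (1) a k-state spatial
#' GMM-HMM segments the recording ([first_round_segment()]); (2) each
#' segment's velocity trace is classified by a 3-state GMM-HMM
#' ([second_round_classify()]); (3) per-segment labels are concatenated in
#' temporal order into one labelled sequence. Deterministic for a fixed
#' seed.
#'
#' @param seq A `gaze_sequence` of length >= 4.
#' @param cfg A [classifier_config()].
#' @param seed Integer seed governing every stochastic stage.
#' @return A `labeled_sequence` with attributes `k` (elbow-selected cluster
#'   count) and `segments` (the first-round segmentation).
#' @export
classify_gaze <- function(seq, cfg = classifier_config(), seed = 1) {
  seq <- as_gaze_sequence(seq)
  n <- nrow(seq)
  if (n < 4L) stop("classification needs at least 4 samples")
  velocity <- compute_velocity(seq, cfg$smooth_window)
  K_m <- min(cfg$K_m, n)
  curve <- tryCatch(
    sse_curve(seq, K_m = K_m, max_iter = cfg$kmeans_max_iter,
              seed = seed, n_restarts = cfg$n_restarts),
    error = function(e) stop("segmentation stage failed: ",
                             conditionMessage(e)))
  k <- select_k_elbow(curve)
  regimes <- global_velocity_regimes(velocity, cfg, seed + 1000L)
  segs <- tryCatch(
    first_round_segment(seq, k, cfg, seed = seed + 2000L),
    error = function(e) stop("first-round stage failed: ",
                             conditionMessage(e)))
  labels <- character(n)
  for (s in seq_len(nrow(segs))) {
    idx <- segs$start[s]:segs$end[s]
    if (length(idx) < 2L) {
      # too short to classify: inherit the previous sample's label
      labels[idx] <- if (segs$start[s] > 1L) labels[segs$start[s] - 1L]
                     else "fixation"
      next
    }
    lab <- tryCatch(
      second_round_classify(seq, c(segs$start[s], segs$end[s]), cfg,
                            seed = seed + 3000L + s, velocity = velocity,
                            regimes = regimes),
      error = function(e) stop("second-round stage failed on segment ", s,
                               ": ", conditionMessage(e)))
    labels[idx] <- as.character(lab)
  }
  out <- labeled_sequence(seq, labels)
  attr(out, "k") <- k
  attr(out, "segments") <- segs
  out
}
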