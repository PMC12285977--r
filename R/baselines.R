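#' Threshold configuration for the I-VT / I-VDT baselines
#'
#' @param v_saccade Velocity threshold separating saccades, px/s
#'   (default 1000).
#' @param dispersion Dispersion threshold, px (default 40); dispersion of a
#'   window is `(max x - min x) + (max y - min y)`.
#' @param window Duration window in seconds (default 0.110).
#' @return A list of class `threshold_config`.
#' @export
threshold_config <- function(v_saccade = 1000, dispersion = 40,
                             window = 0.110) {
  if (v_saccade <= 0 || dispersion <= 0 || window <= 0)
    stop("all thresholds must be positive")
  structure(list(v_saccade = v_saccade, dispersion = dispersion,
                 window = window), class = "threshold_config")
}

#' Bayesian-decision configuration for the I-BDT baseline
#'
#' @param prior_window Rolling window (seconds) over which class priors are
#'   accumulated (default 1).
#' @param v_saccade Velocity scale separating the saccade likelihood model,
#'   px/s (default 1000).
#' @param pursuit_window Window (seconds) for the drift-ratio pursuit
#'   feature (default 0.110).
#' @return A list of class `bdt_config`.
#' @export
bdt_config <- function(prior_window = 1, v_saccade = 1000,
                       pursuit_window = 0.110) {
  if (prior_window <= 0) stop("prior_window must be positive")
  structure(list(prior_window = prior_window, v_saccade = v_saccade,
                 pursuit_window = pursuit_window), class = "bdt_config")
}

#' I-VT: velocity-threshold identification (binary)
#'
#' Samples with speed strictly above `v_saccade` are saccades; the rest,
#' including exact threshold ties, are fixations.
#'
#' @param seq A `gaze_sequence` with at least 2 samples.
#' @param cfg A [threshold_config()].
#' @return A `labeled_sequence` (labels fixation/saccade only).
#' @export
classify_ivt <- function(seq, cfg = threshold_config()) {
  seq <- as_gaze_sequence(seq)
  v <- compute_velocity(seq)
  labeled_sequence(seq, ifelse(v > cfg$v_saccade, "saccade", "fixation"))
}

#' I-VDT: velocity + dispersion threshold identification (ternary)
#'
#' Stage 1 marks samples with speed above `v_saccade` as saccades. Stage 2
#' slides a duration window over each non-saccade run: while the window's
#' dispersion `(max x - min x) + (max y - min y)` stays at or below the
#' threshold the window expands and its samples become fixations; otherwise
#' the window's first sample is labelled pursuit and the window shifts.
#'
#' @inheritParams classify_ivt
#' @return A ternary `labeled_sequence`.
#' @export
classify_ivdt <- function(seq, cfg = threshold_config()) {
  seq <- as_gaze_sequence(seq)
  v <- compute_velocity(seq)
  n <- nrow(seq)
  labels <- ifelse(v > cfg$v_saccade, "saccade", NA_character_)
  win_n <- max(2L, round(cfg$window / stats::median(diff(seq$t))))
  disp <- function(i, j) {
    (max(seq$x[i:j]) - min(seq$x[i:j])) +
      (max(seq$y[i:j]) - min(seq$y[i:j]))
  }
  runs <- label_runs(is.na(labels))
  for (r in which(runs$value)) {
    a <- runs$start[r]; b <- runs$end[r]
    i <- a
    while (i <= b) {
      j <- min(i + win_n - 1L, b)
      if (j - i + 1L < win_n || disp(i, j) > cfg$dispersion) {
        # cannot open a compliant fixation window here
        labels[i] <- "pursuit"
        i <- i + 1L
        next
      }
      while (j < b && disp(i, j + 1L) <= cfg$dispersion) j <- j + 1L
      labels[i:j] <- "fixation"
      i <- j + 1L
    }
  }
  labeled_sequence(seq, labels)
}

#' I-BDT: Bayesian decision theory identification (ternary)
#'
#' Maintains rolling class priors over `prior_window`, computes per-class
#' likelihoods from velocity and the window-shift-over-time feature (the
#' net displacement of a trailing window divided by its duration, which
#' cancels stationary jitter but tracks sustained pursuit motion), and
#' assigns the maximum-posterior class per sample; ties go to fixation.
#' Deterministic, no random number use.
#'
#' @param seq A `gaze_sequence` with at least 2 samples.
#' @param cfg A [bdt_config()].
#' @return A ternary `labeled_sequence`; attribute `posterior` holds the
#'   per-sample class posterior matrix (rows sum to 1).
#' @export
classify_ibdt <- function(seq, cfg = bdt_config()) {
  seq <- as_gaze_sequence(seq)
  v <- compute_velocity(seq)
  n <- nrow(seq)
  dt <- stats::median(diff(seq$t))
  win_n <- max(2L, round(cfg$pursuit_window / dt))
  prior_n <- max(1L, round(cfg$prior_window / dt))
  # window-shift speed: net displacement of the trailing window over its
  # duration; jitter cancels, sustained motion does not
  w <- numeric(n)
  for (i in seq_len(n)) {
    a <- max(1L, i - win_n + 1L)
    if (i == a) { w[i] <- 0; next }
    net <- sqrt((seq$x[i] - seq$x[a])^2 + (seq$y[i] - seq$y[a])^2)
    w[i] <- net / (seq$t[i] - seq$t[a])
  }
  # fixation-scale shift speed learned from the recording itself
  sigma_f <- max(stats::median(w), 1)
  lev <- event_levels()
  prior <- rep(1 / 3, 3)
  post <- matrix(0, n, 3, dimnames = list(NULL, lev))
  labels <- character(n)
  recent <- integer(0)
  for (i in seq_len(n)) {
    l_fix_w <- exp(-0.5 * (w[i] / (3 * sigma_f))^2)
    l_sac <- 1 - exp(-0.5 * (v[i] / cfg$v_saccade)^2)
    lik <- c(fixation = l_fix_w * (1 - l_sac),
             pursuit = (1 - l_fix_w) * (1 - l_sac),
             saccade = l_sac)
    p <- prior * lik
    if (sum(p) <= 0) p <- c(1, 0, 0)
    post[i, ] <- p / sum(p)
    ci <- which.max(post[i, ])  # ties: first index = fixation
    labels[i] <- lev[ci]
    recent <- c(recent, ci)
    if (length(recent) > prior_n) recent <- recent[-1]
    prior <- (tabulate(recent, 3) + 1) / (length(recent) + 3)
  }
  out <- labeled_sequence(seq, labels)
  attr(out, "posterior") <- post
  out
}
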