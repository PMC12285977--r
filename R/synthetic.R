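#' Generator parameters for synthetic gaze trajectories
#'
#' Defaults emulate a 90 Hz screen-based tracker on a 1920 x 1080 display:
#' fixations are an anchor plus slow linear drift and smooth jitter with
#' marginal SD `noise_sd`; smooth pursuit is linear target motion at
#' `pursuit_speed`; saccades are minimum-jerk jumps of `saccade_amplitude`
#' completed in `saccade_duration`, giving the brief, strongly peaked
#' velocity profile of real saccades.
#'
#' @param noise_sd Marginal SD of gaze jitter in px (default 8).
#' @param noise_smooth Correlation length of the jitter process in seconds
#'   (default 0.35); jitter is white noise filtered by a Gaussian kernel of
#'   this width, emulating slow fixational drift/wander rather than white
#'   sensor noise.
#' @param drift_speed Linear drift speed during fixations, px/s (default 10).
#' @param pursuit_speed Smooth-pursuit target speed, px/s (default 200).
#' @param saccade_amplitude Saccade jump size, px (default 400).
#' @param saccade_duration Saccade duration, s (default 0.044).
#' @param screen Screen bounds in px, `c(width, height)` (default 1920x1080);
#'   trajectories are clipped to the screen.
#' @return A list of class `generator_params`.
#' @export
generator_params <- function(noise_sd = 8, noise_smooth = 0.35,
                             drift_speed = 10, pursuit_speed = 200,
                             saccade_amplitude = 400,
                             saccade_duration = 0.044,
                             screen = c(1920, 1080)) {
  p <- list(noise_sd = noise_sd, noise_smooth = noise_smooth,
            drift_speed = drift_speed, pursuit_speed = pursuit_speed,
            saccade_amplitude = saccade_amplitude,
            saccade_duration = saccade_duration, screen = screen)
  if (any(unlist(p[1:6]) <= 0) || any(screen <= 0))
    stop("all generator parameters must be positive")
  class(p) <- "generator_params"
  p
}

#' Scenario specification
#'
#' An ordered list of behavior episodes. Each episode is a list with fields
#' `behavior` (one of [event_levels()]), `duration` (s), and optional
#' overrides: `direction` (angle, radians), `speed` (px/s, pursuit),
#' `amplitude` (px, saccade), `drift_speed` (px/s, fixation). Directions
#' left `NULL` are drawn at simulation time (kept inside the screen).
#'
#' @param episodes List of episode lists.
#' @param sample_rate Sampling rate in Hz (default 90).
#' @param start Optional starting gaze position `c(x, y)` in px; `NULL`
#'   draws one at simulation time.
#' @return A list of class `scenario_spec`.
#' @export
scenario_spec <- function(episodes, sample_rate = 90, start = NULL) {
  if (!length(episodes)) stop("at least one episode is required")
  for (ep in episodes) {
    if (!ep$behavior %in% event_levels())
      stop("unknown behavior: ", ep$behavior)
    if (is.null(ep$duration) || ep$duration <= 0)
      stop("episode durations must be positive")
  }
  if (sample_rate <= 0) stop("sample_rate must be positive")
  structure(list(episodes = episodes, sample_rate = sample_rate,
                 start = start), class = "scenario_spec")
}

episode <- function(behavior, duration, ...) {
  c(list(behavior = behavior, duration = duration), list(...))
}

# smooth jitter: white noise filtered with a Gaussian kernel, scaled to
# marginal sd `sd` using the theoretical filter gain
smooth_jitter <- function(n, sd, sigma_samples) {
  half <- max(1L, ceiling(3 * sigma_samples))
  w <- exp(-((-half):half)^2 / (2 * sigma_samples^2))
  gain <- sqrt(sum(w^2)) / sum(w)   # sd of (w/sum(w)) * white noise
  e <- stats::rnorm(n + 2 * half)
  sm <- stats::filter(e, w / sum(w), sides = 2)
  as.numeric(sm[(half + 1):(half + n)]) / gain * sd
}

# direction that keeps current + dist * (cos a, sin a) inside the bounds
pick_direction <- function(pos, dist, screen, margin = 80) {
  for (i in 1:100) {
    a <- stats::runif(1, 0, 2 * pi)
    tgt <- pos + dist * c(cos(a), sin(a))
    if (tgt[1] > margin && tgt[1] < screen[1] - margin &&
        tgt[2] > margin && tgt[2] < screen[2] - margin)
      return(a)
  }
  atan2(screen[2] / 2 - pos[2], screen[1] / 2 - pos[1])
}

# minimum-jerk position fraction on [0, 1]
minjerk <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5

#' Simulate a labeled gaze sequence
#'
#' Generates the deterministic episode path (fixation anchor + drift,
#' linear pursuit, minimum-jerk saccades; episodes concatenated
#' continuously), adds smooth gaze jitter, clips to the screen, and attaches
#' the ground-truth per-sample labels. Deterministic for a fixed seed.
#'
#' @param spec A [scenario_spec()].
#' @param params A [generator_params()].
#' @param seed Integer seed.
#' @return A `labeled_sequence`.
#' @export
simulate_gaze <- function(spec, params = generator_params(), seed = 1) {
  set.seed(seed)
  rate <- spec$sample_rate
  ns <- vapply(spec$episodes, function(ep) {
    n <- round(ep$duration * rate)
    if (n < 1L) stop("episode too short for one sample at ", rate, " Hz")
    as.integer(n)
  }, integer(1))
  n_tot <- sum(ns)
  pos <- spec$start
  if (is.null(pos))
    pos <- c(stats::runif(1, 460, params$screen[1] - 460),
             stats::runif(1, 300, params$screen[2] - 300))
  xs <- numeric(n_tot); ys <- numeric(n_tot); labels <- character(n_tot)
  i0 <- 0L
  for (e in seq_along(spec$episodes)) {
    ep <- spec$episodes[[e]]
    n <- ns[e]
    tt <- seq_len(n) / rate
    if (ep$behavior == "fixation") {
      sp <- if (!is.null(ep$drift_speed)) ep$drift_speed else
        params$drift_speed
      a <- if (!is.null(ep$direction)) ep$direction else
        pick_direction(pos, sp * ep$duration, params$screen)
      px <- pos[1] + sp * cos(a) * tt
      py <- pos[2] + sp * sin(a) * tt
    } else if (ep$behavior == "pursuit") {
      sp <- if (!is.null(ep$speed)) ep$speed else params$pursuit_speed
      a <- if (!is.null(ep$direction)) ep$direction else
        pick_direction(pos, sp * ep$duration, params$screen)
      px <- pos[1] + sp * cos(a) * tt
      py <- pos[2] + sp * sin(a) * tt
    } else {  # saccade
      amp <- if (!is.null(ep$amplitude)) ep$amplitude else
        params$saccade_amplitude
      a <- if (!is.null(ep$direction)) ep$direction else
        pick_direction(pos, amp, params$screen)
      tgt <- pos + amp * c(cos(a), sin(a))
      frac <- minjerk(seq_len(n) / n)
      px <- pos[1] + (tgt[1] - pos[1]) * frac
      py <- pos[2] + (tgt[2] - pos[2]) * frac
    }
    idx <- i0 + seq_len(n)
    xs[idx] <- px; ys[idx] <- py
    labels[idx] <- ep$behavior
    pos <- c(px[n], py[n])
    i0 <- i0 + n
  }
  sigma_samples <- params$noise_smooth * rate
  xs <- xs + smooth_jitter(n_tot, params$noise_sd, sigma_samples)
  ys <- ys + smooth_jitter(n_tot, params$noise_sd, sigma_samples)
  xs <- pmin(pmax(xs, 0), params$screen[1])
  ys <- pmin(pmax(ys, 0), params$screen[2])
  t <- (seq_len(n_tot) - 1L) / rate
  labeled_sequence(gaze_sequence(t, xs, ys, sample_rate_hint = rate), labels)
}

#' The 4.5 s worked-example scenario
#'
#' A 4.5 s sequence at 90 Hz: fixation 0-0.5 s, smooth pursuit 0.5-1.5 s,
#' fixation 1.5-2.5 s, a saccade at 2.5 s, fixation to 3.5 s, a second
#' saccade at 3.5 s, and fixation to 4.5 s (405 samples). Optionally an
#' elevated-drift burst at 3.6 s inside the final fixation emulates the
#' slight gaze drift a real recording can show there.
#'
#' @param drift_burst If `TRUE`, the final fixation contains a 0.3 s burst
#'   of elevated drift starting at 3.6 s (ground truth stays fixation).
#' @param sample_rate Sampling rate in Hz (default 90).
#' @return A [scenario_spec()].
#' @export
fig4_scenario <- function(drift_burst = FALSE, sample_rate = 90) {
  sac <- 0.044
  tail_fix <- if (drift_burst) list(
    episode("fixation", 1 - sac - 0.9),
    episode("fixation", 0.3, drift_speed = 60),
    episode("fixation", 0.6)
  ) else list(episode("fixation", 1 - sac))
  eps <- c(list(
    episode("fixation", 0.5),
    episode("pursuit", 1.0),
    episode("fixation", 1.0),
    episode("saccade", sac),
    episode("fixation", 1 - sac),
    episode("saccade", sac)),
    tail_fix)
  scenario_spec(eps, sample_rate = sample_rate)
}

#' Step-target protocol scenario
#'
#' Emulates a 2D step-target protocol: the target jumps (saccade) and is
#' then fixated for 1000 ms, with jump directions cycling through four
#' screen directions, one fixation per target.
#'
#' @param n_targets Number of target presentations (>= 1).
#' @param sample_rate Sampling rate in Hz (default 90).
#' @return A [scenario_spec()].
#' @export
step_target_scenario <- function(n_targets, sample_rate = 90) {
  if (n_targets < 1L) stop("n_targets must be >= 1")
  dirs <- c(0, pi / 2, pi, 3 * pi / 2)
  eps <- list()
  for (i in seq_len(n_targets)) {
    eps <- c(eps, list(episode("saccade", 0.044,
                               direction = dirs[(i - 1L) %% 4L + 1L]),
                       episode("fixation", 1.0)))
  }
  scenario_spec(eps, sample_rate = sample_rate,
                start = c(960, 540))
}

#' Standard synthetic benchmark
#'
#' Generates `n_sequences` independent worked-example-style sequences with
#' randomized start anchors and movement directions, one per seed
#' `seed .. seed + n_sequences - 1`. This is the desk-scale stand-in for a
#' multi-participant recording campaign: fixation samples are the most
#' frequent class and saccade samples the least, mirroring real recordings.
#'
#' @param n_sequences Number of sequences (default 50).
#' @param seed Base seed (default 0).
#' @param params A [generator_params()].
#' @return A list of `labeled_sequence` objects.
#' @export
standard_benchmark <- function(n_sequences = 50, seed = 0,
                               params = generator_params()) {
  if (n_sequences < 1L) stop("n_sequences must be >= 1")
  lapply(seq_len(n_sequences), function(i)
    simulate_gaze(fig4_scenario(), params = params, seed = seed + i - 1L))
}
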