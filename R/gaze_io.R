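#' Event label vocabulary
#'
#' The closed set of ternary eye-movement event labels, in canonical order:
#' fixation (gaze held on a point), smooth pursuit (sustained tracking of a
#' moving target), saccade (rapid ballistic jump).
#'
#' @return Character vector `c("fixation", "pursuit", "saccade")`.
#' @export
event_levels <- function() c("fixation", "pursuit", "saccade")

#' Construct a gaze sequence
#'
#' A gaze sequence is a time-ordered table of gaze samples with timestamps in
#' seconds and screen-pixel coordinates (origin top-left, x rightward,
#' y downward).
#'
#' @param t Numeric vector of timestamps in seconds, strictly increasing.
#' @param x,y Numeric vectors of gaze coordinates in screen pixels.
#' @param sample_rate_hint Nominal sampling rate in Hz (default 90).
#' @return An object of class `gaze_sequence`: a data.frame with columns
#'   `t`, `x`, `y` and attribute `sample_rate_hint`.
#' @export
gaze_sequence <- function(t, x, y, sample_rate_hint = 90) {
  t <- as.numeric(t); x <- as.numeric(x); y <- as.numeric(y)
  n <- length(t)
  if (n < 1L) stop("gaze sequence must contain at least one sample")
  if (length(x) != n || length(y) != n)
    stop("t, x and y must have equal length")
  if (!all(is.finite(t)) || !all(is.finite(x)) || !all(is.finite(y)))
    stop("timestamps and coordinates must be finite")
  if (n > 1L && any(diff(t) <= 0))
    stop("timestamps must be strictly increasing (duplicate or disordered t)")
  out <- data.frame(t = t, x = x, y = y)
  attr(out, "sample_rate_hint") <- sample_rate_hint
  class(out) <- c("gaze_sequence", "data.frame")
  out
}

#' Attach per-sample event labels to a gaze sequence
#'
#' @param seq A [gaze_sequence()].
#' @param labels Character vector or factor of event labels (one per sample),
#'   from the vocabulary of [event_levels()]; matching is case-insensitive.
#' @return An object of class `labeled_sequence` (also a `gaze_sequence`) with
#'   an extra factor column `label`.
#' @export
labeled_sequence <- function(seq, labels) {
  seq <- as_gaze_sequence(seq)
  if (length(labels) == 0L) stop("labels are required")
  if (length(labels) != nrow(seq))
    stop("labels length (", length(labels), ") must equal number of samples (",
         nrow(seq), ")")
  lab <- tolower(trimws(as.character(labels)))
  bad <- setdiff(unique(lab), event_levels())
  if (length(bad))
    stop("unknown event label(s): ", paste(bad, collapse = ", "))
  seq$label <- factor(lab, levels = event_levels())
  class(seq) <- unique(c("labeled_sequence", class(seq)))
  seq
}

#' Coerce to a gaze sequence
#'
#' @param x A `gaze_sequence` or a data.frame with columns `t`, `x`, `y`.
#' @return A `gaze_sequence`.
#' @export
as_gaze_sequence <- function(x) {
  if (inherits(x, "gaze_sequence")) return(x)
  if (is.data.frame(x) && all(c("t", "x", "y") %in% names(x))) {
    hint <- attr(x, "sample_rate_hint")
    return(gaze_sequence(x$t, x$x, x$y,
                         sample_rate_hint = if (is.null(hint)) 90 else hint))
  }
  stop("cannot coerce object to gaze_sequence")
}

#' @export
print.gaze_sequence <- function(x, ...) {
  cat(sprintf("<%s> %d samples, %.3f-%.3f s",
              if (inherits(x, "labeled_sequence")) "labeled_sequence"
              else "gaze_sequence",
              nrow(x), x$t[1], x$t[nrow(x)]))
  if (!is.null(x$label)) {
    tab <- table(x$label)
    cat("  [", paste(sprintf("%s:%d", names(tab), tab), collapse = " "), "]")
  }
  cat("\n")
  invisible(x)
}

#' Read a gaze table from delimited text
#'
#' Reads a UTF-8 delimited text file with a header row and columns holding
#' timestamp (s), x and y (px), and optionally a per-sample event label.
#' A `dialect` mapping allows files with other column names (for example
#' public datasets) to be read without modification.
#'
#' @param path Path to the file.
#' @param dialect Named character vector mapping canonical names (`t`, `x`,
#'   `y`, `label`) to the file's column names. Defaults to identity.
#' @param sep Field separator (default comma).
#' @param sample_rate_hint Nominal sampling rate in Hz.
#' @return A `gaze_sequence`, or a `labeled_sequence` when a label column is
#'   present. Rows are sorted by timestamp; duplicated timestamps are an error.
#' @export
read_gaze_table <- function(path, dialect = NULL, sep = ",",
                            sample_rate_hint = 90) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  cols <- c(t = "t", x = "x", y = "y", label = "label")
  if (!is.null(dialect)) cols[names(dialect)] <- dialect
  for (canon in c("t", "x", "y")) {
    if (!cols[[canon]] %in% names(df))
      stop("missing required column '", cols[[canon]], "' (", canon,
           ") in ", path)
  }
  ord <- order(df[[cols[["t"]]]])
  df <- df[ord, , drop = FALSE]
  tt <- df[[cols[["t"]]]]
  if (anyDuplicated(tt))
    stop("duplicated timestamps in ", path)
  seq <- gaze_sequence(tt, df[[cols[["x"]]]], df[[cols[["y"]]]],
                       sample_rate_hint = sample_rate_hint)
  if (cols[["label"]] %in% names(df))
    seq <- labeled_sequence(seq, df[[cols[["label"]]]])
  seq
}

#' Write a labeled gaze sequence to delimited text
#'
#' Writes columns `t,x,y,label`; the written file round-trips through
#' [read_gaze_table()] with timestamps, coordinates and labels preserved.
#'
#' @param seq A `labeled_sequence`.
#' @param path Output file path.
#' @param sep Field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_labeled_table <- function(seq, path, sep = ",") {
  if (!inherits(seq, "labeled_sequence") || is.null(seq$label))
    stop("a labeled sequence (with labels) is required")
  df <- data.frame(t = format(seq$t, digits = 17, trim = TRUE),
                   x = format(seq$x, digits = 17, trim = TRUE),
                   y = format(seq$y, digits = 17, trim = TRUE),
                   label = as.character(seq$label))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-sample gaze speed
#'
#' Backward finite-difference speed in px/s:
#' `v[i] = ||(x,y)[i] - (x,y)[i-1]|| / (t[i] - t[i-1])` for `i >= 2`, with
#' `v[1] = v[2]` so the trace aligns 1:1 with the samples. Optionally a
#' centered moving-average smoother can be applied (off by default; smoothing
#' changes downstream classification and is opt-in).
#'
#' @param seq A `gaze_sequence` with at least 2 samples.
#' @param smooth_window Odd integer width of a centered moving-average
#'   smoother in samples; `0` or `1` disables smoothing (default).
#' @return Numeric vector of speeds (px/s), same length as the sequence.
#' @export
compute_velocity <- function(seq, smooth_window = 0) {
  seq <- as_gaze_sequence(seq)
  n <- nrow(seq)
  if (n < 2L) stop("at least 2 samples are required to compute velocity")
  dt <- diff(seq$t)
  disp <- sqrt(diff(seq$x)^2 + diff(seq$y)^2)
  v <- c(NA_real_, disp / dt)
  v[1] <- v[2]
  if (smooth_window > 1L) {
    w <- as.integer(smooth_window)
    if (w %% 2L == 0L) stop("smooth_window must be odd")
    k <- rep(1 / w, w)
    pad <- (w - 1L) %/% 2L
    vp <- c(rep(v[1], pad), v, rep(v[n], pad))
    v <- as.numeric(stats::filter(vp, k, sides = 2))[(pad + 1L):(pad + n)]
  }
  v
}

# internal: contiguous runs of equal values; returns data.frame(start, end, value)
label_runs <- function(values) {
  n <- length(values)
  if (n == 0L) return(data.frame(start = integer(), end = integer(),
                                 value = values))
  chg <- c(TRUE, values[-1] != values[-n])
  start <- which(chg)
  end <- c(start[-1] - 1L, n)
  data.frame(start = start, end = end, value = values[start])
}
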