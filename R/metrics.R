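#' Confusion matrix of two labelled sequences
#'
#' @param truth,pred `labeled_sequence` objects of equal length over the
#'   same timestamps (or plain label vectors/factors of equal length).
#' @return A 3x3 table of class `confusion_matrix`: rows = true class,
#'   columns = predicted class, in [event_levels()] order.
#' @export
confusion <- function(truth, pred) {
  tl <- extract_labels(truth)
  pl <- extract_labels(pred)
  if (length(tl) != length(pl))
    stop("truth and prediction have different lengths")
  if (inherits(truth, "gaze_sequence") && inherits(pred, "gaze_sequence") &&
      !isTRUE(all.equal(truth$t, pred$t)))
    stop("truth and prediction timestamps do not align")
  cm <- table(truth = factor(tl, levels = event_levels()),
              pred = factor(pl, levels = event_levels()))
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

extract_labels <- function(x) {
  if (inherits(x, "labeled_sequence")) return(as.character(x$label))
  if (is.data.frame(x) && !is.null(x$label)) return(as.character(x$label))
  as.character(x)
}

#' Per-class and aggregate classification metrics
#'
#' Derives one-vs-rest TP/FP/TN/FN per class and reports accuracy
#' `(TP+TN)/(TP+FP+TN+FN)`, recall `TP/(TP+FN)`, precision `TP/(TP+FP)`
#' and `F1 = 2 PR/(P+R)` per class, plus overall sample accuracy
#' (diagonal/total) and unweighted macro averages. Undefined ratios
#' (zero denominators) are reported as 0.
#'
#' @param cm A [confusion()] matrix.
#' @param drop_absent Exclude classes absent from both truth and prediction
#'   from the macro averages (default `FALSE`).
#' @return A list of class `metrics_report` with elements `per_class`
#'   (data.frame: class, accuracy, precision, recall, f1), `accuracy`
#'   (overall sample accuracy), `macro_precision`, `macro_recall`,
#'   `macro_f1`, `macro_accuracy`.
#' @export
report <- function(cm, drop_absent = FALSE) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  lev <- rownames(cm)
  per <- lapply(seq_along(lev), function(i) {
    tp <- cm[i, i]
    fp <- sum(cm[-i, i])
    fn <- sum(cm[i, -i])
    tn <- total - tp - fp - fn
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    data.frame(class = lev[i], accuracy = (tp + tn) / total,
               precision = prec, recall = rec, f1 = f1,
               present = (tp + fn + fp) > 0)
  })
  per <- do.call(rbind, per)
  keep <- if (drop_absent) per$present else rep(TRUE, nrow(per))
  out <- list(per_class = per[, setdiff(names(per), "present")],
              accuracy = sum(diag(cm)) / total,
              macro_precision = mean(per$precision[keep]),
              macro_recall = mean(per$recall[keep]),
              macro_f1 = mean(per$f1[keep]),
              macro_accuracy = mean(per$accuracy[keep]))
  class(out) <- "metrics_report"
  out
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Overall sample accuracy:", sprintf("%.4f", x$accuracy), "\n")
  df <- x$per_class
  df[, -1] <- round(df[, -1], 4)
  print(df, row.names = FALSE)
  cat(sprintf("macro: precision %.4f  recall %.4f  F1 %.4f\n",
              x$macro_precision, x$macro_recall, x$macro_f1))
  invisible(x)
}

#' Write a metrics report as delimited text
#'
#' One row per class (precision, recall, F1, one-vs-rest accuracy) plus a
#' macro row and the overall sample accuracy, mirroring a comparison-table
#' layout.
#'
#' @param x A [report()] result.
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_metrics_report <- function(x, path, sep = ",") {
  df <- x$per_class
  df <- rbind(df, data.frame(class = "macro", accuracy = x$macro_accuracy,
                             precision = x$macro_precision,
                             recall = x$macro_recall, f1 = x$macro_f1))
  df$overall_accuracy <- x$accuracy
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Benchmark several classifiers on synthetic sequences
#'
#' Runs the hierarchical GMM-HMM classifier and the requested baselines on a
#' list of labelled sequences and summarises per-sequence metrics
#' (mean and SD of overall accuracy and macro precision/recall/F1).
#'
#' @param sequences List of ground-truth `labeled_sequence` objects (for
#'   example from [standard_benchmark()]).
#' @param methods Character vector from `c("gmmhmm", "ivt", "ivdt", "ibdt")`.
#' @param cfg [classifier_config()] for the GMM-HMM method.
#' @param seed Base seed; sequence i is classified with `seed + i - 1`.
#' @return A list with `summary` (data.frame of mean/SD per method) and
#'   `per_sequence` (data.frame of per-sequence metrics).
#' @export
run_benchmark <- function(sequences,
                          methods = c("gmmhmm", "ivt", "ivdt", "ibdt"),
                          cfg = classifier_config(), seed = 0) {
  methods <- match.arg(methods, several.ok = TRUE)
  rows <- list()
  for (m in methods) {
    for (i in seq_along(sequences)) {
      truth <- sequences[[i]]
      pred <- switch(m,
        gmmhmm = classify_gaze(truth, cfg, seed = seed + i - 1L),
        ivt = classify_ivt(truth),
        ivdt = classify_ivdt(truth),
        ibdt = classify_ibdt(truth))
      rep_i <- report(confusion(truth, pred))
      rows[[length(rows) + 1L]] <- data.frame(
        method = m, sequence = i, accuracy = rep_i$accuracy,
        macro_precision = rep_i$macro_precision,
        macro_recall = rep_i$macro_recall, macro_f1 = rep_i$macro_f1)
    }
  }
  per_seq <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(per_seq, per_seq$method), function(d)
    data.frame(method = d$method[1],
               accuracy_mean = mean(d$accuracy),
               accuracy_sd = stats::sd(d$accuracy),
               macro_f1_mean = mean(d$macro_f1),
               macro_f1_sd = stats::sd(d$macro_f1))))
  agg <- agg[match(methods, agg$method), ]
  rownames(agg) <- NULL
  list(summary = agg, per_sequence = per_seq)
}
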