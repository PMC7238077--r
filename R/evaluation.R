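# Binary PHI-vs-non-PHI token scoring: a predicted PHI token is a true
# positive iff the gold label is any PHI class; the specific class is
# deliberately ignored.

#' Binary PHI token scores
#'
#' Scores token predictions on the PHI-vs-non-PHI decision only: a token
#' counts as a true positive when both the predicted and the gold label are
#' PHI labels (of any class), as a false positive when only the prediction is
#' PHI, and as a false negative when only the gold label is.
#'
#' When no gold PHI exists and none is predicted (tp = fp = fn = 0) the
#' metrics are defined as 1 (vacuously perfect), so PHI-free fragments do not
#' poison averages; corpus-level scoring is unaffected.
#'
#' @param pred_labels,gold_labels character vectors of equal length with
#'   labels from the scheme.
#' @param scheme a label scheme from [build_label_scheme()].
#' @return object of class `phi_metrics`: list with `tp`, `fp`, `fn`, `tn`,
#'   `precision`, `recall`, `f1`.
#' @export
binary_phi_scores <- function(pred_labels, gold_labels,
                              scheme = build_label_scheme()) {
  if (length(pred_labels) != length(gold_labels))
    stop_phideid("prediction/gold length mismatch (%d vs %d)",
                 length(pred_labels), length(gold_labels))
  pred_phi <- is_phi_label(scheme, pred_labels)
  gold_phi <- is_phi_label(scheme, gold_labels)
  phi_metrics_from_counts(tp = sum(pred_phi & gold_phi),
                          fp = sum(pred_phi & !gold_phi),
                          fn = sum(!pred_phi & gold_phi),
                          tn = sum(!pred_phi & !gold_phi))
}

phi_metrics_from_counts <- function(tp, fp, fn, tn) {
  precision <- if (tp + fp > 0) tp / (tp + fp) else if (fn == 0) 1 else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else if (fp == 0) 1 else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn),
                 precision = precision, recall = recall, f1 = f1),
            class = "phi_metrics")
}

#' @export
print.phi_metrics <- function(x, ...) {
  cat(sprintf(paste0("<phi_metrics: tp %d fp %d fn %d tn %d | ",
                     "P %.4f R %.4f F1 %.4f>\n"),
              x$tp, x$fp, x$fn, x$tn, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Evaluate a tagger on a document set
#'
#' Predicts labels for every document and micro-averages the binary PHI
#' counts over the concatenated token stream.
#'
#' @param params a `parameter_vector`.
#' @param docs list of labeled documents (the test set).
#' @param table an [embedding_table()].
#' @param scheme label scheme.
#' @return a `phi_metrics`.
#' @export
evaluate_tagger <- function(params, docs, table,
                            scheme = build_label_scheme()) {
  tp <- fp <- fn <- tn <- 0L
  for (d in docs) {
    pred <- predict_labels(d, params, table, scheme = scheme)
    pp <- is_phi_label(scheme, pred)
    gp <- is_phi_label(scheme, d$labels)
    tp <- tp + sum(pp & gp); fp <- fp + sum(pp & !gp)
    fn <- fn + sum(!pp & gp); tn <- tn + sum(!pp & !gp)
  }
  phi_metrics_from_counts(tp, fp, fn, tn)
}

#' Aggregate learning curves from a run log
#'
#' For every (strategy, epoch) cell, computes the mean, minimum and maximum
#' F1 over workers — the mean-line-plus-range summary used for multi-worker
#' strategies. Single-worker strategies pass through (mean = min = max).
#' Record order in the log is irrelevant.
#'
#' @param run_log data.frame with columns `strategy`, `worker`, `epoch`,
#'   `precision`, `recall`, `f1` (see [write_run_log()]).
#' @return data.frame with columns `strategy`, `epoch`, `mean_f1`, `min_f1`,
#'   `max_f1`, ordered by strategy then epoch.
#' @export
aggregate_curves <- function(run_log) {
  req <- c("strategy", "worker", "epoch", "f1")
  if (!is.data.frame(run_log) || !all(req %in% names(run_log)))
    stop_phideid("run_log must have columns %s", paste(req, collapse = ", "))
  if (nrow(run_log) == 0L) stop_phideid("empty run log")
  agg <- stats::aggregate(run_log$f1,
                   by = list(strategy = run_log$strategy,
                             epoch = run_log$epoch),
                   FUN = function(v) c(mean(v), min(v), max(v)))
  out <- data.frame(strategy = agg$strategy, epoch = agg$epoch,
                    mean_f1 = agg$x[, 1], min_f1 = agg$x[, 2],
                    max_f1 = agg$x[, 3], stringsAsFactors = FALSE)
  out[order(out$strategy, out$epoch), , drop = FALSE]
}

#' Read / write tab-separated run logs
#'
#' One record per evaluation: strategy, worker, epoch, precision, recall, f1.
#'
#' @param run_log data.frame of evaluation records.
#' @param path file path.
#' @return `write_run_log`: `path` invisibly; `read_run_log`: the data.frame.
#' @export
write_run_log <- function(run_log, path) {
  utils::write.table(run_log, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_run_log
#' @export
read_run_log <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
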