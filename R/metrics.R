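#' Confusion counts from query results
#'
#' @param results data.frame with integer columns `true` and `pred` in
#'   \{0, 1\} (as produced by [evaluate_episode()]).
#' @return Named integer vector `(tp, fp, tn, fn)`; positives are label 1.
#' @export
confusion <- function(results) {
  stopifnot(all(c("true", "pred") %in% names(results)))
  t <- results$true
  p <- results$pred
  c(tp = sum(t == 1L & p == 1L), fp = sum(t == 0L & p == 1L),
    tn = sum(t == 0L & p == 0L), fn = sum(t == 1L & p == 0L))
}

#' ROC-AUC by the exact Mann-Whitney statistic
#'
#' The area under the ROC curve equals the probability that a random
#' positive outscores a random negative, ties counted half:
#' `AUC = (#\{score_pos > score_neg\} + 0.5 * #ties) / (n_pos * n_neg)`.
#' Computed exactly from midranks (no threshold interpolation), so it is
#' invariant under any strictly monotone transform of the scores.
#'
#' @param scores Numeric scores, higher = more positive-class.
#' @param labels Binary labels in \{0, 1\}.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) {
    input_error("scores and labels differ in length")
  }
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    metric_error("ROC-AUC is undefined when only one class is present")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Summarize query results into a metrics report
#'
#' @param results data.frame with `true`, `pred` and `score` columns.
#' @return An object of class `metrics_report`: list with `n`, `tp`, `fp`,
#'   `tn`, `fn`, `acc`, `sen`, `spe`, `auc` and `schema_version`. `sen`
#'   (`spe`) is `NULL` — not 0 — when there are no positives (negatives)
#'   among the true labels, and serializes to JSON `null`.
#' @export
summarize_results <- function(results) {
  cm <- confusion(results)
  n <- sum(cm)
  sen <- if (cm[["tp"]] + cm[["fn"]] > 0) {
    cm[["tp"]] / (cm[["tp"]] + cm[["fn"]])
  }
  spe <- if (cm[["tn"]] + cm[["fp"]] > 0) {
    cm[["tn"]] / (cm[["tn"]] + cm[["fp"]])
  }
  structure(list(
    n = n, tp = cm[["tp"]], fp = cm[["fp"]], tn = cm[["tn"]],
    fn = cm[["fn"]], acc = (cm[["tp"]] + cm[["tn"]]) / n,
    sen = sen, spe = spe,
    auc = roc_auc(results$score, results$true),
    schema_version = 1L), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  fmt <- function(v) if (is.null(v)) "NA" else sprintf("%.3f", v)
  cat(sprintf(
    "<metrics: n=%d acc=%s sen=%s spe=%s auc=%s (tp %d, fp %d, tn %d, fn %d)>\n",
    x$n, fmt(x$acc), fmt(x$sen), fmt(x$spe), fmt(x$auc),
    x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Write a metrics report as JSON
#'
#' @param x A `metrics_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(x, path) {
  stopifnot(inherits(x, "metrics_report"))
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
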