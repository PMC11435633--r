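# Classification metrics: confusion matrix, the five summary indices
# (accuracy, macro sensitivity/precision/specificity, Cohen's kappa) and
# per-class one-vs-rest ROC curves.

#' Compute a metrics report from truth and scores
#'
#' Predictions are the argmax of each score row. Sensitivity, precision and
#' specificity are macro-averaged over one-vs-rest contrasts; classes absent
#' from `y_true` are excluded from the macro means with a warning. A class
#' never predicted contributes precision 0. Cohen's kappa is
#' `(p_o - p_e) / (1 - p_e)` with the chance agreement `p_e` from the
#' confusion-matrix marginals.
#'
#' @param y_true true labels (factor or character).
#' @param scores `[n x n_classes]` score matrix, rows summing to 1; column
#'   order follows `levels`.
#' @param levels class levels in score-column order (default: factor levels
#'   of `y_true`).
#' @param roc also compute per-class ROC points.
#' @return a `metrics_report`: `confusion` (rows = truth), `accuracy`,
#'   `sensitivity`, `precision`, `specificity`, `kappa`, `per_class`
#'   data.frame, and `roc` (list of FPR/TPR/threshold data.frames).
#' @export
compute_metrics <- function(y_true, scores, levels = NULL, roc = TRUE) {
  if (is.null(levels)) levels <- if (is.factor(y_true)) base::levels(y_true)
                                 else sort(unique(as.character(y_true)))
  y_true <- factor(as.character(y_true), levels = levels)
  scores <- as.matrix(scores)
  stopifnot(length(y_true) == nrow(scores), ncol(scores) == length(levels))
  pred <- factor(levels[max.col(scores)], levels = levels)
  cm <- table(truth = y_true, pred = pred)
  report_from_confusion(cm, levels = levels,
                        roc = if (roc) roc_points(y_true, scores, levels) else NULL)
}

#' Metrics from an existing confusion matrix
#'
#' @param cm square confusion matrix, rows = truth.
#' @param levels optional class names.
#' @param roc optional precomputed ROC list to attach.
#' @return a `metrics_report`.
#' @export
report_from_confusion <- function(cm, levels = NULL, roc = NULL) {
  cm <- as.matrix(cm)
  stopifnot(nrow(cm) == ncol(cm))
  levels <- levels %||% rownames(cm) %||% as.character(seq_len(nrow(cm)))
  n <- sum(cm)
  acc <- sum(diag(cm)) / n
  per <- lapply(seq_len(nrow(cm)), function(i) {
    TP <- cm[i, i]
    FN <- sum(cm[i, ]) - TP
    FP <- sum(cm[, i]) - TP
    TN <- n - TP - FN - FP
    data.frame(class = levels[i],
               support = TP + FN,
               sensitivity = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
               precision = if (TP + FP > 0) TP / (TP + FP) else 0,
               specificity = if (TN + FP > 0) TN / (TN + FP) else NA_real_)
  })
  per <- do.call(rbind, per)
  present <- per$support > 0
  if (!all(present))
    warning(sprintf("class(es) absent from truth excluded from macro means: %s",
                    paste(per$class[!present], collapse = ", ")))
  p_row <- rowSums(cm) / n
  p_col <- colSums(cm) / n
  p_e <- sum(p_row * p_col)
  kappa <- if (p_e < 1) (acc - p_e) / (1 - p_e) else 0
  structure(list(confusion = cm,
                 accuracy = acc,
                 sensitivity = mean(per$sensitivity[present]),
                 precision = mean(per$precision[present]),
                 specificity = mean(per$specificity[present]),
                 kappa = kappa,
                 per_class = per,
                 roc = roc),
            class = "metrics_report")
}

# one-vs-rest ROC by threshold sweep over each class's score column
roc_points <- function(y_true, scores, levels) {
  out <- list()
  for (i in seq_along(levels)) {
    s <- scores[, i]
    pos <- y_true == levels[i]
    np <- sum(pos); nn <- sum(!pos)
    if (np == 0 || nn == 0) { out[[levels[i]]] <- NULL; next }
    thr <- c(Inf, sort(unique(s), decreasing = TRUE))
    tpr <- vapply(thr, function(t) sum(s >= t & pos) / np, numeric(1))
    fpr <- vapply(thr, function(t) sum(s >= t & !pos) / nn, numeric(1))
    out[[levels[i]]] <- data.frame(threshold = thr, fpr = fpr, tpr = tpr)
  }
  out
}

#' Area under a ROC curve by trapezoid rule
#' @param roc_df data.frame with `fpr`, `tpr` (as from [compute_metrics()]).
#' @return scalar AUC.
#' @export
roc_auc <- function(roc_df) {
  o <- order(roc_df$fpr, roc_df$tpr)
  f <- roc_df$fpr[o]; t <- roc_df$tpr[o]
  sum(diff(f) * (utils::head(t, -1) + utils::tail(t, -1)) / 2)
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  print(x$confusion)
  cat(sprintf("  accuracy %.4f  sensitivity %.4f  precision %.4f  specificity %.4f  kappa %.4f\n",
              x$accuracy, x$sensitivity, x$precision, x$specificity, x$kappa))
  invisible(x)
}

#' Write a metrics report as JSON (+ optional CSV confusion matrix)
#' @param report a `metrics_report`; @param path JSON output path.
#' @export
write_metrics_json <- function(report, path) {
  jsonlite::write_json(list(confusion = unclass(as.matrix(report$confusion)),
                            accuracy = report$accuracy,
                            sensitivity = report$sensitivity,
                            precision = report$precision,
                            specificity = report$specificity,
                            kappa = report$kappa),
                       path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}
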