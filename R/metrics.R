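#' Yield bins
#'
#' The four-level discretization of reaction yield used for the confusion
#' analysis: no reaction (<= 1%), poor (>1-11%), medium (>11-35%), high
#' (>35%). Boundary values 1, 11 and 35 fall in the lower bin.
#'
#' @param y_pct numeric vector of yields in percent, each in \[0, 100\].
#' @return factor with levels `no_reaction`, `poor`, `medium`, `high`.
#' @export
yield_bin <- function(y_pct) {
  y <- as.numeric(y_pct)
  if (any(is.na(y)) || any(y < 0 | y > 100)) {
    stop("yields must lie in [0, 100]", call. = FALSE)
  }
  cut(y, breaks = c(-Inf, 1, 11, 35, Inf),
      labels = c("no_reaction", "poor", "medium", "high"), right = TRUE)
}

#' F-score from confusion counts
#'
#' `F1 = 2 tp / (2 tp + fp + fn)`, the harmonic mean of precision and
#' recall.
#'
#' @param tp,fp,fn true positives, false positives, false negatives.
#' @return F1 in \[0, 1\]; `NaN` when all three counts are zero.
#' @export
f_score <- function(tp, fp, fn) 2 * tp / (2 * tp + fp + fn)

#' Evaluate predictions against observed outcomes
#'
#' For the yield task, predictions and truths are on the percent scale:
#' reports MAE (%), the Pearson correlation (reported as `NA` when either
#' vector has zero variance, never as 0), the 4x4 yield-bin confusion
#' matrix and the bin accuracy. For the binary task, propensities are
#' thresholded at 0.5: reports tp/fp/fn/tn, absolute accuracy and F-score.
#' Accuracies and the F-score are percentages.
#'
#' @param preds numeric predictions (percent yields, or propensities in
#'   \[0, 1\] for the binary task).
#' @param truths observed values (percent yields, or 0/1 labels).
#' @param task `"yield"` or `"binary"`.
#' @param threshold classification threshold on the propensity.
#' @return object of class `eval_report`.
#' @export
evaluate_predictions <- function(preds, truths, task = c("yield", "binary"),
                                 threshold = 0.5) {
  task <- match.arg(task)
  stopifnot(length(preds) == length(truths), length(preds) >= 2)
  out <- list(task = task, n = length(preds))
  if (task == "yield") {
    out$mae_pct <- mean(abs(preds - truths))
    out$pearson_r <- if (stats::sd(preds) < 1e-12 ||
                         stats::sd(truths) < 1e-12) {
      warning("zero variance: Pearson r undefined, reported as NA",
              call. = FALSE)
      NA_real_
    } else stats::cor(preds, truths)
    pb <- yield_bin(preds)
    tb <- yield_bin(truths)
    out$bin_confusion <- table(truth = tb, prediction = pb)
    out$bin_accuracy_pct <- 100 * sum(diag(out$bin_confusion)) / out$n
  } else {
    lab <- as.integer(preds >= threshold)
    y <- as.integer(truths)
    out$tp <- sum(lab == 1 & y == 1)
    out$fp <- sum(lab == 1 & y == 0)
    out$fn <- sum(lab == 0 & y == 1)
    out$tn <- sum(lab == 0 & y == 0)
    out$binary_accuracy_pct <- 100 * (out$tp + out$tn) / out$n
    out$f_score_pct <- 100 * f_score(out$tp, out$fp, out$fn)
  }
  structure(out, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  if (x$task == "yield") {
    cat(sprintf("yield: n=%d  MAE=%.2f%%  r=%.3f  bin accuracy=%.1f%%\n",
                x$n, x$mae_pct, x$pearson_r, x$bin_accuracy_pct))
    print(x$bin_confusion)
  } else {
    cat(sprintf(
      "binary: n=%d  accuracy=%.1f%%  F1=%.1f%%  (tp=%d fp=%d fn=%d tn=%d)\n",
      x$n, x$binary_accuracy_pct, x$f_score_pct, x$tp, x$fp, x$fn, x$tn))
  }
  invisible(x)
}

#' Evaluate a trained model on held-out records
#'
#' @param model a `gtnn_model`.
#' @param records held-out reaction records.
#' @param graphs optional featurization cache.
#' @return an `eval_report` for the model's task.
#' @export
evaluate_model <- function(model, records, graphs = NULL) {
  preds <- gtnn_forward(model, records, graphs)
  if (model$config$task == "yield") {
    truths <- vapply(records, `[[`, numeric(1), "combined_yield_pct")
    evaluate_predictions(100 * preds, truths, task = "yield")
  } else {
    truths <- vapply(records, `[[`, integer(1), "outcome")
    evaluate_predictions(preds, truths, task = "binary")
  }
}
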