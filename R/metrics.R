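# Evaluation: the six metrics (accuracy, AP, sensitivity, specificity, F1,
# AUC) with malignant as the positive class, plus the ROC curve. AUC uses the
# Mann-Whitney rank formulation (ties count 1/2); AP is the step-interpolated
# area under the precision-recall curve.

#' Six-metric evaluation of malignancy scores
#'
#' Thresholded metrics (accuracy, sensitivity, specificity, F1) use the given
#' decision threshold on the malignant probability; ranking metrics (AUC, AP)
#' use the scores directly. With a single class present, AUC and AP are
#' undefined and returned as `NA` with `auc_defined = FALSE`.
#'
#' @param scores Malignant-class probabilities in `[0, 1]`.
#' @param labels True labels: 0/1 or `"benign"`/`"malignant"` (malignant = 1,
#'   the positive class).
#' @param threshold Decision threshold (default 0.5; a score at the threshold
#'   predicts malignant).
#' @return A `usv_metrics` list: the six metrics, confusion counts
#'   (`tp`, `fn`, `tn`, `fp`), `threshold`, `auc_defined`.
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5) {
  y <- label_to_int(labels)
  if (length(scores) != length(y) || length(y) < 1) {
    stop("compute_metrics: scores and labels must have equal length >= 1")
  }
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & y == 1)
  fn <- sum(pred == 0 & y == 1)
  tn <- sum(pred == 0 & y == 0)
  fp <- sum(pred == 1 & y == 0)
  acc <- (tp + tn) / length(y)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(sens) && (prec + sens) > 0) {
    2 * prec * sens / (prec + sens)
  } else NA_real_
  both <- length(unique(y)) == 2
  auc <- if (both) auc_mann_whitney(scores, y) else NA_real_
  ap <- if (both) average_precision(scores, y) else NA_real_
  structure(list(accuracy = acc, average_precision = ap, sensitivity = sens,
                 specificity = spec, f1 = f1, auc = auc,
                 tp = tp, fn = fn, tn = tn, fp = fp,
                 threshold = threshold, auc_defined = both),
            class = "usv_metrics")
}

# AUC as the normalized Mann-Whitney U statistic; ties contribute 1/2.
auc_mann_whitney <- function(scores, y) {
  r <- rank(scores)  # midranks handle ties
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Area under the precision-recall curve with step interpolation:
# sum over positives, in descending-score order, of precision * delta-recall.
average_precision <- function(scores, y) {
  o <- order(scores, decreasing = TRUE)
  ys <- y[o]
  ss <- scores[o]
  tp <- cumsum(ys)
  prec <- tp / seq_along(ys)
  rec <- tp / sum(ys)
  # with tied scores, only the last point of each tie group is attainable
  keep <- c(ss[-length(ss)] != ss[-1], TRUE)
  drec <- diff(c(0, rec[keep]))
  sum(prec[keep] * drec)
}

#' ROC curve points
#'
#' Sweeps the decision threshold over the distinct scores and returns the
#' (FPR, TPR) staircase from (0, 0) to (1, 1). Its trapezoidal area equals
#' the Mann-Whitney AUC (ties appear as diagonal segments).
#'
#' @inheritParams compute_metrics
#' @return A `usv_roc` tibble: `threshold`, `fpr`, `tpr`.
#' @export
roc_curve <- function(scores, labels) {
  y <- label_to_int(labels)
  if (length(unique(y)) < 2) {
    stop("roc_curve: both classes must be present")
  }
  o <- order(scores, decreasing = TRUE)
  ys <- y[o]
  ss <- scores[o]
  keep <- c(ss[-length(ss)] != ss[-1], TRUE)
  tpr <- cumsum(ys)[keep] / sum(y)
  fpr <- cumsum(1 - ys)[keep] / sum(1 - y)
  out <- tibble::tibble(threshold = c(Inf, ss[keep]),
                        fpr = c(0, fpr), tpr = c(0, tpr))
  class(out) <- c("usv_roc", class(out))
  out
}

# Trapezoidal area under a usv_roc.
roc_auc_trapezoid <- function(roc) {
  sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
}

#' @export
print.usv_metrics <- function(x, ...) {
  cat(sprintf(paste0("accuracy %.4f | AP %s | sensitivity %.4f | ",
                     "specificity %.4f | F1 %.4f | AUC %s\n"),
              x$accuracy,
              ifelse(x$auc_defined, sprintf("%.4f", x$average_precision), "NA"),
              x$sensitivity, x$specificity, x$f1,
              ifelse(x$auc_defined, sprintf("%.4f", x$auc), "NA")))
  cat(sprintf("confusion @%.2f: TP %d FN %d TN %d FP %d\n", x$threshold,
              x$tp, x$fn, x$tn, x$fp))
  invisible(x)
}

#' @rdname tidy
#' @param x A `usv_metrics` object.
#' @param ... Unused.
#' @method tidy usv_metrics
#' @export
tidy.usv_metrics <- function(x, ...) {
  tibble::tibble(
    metric = c("accuracy", "average_precision", "sensitivity", "specificity",
               "f1", "auc"),
    value = c(x$accuracy, x$average_precision, x$sensitivity, x$specificity,
              x$f1, x$auc)
  )
}

#' Tidy / glance methods
#'
#' `tidy()` on a `usv_metrics` gives a metric/value tibble; on a `usv_model`
#' the per-epoch training history. `glance()` on a `usv_model` gives a
#' one-row summary with the final test metrics.
#'
#' @name tidy
NULL

#' @rdname tidy
#' @method tidy usv_model
#' @export
tidy.usv_model <- function(x, ...) x$history

#' @rdname tidy
#' @method glance usv_model
#' @export
glance.usv_model <- function(x, ...) {
  out <- tibble::tibble(
    epochs = if (is.null(x$history)) NA_integer_ else max(x$history$epoch),
    final_train_loss = if (is.null(x$history)) NA_real_ else
      tail(x$history$train_loss, 1)
  )
  if (!is.null(x$metrics)) {
    out <- dplyr::bind_cols(out, tibble::as_tibble(
      x$metrics[c("accuracy", "average_precision", "sensitivity",
                  "specificity", "f1", "auc")]))
  }
  out
}

#' @rdname autoplot_usvid
#' @method autoplot usv_roc
#' @export
autoplot.usv_roc <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False-positive rate (1 - specificity)",
                  y = "True-positive rate (sensitivity)",
                  title = "ROC curve") +
    ggplot2::theme_minimal()
}

#' Plot methods for usvid result objects
#'
#' `autoplot()` on a `usv_roc` draws the ROC staircase; on a `usv_model` the
#' training-loss history (with test metrics where recorded).
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @name autoplot_usvid
NULL

#' @rdname autoplot_usvid
#' @method autoplot usv_model
#' @export
autoplot.usv_model <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history,
                           dplyr::any_of(c("train_loss", "test_accuracy",
                                           "test_auc")),
                           names_to = "series", values_to = "value")
  h <- h[!is.na(h$value), ]
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::labs(x = "Epoch", y = NULL, title = "Training history") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
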