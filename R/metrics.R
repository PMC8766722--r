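#' Confusion-matrix classification metrics
#'
#' AD (label 1) is the positive class: sensitivity = TP / (TP + FN),
#' specificity = TN / (TN + FP), balanced accuracy = their mean.
#'
#' @param truth Integer 0/1 vector of true labels.
#' @param predicted Integer 0/1 vector of predicted labels, same length.
#' @return Named numeric vector: `accuracy`, `sensitivity`, `specificity`,
#'   `balanced_accuracy`.
#' @export
confusion_metrics <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    nf_stop("label vectors differ in length", class = "neurofuse_input_error")
  }
  truth <- as.integer(truth)
  predicted <- as.integer(predicted)
  tp <- sum(truth == 1L & predicted == 1L)
  fn <- sum(truth == 1L & predicted == 0L)
  tn <- sum(truth == 0L & predicted == 0L)
  fp <- sum(truth == 0L & predicted == 1L)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  c(accuracy = (tp + tn) / length(truth),
    sensitivity = sens, specificity = spec,
    balanced_accuracy = (sens + spec) / 2)
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision threshold over the unique score values (scores tied at
#' a threshold move together), tracing (FPR, TPR) from (0,0) to (1,1). AUC is
#' the trapezoidal integral of the curve, which assigns tied score pairs the
#' conventional 1/2 credit (equals the Mann-Whitney rank statistic
#' U / (n1 * n0)).
#'
#' @param truth Integer 0/1 vector; both classes must be present.
#' @param scores Numeric score vector (higher = more AD-like).
#' @return An object of class `roc_curve`: list with `fpr`, `tpr` (the sweep
#'   points) and `auc`.
#' @export
roc_and_auc <- function(truth, scores) {
  if (length(truth) != length(scores)) {
    nf_stop("labels and scores differ in length", class = "neurofuse_input_error")
  }
  truth <- as.integer(truth)
  n1 <- sum(truth == 1L)
  n0 <- sum(truth == 0L)
  if (n1 == 0 || n0 == 0) {
    nf_stop("both classes must be present to trace a ROC curve",
            class = "neurofuse_input_error")
  }
  ord <- order(-scores)
  s <- scores[ord]
  y <- truth[ord]
  # group subjects with tied scores so they cross the threshold together
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y == 1L)
  fp <- cumsum(y == 0L)
  last <- which(!duplicated(grp, fromLast = TRUE))
  tpr <- c(0, tp[last] / n1)
  fpr <- c(0, fp[last] / n0)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(fpr = fpr, tpr = tpr, auc = auc), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d points, AUC = %.4f\n", length(x$fpr), x$auc))
  invisible(x)
}

#' Vertical averaging of ROC curves on a common FPR grid
#'
#' Each curve is interpolated onto the grid as the step function it is — at
#' grid point f the curve contributes the TPR of its last knot with FPR at
#' most f (upper envelope at vertical segments), with (0,0) and (1,1)
#' anchored — and the TPRs are averaged pointwise.
#'
#' @param curves List of `roc_curve` objects (or lists with `fpr`/`tpr`).
#' @param fpr_grid Ascending FPR grid in [0, 1]; default 101 points at step
#'   0.01.
#' @return List with `fpr` (the grid), `mean_tpr` and `sd_tpr`.
#' @export
mean_roc <- function(curves, fpr_grid = seq(0, 1, by = 0.01)) {
  if (!length(curves)) {
    nf_stop("empty curve list", class = "neurofuse_input_error")
  }
  if (is.unsorted(fpr_grid) || any(fpr_grid < 0 | fpr_grid > 1)) {
    nf_stop("fpr_grid must be ascending within [0, 1]",
            class = "neurofuse_input_error")
  }
  tprs <- vapply(curves, function(cv) {
    fpr <- c(0, cv$fpr, 1)
    tpr <- c(0, cv$tpr, 1)
    # collapse vertical segments to their upper envelope
    up <- tapply(tpr, fpr, max)
    xs <- sort(unique(fpr))
    stats::approx(xs, as.numeric(up), xout = fpr_grid, method = "constant",
                  f = 0, rule = 2, ties = "ordered")$y
  }, numeric(length(fpr_grid)))
  tprs <- matrix(tprs, nrow = length(fpr_grid))
  list(fpr = fpr_grid,
       mean_tpr = rowMeans(tprs),
       sd_tpr = apply(tprs, 1, stats::sd))
}
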