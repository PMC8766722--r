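#' Repeated-holdout evaluation configuration
#'
#' @param n_cycles Number of random split-train-test cycles (default 2000).
#' @param train_fraction Fraction of each class assigned to training
#'   (default 0.8).
#' @param fpr_grid FPR grid for vertical ROC averaging; default 101 points,
#'   0 to 1 in steps of 0.01.
#' @param seed Integer master seed; per-cycle seeds derive from it.
#' @return An object of class `eval_config`.
#' @export
eval_config <- function(n_cycles = 2000, train_fraction = 0.8,
                        fpr_grid = seq(0, 1, by = 0.01), seed = 1) {
  if (!is_count(n_cycles)) {
    nf_stop("n_cycles must be a positive integer", class = "neurofuse_config_error")
  }
  if (!is_number(train_fraction) || train_fraction <= 0 || train_fraction >= 1) {
    nf_stop("train_fraction must lie in (0, 1)", class = "neurofuse_config_error")
  }
  if (is.unsorted(fpr_grid) || any(fpr_grid < 0 | fpr_grid > 1)) {
    nf_stop("fpr_grid must be ascending within [0, 1]",
            class = "neurofuse_config_error")
  }
  structure(list(n_cycles = as.integer(n_cycles),
                 train_fraction = train_fraction,
                 fpr_grid = fpr_grid, seed = as.integer(seed)),
            class = "eval_config")
}

# Class-stratified holdout split: per-class test counts rounded to nearest
# with at least one test subject per class.
stratified_split <- function(label, train_fraction) {
  idx0 <- which(label == 0L)
  idx1 <- which(label == 1L)
  n_te0 <- max(1L, round(length(idx0) * (1 - train_fraction)))
  n_te1 <- max(1L, round(length(idx1) * (1 - train_fraction)))
  if (n_te0 >= length(idx0) || n_te1 >= length(idx1)) {
    nf_stop("infeasible split: a class would have no training subjects",
            class = "neurofuse_input_error")
  }
  test <- c(sample(idx0, n_te0), sample(idx1, n_te1))
  list(train = setdiff(seq_along(label), test), test = sort(test))
}

#' Repeated stratified-holdout evaluation of a single-modality classifier
#'
#' At each cycle the subjects are shuffled into a class-stratified
#' train/test split, a fresh SVM (including standardization, refit each
#' cycle on the training portion only) is trained on the training subjects
#' restricted to the selected features, and the test subjects are scored.
#' Accuracy, sensitivity, specificity, balanced accuracy, the ROC curve and
#' its AUC are stored per cycle; the aggregate reports their means and
#' standard deviations and the vertically averaged mean ROC curve.
#'
#' @param table A [feature_table()].
#' @param selected Feature names entering the classifier (default: all).
#' @param svm An [svm_config()].
#' @param config An [eval_config()].
#' @return An object of class `holdout_eval`: list with `cycles` (data frame
#'   of per-cycle metrics), `mean`, `sd` (named metric vectors), `mean_roc`
#'   (list fpr / mean_tpr / sd_tpr) and the configs.
#' @export
#' @examples
#' cfg <- cohort_config(10, list(
#'   modality_spec("pet", 5, n_informative = 2, effect_size = 2)
#' ), seed = 5)
#' tab <- generate_multimodal_cohort(cfg)$tables$pet
#' ev <- repeated_holdout_evaluation(tab, config = eval_config(n_cycles = 50))
#' ev
repeated_holdout_evaluation <- function(table, selected = NULL,
                                        svm = svm_config(),
                                        config = eval_config()) {
  stopifnot(inherits(table, "feature_table"), inherits(config, "eval_config"))
  if (is.null(selected)) selected <- colnames(table$x)
  tab <- subset_table(table, features = selected)
  scalars <- c("accuracy", "sensitivity", "specificity",
               "balanced_accuracy", "auc")
  cycles <- matrix(NA_real_, config$n_cycles, length(scalars),
                   dimnames = list(NULL, scalars))
  curves <- vector("list", config$n_cycles)

  for (i in seq_len(config$n_cycles)) {
    with_seed(derive_seed(config$seed, i), {
      sp <- stratified_split(tab$label, config$train_fraction)
      train <- subset_table(tab, subjects = sp$train)
      test <- subset_table(tab, subjects = sp$test)
      model <- train_modality_model(train, config = svm)
      prob <- predict(model, test, type = "prob")
      cm <- confusion_metrics(test$label, as.integer(prob >= 0.5))
      roc <- roc_and_auc(test$label, prob)
      cycles[i, ] <- c(cm, roc$auc)
      curves[[i]] <- roc
    })
  }
  mroc <- mean_roc(curves, config$fpr_grid)
  structure(
    list(cycles = as.data.frame(cycles),
         mean = colMeans(cycles), sd = apply(cycles, 2, stats::sd),
         mean_roc = mroc, selected = selected, modality = tab$modality,
         svm = svm, config = config),
    class = "holdout_eval"
  )
}

#' @export
print.holdout_eval <- function(x, ...) {
  cat(sprintf("<holdout_eval> '%s': %d cycles, %d features\n",
              x$modality, nrow(x$cycles), length(x$selected)))
  m <- x$mean; s <- x$sd
  for (k in names(m)) {
    cat(sprintf("  %-18s %.3f +/- %.3f\n", k, m[k], s[k]))
  }
  invisible(x)
}

#' @export
summary.holdout_eval <- function(object, ...) print(object, ...)

#' Write evaluation metrics and the mean ROC curve to disk
#'
#' Per-cycle metrics go to `<prefix>_cycles.csv`, the aggregate to
#' `<prefix>_metrics.json`, and the mean ROC to `<prefix>_roc.csv`
#' (columns fpr, mean_tpr, sd_tpr).
#'
#' @param eval A `holdout_eval`.
#' @param prefix Output path prefix.
#' @return Character vector of written paths, invisibly.
#' @export
write_holdout_eval <- function(eval, prefix) {
  stopifnot(inherits(eval, "holdout_eval"))
  p_cyc <- paste0(prefix, "_cycles.csv")
  p_met <- paste0(prefix, "_metrics.json")
  p_roc <- paste0(prefix, "_roc.csv")
  utils::write.csv(eval$cycles, p_cyc, row.names = FALSE)
  jsonlite::write_json(
    list(modality = eval$modality, n_cycles = nrow(eval$cycles),
         selected = eval$selected,
         mean = as.list(eval$mean), sd = as.list(eval$sd)),
    p_met, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(
    data.frame(fpr = eval$mean_roc$fpr, mean_tpr = eval$mean_roc$mean_tpr,
               sd_tpr = eval$mean_roc$sd_tpr),
    p_roc, row.names = FALSE)
  invisible(c(p_cyc, p_met, p_roc))
}
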