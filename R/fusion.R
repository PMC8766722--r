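#' Convex ensemble weights over modality classifiers
#'
#' Late fusion combines per-modality AD probabilities with convex
#' coefficients: each weight lies in [0, 1] and they sum to one.
#'
#' @param weights Numeric vector of coefficients, optionally named by
#'   modality.
#' @return A validated numeric vector of class `ensemble_weights`.
#' @export
ensemble_weights <- function(weights) {
  if (!is.numeric(weights) || !length(weights)) {
    nf_stop("weights must be a non-empty numeric vector",
            class = "neurofuse_config_error")
  }
  if (any(weights < 0 | weights > 1)) {
    nf_stop("each weight must lie in [0, 1]", class = "neurofuse_config_error")
  }
  if (abs(sum(weights) - 1) > 1e-12) {
    nf_stop("weights must sum to 1 (got ", format(sum(weights), digits = 15),
            ")", class = "neurofuse_config_error")
  }
  structure(as.numeric(weights), names = names(weights),
            class = "ensemble_weights")
}

#' Weighted late fusion of per-modality probabilities
#'
#' Computes the fused probability `Y_i = sum_k c_k * y_ki` per subject; the
#' hard label is AD when `Y_i >= 0.5`.
#'
#' @param probabilities Matrix of per-subject (rows) per-modality (columns)
#'   probabilities, or a list of equal-length named probability vectors over
#'   identical subjects in identical order.
#' @param weights An [ensemble_weights()] vector, one weight per modality.
#' @return Named numeric vector of fused probabilities.
#' @export
fuse_probabilities <- function(probabilities, weights) {
  weights <- ensemble_weights(weights)
  if (is.list(probabilities)) {
    nm <- lapply(probabilities, names)
    if (length(probabilities) > 1) {
      for (k in 2:length(probabilities)) {
        if (!identical(nm[[k]], nm[[1]])) {
          nf_stop("modalities cover different subjects (or ordering differs)",
                  class = "neurofuse_input_error")
        }
      }
    }
    probabilities <- do.call(cbind, probabilities)
  }
  if (ncol(probabilities) != length(weights)) {
    nf_stop("need one weight per modality (", ncol(probabilities),
            " modalities, ", length(weights), " weights)",
            class = "neurofuse_input_error")
  }
  drop(probabilities %*% as.numeric(weights))
}

#' Evaluate one weighted combination of modality classifiers
#'
#' Inner-joins subjects across the supplied tables by identifier, scores
#' each model on its own modality's features, fuses the probabilities with
#' the given weights, and computes confusion metrics (threshold 0.5, ties to
#' AD) and the ROC/AUC of the fused probability.
#'
#' @param models Named list of `modality_model` objects.
#' @param tables Named list of [feature_table()]s, one per model (matched by
#'   name when both are named).
#' @param weights An [ensemble_weights()] vector, one per model.
#' @return An object of class `fusion_result`: list with `fused` (per-subject
#'   Y), `labels`, `predicted`, `probabilities` (per-modality matrix),
#'   `weights`, `metrics` and `roc`.
#' @export
evaluate_combination <- function(models, tables, weights) {
  if (inherits(models, "modality_model")) models <- list(models)
  if (inherits(tables, "feature_table")) tables <- list(tables)
  weights <- ensemble_weights(weights)
  if (length(models) != length(tables) || length(models) != length(weights)) {
    nf_stop("models, tables and weights must have equal length",
            class = "neurofuse_input_error")
  }
  if (!is.null(names(models)) && !is.null(names(tables))) {
    if (!all(names(models) %in% names(tables))) {
      nf_stop("tables missing for model(s): ",
              paste(setdiff(names(models), names(tables)), collapse = ", "),
              class = "neurofuse_input_error")
    }
    tables <- tables[names(models)]
  }
  ids <- Reduce(intersect, lapply(tables, function(t) rownames(t$x)))
  if (!length(ids)) {
    nf_stop("no subjects are shared across the supplied modalities",
            class = "neurofuse_input_error")
  }
  tables <- lapply(tables, subset_table, subjects = ids)
  labels <- tables[[1]]$label
  for (t in tables[-1]) {
    if (!identical(t$label, labels)) {
      nf_stop("diagnosis labels disagree across modalities for shared subjects",
              class = "neurofuse_input_error")
    }
  }
  probs <- vapply(seq_along(models),
                  function(k) predict(models[[k]], tables[[k]], type = "prob"),
                  numeric(length(ids)))
  probs <- matrix(probs, nrow = length(ids),
                  dimnames = list(ids, names(models)))
  fused <- fuse_probabilities(probs, weights)
  predicted <- as.integer(fused >= 0.5)
  structure(
    list(fused = fused, labels = labels, predicted = predicted,
         probabilities = probs, weights = weights,
         metrics = confusion_metrics(labels, predicted),
         roc = roc_and_auc(labels, fused)),
    class = "fusion_result"
  )
}

#' @export
print.fusion_result <- function(x, ...) {
  nm <- names(x$weights)
  if (is.null(nm)) nm <- paste0("m", seq_along(x$weights))
  cat(sprintf("<fusion_result> %s on %d subjects\n",
              paste(sprintf("%s (%.3g)", nm, x$weights), collapse = " + "),
              length(x$fused)))
  cat(sprintf("  accuracy %.3f | sensitivity %.3f | specificity %.3f | BACC %.3f | AUC %.3f\n",
              x$metrics["accuracy"], x$metrics["sensitivity"],
              x$metrics["specificity"], x$metrics["balanced_accuracy"],
              x$roc$auc))
  invisible(x)
}

#' Evaluate every multimodal combination at equal weights
#'
#' Scores each modality subset of size two or more with equal weights
#' 1/|subset| on the inner-joined subjects, alongside each single-modality
#' baseline on the same joined cohort.
#'
#' @param models Named list of at least two `modality_model` objects.
#' @param tables Named list of matching [feature_table()]s.
#' @return An object of class `combination_report`: list with `baselines`
#'   and `combinations` (named lists of `fusion_result`) and `comparison`
#'   (data frame of metrics per modality set).
#' @export
enumerate_combinations <- function(models, tables) {
  if (length(models) < 2) {
    nf_stop("need at least 2 models to enumerate combinations",
            class = "neurofuse_input_error")
  }
  nm <- names(models)
  if (is.null(nm)) {
    nm <- vapply(models, `[[`, "", "modality")
    names(models) <- nm
  }
  baselines <- lapply(nm, function(m) {
    evaluate_combination(models[m], tables[m], ensemble_weights(stats::setNames(1, m)))
  })
  names(baselines) <- nm
  subsets <- list()
  for (size in 2:length(nm)) {
    cs <- utils::combn(nm, size, simplify = FALSE)
    subsets <- c(subsets, cs)
  }
  combos <- lapply(subsets, function(s) {
    w <- ensemble_weights(stats::setNames(rep(1 / length(s), length(s)), s))
    evaluate_combination(models[s], tables[s], w)
  })
  names(combos) <- vapply(subsets, paste, "", collapse = "+")
  rows <- lapply(c(baselines, combos), function(fr) {
    c(fr$metrics, auc = fr$roc$auc)
  })
  comparison <- data.frame(
    modalities = names(rows),
    do.call(rbind, rows),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(baselines = baselines, combinations = combos,
                 comparison = comparison),
            class = "combination_report")
}

#' @export
print.combination_report <- function(x, ...) {
  cat("<combination_report>\n")
  df <- x$comparison
  df[-1] <- lapply(df[-1], round, 4)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Sweep fusion weights over a simplex grid
#'
#' Optional exploration beyond the equal-weight scheme: evaluates
#' [evaluate_combination()] at every weight vector on a regular grid over
#' the probability simplex.
#'
#' @param models Named list of `modality_model` objects (two or more).
#' @param tables Named list of matching [feature_table()]s.
#' @param step Grid resolution in weight units (default 0.1).
#' @return Data frame with one row per grid point: the weights, accuracy,
#'   balanced accuracy and AUC.
#' @export
sweep_weights <- function(models, tables, step = 0.1) {
  if (length(models) < 2) {
    nf_stop("need at least 2 models for a weight sweep",
            class = "neurofuse_input_error")
  }
  k <- length(models)
  ticks <- seq(0, 1, by = step)
  grid <- expand.grid(rep(list(ticks), k))
  grid <- grid[abs(rowSums(grid) - 1) < 1e-9, , drop = FALSE]
  nm <- names(models)
  colnames(grid) <- nm
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    w <- ensemble_weights(stats::setNames(as.numeric(grid[i, ]), nm))
    fr <- evaluate_combination(models, tables, w)
    c(as.numeric(grid[i, ]), fr$metrics[c("accuracy", "balanced_accuracy")],
      auc = fr$roc$auc)
  })
  out <- as.data.frame(do.call(rbind, rows))
  colnames(out) <- c(nm, "accuracy", "balanced_accuracy", "auc")
  out
}
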