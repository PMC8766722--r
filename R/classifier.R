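#' Fit feature standardization parameters on training subjects
#'
#' Per-feature mean and sample standard deviation (n - 1 denominator),
#' estimated on the training table only. Applying them back to the training
#' data yields zero mean and unit variance per feature; test and external
#' subjects are always transformed with these training-derived parameters —
#' never refit — so a distribution shift in new data remains visible.
#'
#' @param table A [feature_table()] (or numeric matrix) of training subjects.
#' @return An object of class `standardization_params`: list with named
#'   numeric vectors `mean` and `sd`.
#' @export
standardize_fit <- function(table) {
  x <- if (inherits(table, "feature_table")) table$x else table
  if (nrow(x) < 2) {
    nf_stop("need at least 2 training subjects", class = "neurofuse_input_error")
  }
  mu <- colMeans(x)
  s <- apply(x, 2, stats::sd)
  if (any(s == 0)) {
    nf_stop("constant training feature: ", colnames(x)[which(s == 0)[1]],
            class = "neurofuse_input_error")
  }
  structure(list(mean = mu, sd = s), class = "standardization_params")
}

#' Apply fitted standardization parameters
#'
#' Computes `(x - mean) / sd` elementwise with the training-derived
#' parameters.
#'
#' @param params A `standardization_params` from [standardize_fit()].
#' @param table A [feature_table()] or matrix with exactly the fitted
#'   features.
#' @return Same type as `table`, standardized.
#' @export
standardize_apply <- function(params, table) {
  stopifnot(inherits(params, "standardization_params"))
  x <- if (inherits(table, "feature_table")) table$x else table
  if (is.null(colnames(x)) || !identical(colnames(x), names(params$mean))) {
    nf_stop("features do not match the fitted standardization parameters",
            class = "neurofuse_input_error")
  }
  xs <- sweep(sweep(x, 2, params$mean, "-"), 2, params$sd, "/")
  if (inherits(table, "feature_table")) {
    feature_table(xs, table$label, table$modality)
  } else xs
}

#' SVM classifier configuration
#'
#' @param cost Soft-margin cost C of the RBF-kernel SVM; default 0.1.
#' @param gamma Kernel width: `"scale"` (default) means
#'   `1 / (n_features * mean feature variance of the training matrix)`,
#'   or a positive number.
#' @param kernel `"radial"` (default) or `"linear"`.
#' @param seed Integer seed recorded with the model.
#' @return An object of class `svm_config`.
#' @export
svm_config <- function(cost = 0.1, gamma = "scale",
                       kernel = c("radial", "linear"), seed = 1) {
  kernel <- match.arg(kernel)
  if (!is_number(cost) || cost <= 0) {
    nf_stop("cost must be a positive number", class = "neurofuse_config_error")
  }
  if (!(identical(gamma, "scale") || (is_number(gamma) && gamma > 0))) {
    nf_stop("gamma must be \"scale\" or a positive number",
            class = "neurofuse_config_error")
  }
  structure(list(cost = cost, gamma = gamma, kernel = kernel,
                 seed = as.integer(seed)),
            class = "svm_config")
}

# Monotone sigmoid map from SVM decision values to [0,1], fitted on training
# decision values by logistic regression. Degenerate decision values fall
# back to an intercept-only fit.
fit_calibration <- function(decision, label) {
  df <- data.frame(y = label, d = decision)
  fit <- if (stats::sd(decision) < 1e-12) {
    suppressWarnings(stats::glm(y ~ 1, data = df, family = stats::binomial()))
  } else {
    suppressWarnings(stats::glm(y ~ d, data = df, family = stats::binomial()))
  }
  co <- stats::coef(fit)
  list(intercept = unname(co[1]),
       slope = if (length(co) > 1 && is.finite(co[2])) unname(co[2]) else 0)
}

#' Train a single-modality SVM classifier
#'
#' Standardizes the selected features on the training subjects (see
#' [standardize_fit()]), fits an RBF-kernel SVM, and fits a monotone sigmoid
#' probability calibration on the training decision values. The returned
#' model carries everything needed to score new tables.
#'
#' @param table Training [feature_table()] with both classes present.
#' @param selected Feature names to use (defaults to all features).
#' @param config An [svm_config()].
#' @return An object of class `modality_model`.
#' @export
#' @examples
#' cfg <- cohort_config(15, list(
#'   modality_spec("pet", 6, n_informative = 3, effect_size = 2)
#' ), seed = 11)
#' tab <- generate_multimodal_cohort(cfg)$tables$pet
#' fit <- train_modality_model(tab, config = svm_config())
#' summary(fit)
train_modality_model <- function(table, selected = NULL,
                                 config = svm_config()) {
  stopifnot(inherits(table, "feature_table"), inherits(config, "svm_config"))
  if (length(unique(table$label)) < 2) {
    nf_stop("training data contain a single class", class = "neurofuse_input_error")
  }
  if (is.null(selected)) selected <- colnames(table$x)
  tab <- subset_table(table, features = selected)
  params <- standardize_fit(tab)
  xs <- standardize_apply(params, tab)$x
  gamma <- if (identical(config$gamma, "scale")) {
    1 / (ncol(xs) * mean(apply(xs, 2, stats::var)))
  } else config$gamma
  y <- factor(tab$label, levels = c(0L, 1L))
  fit <- e1071::svm(x = xs, y = y, kernel = config$kernel,
                    cost = config$cost, gamma = gamma, scale = FALSE)
  dec <- as.numeric(attr(stats::predict(fit, xs, decision.values = TRUE),
                         "decision.values"))
  calib <- fit_calibration(dec, tab$label)
  structure(
    list(modality = table$modality, selected = selected,
         standardization = params, svm = fit, gamma = gamma,
         calibration = calib, config = config,
         n_train = nrow(xs), class_counts = table(tab$label)),
    class = "modality_model"
  )
}

#' @export
print.modality_model <- function(x, ...) {
  cat(sprintf(
    "<modality_model> '%s': %s-kernel SVM (C = %g, gamma = %.4g), %d features, %d training subjects\n",
    x$modality, x$config$kernel, x$config$cost, x$gamma,
    length(x$selected), x$n_train))
  invisible(x)
}

#' @export
summary.modality_model <- function(object, ...) {
  print(object)
  cat("  features:", paste(object$selected, collapse = ", "), "\n")
  cat(sprintf("  calibration: p = plogis(%.4g %+.4g * decision)\n",
              object$calibration$intercept, object$calibration$slope))
  invisible(object)
}

#' Predicted AD probability for new subjects
#'
#' Standardizes the table with the model's training-derived parameters,
#' evaluates the SVM decision values and maps them through the fitted
#' sigmoid calibration. The hard label is AD when the probability is at
#' least 0.5 (ties classify as AD).
#'
#' @param object A `modality_model`.
#' @param table A [feature_table()] containing the model's features.
#' @param type `"prob"` (default) for probabilities, `"class"` for 0/1
#'   labels.
#' @param ... Unused.
#' @return Named numeric (probabilities in [0,1]) or integer (0/1) vector,
#'   one entry per subject.
#' @export
predict.modality_model <- function(object, table, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  stopifnot(inherits(table, "feature_table"))
  miss <- setdiff(object$selected, colnames(table$x))
  if (length(miss)) {
    nf_stop("table lacks model feature(s): ", paste(miss, collapse = ", "),
            class = "neurofuse_input_error")
  }
  tab <- subset_table(table, features = object$selected)
  xs <- standardize_apply(object$standardization, tab)$x
  dec <- as.numeric(attr(stats::predict(object$svm, xs, decision.values = TRUE),
                         "decision.values"))
  p <- stats::plogis(object$calibration$intercept + object$calibration$slope * dec)
  names(p) <- rownames(xs)
  if (type == "prob") p else {
    stats::setNames(as.integer(p >= 0.5), rownames(xs))
  }
}

#' Alias for scoring a table with a modality model
#'
#' @inheritParams predict.modality_model
#' @return Named probability vector.
#' @export
predict_probability <- function(object, table) {
  predict(object, table, type = "prob")
}
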