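#' Feature-selection configuration
#'
#' Defaults follow the standard protocol for small AD cohorts: random subsets
#' of 8 features over 2,000 random-forest iterations (embedded method),
#' p-value cutoff 0.05 (filter method), an importance filter at 0.55 times
#' the top importance, correlation pruning at |r| > 0.55 against the top
#' feature then |r| > 0.70 pairwise, and a final cap of 8 features (one per
#' five cases at n approximately 40).
#'
#' @param method `"ebm"` (embedded, random-forest importance) or `"fbm"`
#'   (filter, two-sample t-test).
#' @param subset_size Features drawn per embedded iteration.
#' @param n_runs Number of embedded iterations.
#' @param importance_ratio Keep features with mean importance at least this
#'   fraction of the maximum (strict "less than" removal, so the boundary
#'   survives).
#' @param p_threshold Filter method: remove features with p > this value.
#' @param r_top Stage-1 pruning cutoff against the top-ranked feature.
#' @param r_pairwise Stage-2 greedy pairwise pruning cutoff.
#' @param max_features Final cap on the selected set.
#' @param train_fraction Fraction of subjects in the balanced split drawn at
#'   each embedded iteration, mirroring the classifier's training environment.
#' @param ntree Trees per random forest.
#' @param var_equal Classical (Student) two-sample t-test when `TRUE`
#'   (default); Welch when `FALSE`.
#' @param seed Integer seed driving the embedded iterations.
#' @return An object of class `selection_config`.
#' @export
selection_config <- function(method = c("ebm", "fbm"), subset_size = 8,
                             n_runs = 2000, importance_ratio = 0.55,
                             p_threshold = 0.05, r_top = 0.55,
                             r_pairwise = 0.70, max_features = 8,
                             train_fraction = 0.8, ntree = 500,
                             var_equal = TRUE, seed = 1) {
  method <- match.arg(method)
  if (!is_count(subset_size)) {
    nf_stop("subset_size must be a positive integer", class = "neurofuse_config_error")
  }
  if (!is_count(n_runs)) {
    nf_stop("n_runs must be a positive integer", class = "neurofuse_config_error")
  }
  if (!is_number(importance_ratio) || importance_ratio <= 0 || importance_ratio > 1) {
    nf_stop("importance_ratio must lie in (0, 1]", class = "neurofuse_config_error")
  }
  for (nm in c("r_top", "r_pairwise")) {
    v <- get(nm)
    if (!is_number(v) || v <= 0 || v > 1) {
      nf_stop(nm, " must lie in (0, 1]", class = "neurofuse_config_error")
    }
  }
  if (!is_number(p_threshold) || p_threshold <= 0 || p_threshold > 1) {
    nf_stop("p_threshold must lie in (0, 1]", class = "neurofuse_config_error")
  }
  if (!is_count(max_features)) {
    nf_stop("max_features must be a positive integer", class = "neurofuse_config_error")
  }
  if (!is_number(train_fraction) || train_fraction <= 0 || train_fraction >= 1) {
    nf_stop("train_fraction must lie in (0, 1)", class = "neurofuse_config_error")
  }
  structure(
    list(method = method, subset_size = as.integer(subset_size),
         n_runs = as.integer(n_runs), importance_ratio = importance_ratio,
         p_threshold = p_threshold, r_top = r_top, r_pairwise = r_pairwise,
         max_features = as.integer(max_features),
         train_fraction = train_fraction, ntree = as.integer(ntree),
         var_equal = isTRUE(var_equal), seed = as.integer(seed)),
    class = "selection_config"
  )
}

# Order feature names by a statistic, descending, ties broken
# lexicographically on the name for determinism.
rank_features <- function(names, stat) {
  names[order(-stat, names, method = "radix")]
}

#' Embedded feature importance by random-subset random forests
#'
#' At each of `n_runs` iterations, a balanced (class-stratified) random
#' subset of subjects is drawn, a uniform random subset of `subset_size`
#' features is drawn, and a random forest is fit on that training portion;
#' the impurity importance of each participating feature is recorded. A
#' feature's final importance is the mean over the iterations in which it
#' appeared.
#'
#' @param table A [feature_table()] with both classes present.
#' @param config A [selection_config()].
#' @return An object of class `importance_profile`: data frame with columns
#'   `feature`, `mean_importance`, `appearance_count`, ordered by descending
#'   importance, plus attribute `method = "ebm"`.
#' @export
ebm_importance <- function(table, config = selection_config()) {
  stopifnot(inherits(table, "feature_table"), inherits(config, "selection_config"))
  if (length(unique(table$label)) < 2) {
    nf_stop("both diagnostic classes must be present",
            class = "neurofuse_input_error")
  }
  p <- ncol(table$x)
  if (config$subset_size > p) {
    nf_stop("subset_size (", config$subset_size, ") exceeds feature count (",
            p, ")", class = "neurofuse_config_error")
  }
  feats <- colnames(table$x)
  idx0 <- which(table$label == 0L)
  idx1 <- which(table$label == 1L)
  n_tr0 <- max(1L, round(length(idx0) * config$train_fraction))
  n_tr1 <- max(1L, round(length(idx1) * config$train_fraction))

  imp_sum <- stats::setNames(numeric(p), feats)
  imp_cnt <- stats::setNames(integer(p), feats)

  for (run in seq_len(config$n_runs)) {
    with_seed(derive_seed(config$seed, run), {
      tr <- c(sample(idx0, n_tr0), sample(idx1, n_tr1))
      sel <- sample(feats, config$subset_size)
      rf <- randomForest::randomForest(
        x = table$x[tr, sel, drop = FALSE],
        y = factor(table$label[tr], levels = c(0L, 1L)),
        ntree = config$ntree
      )
      imp <- rf$importance[, "MeanDecreaseGini"]
      imp_sum[sel] <- imp_sum[sel] + imp[sel]
      imp_cnt[sel] <- imp_cnt[sel] + 1L
    })
  }
  mean_imp <- ifelse(imp_cnt > 0, imp_sum / imp_cnt, NA_real_)
  ord <- order(-ifelse(is.na(mean_imp), -Inf, mean_imp), feats, method = "radix")
  structure(
    data.frame(feature = feats[ord], mean_importance = mean_imp[ord],
               appearance_count = imp_cnt[ord], row.names = NULL,
               stringsAsFactors = FALSE),
    class = c("importance_profile", "data.frame"),
    method = "ebm"
  )
}

#' Importance filter relative to the top feature
#'
#' Removes every feature whose mean importance is strictly less than
#' `importance_ratio` times the most important feature's value; features at
#' the boundary survive. Output is ranked from the biggest to the smallest
#' importance.
#'
#' @param profile An `importance_profile` from [ebm_importance()].
#' @param importance_ratio Retention fraction of the maximum importance.
#' @return Character vector of surviving feature names, ranked.
#' @export
importance_filter <- function(profile, importance_ratio = 0.55) {
  stopifnot(inherits(profile, "importance_profile"))
  imp <- profile$mean_importance
  keep <- !is.na(imp)
  if (!any(keep)) {
    nf_stop("no feature has a defined importance", class = "neurofuse_input_error")
  }
  cutoff <- importance_ratio * max(imp[keep])
  surv <- keep & imp >= cutoff  # strict "lesser than" removal
  rank_features(profile$feature[surv], imp[surv])
}

#' Filter-method univariate screening by two-sample t-test
#'
#' Performs a two-sided two-sample t-test per feature comparing the AD and
#' CN groups, removes features with p above `p_threshold`, and ranks the
#' survivors by descending absolute t statistic.
#'
#' @param table A [feature_table()]; each group needs at least 2 subjects.
#' @param p_threshold Removal cutoff (features with p > threshold go).
#' @param var_equal Classical Student form when `TRUE` (default), Welch
#'   otherwise.
#' @return An `importance_profile` restricted to survivors: data frame with
#'   columns `feature`, `t_value`, `p_value`, ordered by descending |t|;
#'   attribute `removed` holds the screened-out features.
#' @export
fbm_univariate <- function(table, p_threshold = 0.05, var_equal = TRUE) {
  stopifnot(inherits(table, "feature_table"))
  g0 <- table$label == 0L
  g1 <- table$label == 1L
  if (sum(g0) < 2 || sum(g1) < 2) {
    nf_stop("each group needs at least 2 subjects for the t-test",
            class = "neurofuse_input_error")
  }
  res <- apply(table$x, 2, function(v) {
    ht <- stats::t.test(v[g1], v[g0], var.equal = var_equal)
    c(t = unname(ht$statistic), p = ht$p.value)
  })
  tv <- res["t", ]
  pv <- res["p", ]
  feats <- colnames(table$x)
  surv <- pv <= p_threshold
  ord <- order(-abs(tv[surv]), feats[surv], method = "radix")
  out <- data.frame(
    feature = feats[surv][ord], t_value = tv[surv][ord],
    p_value = pv[surv][ord], row.names = NULL, stringsAsFactors = FALSE
  )
  structure(out,
            class = c("importance_profile", "data.frame"),
            method = "fbm",
            removed = data.frame(feature = feats[!surv],
                                 t_value = tv[!surv], p_value = pv[!surv],
                                 row.names = NULL, stringsAsFactors = FALSE))
}

#' Two-stage Pearson correlation pruning
#'
#' Redundancy filter applied to an already-ranked feature list. Pearson
#' correlations are computed on the raw (pre-standardization) values over all
#' subjects. Stage 1 removes every feature with |r| > `r_top` against the
#' top-ranked feature (which always survives). Stage 2 walks the survivors in
#' rank order from the second onward; each anchor removes any lower-ranked
#' survivor with |r| > `r_pairwise` against it. Both removals are strict.
#'
#' @param table A [feature_table()] containing the ranked features.
#' @param ranked_features Character vector of feature names in rank order
#'   (most important first).
#' @param r_top Stage-1 cutoff.
#' @param r_pairwise Stage-2 cutoff.
#' @return An object of class `selection_result`: list with `selected`
#'   (ordered survivors), `removed` (data frame: feature, stage, anchor, r),
#'   and `correlation_matrix` over the entering features.
#' @export
correlation_prune <- function(table, ranked_features, r_top = 0.55,
                              r_pairwise = 0.70) {
  stopifnot(inherits(table, "feature_table"))
  if (!length(ranked_features)) {
    nf_stop("no ranked features supplied", class = "neurofuse_input_error")
  }
  miss <- setdiff(ranked_features, colnames(table$x))
  if (length(miss)) {
    nf_stop("unknown feature(s): ", paste(miss, collapse = ", "),
            class = "neurofuse_input_error")
  }
  xs <- table$x[, ranked_features, drop = FALSE]
  sds <- apply(xs, 2, stats::sd)
  if (any(sds == 0)) {
    nf_stop("constant feature (undefined correlation): ",
            ranked_features[which(sds == 0)[1]],
            class = "neurofuse_input_error")
  }
  cm <- stats::cor(xs)

  removed <- data.frame(feature = character(), stage = character(),
                        anchor = character(), r = numeric(),
                        stringsAsFactors = FALSE)
  surv <- ranked_features
  if (length(surv) > 1) {
    top <- surv[1]
    hit <- surv[-1][abs(cm[top, surv[-1]]) > r_top]
    if (length(hit)) {
      removed <- rbind(removed, data.frame(
        feature = hit, stage = "r_top", anchor = top,
        r = unname(cm[top, hit]), stringsAsFactors = FALSE))
      surv <- setdiff(surv, hit)
    }
  }
  i <- 2L
  while (i <= length(surv)) {
    anchor <- surv[i]
    lower <- surv[-seq_len(i)]
    hit <- lower[abs(cm[anchor, lower]) > r_pairwise]
    if (length(hit)) {
      removed <- rbind(removed, data.frame(
        feature = hit, stage = "r_pairwise", anchor = anchor,
        r = unname(cm[anchor, hit]), stringsAsFactors = FALSE))
      surv <- setdiff(surv, hit)
    }
    i <- i + 1L
  }
  structure(
    list(selected = surv, removed = removed, correlation_matrix = cm),
    class = "selection_result"
  )
}

#' Run the full feature-selection pipeline for one modality
#'
#' Embedded route: [ebm_importance()] then [importance_filter()] then
#' [correlation_prune()]. Filter route: [fbm_univariate()] then
#' [correlation_prune()]. Either way the surviving ranked list is finally
#' truncated to the `max_features` best features; a shorter list is returned
#' as-is.
#'
#' @param table A [feature_table()].
#' @param config A [selection_config()].
#' @return A `selection_result` with the full removal audit across stages
#'   (`importance_filter` / `p_filter`, `r_top`, `r_pairwise`, `truncation`)
#'   and the ranking profile as attribute `profile`.
#' @export
#' @examples
#' cfg <- cohort_config(15, list(
#'   modality_spec("pet", 12, n_informative = 3, effect_size = 2)
#' ), seed = 3)
#' tab <- generate_multimodal_cohort(cfg)$tables$pet
#' sel <- select_features(tab, selection_config("fbm"))
#' sel
select_features <- function(table, config = selection_config()) {
  stopifnot(inherits(table, "feature_table"), inherits(config, "selection_config"))
  if (config$method == "ebm") {
    profile <- ebm_importance(table, config)
    ranked <- importance_filter(profile, config$importance_ratio)
    pre_removed <- data.frame(
      feature = setdiff(profile$feature, ranked),
      stage = "importance_filter", anchor = NA_character_, r = NA_real_,
      stringsAsFactors = FALSE)
  } else {
    profile <- fbm_univariate(table, config$p_threshold, config$var_equal)
    ranked <- profile$feature
    dropped <- attr(profile, "removed")
    pre_removed <- data.frame(
      feature = dropped$feature,
      stage = rep("p_filter", nrow(dropped)),
      anchor = rep(NA_character_, nrow(dropped)),
      r = rep(NA_real_, nrow(dropped)),
      stringsAsFactors = FALSE)
  }
  if (!length(ranked)) {
    nf_stop("no features survive the ", config$method, " ranking filter",
            class = "neurofuse_empty_selection")
  }
  pruned <- correlation_prune(table, ranked, config$r_top, config$r_pairwise)
  selected <- pruned$selected
  removed <- rbind(pre_removed, pruned$removed)
  if (length(selected) > config$max_features) {
    cut <- selected[-seq_len(config$max_features)]
    removed <- rbind(removed, data.frame(
      feature = cut, stage = "truncation", anchor = NA_character_,
      r = NA_real_, stringsAsFactors = FALSE))
    selected <- selected[seq_len(config$max_features)]
  }
  if (!length(selected)) {
    nf_stop("feature selection left no features", class = "neurofuse_empty_selection")
  }
  structure(
    list(selected = selected, removed = removed,
         correlation_matrix = pruned$correlation_matrix,
         method = config$method, modality = table$modality),
    class = "selection_result",
    profile = profile
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result>%s %d feature(s) selected%s\n",
              if (!is.null(x$method)) paste0(" [", x$method, "]") else "",
              length(x$selected),
              if (!is.null(x$modality)) paste0(" for '", x$modality, "'") else ""))
  cat("  selected:", paste(x$selected, collapse = ", "), "\n")
  if (nrow(x$removed)) {
    tab <- table(x$removed$stage)
    cat("  removed: ", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Serialize a selection result to JSON
#'
#' Writes the selected list, the removal audit trail, and the correlation
#' matrix as a dense array with feature-name headers.
#'
#' @param result A `selection_result`.
#' @param path Output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_selection_result <- function(result, path) {
  stopifnot(inherits(result, "selection_result"))
  cm <- result$correlation_matrix
  jsonlite::write_json(
    list(
      method = result$method,
      modality = result$modality,
      selected = result$selected,
      removed = result$removed,
      correlation = list(features = colnames(cm),
                         matrix = unname(as.matrix(cm)))
    ),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"
  )
  invisible(path)
}
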