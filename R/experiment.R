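#' End-to-end experiment configuration
#'
#' Bundles every stage configuration of the multimodal classification
#' experiment: cohort simulation, per-modality feature selection, SVM and
#' repeated-holdout evaluation settings, and the master seed. All defaults
#' equal the standard protocol values (8-feature cap, 2,000 selection
#' iterations and evaluation cycles, 0.55/0.70/0.05 thresholds, 80/20
#' splits, C = 0.1).
#'
#' @param cohort A [cohort_config()].
#' @param selection A [selection_config()], or a named list with one per
#'   modality.
#' @param svm An [svm_config()].
#' @param evaluation An [eval_config()].
#' @param seed Master seed; stage seeds derive from it deterministically and
#'   override the seeds of the sub-configs.
#' @param verbose Emit per-stage progress messages.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(cohort, selection = selection_config(),
                              svm = svm_config(), evaluation = eval_config(),
                              seed = 1, verbose = TRUE) {
  stopifnot(inherits(cohort, "cohort_config"))
  mods <- names(cohort$modalities)
  if (inherits(selection, "selection_config")) {
    selection <- stats::setNames(rep(list(selection), length(mods)), mods)
  }
  if (!all(mods %in% names(selection))) {
    nf_stop("selection config missing for modality(ies): ",
            paste(setdiff(mods, names(selection)), collapse = ", "),
            class = "neurofuse_config_error")
  }
  stopifnot(all(vapply(selection, inherits, TRUE, "selection_config")),
            inherits(svm, "svm_config"), inherits(evaluation, "eval_config"))
  structure(
    list(cohort = cohort, selection = selection[mods], svm = svm,
         evaluation = evaluation, seed = as.integer(seed),
         verbose = isTRUE(verbose)),
    class = "experiment_config"
  )
}

#' Read an experiment configuration from YAML
#'
#' The YAML mirrors the constructor arguments: top-level keys `seed`,
#' `cohort` (with `n_per_group`, `external_shift`, `external_scale`,
#' `dropout_fraction` and a `modalities` list of [modality_spec()] fields),
#' and optional `selection`, `svm`, `evaluation` blocks whose keys override
#' the defaults. Unknown keys raise an error naming the offender.
#'
#' @param path Path to a YAML file.
#' @return An [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  if (!file.exists(path)) {
    nf_stop("config file not found: ", path, class = "neurofuse_io_error")
  }
  y <- yaml::read_yaml(path)
  known <- c("seed", "verbose", "cohort", "selection", "svm", "evaluation")
  bad <- setdiff(names(y), known)
  if (length(bad)) {
    nf_stop("unknown config key(s): ", paste(bad, collapse = ", "),
            class = "neurofuse_config_error")
  }
  if (is.null(y$cohort) || is.null(y$cohort$modalities)) {
    nf_stop("config must define cohort.modalities", class = "neurofuse_config_error")
  }
  check_keys <- function(block, allowed, where) {
    bad <- setdiff(names(block), allowed)
    if (length(bad)) {
      nf_stop("unknown key(s) in ", where, ": ", paste(bad, collapse = ", "),
              class = "neurofuse_config_error")
    }
  }
  check_keys(y$cohort, c("n_per_group", "modalities", "seed", "external_shift",
                         "external_scale", "dropout_fraction"), "cohort")
  mods <- lapply(y$cohort$modalities, function(m) {
    check_keys(m, names(formals(modality_spec)), "cohort.modalities")
    do.call(modality_spec, m)
  })
  cohort <- do.call(cohort_config,
                    c(list(modalities = mods),
                      y$cohort[setdiff(names(y$cohort), "modalities")]))
  build <- function(block, ctor, where) {
    if (is.null(block)) return(ctor())
    check_keys(block, names(formals(ctor)), where)
    do.call(ctor, block)
  }
  experiment_config(
    cohort = cohort,
    selection = build(y$selection, selection_config, "selection"),
    svm = build(y$svm, svm_config, "svm"),
    evaluation = build(y$evaluation, eval_config, "evaluation"),
    seed = if (is.null(y$seed)) 1L else y$seed,
    verbose = if (is.null(y$verbose)) TRUE else y$verbose
  )
}

# Stage logger: message + appended log line with wall time and derived seed.
stage_log <- function(state, stage, seed = NA, t0 = NULL) {
  line <- if (is.null(t0)) {
    sprintf("stage %-12s start  seed=%s", stage,
            if (is.na(seed)) "-" else seed)
  } else {
    sprintf("stage %-12s done   %.2fs", stage,
            as.numeric(proc.time()["elapsed"]) - t0)
  }
  if (state$verbose) message(line)
  cat(line, "\n", file = state$log, append = TRUE)
}

#' Run the full multimodal classification experiment
#'
#' Simulates three disjoint cohorts (model-building, held-out ensemble, and
#' distribution-shifted external), selects features per modality on the
#' model-building cohort, runs the repeated-holdout evaluation per modality,
#' trains final per-modality models on the full model-building cohort,
#' evaluates every equal-weight modality combination on the ensemble cohort,
#' and finally scores models and the all-modality ensemble on the external
#' cohort. All artifacts (metrics CSV/JSON, ROC CSVs, selection audit JSON,
#' run manifest) are written under `out_dir` and are byte-reproducible for a
#' fixed config and seed.
#'
#' @param config An [experiment_config()] (or path to a YAML file accepted by
#'   [read_experiment_config()]).
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list with the in-memory results per stage
#'   (`selection`, `evaluation`, `models`, `ensemble`, `external`,
#'   `artifacts`).
#' @export
run_experiment <- function(config, out_dir) {
  if (is.character(config)) config <- read_experiment_config(config)
  stopifnot(inherits(config, "experiment_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  state <- list(verbose = config$verbose, log = file.path(out_dir, "log.txt"))
  cat("", file = state$log)
  artifacts <- character()
  wrap_stage <- function(stage, code) {
    t0 <- as.numeric(proc.time()["elapsed"])
    stage_log(state, stage)
    out <- tryCatch(code, error = function(e) {
      nf_stop("stage '", stage, "' failed: ", conditionMessage(e))
    })
    stage_log(state, stage, t0 = t0)
    out
  }
  mods <- names(config$cohort$modalities)

  cohorts <- wrap_stage("simulate", {
    base <- config$cohort
    cfg_build <- base; cfg_build$seed <- derive_seed(config$seed, 101)
    cfg_ens <- base;   cfg_ens$seed <- derive_seed(config$seed, 102)
    cfg_ext <- base;   cfg_ext$seed <- derive_seed(config$seed, 103)
    list(build = generate_multimodal_cohort(cfg_build),
         ensemble = generate_multimodal_cohort(cfg_ens),
         external = generate_external_cohort(cfg_ext))
  })

  selections <- wrap_stage("select", {
    out <- lapply(mods, function(m) {
      sc <- config$selection[[m]]
      sc$seed <- derive_seed(config$seed, 200 + match(m, mods))
      sel <- select_features(cohorts$build$tables[[m]], sc)
      p <- file.path(out_dir, paste0("selection_", m, ".json"))
      write_selection_result(sel, p)
      artifacts <<- c(artifacts, p)
      sel
    })
    stats::setNames(out, mods)
  })

  evaluations <- wrap_stage("evaluate", {
    out <- lapply(mods, function(m) {
      ec <- config$evaluation
      ec$seed <- derive_seed(config$seed, 300 + match(m, mods))
      ev <- repeated_holdout_evaluation(
        cohorts$build$tables[[m]], selections[[m]]$selected,
        svm = config$svm, config = ec)
      artifacts <<- c(artifacts,
                      write_holdout_eval(ev, file.path(out_dir, paste0("eval_", m))))
      ev
    })
    stats::setNames(out, mods)
  })

  models <- wrap_stage("train", {
    out <- lapply(mods, function(m) {
      train_modality_model(cohorts$build$tables[[m]],
                           selections[[m]]$selected, config$svm)
    })
    stats::setNames(out, mods)
  })

  ensemble <- if (length(mods) >= 2) {
    wrap_stage("ensemble", {
      rep <- enumerate_combinations(models, cohorts$ensemble$tables)
      p <- file.path(out_dir, "ensemble_comparison.csv")
      utils::write.csv(rep$comparison, p, row.names = FALSE)
      artifacts <<- c(artifacts, p)
      rep
    })
  } else {
    msg <- "single modality: ensemble stage skipped"
    if (config$verbose) message(msg)
    cat(msg, "\n", file = state$log, append = TRUE)
    NULL
  }

  external <- wrap_stage("external", {
    per_mod <- lapply(mods, function(m) {
      tab <- cohorts$external$tables[[m]]
      prob <- predict(models[[m]], tab, type = "prob")
      c(confusion_metrics(tab$label, as.integer(prob >= 0.5)),
        auc = roc_and_auc(tab$label, prob)$auc)
    })
    names(per_mod) <- mods
    fused <- if (length(mods) >= 2) {
      w <- ensemble_weights(stats::setNames(rep(1 / length(mods), length(mods)), mods))
      fr <- evaluate_combination(models, cohorts$external$tables, w)
      as.list(c(fr$metrics, auc = fr$roc$auc))
    } else NULL
    res <- list(per_modality = lapply(per_mod, as.list), ensemble = fused)
    p <- file.path(out_dir, "external_metrics.json")
    jsonlite::write_json(res, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    artifacts <<- c(artifacts, p)
    res
  })

  manifest <- list(
    package = "neurofuse",
    package_version = as.character(utils::packageVersion("neurofuse")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config = serialize_config(config)
  )
  p_man <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, p_man, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  artifacts <- c(artifacts, p_man)

  invisible(list(cohorts = cohorts, selection = selections,
                 evaluation = evaluations, models = models,
                 ensemble = ensemble, external = external,
                 artifacts = artifacts))
}

# Plain-list view of an experiment_config for the JSON manifest.
serialize_config <- function(config) {
  coh <- unclass(config$cohort)
  coh$modalities <- lapply(coh$modalities, unclass)
  list(
    seed = config$seed,
    cohort = coh,
    selection = lapply(config$selection, unclass),
    svm = unclass(config$svm),
    evaluation = unclass(config$evaluation)
  )
}
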