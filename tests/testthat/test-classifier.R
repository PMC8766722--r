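test_that("standardization fits on training data only and round-trips", {
  x <- matrix(c(1, 2, 3, 10, 20, 30), 3, 2,
              dimnames = list(paste0("s", 1:3), c("a", "b")))
  tab <- feature_table(x, c(0, 0, 1))
  par <- standardize_fit(tab)
  expect_equal(unname(par$mean), c(2, 20))
  expect_equal(unname(par$sd), c(1, 10))

  xs <- standardize_apply(par, tab)
  expect_equal(unname(xs$x[, "a"]), c(-1, 0, 1))
  expect_lt(max(abs(colMeans(xs$x))), 1e-10)
  expect_lt(max(abs(apply(xs$x, 2, sd) - 1)), 1e-10)

  # invert: x' * s + mean recovers the input
  back <- sweep(sweep(xs$x, 2, par$sd, "*"), 2, par$mean, "+")
  expect_equal(back, x, tolerance = 1e-12)

  xc <- x; xc[, 2] <- 5
  expect_error(standardize_fit(feature_table(xc, c(0, 0, 1))), "b")
  bad <- tab; colnames(bad$x) <- c("a", "zz")
  expect_error(standardize_apply(par, bad), "match")

  # no refitting on shifted data: the injected shift stays visible
  shifted <- feature_table(x + 5, c(0, 0, 1))
  out <- standardize_apply(par, shifted)
  expect_true(all(abs(colMeans(out$x)) > 0.4))
})

test_that("modality model trains, predicts in [0,1], and separates wide margins", {
  # widely separated classes: training accuracy 1, sane probabilities
  tab <- make_table(n_per_group = 15, p = 4, n_inf = 4, d = 6, seed = 4)
  fit <- train_modality_model(tab)
  p <- predict(fit, tab, type = "prob")
  expect_true(all(p >= 0 & p <= 1))
  expect_identical(unname(predict(fit, tab, type = "class")), tab$label)

  # a deep-in-class CN subject scores below 0.5
  centroid <- matrix(colMeans(tab$x[tab$label == 0, ]), 1,
                     dimnames = list("probe", colnames(tab$x)))
  probe <- feature_table(centroid, 0)
  expect_lt(predict(fit, probe, type = "prob"), 0.5)

  # gamma "scale" on standardized features is 1 / n_features
  expect_equal(fit$gamma, 1 / 4, tolerance = 1e-12)

  # determinism
  fit2 <- train_modality_model(tab)
  expect_equal(predict(fit2, tab), p, tolerance = 0)

  # contradictory duplicate subjects: trains, imperfect accuracy
  xdup <- matrix(c(1, 1, 4, 4, 2, 2, 5, 5), 4, 2,
                 dimnames = list(c("u", "v", "w", "z"), c("a", "b")))
  tdup <- feature_table(xdup, c(0, 1, 0, 1))
  fdup <- train_modality_model(tdup)
  acc <- mean(predict(fdup, tdup, type = "class") == tdup$label)
  expect_lt(acc, 1)

  expect_error(train_modality_model(
    feature_table(tab$x, rep(1, nrow(tab$x)))), "single class")
  expect_error(predict(fit, make_table(5, 2, seed = 1)), "lacks")
})

test_that("probability 0.5 classifies as AD (documented tie rule)", {
  tab <- make_table(n_per_group = 10, p = 3, n_inf = 3, d = 2, seed = 6)
  fit <- train_modality_model(tab)
  fit$calibration$intercept <- 0
  fit$calibration$slope <- 0  # forces p = 0.5 everywhere
  cls <- predict(fit, tab, type = "class")
  expect_true(all(cls == 1L))
})

test_that("confusion_metrics computes the standard ratios", {
  truth <- c(rep(1, 10), rep(0, 10))
  pred <- c(rep(1, 9), 0, rep(0, 8), 1, 1)
  m <- confusion_metrics(truth, pred)
  expect_equal(unname(m["sensitivity"]), 0.90)
  expect_equal(unname(m["specificity"]), 0.80)
  expect_equal(unname(m["accuracy"]), 0.85)
  expect_equal(unname(m["balanced_accuracy"]), 0.85)

  expect_equal(unname(confusion_metrics(truth, truth)), rep(1, 4))
  inv <- confusion_metrics(truth, 1 - truth)
  expect_equal(unname(inv["accuracy"]), 0)
  expect_equal(unname(inv["balanced_accuracy"]), 0)
  expect_error(confusion_metrics(truth, pred[-1]), "length")
})

test_that("roc_and_auc matches hand values and handles edge rankings", {
  r <- roc_and_auc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8))
  expect_equal(r$auc, 0.75, tolerance = 1e-12)
  expect_equal(auc_rank_oracle(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8)), 0.75)

  expect_equal(roc_and_auc(c(0, 1, 0, 1), c(0.1, 0.9, 0.2, 0.8))$auc, 1)
  expect_equal(roc_and_auc(c(1, 1, 0, 0), c(0.1, 0.2, 0.8, 0.9))$auc, 0)
  # all scores tied: chance
  expect_equal(roc_and_auc(c(0, 1, 0, 1), rep(0.5, 4))$auc, 0.5)
  expect_error(roc_and_auc(c(1, 1), c(0.2, 0.3)), "both classes")
})

test_that("sweep AUC equals the Mann-Whitney oracle on random tied instances", {
  set.seed(7)
  for (i in 1:200) {
    n <- sample(4:50, 1)
    truth <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- round(runif(n), sample(1:3, 1))  # heavy ties
    expect_equal(roc_and_auc(truth, scores)$auc,
                 auc_rank_oracle(truth, scores), tolerance = 1e-12)
  }
})

test_that("mean_roc vertically averages on the grid", {
  grid <- seq(0, 1, by = 0.25)
  c1 <- roc_and_auc(c(0, 1, 0, 1), c(0.1, 0.9, 0.2, 0.8))  # perfect
  c2 <- roc_and_auc(c(1, 1, 0, 0), c(0.1, 0.2, 0.8, 0.9))  # anti-perfect

  # idempotence on identical curves
  m1 <- mean_roc(list(c1, c1), grid)
  expect_equal(m1$mean_tpr, c(1, 1, 1, 1, 1))
  expect_equal(m1$sd_tpr, rep(0, 5))

  # symmetric pair averages to 0.5 at interior grid points
  m2 <- mean_roc(list(c1, c2), grid)
  expect_equal(m2$mean_tpr[2:4], rep(0.5, 3))

  # independent per-point re-averaging on random curves
  set.seed(3)
  curves <- lapply(1:100, function(i) {
    truth <- sample(0:1, 20, replace = TRUE)
    if (length(unique(truth)) == 1) truth[1] <- 1 - truth[1]
    roc_and_auc(truth, runif(20))
  })
  grid2 <- seq(0, 1, by = 0.01)
  mm <- mean_roc(curves, grid2)
  per_curve <- sapply(curves, function(cv) {
    vapply(grid2, function(f) max(cv$tpr[cv$fpr <= f]), 0)
  })
  expect_equal(mm$mean_tpr, rowMeans(per_curve), tolerance = 1e-12)
  expect_true(all(diff(mm$mean_tpr) >= -1e-12))

  expect_error(mean_roc(list()), "empty")
})

test_that("repeated holdout evaluation stratifies splits and aggregates", {
  tab <- make_table(n_per_group = 20, p = 5, n_inf = 3, d = 1.5, seed = 10)
  ev <- repeated_holdout_evaluation(tab, config = eval_config(n_cycles = 30, seed = 2))
  expect_identical(nrow(ev$cycles), 30L)
  expect_true(all(ev$cycles$auc >= 0 & ev$cycles$auc <= 1))
  # mean AUC is exactly the arithmetic mean of the per-cycle AUCs
  expect_identical(unname(ev$mean["auc"]), mean(ev$cycles$auc))
  # deterministic on re-run
  ev2 <- repeated_holdout_evaluation(tab, config = eval_config(n_cycles = 30, seed = 2))
  expect_identical(ev$cycles, ev2$cycles)

  # 20+20 at 80/20: every cycle tests exactly 4+4 (8 predictions)
  # sensitivity and specificity are multiples of 1/4
  expect_true(all(abs(ev$cycles$sensitivity * 4 -
                        round(ev$cycles$sensitivity * 4)) < 1e-12))
  expect_true(all(abs(ev$cycles$specificity * 4 -
                        round(ev$cycles$specificity * 4)) < 1e-12))

  expect_error(repeated_holdout_evaluation(
    make_table(3, 3, seed = 1), config = eval_config(train_fraction = 0.1)),
    "infeasible")
})

test_that("well-separated classes give near-perfect repeated-holdout accuracy", {
  tab <- make_table(n_per_group = 20, p = 4, n_inf = 4, d = 3, seed = 12)
  ev <- repeated_holdout_evaluation(tab, config = eval_config(n_cycles = 100))
  expect_gte(ev$mean["accuracy"], 0.99)
  expect_gte(ev$mean["auc"], 0.99)
})

test_that("null-cohort accuracy is unbiased at chance across cohorts", {
  # conditional on one finite cohort the split-averaged accuracy wanders by
  # O(0.05-0.1); across independent null cohorts it must center on 0.5
  accs <- vapply(1:10, function(s) {
    tab <- make_table(n_per_group = 20, p = 8, n_inf = 0, d = 0, seed = s)
    repeated_holdout_evaluation(
      tab, config = eval_config(n_cycles = 150, seed = s + 900))$mean["accuracy"]
  }, 0)
  expect_lt(abs(mean(accs) - 0.5), 0.06)
})

test_that("mean AUC responds monotonically to the planted effect size", {
  mean_aucs <- vapply(c(0, 0.5, 1, 2), function(d) {
    tab <- make_table(n_per_group = 15, p = 4, n_inf = 4, d = d, seed = 77)
    repeated_holdout_evaluation(
      tab, config = eval_config(n_cycles = 60, seed = 5))$mean["auc"]
  }, 0)
  expect_true(all(diff(mean_aucs) > -0.02))
  expect_gt(mean_aucs[4], mean_aucs[1] + 0.2)
})

test_that("evaluation artifacts write cycles, metrics and the mean ROC", {
  tab <- make_table(n_per_group = 10, p = 3, n_inf = 2, d = 2, seed = 14)
  ev <- repeated_holdout_evaluation(tab, config = eval_config(n_cycles = 10))
  dir <- withr::local_tempdir()
  paths <- write_holdout_eval(ev, file.path(dir, "m"))
  expect_true(all(file.exists(paths)))
  roc <- utils::read.csv(paths[3])
  expect_identical(names(roc), c("fpr", "mean_tpr", "sd_tpr"))
  expect_identical(nrow(roc), 101L)
  met <- jsonlite::read_json(paths[2])
  expect_equal(met$mean$auc, unname(ev$mean["auc"]), tolerance = 1e-12)
})
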