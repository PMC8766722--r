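test_that("importance_filter keeps the boundary and ranks descending", {
  prof <- structure(
    data.frame(feature = c("A", "B", "C"),
               mean_importance = c(1.0, 0.6, 0.5),
               appearance_count = c(5L, 5L, 5L)),
    class = c("importance_profile", "data.frame"), method = "ebm")
  expect_identical(importance_filter(prof, 0.55), c("A", "B"))

  # removal is strictly "lesser than": the boundary value survives
  prof$mean_importance <- c(1.0, 0.55, 0.5)
  expect_identical(importance_filter(prof, 0.55), c("A", "B"))

  # all equal importances: everything retained
  prof$mean_importance <- rep(0.7, 3)
  expect_identical(importance_filter(prof, 0.55), c("A", "B", "C"))

  prof$mean_importance <- rep(NA_real_, 3)
  expect_error(importance_filter(prof, 0.55), "importance")
})

test_that("fbm_univariate matches the closed-form Student t and screens by p", {
  x <- cbind(sig = c(1, 2, 3, 4, 5, 6),
             nul = c(1, 5, 3, 3.2, 5.1, 0.9))
  rownames(x) <- paste0("s", 1:6)
  tab <- feature_table(x, c(0, 0, 0, 1, 1, 1))
  prof <- fbm_univariate(tab, p_threshold = 0.05)

  # CN (1,2,3) vs AD (4,5,6): t = 3/sqrt(2/3) = 3.674, df = 4, p ~ 0.0212
  expect_identical(prof$feature, "sig")
  expect_equal(prof$t_value, 3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(prof$p_value, 2 * pt(-3 / sqrt(2 / 3), df = 4),
               tolerance = 1e-12)
  expect_identical(attr(prof, "removed")$feature, "nul")
  expect_gt(attr(prof, "removed")$p_value, 0.5)

  # all features null -> empty survivor list, no error here
  tab0 <- feature_table(x[, "nul", drop = FALSE], c(0, 0, 0, 1, 1, 1))
  expect_identical(nrow(fbm_univariate(tab0)), 0L)

  # degenerate group sizes
  tab1 <- feature_table(x[1:3, ], c(0, 0, 1))
  expect_error(fbm_univariate(tab1), "at least 2 subjects")
})

test_that("correlation_prune applies the two-stage rules", {
  set.seed(1)
  base <- rnorm(30)
  x <- cbind(f1 = base, f2 = base + rnorm(30, sd = 1e-6),
             f3 = rnorm(30))
  rownames(x) <- paste0("s", 1:30)
  tab <- feature_table(x, rep(0:1, 15))

  # duplicate of the top feature is removed at stage 1
  res <- correlation_prune(tab, c("f1", "f2", "f3"))
  expect_identical(res$selected, c("f1", "f3"))
  expect_identical(res$removed$stage, "r_top")
  expect_identical(res$removed$anchor, "f1")

  # orthogonal features: no rule fires
  set.seed(2)
  xo <- matrix(rnorm(300), 30, 10,
               dimnames = list(paste0("s", 1:30), paste0("g", 1:10)))
  tabo <- feature_table(xo, rep(0:1, 15))
  reso <- correlation_prune(tabo, colnames(xo))
  expect_identical(reso$selected, colnames(xo))
  expect_identical(nrow(reso$removed), 0L)

  # constant feature is named in the error
  xc <- cbind(x, flat = rep(2, 30))
  tabc <- feature_table(xc, rep(0:1, 15))
  expect_error(correlation_prune(tabc, colnames(xc)), "flat")
})

test_that("correlation_prune agrees with the brute-force oracle on random instances", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(10:25, 1)
    p <- sample(3:10, 1)
    # correlated design: random factor mixture induces a range of |r| values
    f <- matrix(rnorm(n * 3), n, 3)
    w <- matrix(rnorm(3 * p), 3, p)
    x <- f %*% w + matrix(rnorm(n * p), n, p) * 0.5
    colnames(x) <- paste0("v", seq_len(p))
    rownames(x) <- paste0("s", seq_len(n))
    tab <- feature_table(x, rep_len(0:1, n))
    ranked <- sample(colnames(x))
    r_top <- runif(1, 0.3, 0.9)
    r_pw <- runif(1, 0.3, 0.9)
    got <- correlation_prune(tab, ranked, r_top, r_pw)$selected
    want <- prune_bruteforce(cor(x), ranked, r_top, r_pw)
    expect_identical(got, want)
  }
})

test_that("ebm_importance is deterministic, validated, and finds planted signal", {
  tab <- make_table(n_per_group = 10, p = 10, n_inf = 1, d = 3, seed = 5)
  cfg <- selection_config("ebm", subset_size = 4, n_runs = 40, ntree = 100,
                          seed = 9)
  prof1 <- ebm_importance(tab, cfg)
  prof2 <- ebm_importance(tab, cfg)
  expect_identical(prof1, prof2)
  expect_true(all(prof1$appearance_count > 0))
  expect_identical(sum(prof1$appearance_count), 40L * 4L)

  # the d = 3 feature should clearly top the ranking
  expect_identical(prof1$feature[1], "toy_roi001")

  expect_error(selection_config("ebm", n_runs = 0), "n_runs")
  expect_error(ebm_importance(make_table(4, 3, seed = 1), cfg),
               "subset_size")
  one_class <- feature_table(tab$x, rep(0, nrow(tab$x)))
  expect_error(ebm_importance(one_class, cfg), "both")
})

test_that("ebm importance is approximately exchangeable on pure-noise features", {
  tab <- make_table(n_per_group = 12, p = 6, n_inf = 0, d = 0, seed = 21)
  cfg <- selection_config("ebm", subset_size = 3, n_runs = 400, ntree = 100,
                          seed = 2)
  prof <- ebm_importance(tab, cfg)
  ratio <- max(prof$mean_importance) / min(prof$mean_importance)
  expect_lt(ratio, 1.5)
})

test_that("select_features runs the fixed stage order and truncates to the cap", {
  # plenty of independent signal: filter passes many, cap keeps 8
  tab <- make_table(n_per_group = 30, p = 40, n_inf = 20, d = 2, seed = 13)
  res <- select_features(tab, selection_config("fbm", max_features = 8))
  expect_length(res$selected, 8)
  expect_true(all(res$selected %in% paste0("toy_roi0", sprintf("%02d", 1:20))))
  expect_true("truncation" %in% res$removed$stage)

  # fewer survivors than the cap are returned as-is (19 -> few, PET-like)
  tab2 <- make_table(n_per_group = 20, p = 19, n_inf = 2, d = 1.8, seed = 3)
  res2 <- select_features(tab2, selection_config("fbm"))
  expect_lte(length(res2$selected), 8)
  expect_gte(length(res2$selected), 1)

  # audit is disjoint from the selection and covers all features
  expect_length(intersect(res$selected, res$removed$feature), 0)
  expect_setequal(c(res$selected, res$removed$feature), colnames(tab$x))

  # every feature failing the p filter -> explicit empty-selection error
  tab0 <- make_table(n_per_group = 10, p = 5, n_inf = 0, d = 0, seed = 31)
  expect_error(select_features(tab0, selection_config("fbm")),
               class = "neurofuse_empty_selection")

  # pipeline order: a feature highly correlated with the top one must fall
  # at the r_top stage even though its own statistic would rank it second
  set.seed(8)
  g <- rep(0:1, each = 15)
  sig <- g * 2 + rnorm(30)
  x <- cbind(a = sig, b = sig + rnorm(30, sd = 0.1), c = g * 1.5 + rnorm(30))
  rownames(x) <- paste0("s", 1:30)
  tab3 <- feature_table(x, g)
  res3 <- select_features(tab3, selection_config("fbm"))
  expect_true("b" %in% res3$removed$feature[res3$removed$stage == "r_top"])
  expect_false("b" %in% res3$selected)
})

test_that("selection results serialize to JSON with the full audit", {
  tab <- make_table(n_per_group = 15, p = 10, n_inf = 4, d = 2, seed = 17)
  res <- select_features(tab, selection_config("fbm", max_features = 3))
  path <- withr::local_tempfile(fileext = ".json")
  write_selection_result(res, path)
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_identical(js$selected, res$selected)
  expect_identical(js$correlation$features, colnames(res$correlation_matrix))
  expect_equal(js$correlation$matrix, unname(res$correlation_matrix),
               tolerance = 1e-12)
  expect_setequal(js$removed$feature, res$removed$feature)
})
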