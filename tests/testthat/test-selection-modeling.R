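# CV splits, robustness filtering, two-step selection, classifiers and the
# experiment engine.

test_that("stratified CV reproduces the 2-fold x 30 repetition arithmetic", {
  y <- c(rep(1, 8), rep(0, 129))
  splits <- make_cv_splits(y, folds = 2, repetitions = 30, seed = 1)
  expect_length(splits, 60)
  for (r in 1:30) {
    sp <- splits[(2 * r - 1):(2 * r)]
    # the two test folds partition the cohort
    expect_setequal(c(sp[[1]]$test, sp[[2]]$test), seq_along(y))
    expect_length(intersect(sp[[1]]$test, sp[[2]]$test), 0)
    # 8 events split 4/4
    expect_equal(sum(y[sp[[1]]$test]), 4)
    expect_equal(sum(y[sp[[2]]$test]), 4)
  }
  # train/test complement within every split
  for (sp in splits[1:6]) {
    expect_setequal(c(sp$train, sp$test), seq_along(y))
  }
  expect_identical(splits, make_cv_splits(y, 2, 30, seed = 1))
  expect_error(make_cv_splits(y, folds = 5), "infeasible stratification")
  expect_error(make_cv_splits(rep(1, 10), 2), "both classes")
})

test_that("per-fold class proportions stay within one member of global", {
  withr::with_seed(2, {
    y <- rbinom(101, 1, 0.3)
    splits <- make_cv_splits(y, folds = 3, repetitions = 5, seed = 3)
    for (sp in splits) {
      n_ev <- sum(y[sp$test])
      expect_lte(abs(n_ev - sum(y) / 3), 1)
    }
  })
})

test_that("robustness filter applies a strict threshold with stable order", {
  tab <- data.frame(feature = c("a", "b", "c"), icc = c(0.96, 0.8, 0.5))
  expect_equal(robustness_filter(tab, 0.75), c("a", "b"))
  expect_equal(robustness_filter(tab, 0), c("a", "b", "c"))
  tab2 <- rbind(tab, data.frame(feature = "d", icc = -0.2))
  expect_equal(robustness_filter(tab2, 0), c("a", "b", "c"))  # ICC > 0 only
  # monotone nesting of survivor sets
  withr::with_seed(4, {
    tabr <- data.frame(feature = sprintf("f%02d", 1:50), icc = runif(50, -0.2, 1))
    s0 <- robustness_filter(tabr, 0)
    s75 <- robustness_filter(tabr, 0.75)
    expect_true(all(s75 %in% s0))
  })
  expect_error(robustness_filter(tab, 0.99), "threshold 0.99")
  # undefined ICCs are non-robust
  tab3 <- data.frame(feature = c("a", "b"), icc = c(NA, 0.9))
  expect_equal(robustness_filter(tab3, 0), "b")
})

test_that("bootstrap-ANOVA ranking finds near-perfect separators and skips constants", {
  withr::with_seed(5, {
    y <- rep(c(0, 1), each = 50)
    X <- cbind(strong = y + rnorm(100, sd = 0.1),
               const = rep(1, 100),
               noise = rnorm(100))
    rk <- bootstrap_anova_rank(X, y, top_frac = 1, seed = 5)
    expect_equal(rk$feature[1], "strong")
    expect_equal(rk$frequency[1], 100)
    expect_equal(rk$frequency[rk$feature == "const"], 0)
  })
  expect_error(bootstrap_anova_rank(matrix(1, 4, 2), c(1, 0, 0, 0)),
               "at least 2")
})

test_that("correlation pruning removes the hub of correlated pairs", {
  withr::with_seed(6, {
    # construct r(a,b) ~ 0.9, r(a,c) ~ 0.9, r(b,c) ~ low
    z1 <- rnorm(4000); z2 <- rnorm(4000)
    a <- z1 + z2
    b <- 1.35 * z1 + 0.35 * rnorm(4000)
    cc <- 1.35 * z2 + 0.35 * rnorm(4000)
    X <- cbind(a = a, b = b, c = cc)
    expect_gt(abs(cor(a, b)), 0.6)
    expect_gt(abs(cor(a, cc)), 0.6)
    expect_lt(abs(cor(b, cc)), 0.3)
    keep <- prune_correlated(X, c("a", "b", "c"), r_cut = 0.6)
    expect_setequal(keep, c("b", "c"))
  })
  # duplicated column: exactly one survives
  withr::with_seed(7, {
    v <- rnorm(50)
    X2 <- cbind(x1 = v, x2 = v, y = rnorm(50))
    expect_length(prune_correlated(X2, c("x1", "x2", "y"), 0.6), 2)
  })
  # orthogonal features: all kept, capped at k_max
  withr::with_seed(8, {
    X3 <- matrix(rnorm(200 * 15), 200)
    colnames(X3) <- sprintf("o%02d", 1:15)
    keep3 <- prune_correlated(X3, colnames(X3), r_cut = 0.6, k_max = 10)
    expect_length(keep3, 10)
    expect_equal(keep3, colnames(X3)[1:10])
  })
})

test_that("mRMR selects by relevance first, then penalizes redundancy", {
  withr::with_seed(9, {
    y <- rep(c(0, 1), each = 40)
    # a single informative feature among pure noise is picked first
    X0 <- cbind(info = y + rnorm(80, sd = 0.3),
                n1 = rnorm(80), n2 = rnorm(80), n3 = rnorm(80))
    expect_equal(mrmr_select(X0, y, 1), "info")
    # a near-duplicate of the first pick is deprioritized by redundancy
    info <- y + rnorm(80, sd = 0.3)
    X <- cbind(info = info, dup = info + rnorm(80, sd = 0.05),
               n1 = rnorm(80), n2 = rnorm(80))
    sel <- mrmr_select(X, y, 3)
    expect_true(sel[1] %in% c("info", "dup"))
    expect_false(sel[2] %in% c("info", "dup"))
    # exhaustive selection returns everything in greedy order
    expect_setequal(mrmr_select(X, y, 4), colnames(X))
  })
  expect_error(mrmr_select(matrix(1, 4, 2), c(0, 1, 0, 1), 0), "positive")
})

test_that("every classifier separates a separable toy set and is deterministic", {
  withr::with_seed(10, {
    y <- rep(c(0, 1), each = 30)
    X <- cbind(f1 = y * 4 + rnorm(60, sd = 0.2),
               f2 = -2 * y + rnorm(60, sd = 0.2))
    for (clf in classifier_names()) {
      m <- train_classifier(clf, X, y, seed = 3)
      expect_equal(auc(predict(m, X), y), 1, tolerance = 1e-9)
      m2 <- train_classifier(clf, X, y, seed = 3)
      expect_equal(m$par, m2$par)
      expect_equal(predict(m, X), predict(m2, X))
    }
  })
  expect_error(train_classifier("boost", matrix(1, 4, 1), c(0, 1, 0, 1)),
               "unknown classifier")
})

test_that("evaluate_model scores robustness and generalizability correctly", {
  withr::with_seed(11, {
    y_tr <- rep(c(0, 1), each = 25)
    X_tr <- cbind(f = y_tr + rnorm(50, sd = 0.4))
    y_te <- rep(c(0, 1), each = 15)
    X_te <- cbind(f = y_te + rnorm(30, sd = 0.4))
    m <- train_classifier("ridge", X_tr, y_tr, seed = 1)
    # identity perturbations: ICC 1 and unchanged test AUC
    ev <- evaluate_model(m, X_tr, y_tr, X_te, y_te,
                         perturbed_test = list(X_te, X_te, X_te))
    expect_equal(ev$model_icc, 1)
    expect_equal(ev$test_auc, auc(predict(m, X_te), y_te))
    expect_equal(ev$gap, ev$test_auc - ev$train_auc)
    # pure per-perturbation noise: ICC near zero
    noise_tabs <- lapply(1:20, function(i) {
      cbind(f = rnorm(30))
    })
    ev2 <- evaluate_model(m, X_tr, y_tr, X_te, y_te, noise_tabs)
    expect_lt(abs(ev2$model_icc), 0.25)
    expect_error(evaluate_model(m, X_tr, y_tr, X_te, y_te, list(X_te)),
                 ">= 2")
  })
})

test_that("run_experiment produces the record-count identity and reproduces itself", {
  prof <- truth_profile(60, n_robust_informative = 3, n_fragile_informative = 1)
  sf <- generate_feature_table(80, profile = prof, n_replicates = 6, seed = 12)
  cfg <- experiment_config(classifiers = c("ridge", "knn"), repetitions = 3,
                           n_iter = 20, seed = 12)
  ex <- run_experiment(sf, cfg)
  expect_equal(nrow(ex$records), 6 * 3 * 2)  # splits x thresholds x classifiers
  expect_true(all(ex$records$threshold %in% c(0, 0.75, 0.95)))
  expect_true(all(ex$records$n_selected <= 10))
  expect_true(all(ex$records$train_auc >= 0 & ex$records$train_auc <= 1))
  ex2 <- run_experiment(sf, cfg)
  expect_identical(ex$records, ex2$records)
  # comparisons cover both metrics for both non-baseline thresholds
  expect_equal(nrow(ex$comparisons), 2 * 2 * 2)
})

test_that("feature robustness is computed from training patients only", {
  prof <- truth_profile(40, n_robust_informative = 2, n_fragile_informative = 0)
  sf <- generate_feature_table(60, profile = prof, n_replicates = 5, seed = 13)
  cfg <- experiment_config(classifiers = "ridge", repetitions = 2,
                           n_iter = 20, seed = 13)
  ex <- run_experiment(sf, cfg)
  # corrupt the replicate values of test-side patients in the first split:
  # selections and feature ICCs must not change for that split
  splits <- make_cv_splits(sf$outcomes$label, 2, 2, seed = 13)
  sf_corrupt <- sf
  sf_corrupt$replicates[splits[[1]]$test, , ] <-
    sf_corrupt$replicates[splits[[1]]$test, , ] * 1000 + 7
  icc_clean <- feature_icc_table(sf$replicates[splits[[1]]$train, , ])
  icc_corrupt <- feature_icc_table(sf_corrupt$replicates[splits[[1]]$train, , ])
  expect_identical(icc_clean, icc_corrupt)
  rec1 <- ex$records[ex$records$split == 1, ]
  ex_c <- run_experiment(sf_corrupt, cfg)
  expect_identical(rec1$selected,
                   ex_c$records[ex_c$records$split == 1, ]$selected)
})
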