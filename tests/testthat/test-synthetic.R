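# Synthetic phantom cohorts and calibrated feature tables.

test_that("phantom cohort honours size, event count and determinism", {
  ph <- generate_phantom_cohort(137, 8 / 137, image_shape = c(12, 12, 12),
                                seed = 1)
  expect_length(ph$patients, 137)
  expect_equal(sum(ph$outcomes$label), 8)
  # empty cohort
  ph0 <- generate_phantom_cohort(0, 0.5, seed = 1)
  expect_length(ph0$patients, 0)
  expect_equal(nrow(ph0$outcomes), 0)
  # single-class cohorts are allowed but flagged
  ph1 <- generate_phantom_cohort(5, 0, image_shape = c(10, 10, 10), seed = 1)
  expect_true(ph1$params$single_class)
  expect_error(generate_phantom_cohort(3, 0.5, image_shape = c(0, 5, 5)),
               "non-positive")
})

test_that("phantom masks are non-empty, interior, and reproducible bitwise", {
  ph <- generate_phantom_cohort(4, 0.5, image_shape = c(24, 24, 24),
                                spacing_mm = c(2, 2, 2), seed = 9)
  for (p in ph$patients) {
    expect_gt(mask_voxel_count(p$mask), 0)
    d <- dim(p$mask$data)
    # no foreground voxel touches the array boundary
    expect_equal(sum(p$mask$data[c(1, d[1]), , ]), 0)
    expect_equal(sum(p$mask$data[, c(1, d[2]), ]), 0)
    expect_equal(sum(p$mask$data[, , c(1, d[3])]), 0)
  }
  ph2 <- generate_phantom_cohort(4, 0.5, image_shape = c(24, 24, 24),
                                 spacing_mm = c(2, 2, 2), seed = 9)
  expect_identical(ph, ph2)
  # serialization is byte-identical per seed
  expect_identical(serialize(ph, NULL), serialize(ph2, NULL))
})

test_that("event cases carry the configured extra texture heterogeneity", {
  ph <- generate_phantom_cohort(40, 0.5, texture_effect = 1.5,
                                image_shape = c(20, 20, 20), seed = 12)
  roi_sd <- vapply(ph$patients, function(p) sd(p$image$data[p$mask$data > 0]), 0)
  y <- ph$outcomes$label
  expect_gt(mean(roi_sd[y == 1]), mean(roi_sd[y == 0]))
})

test_that("feature table generator is deterministic and validates input", {
  sf <- generate_feature_table(30, n_features = 10, n_informative = 2,
                               icc_profile = rep(0.8, 10), seed = 4)
  sf2 <- generate_feature_table(30, n_features = 10, n_informative = 2,
                                icc_profile = rep(0.8, 10), seed = 4)
  expect_identical(sf, sf2)
  expect_equal(dim(sf$features), c(30, 10))
  expect_equal(dim(sf$replicates), c(30, 20, 10))
  expect_equal(sum(sf$outcomes$label), 6)  # round(0.2 * 30)
  expect_error(generate_feature_table(-1), "negative")
  expect_error(generate_feature_table(10, 5, icc_profile = rep(1, 5)),
               "target ICC")
  expect_error(generate_feature_table(10, 5, icc_profile = rep(0.5, 3)),
               "length")
  expect_error(generate_feature_table(10, 5, n_informative = 9,
                                      icc_profile = rep(0.5, 5)),
               "n_informative")
})

test_that("replicate noise is calibrated to the target ICC", {
  targets <- c(0.2, 0.5, 0.75, 0.95, 0.99)
  est <- sapply(1:20, function(s) {
    sf <- generate_feature_table(200, n_features = 5, n_informative = 0,
                                 icc_profile = targets, n_replicates = 20,
                                 seed = s)
    feature_icc_table(sf$replicates)$icc
  })
  expect_lt(max(abs(rowMeans(est) - targets)), 0.03)
})

test_that("a strong robust effect feature is ranked first by selection", {
  prof <- truth_profile(40, n_robust_informative = 1,
                        n_fragile_informative = 0, effect_robust = 2.0)
  sf <- generate_feature_table(150, profile = prof, seed = 6)
  rk <- bootstrap_anova_rank(sf$features, sf$outcomes$label, seed = 6)
  expect_equal(rk$feature[1], "f001")
  expect_equal(rk$frequency[1], 100)
})

test_that("with no informative features selection frequencies look uniform", {
  prof <- truth_profile(60, n_robust_informative = 0,
                        n_fragile_informative = 0, noise_df_fragile = Inf)
  sf <- generate_feature_table(120, profile = prof, seed = 8)
  rk <- bootstrap_anova_rank(sf$features, sf$outcomes$label, top_frac = 1,
                             seed = 8)
  # null hit rate per iteration is ~p_cut on average; per-feature counts are
  # overdispersed relative to a binomial because iterations reuse the same
  # cohort, so only the pooled rate and the returned-count rule are checked
  pooled <- mean(rk$frequency) / 100
  expect_lt(abs(pooled - 0.1), 0.08)
  rk10 <- bootstrap_anova_rank(sf$features, sf$outcomes$label, top_frac = 0.1,
                               seed = 8)
  expect_equal(nrow(rk10), ceiling(0.1 * 60))
})

test_that("truth profile structure matches its calibration targets", {
  prof <- truth_profile()
  expect_equal(nrow(prof), 400)
  expect_equal(mean(prof$target_icc > 0.95), 0.11, tolerance = 0.01)
  expect_equal(mean(prof$target_icc > 0.75), 0.50, tolerance = 0.01)
  expect_false(any(duplicated(prof$feature)))
  expect_true(all(prof$target_icc >= 0 & prof$target_icc < 1))
  expect_error(truth_profile(20, n_robust_informative = 19), "exceed")
})
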