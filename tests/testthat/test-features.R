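# Radiomic feature extractor: first-order, shape, texture matrices.

test_that("first-order features match hand computations", {
  f <- extract_firstorder(c(1, 2, 3, 4), n_bins = 4)
  expect_equal(unname(f["mean"]), 2.5)
  expect_equal(unname(f["variance"]), 1.25)  # population variance
  expect_equal(unname(f["median"]), 2.5)
  expect_equal(unname(f["energy"]), 1 + 4 + 9 + 16)
  expect_equal(unname(f["rms"]), sqrt(30 / 4))
  expect_equal(unname(f["entropy"]), 2)  # 4 equally filled bins
  expect_equal(unname(f["uniformity"]), 0.25)
  # constant ROI: degenerate distribution
  fc <- suppressWarnings(extract_firstorder(rep(5, 20), n_bins = 16))
  expect_equal(unname(fc["variance"]), 0)
  expect_equal(unname(fc["entropy"]), 0)
  expect_equal(unname(fc["uniformity"]), 1)
  # symmetric sample: zero skewness
  v <- c(-3, -1, 0, 1, 3)
  expect_lt(abs(extract_firstorder(v, 4)["skewness"]), 1e-12)
  expect_error(extract_firstorder(numeric(0)), "empty")
})

test_that("shape features recover analytic sphere and cube geometry", {
  s <- extract_shape(sphere_mask(20, c(1, 1, 1)))
  expect_lt(abs(s[["volume"]] / (4 / 3 * pi * 20^3) - 1), 0.03)
  expect_gte(s[["sphericity"]], 0.95)
  expect_lte(s[["sphericity"]], 1.02)
  expect_lt(abs(s[["max_diameter_3d"]] / 40 - 1), 0.06)
  expect_gt(s[["elongation"]], 0.97)  # isotropic object
  expect_gt(s[["flatness"]], 0.97)
  cube <- extract_shape(binary_mask(array(1, c(80, 80, 80))))
  expect_equal(cube[["sphericity"]], 0.806, tolerance = 0.02)
  one <- extract_shape(binary_mask(array(c(rep(0, 13), 1, rep(0, 13)),
                                         c(3, 3, 3))))
  expect_equal(one[["volume"]], 1)
  expect_error(extract_shape(binary_mask(array(0, c(3, 3, 3)))), "empty")
})

test_that("texture features on hand-enumerable ROIs", {
  # constant ROI: zero contrast, a single zone
  bc <- array(1, c(3, 3, 3))
  expect_equal(unname(texture_features(bc, "glcm", 2)["glcm_contrast"]), 0)
  zones <- radrobust:::glszm_zones(bc)
  expect_equal(nrow(zones), 1)
  expect_equal(zones$size, 27)
  # 2-voxel ROI, values 1 and 2: symmetric pair counts, contrast 1
  b2 <- array(NA_real_, c(2, 1, 1)); b2[, 1, 1] <- c(1, 2)
  f2 <- texture_features(b2, "glcm", 2)
  expect_equal(unname(f2["glcm_contrast"]), 1)
  expect_equal(unname(f2["glcm_joint_energy"]), 0.5)  # p = (1/2, 1/2) off-diagonal
  # 1x1x4 ROI with bins (1,1,2,2): two runs of length 2 along the line
  b4 <- array(NA_real_, c(1, 1, 4)); b4[1, 1, ] <- c(1, 1, 2, 2)
  runs <- radrobust:::glrlm_runs_one(b4, c(0, 0, 1))
  expect_equal(runs$len, c(2, 2))
  expect_equal(sort(runs$g), c(1, 2))
  expect_error(texture_features(array(NA_real_, c(2, 2, 2)), "glcm"), "ROI")
})

test_that("texture features equal naive brute-force on random ROIs", {
  dirs <- bf_dir_pairs()
  for (seed in c(1, 2, 3)) {
    bins <- random_roi(c(8, 9, 7), n_bins = 4, seed = seed, p_na = 0.1)
    n_vox <- sum(!is.na(bins))
    # GLCM: per-direction matrices and the direction-averaged features
    acc <- NULL
    for (r in seq_len(nrow(dirs))) {
      M_pkg <- radrobust:::glcm_matrix(bins, 4, dirs[r, ])
      M_bf <- bf_glcm(bins, 4, dirs[r, ])
      expect_equal(M_pkg, M_bf)
      f <- radrobust:::glcm_features_one(M_bf)
      acc <- if (is.null(acc)) f else acc + f
    }
    f_pkg <- texture_features(bins, "glcm", 4)
    expect_equal(unname(f_pkg), unname(acc / nrow(dirs)), tolerance = 1e-10)
    # GLRLM: run lists per direction, then the averaged feature vector
    acc_r <- NULL
    for (r in seq_len(nrow(dirs))) {
      runs_bf <- bf_runs(bins, dirs[r, ])
      runs_pkg <- radrobust:::glrlm_runs_one(bins, dirs[r, ])
      expect_equal(sort(runs_pkg$len * 100 + runs_pkg$g),
                   sort(runs_bf$len * 100 + runs_bf$g))
      fr <- bf_rlm_features(runs_bf$g, runs_bf$len, 4, n_vox)
      acc_r <- if (is.null(acc_r)) fr else acc_r + fr
    }
    expect_equal(unname(texture_features(bins, "glrlm", 4)),
                 unname(acc_r / nrow(dirs)), tolerance = 1e-8)
    # GLSZM: zone list from igraph components vs naive flood fill
    z_bf <- bf_zones(bins)
    expect_equal(unname(texture_features(bins, "glszm", 4)),
                 unname(bf_rlm_features(z_bf$g, z_bf$size, 4, n_vox)),
                 tolerance = 1e-8)
  }
})

test_that("texture features are invariant to order-preserving relabeling", {
  bins <- random_roi(c(7, 7, 7), n_bins = 5, seed = 4)
  # a monotone intensity transform with identical binning gives identical
  # bin indices, hence identical features by construction; verify through
  # the discretization layer
  withr::with_seed(5, {
    v <- rnorm(200)
    b1 <- discretize(v, 6)
    b2 <- discretize(exp(v), 6)  # monotone but nonlinear: bins may differ
    b3 <- discretize(2 * v + 3, 6)  # affine: bins identical
    expect_identical(b1, b3)
  })
  f1 <- texture_features(bins, "glcm", 5)
  expect_identical(f1, texture_features(bins, "glcm", 5))
})

test_that("direction-averaged GLCM features are stable under 90-degree rotation", {
  ph <- generate_phantom_cohort(1, 0, image_shape = c(24, 24, 24), seed = 6)
  p <- ph$patients[[1]]
  sel <- p$mask$data > 0
  bins <- array(NA_real_, dim(sel))
  bins[sel] <- discretize(p$image$data[sel], 16)
  # rotate the discretized volume by exactly 90 degrees about SI (axis 3)
  rot_arr <- function(a) aperm(a[dim(a)[1]:1, , , drop = FALSE], c(2, 1, 3))
  f0 <- texture_features(bins, "glcm", 16)
  f90 <- texture_features(rot_arr(bins), "glcm", 16)
  expect_equal(f0, f90, tolerance = 0.01)
})

test_that("extract_all obeys the configured count identity and determinism", {
  cfg <- preprocess_config(bin_counts = c(8, 16), log_sigmas_mm = 2,
                           wavelet = FALSE)
  ph <- generate_phantom_cohort(1, 0, image_shape = c(16, 16, 16),
                                spacing_mm = c(1, 1, 1), seed = 3)
  p <- ph$patients[[1]]
  fv <- extract_all(p$image, p$mask, cfg)
  n_img <- 1 + 1  # original + one LoG
  n_bins <- 2
  expected <- 6 + n_img * 11 + n_img * n_bins * (2 + 11 + 16 + 16)
  expect_length(fv, expected)
  expect_false(any(duplicated(names(fv))))
  expect_equal(attr(fv, "n_missing"), 0)
  fv2 <- extract_all(p$image, p$mask, cfg)
  expect_equal(as.vector(fv), as.vector(fv2))
  # single image, first-order only pathway: count check via bank size
  cfg1 <- preprocess_config(bin_counts = 8, log_sigmas_mm = 1, wavelet = FALSE)
  fv1 <- extract_all(p$image, p$mask, cfg1)
  expect_length(fv1, 6 + 2 * 11 + 2 * 1 * (2 + 11 + 16 + 16))
})

test_that("empty re-segmented masks flag intensity features as missing", {
  arr <- array(1000, c(10, 10, 10))  # all voxels outside [-150, 180]
  msk <- array(0, c(10, 10, 10)); msk[4:7, 4:7, 4:7] <- 1
  fv <- extract_all(image_volume(arr), binary_mask(msk),
                    preprocess_config(bin_counts = 8, log_sigmas_mm = 1,
                                      wavelet = FALSE))
  expect_true(attr(fv, "roi_empty"))
  expect_false(any(is.na(fv[startsWith(names(fv), "shape_")])))
  expect_true(all(is.na(fv[!startsWith(names(fv), "shape_")])))
})
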