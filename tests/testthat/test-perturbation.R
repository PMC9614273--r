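# Perturbation grid, sampling, rigid transforms, noise fields, contour
# randomization, Dice and Hausdorff.

test_that("default grid reproduces the published combination counts", {
  g <- build_perturbation_grid()
  expect_equal(g$counts$translation, 4096)
  expect_equal(g$counts$total, 4423680)
  expect_length(g$translations_mm, 16)
  expect_length(g$rotations_deg, 9)
  expect_length(g$noise_levels, 4)
  expect_equal(g$n_contours, 30)
})

test_that("grid size is the product of its factor cardinalities", {
  for (seed in 1:10) {
    withr::with_seed(seed, {
      tr <- seq(0, runif(1, 1, 4), length.out = sample(1:6, 1))
      ro <- seq(-20, 20, length.out = sample(1:5, 1))
      no <- 0:sample(0:4, 1)
      nc <- sample(1:10, 1)
      g <- build_perturbation_grid(tr, ro, no, nc)
      expect_equal(g$counts$total,
                   length(tr)^3 * length(ro) * length(no) * nc)
    })
  }
  g1 <- build_perturbation_grid(0, 0, 0, 1)
  expect_equal(g1$counts$total, 1)
  expect_error(build_perturbation_grid(numeric(0)), "empty")
})

test_that("per-patient perturbation sampling is distinct and reproducible", {
  g <- build_perturbation_grid()
  s1 <- sample_perturbations(g, 60, "P0001", seed = 9)
  expect_equal(nrow(s1), 60)
  expect_equal(nrow(unique(s1)), 60)
  # all sampled values are grid members
  expect_true(all(s1$t_lm %in% g$translations_mm))
  expect_true(all(s1$rotation_deg %in% g$rotations_deg))
  expect_true(all(s1$noise_level %in% g$noise_levels))
  expect_true(all(s1$contour_index %in% seq_len(g$n_contours)))
  expect_identical(s1, sample_perturbations(g, 60, "P0001", seed = 9))
  s2 <- sample_perturbations(g, 60, "P0002", seed = 9)
  expect_false(identical(s1, s2))
})

test_that("an exhaustive draw on a tiny grid enumerates it exactly once", {
  g <- build_perturbation_grid(c(0, 1), c(0, 5), 0:1, 2)
  n <- g$counts$total
  s <- sample_perturbations(g, n, "P1", seed = 1)
  expect_equal(nrow(unique(s)), n)
  expect_error(sample_perturbations(g, n + 1, "P1", seed = 1), "distinct")
})

test_that("identity rigid transform leaves image and mask untouched", {
  ph <- generate_phantom_cohort(1, 0, image_shape = c(24, 24, 24), seed = 4)
  p <- ph$patients[[1]]
  out <- apply_rigid(p$image, p$mask, c(0, 0, 0), 0)
  expect_identical(out$image$data, p$image$data)
  expect_identical(out$mask$data, p$mask$data)
})

test_that("translation moves the mask centroid by the requested amount", {
  m <- sphere_mask(10, c(1, 1, 1))
  img <- image_volume(array(0, dim(m$data)), m$spacing)
  out <- apply_rigid(img, m, t_mm = c(1, 0, 0), angle_deg = 0)
  shift <- unname(mask_centroid(out$mask) - mask_centroid(m))
  expect_equal(shift[1], 1.0, tolerance = 0.1)
  expect_lt(max(abs(shift[2:3])), 0.1)
})

test_that("rotation about SI conserves sphere volume and is invertible", {
  m <- sphere_mask(12, c(1, 1, 1))
  img <- image_volume(array(rnorm(length(m$data)), dim(m$data)), m$spacing)
  rot <- apply_rigid(img, m, angle_deg = 90)
  expect_lt(abs(mask_volume_mm3(rot$mask) / mask_volume_mm3(m) - 1), 0.02)
  # forward then inverse recovers the mask up to interpolation error
  fwd <- apply_rigid(img, m, t_mm = c(1.4, 0.6, 2), angle_deg = 15)
  back <- apply_rigid(fwd$image, fwd$mask, t_mm = -c(1.4, 0.6, 2) , angle_deg = 0)
  back2 <- apply_rigid(back$image, back$mask, t_mm = c(0, 0, 0), angle_deg = -15)
  expect_gte(dice(back2$mask, m), 0.95)
  expect_error(apply_rigid(img, binary_mask(array(0, dim(m$data)), m$spacing)),
               "empty mask")
})

test_that("noise field has the configured level-scaled standard deviation", {
  img <- image_volume(array(0, c(50, 50, 50)))
  expect_identical(add_noise_field(img, 0, 10, seed = 1)$data, img$data)
  out <- add_noise_field(img, 2, 10, seed = 1)
  delta <- out$data - img$data
  expect_lt(abs(sd(delta) / 20 - 1), 0.05)
  expect_lt(abs(mean(delta)), 3 * 20 / sqrt(length(delta)))
  expect_identical(out$data, add_noise_field(img, 2, 10, seed = 1)$data)
  expect_error(add_noise_field(img, -1), "level")
  expect_error(add_noise_field(img, 1, sigma_base = -5), "sigma_base")
})

test_that("dice matches direct counts and handles edge cases", {
  a <- sphere_mask(8, c(1, 1, 1))
  expect_equal(dice(a, a), 1)
  empty <- binary_mask(array(0, dim(a$data)), a$spacing)
  expect_equal(dice(empty, empty), 1)
  expect_equal(dice(a, empty), 0)
  # hand case: |A| = 4, |B| = 4, overlap 2
  arrA <- array(0, c(4, 4, 1)); arrA[1:4, 1, 1] <- 1
  arrB <- array(0, c(4, 4, 1)); arrB[3:4, 1, 1] <- 1; arrB[1:2, 2, 1] <- 1
  expect_equal(dice(binary_mask(arrA), binary_mask(arrB)), 0.5)
  b <- binary_mask(array(1, c(2, 2, 2)))
  expect_error(dice(a, b), "grid mismatch")
})

test_that("hausdorff equals brute force in physical units", {
  a <- sphere_mask(6, c(1, 1, 1))
  expect_equal(hausdorff(a, a), 0)
  # unit cube shifted 2 voxels at 1 mm
  arrA <- array(0, c(8, 8, 8)); arrA[2:4, 2:4, 2:4] <- 1
  arrB <- array(0, c(8, 8, 8)); arrB[4:6, 2:4, 2:4] <- 1
  expect_equal(hausdorff(binary_mask(arrA), binary_mask(arrB)), 2)
  # anisotropic spacing: 1-voxel shift along the 3 mm axis
  arrC <- array(0, c(6, 6, 6)); arrC[2:4, 2:4, 2] <- 1
  arrD <- array(0, c(6, 6, 6)); arrD[2:4, 2:4, 3] <- 1
  expect_equal(hausdorff(binary_mask(arrC, spacing = c(1, 1, 3)),
                         binary_mask(arrD, spacing = c(1, 1, 3))), 3)
  # property: random blob pairs match the naive double loop
  for (seed in 1:5) {
    ms <- withr::with_seed(seed, {
      arr1 <- array(runif(6^3) < 0.4, c(6, 6, 6))
      arr2 <- array(runif(6^3) < 0.4, c(6, 6, 6))
      list(binary_mask(arr1, spacing = c(1, 2, 1.5)),
           binary_mask(arr2, spacing = c(1, 2, 1.5)))
    })
    if (mask_voxel_count(ms[[1]]) > 0 && mask_voxel_count(ms[[2]]) > 0) {
      expect_equal(hausdorff(ms[[1]], ms[[2]]), bf_hausdorff(ms[[1]], ms[[2]]),
                   tolerance = 1e-10)
    }
  }
  expect_error(hausdorff(a, binary_mask(array(0, dim(a$data)), a$spacing)),
               "empty")
})

test_that("contour randomization respects its constraints", {
  m <- sphere_mask(15, c(2, 2, 2))
  out <- randomize_contour(m, contour_seed = 3)
  expect_gte(dice(m, out), 0.75)
  expect_lte(hausdorff(m, out), 5)
  expect_gt(mask_voxel_count(out), 0)
  # amplitude 0 is the identity field
  expect_identical(randomize_contour(m, 1, amplitude_mm = 0)$data, m$data)
  # determinism per contour seed
  expect_identical(randomize_contour(m, contour_seed = 3)$data, out$data)
  # infeasible constraints fail loudly, naming the violation
  expect_error(
    randomize_contour(m, 1, dice_min = 0.9999, hd_max = 5, amplitude_mm = 8,
                      max_attempts = 5),
    "failed after 5 attempts")
})
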