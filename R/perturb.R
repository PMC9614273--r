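# The four perturbation modes: rigid translation + rotation, Gaussian noise
# field, and contour randomization under Dice/Hausdorff constraints, plus
# the parameter grid they are drawn from.

#' Build the perturbation parameter grid
#'
#' The default grid is translations 0..3 mm in 0.2 mm steps independently on
#' the three anatomical axes (16 values each, 4,096 translation vectors),
#' rotations -20..20 degrees in 5-degree steps about the SI axis (9 values),
#' integer noise levels 0..3, and 30 contour randomizations: 4,423,680
#' combinations in total.
#'
#' @param translations_mm translation values per axis (mm), applied to each
#'   of LM/AP/SI independently.
#' @param rotations_deg rotation angles about the SI axis.
#' @param noise_levels integer noise multipliers (>= 0).
#' @param n_contours number of contour-randomization indices.
#' @return object of class `perturbation_grid` with element `counts`
#'   (translation sub-grid and total).
#' @export
build_perturbation_grid <- function(translations_mm = seq(0, 3, by = 0.2),
                                    rotations_deg = seq(-20, 20, by = 5),
                                    noise_levels = 0:3,
                                    n_contours = 30) {
  if (length(translations_mm) == 0 || length(rotations_deg) == 0 ||
      length(noise_levels) == 0 || n_contours < 1) {
    stop("empty perturbation range after discretization")
  }
  if (any(noise_levels < 0)) stop("noise levels must be >= 0")
  n_t <- length(translations_mm)^3
  total <- n_t * length(rotations_deg) * length(noise_levels) * n_contours
  structure(
    list(translations_mm = translations_mm,
         rotations_deg = rotations_deg,
         noise_levels = as.integer(noise_levels),
         n_contours = as.integer(n_contours),
         counts = list(translation = n_t, total = total)),
    class = "perturbation_grid"
  )
}

#' @export
print.perturbation_grid <- function(x, ...) {
  cat(sprintf(
    "<perturbation_grid> %d translations x %d rotations x %d noise x %d contours = %s combinations\n",
    x$counts$translation, length(x$rotations_deg), length(x$noise_levels),
    x$n_contours, format(x$counts$total, big.mark = ",")))
  invisible(x)
}

# Decode 1-based linear indices into grid coordinates (mixed radix, with
# the LM translation varying fastest).
decode_grid_index <- function(grid, idx) {
  nt <- length(grid$translations_mm)
  nr <- length(grid$rotations_deg)
  nn <- length(grid$noise_levels)
  i <- idx - 1
  i_lm <- i %% nt; i <- i %/% nt
  i_ap <- i %% nt; i <- i %/% nt
  i_si <- i %% nt; i <- i %/% nt
  i_rot <- i %% nr; i <- i %/% nr
  i_noise <- i %% nn; i <- i %/% nn
  i_contour <- i
  data.frame(
    t_lm = grid$translations_mm[i_lm + 1],
    t_ap = grid$translations_mm[i_ap + 1],
    t_si = grid$translations_mm[i_si + 1],
    rotation_deg = grid$rotations_deg[i_rot + 1],
    noise_level = grid$noise_levels[i_noise + 1],
    contour_index = as.integer(i_contour + 1)
  )
}

#' Sample distinct perturbations for one patient
#'
#' Draws `n` distinct grid combinations. The draw is a pure function of
#' `(seed, patient_id)`: the same pair reproduces the same list, and
#' different patients get independent draws under one study seed.
#'
#' @param grid a [build_perturbation_grid()] object.
#' @param n number of perturbations (default 60, as drawn per patient from
#'   the full grid in the motivating design).
#' @param patient_id string identifying the patient stream.
#' @param seed study-level integer seed.
#' @return data.frame of perturbation specs (one row each) with columns
#'   `t_lm`, `t_ap`, `t_si` (mm), `rotation_deg`, `noise_level`,
#'   `contour_index`.
#' @export
sample_perturbations <- function(grid, n = 60, patient_id = "P0001", seed = 1) {
  total <- grid$counts$total
  if (n > total) stop("cannot draw ", n, " distinct specs from a grid of ", total)
  idx <- with_seed(derive_seed(seed, paste0("perturb:", patient_id)), {
    if (total <= .Machine$integer.max) {
      sample.int(total, n)
    } else {
      # rejection sampling of distinct doubles for astronomically large grids
      out <- unique(floor(stats::runif(2 * n, 0, total))) + 1
      while (length(out) < n) {
        out <- unique(c(out, floor(stats::runif(n, 0, total)) + 1))
      }
      out[seq_len(n)]
    }
  })
  decode_grid_index(grid, idx)
}

#' Rigid translation + rotation of an image/mask pair
#'
#' Rotates about the SI axis through the mask centroid, then translates;
#' both volumes move simultaneously and are resampled on the input grid
#' (image: cubic interpolation, mask: trilinear + 0.5 threshold).
#'
#' @param image an `image_volume`.
#' @param mask a non-empty `binary_mask` on the same grid.
#' @param t_mm translation in mm, order (LM, AP, SI).
#' @param angle_deg rotation angle about SI.
#' @return list with transformed `image` and `mask`.
#' @export
apply_rigid <- function(image, mask, t_mm = c(0, 0, 0), angle_deg = 0) {
  stopifnot_same_grid(image, mask)
  if (mask_voxel_count(mask) == 0L) stop("empty mask: rigid transform undefined")
  if (all(t_mm == 0) && angle_deg == 0) {
    return(list(image = image, mask = mask))
  }
  ctr <- mask_centroid(mask)
  d <- dim(image$data)
  ax <- lapply(1:3, function(a) image$origin[a] + (seq_len(d[a]) - 1) * image$spacing[a])
  g <- expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]])
  # inverse map: undo translation, then rotate by -angle about the centroid
  px <- g$x - t_mm[1]; py <- g$y - t_mm[2]; pz <- g$z - t_mm[3]
  th <- -angle_deg * pi / 180
  rx <- ctr[1] + cos(th) * (px - ctr[1]) - sin(th) * (py - ctr[2])
  ry <- ctr[2] + sin(th) * (px - ctr[1]) + cos(th) * (py - ctr[2])
  coords <- cbind((rx - image$origin[1]) / image$spacing[1] + 1,
                  (ry - image$origin[2]) / image$spacing[2] + 1,
                  (pz - image$origin[3]) / image$spacing[3] + 1)
  img_new <- array(interp3(image$data, coords, "cubic"), d)
  msk_new <- array(interp_mask(mask$data, coords), d)
  list(image = image_volume(img_new, image$spacing, image$origin),
       mask = binary_mask(msk_new, mask$spacing, mask$origin))
}

#' Add a Gaussian noise field to an image
#'
#' Zero-mean white Gaussian noise with standard deviation
#' `level * sigma_base` HU; level 0 returns the input unchanged. The noise
#' levels of the perturbation grid are unitless multipliers; `sigma_base`
#' fixes their physical scale.
#'
#' @param image an `image_volume`.
#' @param level integer noise level (>= 0).
#' @param sigma_base noise sd per level step in HU (default 10).
#' @param seed integer seed; the field is deterministic per seed.
#' @return an `image_volume`.
#' @export
add_noise_field <- function(image, level, sigma_base = 10, seed = 1) {
  if (level < 0) stop("noise level must be >= 0")
  if (sigma_base < 0) stop("sigma_base must be non-negative")
  if (level == 0 || sigma_base == 0) return(image)
  noise <- with_seed(derive_seed(seed, "noise"), {
    array(stats::rnorm(length(image$data), 0, level * sigma_base),
          dim(image$data))
  })
  image_volume(image$data + noise, image$spacing, image$origin)
}

#' Dice similarity index of two masks
#' @param a,b `binary_mask`s on the same grid.
#' @return `2|A intersect B| / (|A| + |B|)`; 1.0 when both masks are empty.
#' @export
dice <- function(a, b) {
  stopifnot_same_grid(a, b)
  na <- sum(a$data > 0); nb <- sum(b$data > 0)
  if (na + nb == 0L) return(1.0)
  2 * sum(a$data > 0 & b$data > 0) / (na + nb)
}

# Largest of the two directed max-min surface distances, pairwise over
# surface voxels in physical units.
directed_max_min <- function(pa, pb) {
  # chunk rows of pa to bound the distance-matrix size
  step <- max(1L, floor(2e6 / nrow(pb)))
  worst <- 0
  for (s in seq(1L, nrow(pa), by = step)) {
    rows <- s:min(s + step - 1L, nrow(pa))
    d2 <- outer(rowSums(pa[rows, , drop = FALSE]^2), rowSums(pb^2), `+`) -
      2 * pa[rows, , drop = FALSE] %*% t(pb)
    worst <- max(worst, max(apply(d2, 1, min)))
  }
  sqrt(max(worst, 0))
}

#' Hausdorff distance between two masks (mm)
#'
#' Classical (100th percentile) symmetric Hausdorff distance between the
#' surface voxels of the two masks, in physical units.
#'
#' @param a,b non-empty `binary_mask`s on the same grid.
#' @param spacing optional spacing override (defaults to the masks' own).
#' @return distance in mm.
#' @export
hausdorff <- function(a, b, spacing = NULL) {
  stopifnot_same_grid(a, b)
  if (mask_voxel_count(a) == 0L || mask_voxel_count(b) == 0L) {
    stop("Hausdorff distance undefined for an empty mask")
  }
  sp <- spacing %||% a$spacing
  pa <- sweep(mask_surface_indices(a) - 1, 2, sp, `*`)
  pb <- sweep(mask_surface_indices(b) - 1, 2, sp, `*`)
  max(directed_max_min(pa, pb), directed_max_min(pb, pa))
}

#' Randomize a contour with a smooth deformable vector field
#'
#' Draws a 3-channel white-noise field, smooths it with a Gaussian kernel of
#' width `dvf_sigma_mm`, scales it to a target mean surface displacement,
#' warps the mask, and accepts the result only when it satisfies the Dice
#' and Hausdorff constraints (rejection sampling, deterministic per
#' `contour_seed`).
#'
#' @param mask a non-empty `binary_mask`.
#' @param contour_seed integer seed of the randomization stream.
#' @param dice_min minimum Dice similarity against the input (default 0.75).
#' @param hd_max maximum Hausdorff distance in mm (default 5).
#' @param amplitude_mm target mean displacement magnitude at the surface;
#'   each attempt jitters it by a uniform factor in \[0.5, 1.5\].
#' @param dvf_sigma_mm smoothness (Gaussian width) of the vector field.
#' @param max_attempts rejection-sampling budget.
#' @return an accepted `binary_mask`. Errors, naming the violated
#'   constraint, if no attempt within the budget satisfies both.
#' @export
randomize_contour <- function(mask, contour_seed = 1, dice_min = 0.75,
                              hd_max = 5, amplitude_mm = 2,
                              dvf_sigma_mm = 5, max_attempts = 100) {
  if (mask_voxel_count(mask) == 0L) stop("empty mask cannot be randomized")
  if (dice_min <= 0 || dice_min > 1) stop("dice_min must be in (0, 1]")
  if (hd_max <= 0) stop("hd_max must be positive")
  if (amplitude_mm == 0) return(mask)
  d <- dim(mask$data)
  sp <- mask$spacing
  surf <- mask_surface_indices(mask)
  last_fail <- "no attempt made"
  res <- with_seed(derive_seed(contour_seed, "contour"), {
    for (attempt in seq_len(max_attempts)) {
      amp <- amplitude_mm * stats::runif(1, 0.5, 1.5)
      disp <- lapply(1:3, function(a) {
        gaussian_smooth3(array(stats::rnorm(prod(d)), d), dvf_sigma_mm, sp)
      })
      mag_surf <- sqrt(Reduce(`+`, lapply(1:3, function(a) {
        (disp[[a]][surf] * sp[a])^2
      })))
      scale <- if (mean(mag_surf) > 0) amp / mean(mag_surf) else 0
      # inverse-warp: sample the original mask at index + displacement
      base <- as.matrix(expand.grid(seq_len(d[1]), seq_len(d[2]), seq_len(d[3])))
      coords <- base + scale * cbind(as.vector(disp[[1]]), as.vector(disp[[2]]),
                                     as.vector(disp[[3]]))
      warped <- binary_mask(array(interp_mask(mask$data, coords), d),
                            sp, mask$origin)
      if (mask_voxel_count(warped) == 0L) {
        last_fail <- "empty warped mask"
        next
      }
      dc <- dice(mask, warped)
      if (dc < dice_min) {
        last_fail <- sprintf("Dice %.3f < %.3f", dc, dice_min)
        next
      }
      hd <- hausdorff(mask, warped)
      if (hd > hd_max) {
        last_fail <- sprintf("Hausdorff %.2f mm > %.2f mm", hd, hd_max)
        next
      }
      return(warped)
    }
    NULL
  })
  if (is.null(res)) {
    stop(sprintf(
      "contour randomization failed after %d attempts (last violation: %s)",
      max_attempts, last_fail))
  }
  res
}

#' Apply one full perturbation spec to an image/mask pair
#'
#' Mode order: rigid transform, then noise addition, then contour
#' randomization; the contour constraints are therefore checked on the final
#' mask geometry.
#'
#' @param image,mask the (preprocessed) pair.
#' @param spec one row of [sample_perturbations()] output.
#' @param seed study seed combined with the spec's contour index and the
#'   noise stream.
#' @param sigma_base noise scale passed to [add_noise_field()].
#' @param ... further arguments to [randomize_contour()].
#' @return list with perturbed `image` and `mask`.
#' @export
apply_perturbation <- function(image, mask, spec, seed = 1, sigma_base = 10,
                               ...) {
  rigid <- apply_rigid(image, mask,
                       t_mm = c(spec$t_lm, spec$t_ap, spec$t_si),
                       angle_deg = spec$rotation_deg)
  noisy <- add_noise_field(rigid$image, spec$noise_level, sigma_base,
                           seed = derive_seed(seed, paste0("noise:", spec$noise_level,
                                                           ":", spec$contour_index)))
  warped <- randomize_contour(rigid$mask,
                              contour_seed = derive_seed(seed, paste0("dvf:", spec$contour_index)),
                              ...)
  list(image = noisy, mask = warped)
}
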