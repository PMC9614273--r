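# Preprocessing ahead of feature extraction: isotropic resampling, HU
# re-segmentation, LoG / stationary-wavelet filter banks, fixed-bin-count
# discretization.

#' Preprocessing configuration
#'
#' Defaults follow common radiomics practice for head-and-neck CT: 1 mm
#' isotropic resampling, soft-tissue re-segmentation window \[-150, 180\] HU,
#' LoG sigmas 1/3/6 mm, single-level stationary coiflet-1 wavelet bank, and
#' fixed bin counts 50..350.
#'
#' @param spacing_mm target isotropic spacing.
#' @param reseg_hu length-2 HU window for re-segmentation.
#' @param bin_counts integer vector of fixed bin counts (each >= 2).
#' @param log_sigmas_mm LoG kernel widths in mm (all > 0).
#' @param wavelet enable the 8-sub-band stationary wavelet bank.
#' @param wavelet_family currently only "coif1".
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(spacing_mm = 1,
                              reseg_hu = c(-150, 180),
                              bin_counts = c(50, 100, 150, 200, 250, 300, 350),
                              log_sigmas_mm = c(1, 3, 6),
                              wavelet = TRUE,
                              wavelet_family = "coif1") {
  stopifnot(spacing_mm > 0, length(reseg_hu) == 2, reseg_hu[1] < reseg_hu[2],
            all(bin_counts >= 2), all(log_sigmas_mm > 0))
  structure(list(spacing_mm = spacing_mm, reseg_hu = reseg_hu,
                 bin_counts = as.integer(bin_counts),
                 log_sigmas_mm = log_sigmas_mm,
                 wavelet = wavelet, wavelet_family = wavelet_family),
            class = "preprocess_config")
}

# --- separable 1D convolutions along array axes ---------------------------

# Convolution matrix (n x n) for kernel w centred at offset 0, with mirror
# (reflect) boundary handling. Row i of the result is sum_t w[t] x[refl(i+t)].
conv_matrix_reflect <- function(n, w) {
  r <- (length(w) - 1L) %/% 2L
  A <- matrix(0, n, n)
  offs <- seq_along(w) - r - 1L
  for (t in seq_along(w)) {
    j <- seq_len(n) + offs[t]
    # mirror without repeating the edge sample: 0 -> 2, -1 -> 3, n+1 -> n-1
    j <- ifelse(j < 1L, 2L - j, j)
    j <- ifelse(j > n, 2L * n - j, j)
    j <- pmin(pmax(j, 1L), n)
    A[cbind(seq_len(n), j)] <- A[cbind(seq_len(n), j)] + w[t]
  }
  A
}

# Circulant convolution matrix (periodic boundary), used by the stationary
# wavelet transform.
conv_matrix_periodic <- function(n, w, center = (length(w) - 1L) %/% 2L) {
  A <- matrix(0, n, n)
  offs <- seq_along(w) - center - 1L
  for (t in seq_along(w)) {
    j <- ((seq_len(n) + offs[t] - 1L) %% n) + 1L
    A[cbind(seq_len(n), j)] <- A[cbind(seq_len(n), j)] + w[t]
  }
  A
}

# Apply an n_axis x n_axis convolution matrix along one axis of a 3D array.
conv_axis <- function(arr, A, axis) {
  d <- dim(arr)
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  x <- aperm(arr, perm)
  dp <- dim(x)
  y <- A %*% matrix(x, nrow = dp[1])
  y <- array(y, dp)
  aperm(y, order(perm))
}

gaussian_kernel <- function(sigma_vox) {
  r <- max(1L, as.integer(ceiling(3.5 * sigma_vox)))
  x <- (-r):r
  w <- exp(-x^2 / (2 * sigma_vox^2))
  w / sum(w)
}

#' Separable Gaussian smoothing of a 3D array
#' @param arr 3D numeric array.
#' @param sigma_mm kernel sd per axis in mm (scalar or length 3).
#' @param spacing voxel spacing in mm.
#' @return smoothed array, same dimensions (mirror boundary).
#' @keywords internal
gaussian_smooth3 <- function(arr, sigma_mm, spacing = c(1, 1, 1)) {
  sigma_mm <- rep(sigma_mm, length.out = 3)
  for (a in 1:3) {
    sv <- sigma_mm[a] / spacing[a]
    if (sv > 1e-8) {
      A <- conv_matrix_reflect(dim(arr)[a], gaussian_kernel(sv))
      arr <- conv_axis(arr, A, a)
    }
  }
  arr
}

#' Resample an image/mask pair to a new (isotropic) grid
#'
#' The image is resampled with cubic-convolution interpolation, the mask
#' with trilinear interpolation thresholded at 0.5, exact ties resolved by
#' the nearest neighbour (binary-preserving). The
#' new grid spans the same physical extent, anchored at the input origin.
#'
#' @param image an `image_volume`.
#' @param mask a `binary_mask` on the same grid.
#' @param spacing_mm target spacing, scalar (isotropic) or length 3.
#' @return list with resampled `image` and `mask`.
#' @export
resample_pair <- function(image, mask, spacing_mm = 1) {
  stopifnot_same_grid(image, mask)
  new_sp <- rep(as.numeric(spacing_mm), length.out = 3)
  if (any(!is.finite(new_sp)) || any(new_sp <= 0)) {
    stop("target spacing must be positive")
  }
  d_old <- dim(image$data)
  extent <- (d_old - 1) * image$spacing
  d_new <- pmax(as.integer(floor(extent / new_sp)) + 1L, 1L)
  ax <- lapply(1:3, function(a) {
    ((seq_len(d_new[a]) - 1) * new_sp[a]) / image$spacing[a] + 1
  })
  coords <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  img_new <- array(interp3(image$data, coords, "cubic"), d_new)
  msk_new <- array(interp_mask(mask$data, coords), d_new)
  if (sum(msk_new) == 0L && mask_voxel_count(mask) > 0L) {
    stop("mask emptied by resampling")
  }
  list(image = image_volume(img_new, new_sp, image$origin),
       mask = binary_mask(msk_new, new_sp, image$origin))
}

#' Intensity re-segmentation of a mask
#'
#' Restricts the mask to voxels whose image intensity lies inside the HU
#' window (inclusive). An emptied mask is returned (not an error) with a
#' warning, and carries attribute `empty = TRUE` for downstream flagging.
#'
#' @param image an `image_volume`.
#' @param mask a `binary_mask` on the same grid.
#' @param hu_range length-2 inclusive window, default \[-150, 180\].
#' @return the intensity mask as a `binary_mask`.
#' @export
resegment <- function(image, mask, hu_range = c(-150, 180)) {
  stopifnot_same_grid(image, mask)
  keep <- mask$data > 0 & image$data >= hu_range[1] & image$data <= hu_range[2]
  out <- binary_mask(keep, mask$spacing, mask$origin)
  if (sum(keep) == 0L) {
    warning("re-segmentation produced an empty mask")
    attr(out, "empty") <- TRUE
  }
  out
}

# coiflet-1 decomposition low-pass filter, closed form sqrt(2)/32 *
# {1-s7, 5+s7, 14+2 s7, 14-2 s7, 1-s7, -3+s7}; high-pass by the QMF rule.
coif1_filters <- function() {
  s7 <- sqrt(7)
  lo <- sqrt(2) / 32 * c(1 - s7, 5 + s7, 14 + 2 * s7, 14 - 2 * s7, 1 - s7, -3 + s7)
  n <- length(lo)
  hi <- rev(lo) * (-1)^(seq_len(n) - 1)
  list(lo = lo, hi = hi)
}

# Single-level stationary (undecimated) 3D separable wavelet transform:
# 8 sub-bands named by the filter applied along each axis, L or H, in axis
# order (LM, AP, SI). Periodic boundary; sub-bands keep the image grid.
swt3 <- function(arr, family = "coif1") {
  if (family != "coif1") stop("unsupported wavelet family: ", family)
  f <- coif1_filters()
  d <- dim(arr)
  mats <- lapply(1:3, function(a) list(
    L = conv_matrix_periodic(d[a], f$lo),
    H = conv_matrix_periodic(d[a], f$hi)
  ))
  bands <- list()
  for (b1 in c("L", "H")) {
    x1 <- conv_axis(arr, mats[[1]][[b1]], 1)
    for (b2 in c("L", "H")) {
      x2 <- conv_axis(x1, mats[[2]][[b2]], 2)
      for (b3 in c("L", "H")) {
        bands[[paste0(b1, b2, b3)]] <- conv_axis(x2, mats[[3]][[b3]], 3)
      }
    }
  }
  bands
}

# Scale-normalized Laplacian of Gaussian: smooth at sigma, then sigma^2
# times the discrete Laplacian on the physical grid.
log_filter <- function(arr, sigma_mm, spacing) {
  sm <- gaussian_smooth3(arr, sigma_mm, spacing)
  d <- dim(arr)
  lap <- array(0, d)
  for (a in 1:3) {
    # second difference along axis a with mirror boundary
    A <- conv_matrix_reflect(d[a], c(1, -2, 1)) / spacing[a]^2
    lap <- lap + conv_axis(sm, A, a)
  }
  sigma_mm^2 * lap
}

#' Image filter bank
#'
#' Returns the original image plus LoG-filtered images (one per sigma) and,
#' if enabled, the 8 sub-bands of a single-level stationary coiflet-1
#' wavelet transform. All outputs share the input grid and spacing and carry
#' canonical names (`original`, `log-sigma-1` ..., `wavelet-LLL` ...).
#'
#' @param image an `image_volume` on an isotropic grid.
#' @param config a [preprocess_config()].
#' @return named list of `image_volume`s.
#' @export
filter_bank <- function(image, config = preprocess_config()) {
  if (any(config$log_sigmas_mm <= 0)) stop("LoG sigma must be positive")
  out <- list(original = image)
  for (s in config$log_sigmas_mm) {
    nm <- paste0("log-sigma-", gsub("\\.", "p", format(s)))
    out[[nm]] <- image_volume(log_filter(image$data, s, image$spacing),
                              image$spacing, image$origin)
  }
  if (isTRUE(config$wavelet)) {
    bands <- swt3(image$data, config$wavelet_family)
    for (nm in names(bands)) {
      out[[paste0("wavelet-", nm)]] <-
        image_volume(bands[[nm]], image$spacing, image$origin)
    }
  }
  out
}

#' Fixed-bin-count discretization
#'
#' Equal-width bins spanning the min-max range of the supplied values (the
#' re-segmented in-mask intensities). The minimum maps to bin 1, the maximum
#' to bin `n_bins`. A constant input collapses to bin 1 with a warning.
#'
#' @param values numeric vector, non-empty.
#' @param n_bins number of bins (>= 2).
#' @return integer vector of bin indices in `1..n_bins`.
#' @export
discretize <- function(values, n_bins) {
  if (length(values) == 0L) stop("no values to discretize")
  if (n_bins < 2L) stop("n_bins must be >= 2")
  rng <- range(values)
  if (rng[1] == rng[2]) {
    warning("constant input: all values assigned to bin 1")
    return(rep(1L, length(values)))
  }
  # right-inclusive equal-width bins: values at min map to bin 1, the bin
  # boundary itself belongs to the lower bin (midpoint-split convention)
  idx <- ceiling((values - rng[1]) / (rng[2] - rng[1]) * n_bins)
  pmin(pmax(as.integer(idx), 1L), as.integer(n_bins))
}
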