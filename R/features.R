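# Compact radiomic feature extractor: first-order statistics, 3D shape, and
# GLCM / GLRLM / GLSZM texture, following the IBSI reference definitions.
# Texture matrices are computed in 3D (13 unique directions at distance 1 for
# co-occurrence and run-length, 26-connectivity for size zones) and features
# are aggregated by averaging over directions.

# The 13 unique direction vectors of the 26-neighbourhood (one per
# antipodal pair).
texture_directions <- function() {
  dirs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  dirs <- dirs[!(dirs[, 1] == 0 & dirs[, 2] == 0 & dirs[, 3] == 0), ]
  keep <- dirs[, 3] > 0 |
    (dirs[, 3] == 0 & (dirs[, 2] > 0 | (dirs[, 2] == 0 & dirs[, 1] > 0)))
  dirs[keep, , drop = FALSE]
}

#' First-order intensity statistics
#'
#' Computed on the raw in-mask intensities; `entropy` and `uniformity` are
#' the only members that depend on the discretization and use the
#' fixed-bin-count histogram. Variance/skewness/kurtosis are the population
#' (biased) moments; kurtosis is excess kurtosis (normal = 0).
#'
#' @param values numeric vector of in-mask intensities, non-empty.
#' @param n_bins bin count for the histogram-based members.
#' @return named numeric vector of 13 features.
#' @export
extract_firstorder <- function(values, n_bins = 50) {
  if (length(values) == 0L) stop("empty intensity vector")
  n <- length(values)
  mu <- mean(values)
  m2 <- mean((values - mu)^2)
  m3 <- mean((values - mu)^3)
  m4 <- mean((values - mu)^4)
  bins <- suppressWarnings(discretize(values, n_bins))
  p <- tabulate(bins, n_bins) / n
  p <- p[p > 0]
  c(mean = mu,
    median = stats::median(values),
    minimum = min(values),
    maximum = max(values),
    p10 = unname(stats::quantile(values, 0.10, type = 7)),
    p90 = unname(stats::quantile(values, 0.90, type = 7)),
    variance = m2,
    skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    kurtosis = if (m2 > 0) m4 / m2^2 - 3 else 0,
    energy = sum(values^2),
    rms = sqrt(mean(values^2)),
    entropy = -sum(p * log2(p)),
    uniformity = sum(p^2))
}

# --- shape ----------------------------------------------------------------

# Mesh surface area by marching tetrahedra at iso-level 0.5. The binary
# field is first smoothed slightly (anti-aliasing; default 0.6 voxel sd) so
# that linearly interpolated iso-vertices track the underlying smooth
# surface instead of the voxel staircase; without smoothing the mesh area of
# a digital sphere overestimates the true area by >20%. The mask is
# zero-padded so the surface closes at the array boundary. Cube cells are
# split into 6 tetrahedra around the main diagonal.
mesh_surface_area <- function(mask_arr, spacing, presmooth_vox = 0.8) {
  d <- dim(mask_arr)
  pad <- array(0, d + 4L)
  pad[3:(d[1] + 2L), 3:(d[2] + 2L), 3:(d[3] + 2L)] <- (mask_arr > 0) + 0
  if (presmooth_vox > 0) {
    pad <- gaussian_smooth3(pad, sigma_mm = presmooth_vox, spacing = c(1, 1, 1))
  }
  dp <- dim(pad)
  nc <- dp - 1L
  # corner offsets (binary order used by the tet table below)
  corner <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                  c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  tets <- rbind(c(1, 2, 3, 7), c(1, 3, 4, 7), c(1, 4, 8, 7),
                c(1, 8, 5, 7), c(1, 5, 6, 7), c(1, 6, 2, 7))
  iso <- 0.5
  base <- which(array(TRUE, nc))
  bi <- arrayInd(base, nc)
  vals <- matrix(0, length(base), 8)
  for (cidx in 1:8) {
    vals[, cidx] <- pad[cbind(bi[, 1] + corner[cidx, 1],
                              bi[, 2] + corner[cidx, 2],
                              bi[, 3] + corner[cidx, 3])]
  }
  inside8 <- vals > iso
  s <- rowSums(inside8)
  mixed <- s > 0 & s < 8
  if (!any(mixed)) return(0)
  vals <- vals[mixed, , drop = FALSE]
  bi <- bi[mixed, , drop = FALSE]
  area <- 0
  tri_area <- function(v1, v2, v3) {
    e1 <- v2 - v1; e2 <- v3 - v1
    cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
    cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
    cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
    0.5 * sqrt(cx^2 + cy^2 + cz^2)
  }
  corner_xyz <- function(rows, cidx) {
    sweep((bi[rows, , drop = FALSE] - 1 + corner[rep(cidx, length(rows)), ,
                                                 drop = FALSE]), 2, spacing, `*`)
  }
  # linear interpolation of the iso-crossing along edge (a, b)
  edge_point <- function(rows, a, b) {
    va <- vals[rows, a]; vb <- vals[rows, b]
    t <- (iso - va) / (vb - va)
    t <- pmin(pmax(t, 0), 1)
    pa <- corner_xyz(rows, a); pb <- corner_xyz(rows, b)
    pa + t * (pb - pa)
  }
  for (t in 1:6) {
    tv <- tets[t, ]
    code <- (inside8[mixed, tv[1]] + 0) + 2 * inside8[mixed, tv[2]] +
      4 * inside8[mixed, tv[3]] + 8 * inside8[mixed, tv[4]]
    for (cs in 1:14) {
      rows <- which(code == cs)
      if (length(rows) == 0L) next
      inside <- which(bitwAnd(cs, c(1L, 2L, 4L, 8L)) > 0)
      outside <- setdiff(1:4, inside)
      if (length(inside) == 3L) { inside <- outside; outside <- setdiff(1:4, inside) }
      if (length(inside) == 1L) {
        o <- tv[inside]; rest <- tv[outside]
        v1 <- edge_point(rows, o, rest[1])
        v2 <- edge_point(rows, o, rest[2])
        v3 <- edge_point(rows, o, rest[3])
        area <- area + sum(tri_area(v1, v2, v3))
      } else {
        i1 <- tv[inside[1]]; i2 <- tv[inside[2]]
        o1 <- tv[outside[1]]; o2 <- tv[outside[2]]
        a <- edge_point(rows, i1, o1); b <- edge_point(rows, i1, o2)
        cc <- edge_point(rows, i2, o2); dd <- edge_point(rows, i2, o1)
        area <- area + sum(tri_area(a, b, cc)) + sum(tri_area(a, cc, dd))
      }
    }
  }
  area
}

#' 3D shape features of a mask
#'
#' Volume (voxel count times voxel volume), mesh-based surface area
#' (marching tetrahedra at iso-level 0.5), sphericity
#' \eqn{\pi^{1/3} (6V)^{2/3} / A}, maximum 3D diameter (largest pairwise
#' surface-voxel distance), and elongation/flatness from the principal-axis
#' eigenvalues of the voxel coordinates.
#'
#' @param mask a non-empty `binary_mask`.
#' @param spacing optional spacing override (mm).
#' @return named numeric vector of 6 features.
#' @export
extract_shape <- function(mask, spacing = NULL) {
  if (mask_voxel_count(mask) == 0L) stop("empty mask has no shape")
  sp <- spacing %||% mask$spacing
  vol <- mask_voxel_count(mask) * prod(sp)
  area <- mesh_surface_area(mask$data, sp)
  sphericity <- if (area > 0) pi^(1 / 3) * (6 * vol)^(2 / 3) / area else NA_real_
  surf <- sweep(mask_surface_indices(mask) - 1, 2, sp, `*`)
  max_diam <- if (nrow(surf) >= 2) {
    step <- max(1L, floor(2e6 / nrow(surf)))
    worst <- 0
    for (s in seq(1L, nrow(surf), by = step)) {
      rows <- s:min(s + step - 1L, nrow(surf))
      d2 <- outer(rowSums(surf[rows, , drop = FALSE]^2), rowSums(surf^2), `+`) -
        2 * surf[rows, , drop = FALSE] %*% t(surf)
      worst <- max(worst, max(d2))
    }
    sqrt(max(worst, 0))
  } else 0
  pts <- sweep(mask_indices(mask) - 1, 2, sp, `*`)
  ev <- if (nrow(pts) >= 2) {
    eigen(stats::cov(pts), symmetric = TRUE, only.values = TRUE)$values
  } else c(0, 0, 0)
  ev <- pmax(ev, 0)
  elongation <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else NA_real_
  flatness <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else NA_real_
  c(volume = vol, surface_area = area, sphericity = sphericity,
    max_diameter_3d = max_diam, elongation = elongation, flatness = flatness)
}

# --- texture matrices -----------------------------------------------------

# Shift a 3D array by an integer offset, filling with NA.
shift_array <- function(arr, off) {
  d <- dim(arr)
  out <- array(NA_real_, d)
  src <- lapply(1:3, function(a) {
    s <- seq_len(d[a]) + off[a]
    s[s >= 1 & s <= d[a]]
  })
  dst <- lapply(1:3, function(a) src[[a]] - off[a])
  if (any(lengths(src) == 0)) return(out)
  out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  out
}

glcm_matrix <- function(bins, n_bins, off) {
  nb <- shift_array(bins, off)
  ok <- !is.na(bins) & !is.na(nb)
  if (!any(ok)) return(matrix(0, n_bins, n_bins))
  i <- bins[ok]; j <- nb[ok]
  counts <- matrix(tabulate((j - 1) * n_bins + i, n_bins * n_bins),
                   n_bins, n_bins)
  counts + t(counts)  # symmetric aggregation
}

glcm_features_one <- function(P) {
  total <- sum(P)
  if (total == 0) return(NULL)
  p <- P / total
  nb <- nrow(p)
  i <- matrix(seq_len(nb), nb, nb)
  j <- t(i)
  px <- rowSums(p)
  mu <- sum(seq_len(nb) * px)
  sig2 <- sum((seq_len(nb) - mu)^2 * px)
  diffm <- abs(i - j)
  pnz <- p[p > 0]
  corr <- if (sig2 > 0) (sum(i * j * p) - mu^2) / sig2 else 1
  c(joint_energy = sum(p^2),
    contrast = sum((i - j)^2 * p),
    dissimilarity = sum(diffm * p),
    inverse_difference = sum(p / (1 + diffm)),
    idm = sum(p / (1 + (i - j)^2)),
    correlation = corr,
    joint_entropy = -sum(pnz * log2(pnz)),
    maximum_probability = max(p),
    cluster_shade = sum((i + j - 2 * mu)^3 * p),
    cluster_prominence = sum((i + j - 2 * mu)^4 * p),
    sum_average = sum((i + j) * p))
}

glrlm_runs_one <- function(bins, off) {
  d <- dim(bins)
  idx <- which(!is.na(bins), arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  t_step <- as.vector(idx %*% off)
  k <- sum(off^2)
  base <- k * idx - outer(t_step, off)  # invariant along the line
  key <- paste(base[, 1], base[, 2], base[, 3], sep = ",")
  ord <- order(key, t_step)
  g <- bins[idx][ord]
  kk <- key[ord]
  tt <- t_step[ord]
  # break runs at line changes, gray-level changes, or gaps along the line
  newline <- c(TRUE, kk[-1] != kk[-length(kk)])
  gap <- c(FALSE, tt[-1] != tt[-length(tt)] + k)
  brk <- newline | gap | c(TRUE, g[-1] != g[-length(g)])
  run_id <- cumsum(brk)
  data.frame(g = g[!duplicated(run_id)],
             len = as.vector(table(run_id)))
}

rlm_szm_features <- function(g, size, n_bins, n_vox, prefix) {
  nz <- length(g)
  gl_counts <- tapply(rep(1, nz), factor(g, levels = seq_len(n_bins)), sum)
  gl_counts[is.na(gl_counts)] <- 0
  sz_counts <- table(size)
  p_gs <- table(factor(g, levels = seq_len(n_bins)), size) / nz
  p_nz <- p_gs[p_gs > 0]
  mu_g <- sum(g) / nz
  mu_s <- sum(size) / nz
  f <- c(
    sum(1 / size^2) / nz,                       # short / small emphasis
    sum(size^2) / nz,                           # long / large emphasis
    sum(1 / g^2) / nz,                          # low gray level
    sum(g^2) / nz,                              # high gray level
    sum(1 / (g^2 * size^2)) / nz,
    sum(g^2 / size^2) / nz,
    sum(size^2 / g^2) / nz,
    sum(g^2 * size^2) / nz,
    sum(gl_counts^2) / nz,                      # gray level non-uniformity
    sum(gl_counts^2) / nz^2,                    # ... normalized
    sum(sz_counts^2) / nz,                      # run length / zone size NU
    sum(sz_counts^2) / nz^2,
    nz / n_vox,                                 # run / zone percentage
    sum((g - mu_g)^2) / nz,                     # gray level variance
    sum((size - mu_s)^2) / nz,                  # length / size variance
    -sum(p_nz * log2(p_nz))                     # entropy
  )
  names(f) <- paste0(prefix, c(
    "short_emphasis", "long_emphasis", "low_gl_emphasis", "high_gl_emphasis",
    "short_low_gl", "short_high_gl", "long_low_gl", "long_high_gl",
    "gl_nonuniformity", "gl_nonuniformity_norm",
    "length_nonuniformity", "length_nonuniformity_norm",
    "percentage", "gl_variance", "length_variance", "entropy"))
  f
}

glszm_zones <- function(bins) {
  idx <- which(!is.na(bins))
  if (length(idx) == 0L) return(NULL)
  d <- dim(bins)
  vid <- array(0L, d)
  vid[idx] <- seq_along(idx)
  dirs <- texture_directions()
  edges <- list()
  for (r in seq_len(nrow(dirs))) {
    sh_id <- shift_array(vid + 0, dirs[r, ])
    sh_bin <- shift_array(bins, dirs[r, ])
    ok <- !is.na(bins) & !is.na(sh_bin) & bins == sh_bin
    if (any(ok)) edges[[length(edges) + 1L]] <- cbind(vid[ok], sh_id[ok])
  }
  el <- if (length(edges)) do.call(rbind, edges) else matrix(0L, 0, 2)
  gr <- igraph::make_graph(edges = as.vector(t(el)), n = length(idx),
                           directed = FALSE)
  memb <- igraph::components(gr)$membership
  gvals <- bins[idx]
  data.frame(g = as.vector(tapply(gvals, memb, `[`, 1)),
             size = as.vector(table(memb)))
}

#' Texture features from a discretized ROI
#'
#' @param bins integer 3D array of bin indices, `NA` outside the ROI.
#' @param kind one of `"glcm"`, `"glrlm"`, `"glszm"`.
#' @param n_bins number of gray levels used in the discretization.
#' @return named numeric vector (11 GLCM features averaged over the 13
#'   directions; 16 run-length features averaged over directions; 16
#'   size-zone features).
#' @export
texture_features <- function(bins, kind = c("glcm", "glrlm", "glszm"),
                             n_bins = max(bins, na.rm = TRUE)) {
  kind <- match.arg(kind)
  n_vox <- sum(!is.na(bins))
  if (n_vox < 2L && kind == "glcm") stop("co-occurrence needs >= 2 ROI voxels")
  if (n_vox == 0L) stop("empty ROI")
  dirs <- texture_directions()
  if (kind == "glcm") {
    acc <- NULL; nd <- 0
    for (r in seq_len(nrow(dirs))) {
      f <- glcm_features_one(glcm_matrix(bins, n_bins, dirs[r, ]))
      if (!is.null(f)) { acc <- if (is.null(acc)) f else acc + f; nd <- nd + 1 }
    }
    if (nd == 0) stop("no voxel pairs at distance 1 in any direction")
    out <- acc / nd
    names(out) <- paste0("glcm_", names(out))
    return(out)
  }
  if (kind == "glrlm") {
    acc <- NULL
    for (r in seq_len(nrow(dirs))) {
      runs <- glrlm_runs_one(bins, dirs[r, ])
      f <- rlm_szm_features(runs$g, runs$len, n_bins, n_vox, "glrlm_")
      acc <- if (is.null(acc)) f else acc + f
    }
    return(acc / nrow(dirs))
  }
  zones <- glszm_zones(bins)
  # zone-size features reuse the run-length formula family with sizes as
  # lengths; rename the axis-specific members afterwards
  f <- rlm_szm_features(zones$g, zones$size, n_bins, n_vox, "glszm_")
  names(f) <- sub("short_", "small_", names(f))
  names(f) <- sub("long_", "large_", names(f))
  names(f) <- sub("length_", "zone_", names(f))
  f
}

#' Extract the full feature vector for one patient
#'
#' Loops the filter bank and bin counts: shape features once from the
#' morphological mask; first-order per filter image (histogram members per
#' bin count); GLCM/GLRLM/GLSZM per (filter image, bin count). Intensity and
#' texture features use the re-segmented mask (computed on the original
#' image); when re-segmentation empties the mask those features are `NA`.
#'
#' Canonical names: `shape_{feature}`, `{image}_firstorder_{feature}`,
#' `{image}_b{bins}_firstorder_{entropy|uniformity}`, and
#' `{image}_b{bins}_{glcm|glrlm|glszm}_{feature}`.
#'
#' @param image an `image_volume`, already resampled to the config's grid.
#' @param mask the morphological `binary_mask` on the same grid.
#' @param config a [preprocess_config()].
#' @param resegment_mask apply HU re-segmentation before intensity/texture
#'   extraction (uses `config$reseg_hu`).
#' @return named numeric vector; attribute `n_missing` counts NA features.
#' @export
extract_all <- function(image, mask, config = preprocess_config(),
                        resegment_mask = TRUE) {
  stopifnot_same_grid(image, mask)
  out <- extract_shape(mask)
  names(out) <- paste0("shape_", names(out))
  roi_mask <- if (resegment_mask) {
    suppressWarnings(resegment(image, mask, config$reseg_hu))
  } else mask
  roi_empty <- mask_voxel_count(roi_mask) == 0L
  sel <- roi_mask$data > 0
  images <- filter_bank(image, config)
  fo_raw_names <- c("mean", "median", "minimum", "maximum", "p10", "p90",
                    "variance", "skewness", "kurtosis", "energy", "rms")
  for (img_name in names(images)) {
    vals <- if (roi_empty) numeric(0) else images[[img_name]]$data[sel]
    if (!roi_empty) {
      fo <- extract_firstorder(vals, n_bins = config$bin_counts[1])
      out[paste0(img_name, "_firstorder_", fo_raw_names)] <- fo[fo_raw_names]
    } else {
      out[paste0(img_name, "_firstorder_", fo_raw_names)] <- NA_real_
    }
    for (nbin in config$bin_counts) {
      pre <- paste0(img_name, "_b", nbin, "_")
      if (!roi_empty) {
        bins_vec <- suppressWarnings(discretize(vals, nbin))
        p <- tabulate(bins_vec, nbin) / length(bins_vec)
        p <- p[p > 0]
        out[paste0(pre, "firstorder_entropy")] <- -sum(p * log2(p))
        out[paste0(pre, "firstorder_uniformity")] <- sum(p^2)
        bins_arr <- array(NA_real_, dim(image$data))
        bins_arr[sel] <- bins_vec
        for (kind in c("glcm", "glrlm", "glszm")) {
          f <- tryCatch(texture_features(bins_arr, kind, nbin),
                        error = function(e) NULL)
          if (is.null(f)) {
            f <- stats::setNames(rep(NA_real_, 16), paste0(kind, "_", 1:16))
          }
          out[paste0(pre, names(f))] <- f
        }
      } else {
        out[paste0(pre, "firstorder_entropy")] <- NA_real_
        out[paste0(pre, "firstorder_uniformity")] <- NA_real_
      }
    }
  }
  attr(out, "n_missing") <- sum(is.na(out))
  attr(out, "roi_empty") <- roi_empty
  out
}
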