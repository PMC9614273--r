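# Independent brute-force oracles. These deliberately use naive algorithms
# (explicit loops, direct definitions) so they share no code path with the
# package implementations they check.

# Dice from raw voxel counts.
bf_dice <- function(a, b) {
  A <- a$data > 0; B <- b$data > 0
  if (sum(A) + sum(B) == 0) return(1)
  2 * sum(A & B) / (sum(A) + sum(B))
}

# Hausdorff by direct definition: max over surface voxels of one mask of the
# min distance to the other mask's surface voxels, symmetrized. Surface =
# foreground voxel with some 6-neighbour background (or boundary).
bf_surface <- function(m) {
  arr <- m$data > 0
  d <- dim(arr)
  out <- NULL
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!arr[i, j, k]) next
    nb <- c(
      i == 1 || !arr[i - 1, j, k], i == d[1] || !arr[i + 1, j, k],
      j == 1 || !arr[i, j - 1, k], j == d[2] || !arr[i, j + 1, k],
      k == 1 || !arr[i, j, k - 1], k == d[3] || !arr[i, j, k + 1])
    if (any(nb)) out <- rbind(out, c(i, j, k))
  }
  out
}

bf_hausdorff <- function(a, b) {
  sa <- sweep(bf_surface(a) - 1, 2, a$spacing, `*`)
  sb <- sweep(bf_surface(b) - 1, 2, b$spacing, `*`)
  dmat <- matrix(0, nrow(sa), nrow(sb))
  for (i in seq_len(nrow(sa))) {
    dmat[i, ] <- sqrt(colSums((t(sb) - sa[i, ])^2))
  }
  max(max(apply(dmat, 1, min)), max(apply(dmat, 2, min)))
}

# AUC by explicit enumeration of positive-negative pairs.
bf_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + (p > n) + 0.5 * (p == n)
  }
  tot / (length(pos) * length(neg))
}

# ICC(1,1) through R's own one-way ANOVA fit (independent of the package's
# closed-form mean squares).
bf_icc <- function(m) {
  df <- data.frame(
    value = as.vector(m),
    subject = factor(rep(seq_len(nrow(m)), ncol(m))))
  av <- stats::anova(stats::aov(value ~ subject, data = df))
  ms_r <- av["subject", "Mean Sq"]
  ms_w <- av["Residuals", "Mean Sq"]
  k <- ncol(m)
  (ms_r - ms_w) / (ms_r + (k - 1) * ms_w)
}

# All 26-neighbourhood directions as +/- pairs (for brute-force texture).
bf_all_dirs <- function() {
  d <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  d[rowSums(abs(d)) > 0, , drop = FALSE]
}

bf_dir_pairs <- function() {
  # the package's 13 canonical directions, rederived independently: keep one
  # of each +/- pair by lexicographic sign rule
  d <- bf_all_dirs()
  keep <- apply(d, 1, function(v) {
    v[3] > 0 || (v[3] == 0 && (v[2] > 0 || (v[2] == 0 && v[1] > 0)))
  })
  d[keep, , drop = FALSE]
}

# Naive symmetric GLCM for one direction (loop over every voxel).
bf_glcm <- function(bins, n_bins, off) {
  d <- dim(bins)
  M <- matrix(0, n_bins, n_bins)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (is.na(bins[i, j, k])) next
    ii <- i + off[1]; jj <- j + off[2]; kk <- k + off[3]
    if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 || kk > d[3]) next
    if (is.na(bins[ii, jj, kk])) next
    M[bins[i, j, k], bins[ii, jj, kk]] <- M[bins[i, j, k], bins[ii, jj, kk]] + 1
  }
  M + t(M)
}

# Naive run extraction for one direction: walk every line from its start.
bf_runs <- function(bins, off) {
  d <- dim(bins)
  runs <- list()
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    prev <- c(i, j, k) - off
    has_prev <- all(prev >= 1) && all(prev <= d)
    if (has_prev) next  # only start lines at voxels with no predecessor cell
    p <- c(i, j, k)
    cur_g <- NA; cur_len <- 0
    while (all(p >= 1) && all(p <= d)) {
      g <- bins[p[1], p[2], p[3]]
      if (!is.na(g) && !is.na(cur_g) && g == cur_g) {
        cur_len <- cur_len + 1
      } else {
        if (!is.na(cur_g)) runs[[length(runs) + 1]] <- c(cur_g, cur_len)
        cur_g <- g; cur_len <- if (is.na(g)) 0 else 1
      }
      p <- p + off
    }
    if (!is.na(cur_g)) runs[[length(runs) + 1]] <- c(cur_g, cur_len)
  }
  m <- do.call(rbind, runs)
  data.frame(g = m[, 1], len = m[, 2])
}

# Naive zone extraction: repeated flood fill with an explicit stack,
# 26-connectivity, equal bin value.
bf_zones <- function(bins) {
  d <- dim(bins)
  seen <- array(FALSE, d)
  dirs <- bf_all_dirs()
  zones <- list()
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (is.na(bins[i, j, k]) || seen[i, j, k]) next
    g <- bins[i, j, k]
    stack <- list(c(i, j, k))
    seen[i, j, k] <- TRUE
    size <- 0
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1
      for (r in seq_len(nrow(dirs))) {
        q <- p + dirs[r, ]
        if (any(q < 1) || any(q > d)) next
        if (seen[q[1], q[2], q[3]]) next
        if (is.na(bins[q[1], q[2], q[3]])) next
        if (bins[q[1], q[2], q[3]] != g) next
        seen[q[1], q[2], q[3]] <- TRUE
        stack[[length(stack) + 1]] <- q
      }
    }
    zones[[length(zones) + 1]] <- c(g, size)
  }
  m <- do.call(rbind, zones)
  data.frame(g = m[, 1], size = m[, 2])
}

# The run-length / size-zone feature family from a (g, length) list, written
# directly from the IBSI definitions.
bf_rlm_features <- function(g, len, n_bins, n_vox) {
  nz <- length(g)
  rg <- sapply(seq_len(n_bins), function(v) sum(g == v))
  rl <- sapply(sort(unique(len)), function(v) sum(len == v))
  p <- table(factor(g, levels = 1:n_bins), len) / nz
  pn <- p[p > 0]
  c(short_emphasis = sum(1 / len^2) / nz,
    long_emphasis = sum(len^2) / nz,
    low_gl_emphasis = sum(1 / g^2) / nz,
    high_gl_emphasis = sum(g^2) / nz,
    short_low_gl = sum(1 / (g * len)^2) / nz,
    short_high_gl = sum(g^2 / len^2) / nz,
    long_low_gl = sum(len^2 / g^2) / nz,
    long_high_gl = sum((g * len)^2) / nz,
    gl_nonuniformity = sum(rg^2) / nz,
    gl_nonuniformity_norm = sum(rg^2) / nz^2,
    length_nonuniformity = sum(rl^2) / nz,
    length_nonuniformity_norm = sum(rl^2) / nz^2,
    percentage = nz / n_vox,
    gl_variance = sum((g - sum(g) / nz)^2) / nz,
    length_variance = sum((len - sum(len) / nz)^2) / nz,
    entropy = -sum(pn * log2(pn)))
}

# Random blob-ish test ROI: bin indices with NA outside an ellipsoid.
random_roi <- function(dims, n_bins, seed, p_na = 0) {
  withr::with_seed(seed, {
    bins <- array(sample.int(n_bins, prod(dims), replace = TRUE), dims)
    ax <- lapply(seq_len(3), function(a) {
      (seq_len(dims[a]) - (dims[a] + 1) / 2)^2 / ((dims[a] / 2)^2)
    })
    r2 <- outer(outer(ax[[1]], ax[[2]], `+`), ax[[3]], `+`)
    bins[r2 > 1] <- NA
    if (p_na > 0) bins[stats::runif(length(bins)) < p_na] <- NA
    bins
  })
}
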