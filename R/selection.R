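# Repeated stratified cross-validation splits, robustness filtering, and the
# two-step feature selection (bootstrap-ANOVA frequency ranking followed by
# correlation pruning), plus the mRMR alternate selector used for
# selection-bias checks.

#' Repeated stratified cross-validation splits
#'
#' Per repetition, each class is shuffled and dealt round-robin into folds,
#' so per-fold class counts differ from the proportional share by at most
#' one member. Errors when the scheme cannot give every test fold at least
#' two minority-class members.
#'
#' @param labels binary outcome vector (0/1), both classes present.
#' @param folds number of folds (>= 2).
#' @param repetitions number of repetitions; `folds * repetitions` splits.
#' @param seed integer seed.
#' @return list of splits, each a list with `train`, `test` (integer
#'   indices), `rep`, `fold`.
#' @export
make_cv_splits <- function(labels, folds = 2, repetitions = 30, seed = 1) {
  labels <- as.integer(as.logical(labels))
  n <- length(labels)
  if (folds < 2L) stop("need at least 2 folds")
  counts <- table(factor(labels, levels = c(0, 1)))
  if (any(counts == 0L)) stop("both classes must be present")
  n_min <- min(counts)
  if (floor(n_min / folds) < 2L) {
    stop(sprintf(
      "infeasible stratification: %d folds leave fewer than 2 minority-class members per test fold (minority n = %d)",
      folds, n_min))
  }
  with_seed(derive_seed(seed, "cv"), {
    splits <- list()
    for (r in seq_len(repetitions)) {
      fold_of <- integer(n)
      for (cl in c(0L, 1L)) {
        ids <- which(labels == cl)
        ids <- ids[sample.int(length(ids))]
        fold_of[ids] <- rep_len(seq_len(folds), length(ids))
      }
      for (f in seq_len(folds)) {
        splits[[length(splits) + 1L]] <-
          list(train = which(fold_of != f), test = which(fold_of == f),
               rep = r, fold = f)
      }
    }
    splits
  })
}

#' Filter features by robustness ICC
#'
#' Keeps features whose ICC strictly exceeds the threshold (so threshold 0
#' is the "all features with positive ICC" group). Undefined ICCs are
#' treated as non-robust. Output order is stable (sorted by feature name).
#'
#' @param icc_table data.frame with columns `feature` and `icc` (as from
#'   [feature_icc_table()]), or a named numeric vector.
#' @param threshold robustness threshold (0, 0.75 and 0.95 in the motivating
#'   design).
#' @return character vector of surviving feature names.
#' @export
robustness_filter <- function(icc_table, threshold) {
  if (is.numeric(icc_table) && !is.null(names(icc_table))) {
    icc_table <- data.frame(feature = names(icc_table), icc = unname(icc_table))
  }
  if (nrow(icc_table) == 0L) stop("empty ICC table")
  keep <- !is.na(icc_table$icc) & icc_table$icc > threshold
  out <- sort(icc_table$feature[keep])
  if (length(out) == 0L) {
    stop(sprintf("no features survive the robustness threshold %g", threshold))
  }
  out
}

# Vectorized two-group one-way ANOVA p-values for every column of X.
anova_p_values <- function(X, y) {
  y <- as.integer(as.logical(y))
  n <- length(y)
  n1 <- sum(y == 1L); n0 <- n - n1
  m1 <- colMeans(X[y == 1L, , drop = FALSE])
  m0 <- colMeans(X[y == 0L, , drop = FALSE])
  mg <- colMeans(X)
  ssb <- n1 * (m1 - mg)^2 + n0 * (m0 - mg)^2
  ssw <- colSums(sweep(X[y == 1L, , drop = FALSE], 2, m1)^2) +
    colSums(sweep(X[y == 0L, , drop = FALSE], 2, m0)^2)
  f <- (ssb / 1) / (ssw / (n - 2))
  p <- stats::pf(f, 1, n - 2, lower.tail = FALSE)
  p[!is.finite(f)] <- NA  # zero within-group variance (constant feature)
  p
}

#' Bootstrap-ANOVA feature ranking
#'
#' Repeatedly balances the classes by downsampling the majority class to the
#' minority size without replacement, computes a per-feature one-way ANOVA
#' p-value on the balanced subsample, and counts a "hit" when p is below
#' `p_cut`. Features are ranked by hit frequency (ties by mean p, then
#' name); the top `ceiling(top_frac * n_features)` are returned.
#'
#' @param X patients-by-features numeric matrix (training data).
#' @param y binary outcome, both classes present, minority >= 2.
#' @param n_iter bootstrap iterations (default 100).
#' @param p_cut per-iteration significance cut (default 0.1).
#' @param top_frac fraction of features to keep (default 0.1).
#' @param seed integer seed.
#' @return data.frame with `feature`, `frequency`, `mean_p`, ranked.
#' @export
bootstrap_anova_rank <- function(X, y, n_iter = 100, p_cut = 0.1,
                                 top_frac = 0.1, seed = 1) {
  y <- as.integer(as.logical(y))
  if (n_iter < 1L) stop("n_iter must be >= 1")
  counts <- table(factor(y, levels = c(0, 1)))
  if (any(counts < 2L)) stop("each class needs at least 2 members")
  minority <- which.min(counts) - 1L
  n_min <- min(counts)
  ids_min <- which(y == minority)
  ids_maj <- which(y != minority)
  p_feat <- ncol(X)
  hits <- numeric(p_feat)
  p_sum <- numeric(p_feat)
  p_cnt <- numeric(p_feat)
  with_seed(derive_seed(seed, "anova_boot"), {
    for (it in seq_len(n_iter)) {
      take <- c(ids_min, ids_maj[sample.int(length(ids_maj), n_min)])
      p <- anova_p_values(X[take, , drop = FALSE], y[take])
      ok <- !is.na(p)
      hits[ok & p < p_cut] <- hits[ok & p < p_cut] + 1
      p_sum[ok] <- p_sum[ok] + p[ok]
      p_cnt[ok] <- p_cnt[ok] + 1
    }
  })
  mean_p <- ifelse(p_cnt > 0, p_sum / p_cnt, Inf)
  nm <- colnames(X) %||% paste0("f", seq_len(p_feat))
  ord <- order(-hits, mean_p, nm)
  k <- ceiling(top_frac * p_feat)
  sel <- ord[seq_len(min(k, p_feat))]
  data.frame(feature = nm[sel], frequency = hits[sel], mean_p = mean_p[sel],
             stringsAsFactors = FALSE)
}

#' Correlation pruning of ranked features
#'
#' While any pair of remaining features has |Pearson r| above `r_cut`, the
#' member of the most-correlated pair with the higher mean absolute
#' correlation to all remaining features is removed. The survivors are then
#' capped at `k_max` by the ANOVA frequency rank.
#'
#' @param X patients-by-features matrix containing (at least) the ranked
#'   features.
#' @param ranked character vector of feature names in rank order (best
#'   first).
#' @param r_cut correlation threshold (default 0.6).
#' @param k_max maximum number of features kept (default 10).
#' @return character vector, the final feature list in rank order.
#' @export
prune_correlated <- function(X, ranked, r_cut = 0.6, k_max = 10) {
  keep <- ranked
  if (length(keep) > 1L) {
    C <- abs(stats::cor(X[, keep, drop = FALSE]))
    C[is.na(C)] <- 0
    diag(C) <- 0
    while (length(keep) > 1L && max(C) > r_cut) {
      hit <- which(C == max(C), arr.ind = TRUE)[1, ]
      i <- hit[1]; j <- hit[2]
      mi <- mean(C[i, -i]); mj <- mean(C[j, -j])
      drop_idx <- if (mi > mj) i else if (mj > mi) j else max(i, j)
      keep <- keep[-drop_idx]
      C <- C[-drop_idx, -drop_idx, drop = FALSE]
    }
  }
  keep[seq_len(min(k_max, length(keep)))]
}

#' Minimum-redundancy maximum-relevance feature selection
#'
#' Greedy forward selection: the first feature maximizes relevance to the
#' outcome; each next feature maximizes `relevance - mean |Pearson r| to the
#' already-selected set`. Relevance is the absolute point-biserial
#' correlation with the outcome — a monotone transform of the two-group
#' ANOVA F statistic that lives on the same \[0, 1\] scale as the redundancy
#' term (a raw F would swamp the redundancy penalty). Ties break by feature
#' name.
#'
#' @param X patients-by-features matrix.
#' @param y binary outcome.
#' @param k number of features to select (>= 1).
#' @return character vector of selected features, in greedy order.
#' @export
mrmr_select <- function(X, y, k = 10) {
  if (k <= 0) stop("k must be positive")
  if (k > ncol(X)) stop("k exceeds the number of features")
  y <- as.integer(as.logical(y))
  nm <- colnames(X) %||% paste0("f", seq_len(ncol(X)))
  colnames(X) <- nm
  f_stat <- abs(suppressWarnings(stats::cor(X, y)))[, 1]
  f_stat[is.na(f_stat)] <- 0
  selected <- character(0)
  remaining <- nm
  while (length(selected) < k) {
    if (length(selected) == 0L) {
      score <- f_stat[match(remaining, nm)]
    } else {
      red <- vapply(remaining, function(f) {
        mean(abs(stats::cor(X[, f], X[, selected, drop = FALSE])), na.rm = TRUE)
      }, 0)
      score <- f_stat[match(remaining, nm)] - red
    }
    best <- remaining[order(-score, remaining)][1]
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
  }
  selected
}
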