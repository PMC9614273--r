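#' One-way random-effects intraclass correlation, ICC(1,1)
#'
#' Computes ICC(1,1) from a subjects-by-raters ratings matrix via the one-way
#' random ANOVA decomposition:
#'
#' \deqn{ICC(1,1) = \frac{MS_R - MS_W}{MS_R + (k-1) MS_W}}
#'
#' where \eqn{MS_R} is the between-subject (rows) mean square, \eqn{MS_W} the
#' within-subject residual mean square, and \eqn{k} the number of raters. In
#' the perturbation setting, subjects are patients and raters are
#' perturbations of the same patient. The estimate may be negative (more
#' within- than between-subject variance); negative values are reported raw.
#'
#' @param m numeric matrix, subjects in rows (>= 2), raters in columns (>= 2),
#'   no missing cells.
#' @param conf_level confidence level for the F-based interval (reporting
#'   only).
#' @return object of class `icc_report`: list with `icc`, `ms_r`, `ms_w`,
#'   `n`, `k`, `lower`, `upper`.
#' @export
icc_1_1 <- function(m, conf_level = 0.95) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("ratings matrix must have no missing cells")
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L) stop("need at least 2 subjects and 2 raters")
  row_means <- rowMeans(m)
  grand <- mean(m)
  ms_r <- k * sum((row_means - grand)^2) / (n - 1)
  ms_w <- sum((m - row_means)^2) / (n * (k - 1))
  if (ms_r <= 0 && ms_w <= 0) {
    stop("ICC undefined: zero total variance (all ratings equal)")
  }
  icc <- (ms_r - ms_w) / (ms_r + (k - 1) * ms_w)
  # exact F interval for the one-way model (Searle); reporting only
  if (ms_w > 0) {
    f_obs <- ms_r / ms_w
    alpha <- 1 - conf_level
    f_l <- f_obs / stats::qf(1 - alpha / 2, n - 1, n * (k - 1))
    f_u <- f_obs * stats::qf(1 - alpha / 2, n * (k - 1), n - 1)
    lower <- (f_l - 1) / (f_l + k - 1)
    upper <- (f_u - 1) / (f_u + k - 1)
  } else {
    lower <- upper <- 1
  }
  structure(
    list(icc = icc, ms_r = ms_r, ms_w = ms_w, n = n, k = k,
         lower = lower, upper = upper),
    class = "icc_report"
  )
}

#' @export
print.icc_report <- function(x, ...) {
  cat(sprintf("ICC(1,1) = %.4f  [%.4f, %.4f]  (n = %d subjects, k = %d raters)\n",
              x$icc, x$lower, x$upper, x$n, x$k))
  cat(sprintf("  MS_R = %.6g, MS_W = %.6g\n", x$ms_r, x$ms_w))
  invisible(x)
}

#' Per-feature ICC(1,1) across perturbation replicates
#'
#' @param replicates either a list of subjects-by-raters matrices (one per
#'   feature, named) or a 3D array subjects x raters x features with feature
#'   names on the third dimension.
#' @return data.frame with columns `feature`, `icc`, `ms_r`, `ms_w`, `n`,
#'   `k`, `defined`. Features whose ICC is undefined (zero total variance)
#'   get `icc = NA` and `defined = FALSE`; downstream filtering treats them
#'   as non-robust.
#' @export
feature_icc_table <- function(replicates) {
  if (is.array(replicates) && length(dim(replicates)) == 3L) {
    nm <- dimnames(replicates)[[3]] %||% paste0("f", seq_len(dim(replicates)[3]))
    replicates <- lapply(seq_len(dim(replicates)[3]),
                         function(j) replicates[, , j])
    names(replicates) <- nm
  }
  nm <- names(replicates) %||% paste0("f", seq_along(replicates))
  rows <- lapply(seq_along(replicates), function(j) {
    rep_j <- as.matrix(replicates[[j]])
    res <- tryCatch(icc_1_1(rep_j), error = function(e) NULL)
    if (is.null(res)) {
      data.frame(feature = nm[j], icc = NA_real_, ms_r = NA_real_,
                 ms_w = NA_real_, n = nrow(rep_j), k = ncol(rep_j),
                 defined = FALSE)
    } else {
      data.frame(feature = nm[j], icc = res$icc, ms_r = res$ms_r,
                 ms_w = res$ms_w, n = res$n, k = res$k, defined = TRUE)
    }
  })
  do.call(rbind, rows)
}

#' Area under the ROC curve (rank statistic)
#'
#' The probability that a random positive case is scored above a random
#' negative case, with ties counted one half (midrank / Mann-Whitney form).
#'
#' @param scores numeric prediction scores, larger = more positive.
#' @param labels binary labels (0/1 or logical), both classes present.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Train-test generalizability gap
#'
#' `test_auc - train_auc`; negative when the model degrades on unseen data,
#' near zero when it transfers. Reporting layers may present the absolute
#' value.
#'
#' @param train_auc,test_auc AUCs in \[0, 1\].
#' @return signed gap.
#' @export
generalizability_gap <- function(train_auc, test_auc) {
  stopifnot(all(train_auc >= 0 & train_auc <= 1),
            all(test_auc >= 0 & test_auc <= 1))
  test_auc - train_auc
}

#' Two-sided paired t-test
#'
#' @param a,b paired numeric vectors (length >= 3). Errors when the
#'   differences have zero variance (the statistic is undefined).
#' @return list with `t`, `p`, `df`, `mean_diff` (mean of a - b).
#' @export
paired_ttest <- function(a, b) {
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  if (length(a) < 3L) stop("need at least 3 pairs")
  d <- a - b
  if (stats::var(d) <= .Machine$double.eps * max(1, mean(d)^2)) {
    stop("zero-variance differences: paired t statistic undefined")
  }
  ht <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), mean_diff = unname(ht$estimate))
}
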