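# The experiment engine: repeated stratified CV, per-split feature
# robustness filtering, two-step selection, classifier training, and the
# robustness / generalizability evaluation with threshold group comparisons.

#' Experiment configuration
#'
#' @param thresholds robustness filtering thresholds, ascending (default the
#'   three groups 0 / 0.75 / 0.95).
#' @param classifiers classifier names (subset of [classifier_names()]).
#' @param folds,repetitions CV scheme (default stratified 2-fold, 30
#'   repetitions: 60 splits).
#' @param n_iter,p_cut,top_frac bootstrap-ANOVA ranking parameters.
#' @param r_cut,k_max correlation-pruning parameters.
#' @param selector `"anova"` (bootstrap-ANOVA + pruning) or `"mrmr"` (the
#'   alternate selector used for bias evaluation).
#' @param average_perturbed model on features averaged over perturbation
#'   replicates instead of the unperturbed table (off by default; the
#'   per-perturbation evaluation is unchanged).
#' @param seed global experiment seed.
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(thresholds = c(0, 0.75, 0.95),
                              classifiers = "ridge",
                              folds = 2, repetitions = 30,
                              n_iter = 100, p_cut = 0.1, top_frac = 0.1,
                              r_cut = 0.6, k_max = 10,
                              selector = c("anova", "mrmr"),
                              average_perturbed = FALSE,
                              seed = 1) {
  stopifnot(all(diff(thresholds) > 0), all(classifiers %in% classifier_names()))
  selector <- match.arg(selector)
  structure(as.list(environment()), class = "experiment_config")
}

#' Evaluate a fitted model's generalizability and robustness
#'
#' Train and test AUC are computed on unperturbed tables; the model
#' robustness ICC is the ICC(1,1) of the patients-by-perturbations matrix of
#' continuous scores over the perturbed test tables.
#'
#' @param model an `rr_model`.
#' @param X_train,y_train,X_test,y_test unperturbed tables and outcomes.
#' @param perturbed_test list of patients-by-features matrices, one per
#'   perturbation replicate, sharing the test table's rows and features.
#' @return list with `train_auc`, `test_auc`, `gap`, `model_icc`, `k`.
#' @export
evaluate_model <- function(model, X_train, y_train, X_test, y_test,
                           perturbed_test) {
  if (length(perturbed_test) < 2L) stop("need >= 2 perturbation replicates")
  train_auc <- auc(stats::predict(model, X_train), y_train)
  test_auc <- auc(stats::predict(model, X_test), y_test)
  scores <- vapply(perturbed_test, function(Xp) {
    stats::predict(model, Xp)
  }, numeric(nrow(X_test)))
  model_icc <- tryCatch(icc_1_1(scores)$icc, error = function(e) NA_real_)
  list(train_auc = train_auc, test_auc = test_auc,
       gap = generalizability_gap(train_auc, test_auc),
       model_icc = model_icc, k = length(perturbed_test))
}

# Feature selection for one training split: robustness filter at `thr`,
# then the configured selector, capped at k_max features.
select_features <- function(X_train, y_train, icc_tab, thr, config, seed) {
  survivors <- robustness_filter(icc_tab, thr)
  if (config$selector == "mrmr") {
    k <- min(config$k_max, length(survivors))
    return(mrmr_select(X_train[, survivors, drop = FALSE], y_train, k))
  }
  ranked <- bootstrap_anova_rank(X_train[, survivors, drop = FALSE], y_train,
                                 n_iter = config$n_iter, p_cut = config$p_cut,
                                 top_frac = config$top_frac, seed = seed)
  prune_correlated(X_train[, survivors, drop = FALSE], ranked$feature,
                   r_cut = config$r_cut, k_max = config$k_max)
}

#' Run the robustness/generalizability experiment
#'
#' For every CV split: compute per-feature ICC(1,1) from the training-side
#' perturbation replicates only (no test leakage), filter at each threshold,
#' select features, train each classifier, and evaluate train/test AUC, the
#' generalizability gap, and the model robustness ICC on perturbed test
#' tables. Afterwards, paired t-tests compare model ICC and |gap| between
#' the lowest threshold and each higher one, per classifier.
#'
#' @param sf a `synthetic_features` object (or any list with elements
#'   `features`, `replicates`, `outcomes` of the same shape, e.g. from
#'   [cohort_feature_tables()]).
#' @param config an [experiment_config()].
#' @return list of class `rr_experiment`: `records` (one row per split x
#'   threshold x classifier), `comparisons` (paired t-tests), `config`.
#' @export
run_experiment <- function(sf, config = experiment_config()) {
  X <- sf$features
  y <- sf$outcomes$label
  reps <- sf$replicates
  k_pert <- dim(reps)[2]
  splits <- make_cv_splits(y, folds = config$folds,
                           repetitions = config$repetitions,
                           seed = config$seed)
  records <- list()
  for (s in seq_along(splits)) {
    sp <- splits[[s]]
    icc_tab <- feature_icc_table(reps[sp$train, , , drop = FALSE])
    X_model <- if (config$average_perturbed) {
      apply(reps, c(1, 3), mean)
    } else X
    for (thr in config$thresholds) {
      final <- tryCatch(
        select_features(X_model[sp$train, , drop = FALSE], y[sp$train],
                        icc_tab, thr, config,
                        seed = derive_seed(config$seed, paste0("sel:", s, ":", thr))),
        error = function(e) {
          stop(sprintf("split %d, threshold %g: %s", s, thr, conditionMessage(e)))
        })
      perturbed_test <- lapply(seq_len(k_pert), function(r) {
        matrix(reps[sp$test, r, final], nrow = length(sp$test),
               dimnames = list(NULL, final))
      })
      for (clf in config$classifiers) {
        model <- train_classifier(clf, X_model[sp$train, final, drop = FALSE],
                                  y[sp$train],
                                  seed = derive_seed(config$seed,
                                                     paste0(clf, ":", s, ":", thr)))
        ev <- evaluate_model(model, X_model[sp$train, final, drop = FALSE],
                             y[sp$train], X_model[sp$test, final, drop = FALSE],
                             y[sp$test], perturbed_test)
        records[[length(records) + 1L]] <- data.frame(
          split = s, rep = sp$rep, fold = sp$fold, threshold = thr,
          classifier = clf, n_selected = length(final),
          train_auc = ev$train_auc, test_auc = ev$test_auc, gap = ev$gap,
          model_icc = ev$model_icc, k_perturbations = ev$k,
          mean_feature_icc = mean(icc_tab$icc[match(final, icc_tab$feature)],
                                  na.rm = TRUE),
          selected = paste(final, collapse = ";"),
          stringsAsFactors = FALSE)
      }
    }
  }
  records <- do.call(rbind, records)
  comparisons <- compare_thresholds(records)
  structure(list(records = records, comparisons = comparisons,
                 config = config),
            class = "rr_experiment")
}

#' Paired threshold comparisons of model robustness and generalizability
#'
#' For each classifier and each threshold above the baseline (the lowest
#' threshold present), paired two-sided t-tests across CV splits of (a) the
#' model robustness ICC and (b) the absolute generalizability gap.
#'
#' @param records the record table from [run_experiment()].
#' @return data.frame with one row per classifier x threshold x metric.
#' @export
compare_thresholds <- function(records) {
  base_thr <- min(records$threshold)
  out <- list()
  for (clf in unique(records$classifier)) {
    rec_c <- records[records$classifier == clf, ]
    base <- rec_c[rec_c$threshold == base_thr, ]
    base <- base[order(base$split), ]
    for (thr in setdiff(sort(unique(rec_c$threshold)), base_thr)) {
      cur <- rec_c[rec_c$threshold == thr, ]
      cur <- cur[order(cur$split), ]
      for (metric in c("model_icc", "abs_gap")) {
        a <- if (metric == "abs_gap") abs(cur$gap) else cur$model_icc
        b <- if (metric == "abs_gap") abs(base$gap) else base$model_icc
        tt <- tryCatch(paired_ttest(a, b), error = function(e) {
          list(t = NA_real_, p = NA_real_, mean_diff = mean(a - b))
        })
        out[[length(out) + 1L]] <- data.frame(
          classifier = clf, threshold = thr, baseline = base_thr,
          metric = metric, mean_baseline = mean(b, na.rm = TRUE),
          mean_threshold = mean(a, na.rm = TRUE),
          mean_diff = mean(a - b, na.rm = TRUE),
          t = tt$t, p = tt$p, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' @export
print.rr_experiment <- function(x, ...) {
  cat(sprintf("<rr_experiment> %d records (%d splits x %d thresholds x %d classifiers)\n",
              nrow(x$records), length(unique(x$records$split)),
              length(unique(x$records$threshold)),
              length(unique(x$records$classifier))))
  agg <- stats::aggregate(cbind(model_icc, gap, train_auc, test_auc) ~ threshold,
                          data = x$records, FUN = mean)
  print(agg, row.names = FALSE)
  invisible(x)
}
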