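# Glue between the image stack and the experiment engine: extract feature
# tables (unperturbed and per-perturbation) from a phantom cohort so
# run_experiment() can consume image-derived data exactly like the direct
# feature-table generator's output.

#' Extract unperturbed and perturbed feature tables from a cohort
#'
#' For each patient: preprocess (resample to the config's isotropic grid),
#' extract the full feature vector, then draw `n_perturbations` specs from
#' the grid (a pure function of the seed and patient id), apply each
#' perturbation (rigid transform, noise field, constrained contour
#' randomization) and re-extract. Features that are `NA` anywhere (e.g.
#' emptied re-segmentation masks) are dropped from all tables, with a
#' message.
#'
#' @param cohort a `phantom_cohort`.
#' @param config a [preprocess_config()]; desk-scale analyses shrink
#'   `bin_counts`/filters here rather than in the extractor.
#' @param grid a [build_perturbation_grid()].
#' @param n_perturbations perturbation replicates per patient.
#' @param seed study seed for the perturbation draws.
#' @param sigma_base noise scale (HU) per level step.
#' @param dice_min,hd_max contour randomization constraints.
#' @return list shaped like a `synthetic_features` object: `features`
#'   (patients x features), `replicates` (patients x perturbations x
#'   features array), `outcomes`, `specs` (per-patient perturbation specs).
#' @export
cohort_feature_tables <- function(cohort,
                                  config = preprocess_config(),
                                  grid = build_perturbation_grid(),
                                  n_perturbations = 20,
                                  seed = 1,
                                  sigma_base = 10,
                                  dice_min = 0.75, hd_max = 5) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  n <- length(cohort$patients)
  if (n == 0L) stop("empty cohort")
  feats <- NULL
  reps <- NULL
  specs <- list()
  for (i in seq_len(n)) {
    pat <- cohort$patients[[i]]
    pre <- resample_pair(pat$image, pat$mask, config$spacing_mm)
    fv <- extract_all(pre$image, pre$mask, config)
    if (is.null(feats)) {
      feats <- matrix(NA_real_, n, length(fv),
                      dimnames = list(cohort$outcomes$id, names(fv)))
      reps <- array(NA_real_, c(n, n_perturbations, length(fv)),
                    dimnames = list(cohort$outcomes$id,
                                    paste0("pert", seq_len(n_perturbations)),
                                    names(fv)))
    }
    feats[i, ] <- fv
    sp_i <- sample_perturbations(grid, n_perturbations, pat$id, seed)
    specs[[pat$id]] <- sp_i
    for (r in seq_len(n_perturbations)) {
      pert <- apply_perturbation(pre$image, pre$mask, sp_i[r, ],
                                 seed = derive_seed(seed, paste0(pat$id, ":", r)),
                                 sigma_base = sigma_base,
                                 dice_min = dice_min, hd_max = hd_max)
      reps[i, r, ] <- extract_all(pert$image, pert$mask, config)
    }
  }
  ok <- !apply(is.na(feats), 2, any) & !apply(is.na(reps), 3, any)
  if (any(!ok)) {
    message(sum(!ok), " features dropped (missing under some perturbation)")
  }
  list(features = feats[, ok, drop = FALSE],
       replicates = reps[, , ok, drop = FALSE],
       outcomes = cohort$outcomes,
       specs = specs,
       truth = cohort$truth)
}
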