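# End-to-end drivers: from a cohort to per-feature-set matrices, LOSO
# detection of loneliness level or change, and classifier-guided rule
# mining. These are the steps the analysis scripts chain together.

#' Extract, clean and align the per-feature-set matrices of a cohort
#'
#' Runs feature extraction for every participant, then applies the
#' missing-data policy independently to each of the seven feature-set
#' matrices.
#'
#' @param cohort an `ls_cohort`
#' @param feature_cfg an [feature_config()]
#' @param pipeline_cfg an [pipeline_config()] (missing-policy thresholds)
#' @param verbose print per-participant progress
#' @return list: `matrices` (imputed), `dropped` (per set: features and
#'   participants removed by the policy)
#' @export
prepare_feature_matrices <- function(cohort, feature_cfg = feature_config(),
                                     pipeline_cfg = pipeline_config(),
                                     verbose = FALSE) {
  raw <- extract_cohort_features(cohort, feature_cfg, verbose = verbose)
  cleaned <- lapply(raw, apply_missing_policy,
                    max_col_missing = pipeline_cfg$max_col_missing,
                    max_row_missing_frac = pipeline_cfg$max_row_missing_frac)
  list(matrices = lapply(cleaned, `[[`, "matrix"),
       dropped = lapply(cleaned, function(x)
         x[c("dropped_features", "dropped_participants")]))
}

#' Outcome labels of a cohort
#'
#' @param cohort an `ls_cohort`
#' @param task "level" (post-semester LL/HL) or "change" (DL/IL/UL)
#' @return named character vector keyed by participant id
#' @export
cohort_labels <- function(cohort, task = c("level", "change")) {
  task <- match.arg(task)
  tr <- cohort$truth
  lab <- if (task == "level") tr$post_level else tr$change
  stats::setNames(lab, tr$participant_id)
}

#' Detect loneliness level or change with the full pipeline
#'
#' NRLR feature selection and per-feature-set model training under
#' leave-one-subject-out cross-validation, followed by AdaBoost fusion of
#' the per-set detection probabilities.
#'
#' @param matrices named list of imputed per-feature-set matrices
#' @param labels named outcome vector (see [cohort_labels()])
#' @param seed top-level seed for all stochastic components
#' @param pipeline_cfg an [pipeline_config()]
#' @param verbose print fold progress
#' @return list: `loso` (per-set probabilities and fold details),
#'   `ensemble` (predictions and metrics), `selection_rates` (per feature
#'   name: share of folds that selected it)
#' @export
detect_loneliness <- function(matrices, labels, seed = 1L,
                              pipeline_cfg = pipeline_config(),
                              verbose = FALSE) {
  loso <- loso_cross_validate(matrices, labels, seed = seed,
                              config = pipeline_cfg, verbose = verbose)
  ens <- ensemble_combine(loso, labels, seed = seed, config = pipeline_cfg)
  sel <- table(unlist(loso$folds$selected))
  n_folds <- length(unique(loso$folds$participant_id))
  list(loso = loso, ensemble = ens,
       selection_rates = sort(as.numeric(sel) / n_folds,
                              decreasing = TRUE) |>
         stats::setNames(names(sel)[order(as.numeric(sel), decreasing = TRUE)]))
}

#' Share of LOSO folds whose selections match a feature-name pattern
#'
#' @param loso an `ls_loso`
#' @param pattern regular expression on feature names
#' @param sets optionally restrict to some feature sets
#' @return fraction of folds selecting at least one matching feature
#' @export
fold_selection_coverage <- function(loso, pattern, sets = NULL) {
  folds <- loso$folds
  if (!is.null(sets)) folds <- folds[feature_set %in% sets]
  per_fold <- folds[, .(hit = any(grepl(pattern, unlist(selected)))),
                    by = participant_id]
  mean(per_fold$hit)
}

#' Mine behavior rules from the classifier-selected features
#'
#' Restricts the feature matrices to the features selected in at least
#' `min_fold_share` of LOSO folds, discretizes them and runs the Apriori
#' rule analysis against the requested outcome.
#'
#' @param matrices per-feature-set matrices (pre-imputation values are
#'   recommended; -1 imputation markers are converted back to NA)
#' @param loso an `ls_loso` from [detect_loneliness()]
#' @param labels outcome vector keyed by participant id
#' @param outcome_prefix consequent item prefix
#' @param min_fold_share minimum share of folds a feature must be selected
#'   in (more than half of folds marks the stable selection set)
#' @param min_support,min_confidence Apriori thresholds
#' @param max_itemset_size cap on the frequent-itemset size
#' @return list from [mine_behavior_associations()] plus `features_used`
#' @export
mine_selected_behavior_rules <- function(matrices, loso, labels,
                                         outcome_prefix = "postlevel",
                                         min_fold_share = 0.5,
                                         min_support = 0.10,
                                         min_confidence = 0.90,
                                         max_itemset_size = 4) {
  sel <- table(unlist(loso$folds$selected))
  n_folds <- length(unique(loso$folds$participant_id))
  keep <- names(sel)[as.numeric(sel) / n_folds > min_fold_share]
  big <- do.call(cbind, unname(matrices))
  big[big == -1] <- NA
  keep <- intersect(keep, colnames(big))
  ids <- rownames(big)
  res <- mine_behavior_associations(big[, keep, drop = FALSE],
                                    labels[ids],
                                    outcome_prefix = outcome_prefix,
                                    min_support = min_support,
                                    min_confidence = min_confidence,
                                    max_itemset_size = max_itemset_size)
  res$features_used <- keep
  res
}
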