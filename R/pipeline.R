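# Classification pipeline: missing-data policy, nested randomized logistic
# regression (NRLR) feature selection, per-feature-set models (logistic
# regression vs gradient boosting), leave-one-subject-out cross-validation,
# and the AdaBoost probability-fusion ensemble with its ablation study.

#' Pipeline configuration
#'
#' @param n_subsamples randomized-LR subsamples per stability-selection pass
#' @param subsample_frac row fraction of each subsample
#' @param selection_threshold minimum selection frequency of a kept feature
#' @param weakness lower bound of the random per-feature penalty scaling
#' @param target_df approximate sparsity of each randomized-LR fit; defaults
#'   to `max(3, ceiling(sqrt(p)))` when NULL
#' @param inner_folds inner CV folds for model selection
#' @param xgb_nrounds gradient-boosting rounds of the per-set models
#' @param ada_rounds AdaBoost rounds of the fusion ensemble
#' @param ada_xgb_nrounds gradient-boosting rounds of each AdaBoost base
#'   estimator
#' @param max_col_missing drop a feature missing for more than this many
#'   participants
#' @param max_row_missing_frac drop a participant missing at least this
#'   fraction of features
#' @return list of class `ls_pipeline_config`
#' @export
pipeline_config <- function(n_subsamples = 200L, subsample_frac = 0.75,
                            selection_threshold = 0.25, weakness = 0.5,
                            target_df = NULL, inner_folds = 5L,
                            xgb_nrounds = 30L, ada_rounds = 10L,
                            ada_xgb_nrounds = 20L,
                            max_col_missing = 30L,
                            max_row_missing_frac = 0.2) {
  structure(as.list(environment()), class = "ls_pipeline_config")
}

#' Apply the missing-data policy to a feature matrix
#'
#' Drops features missing for more than `max_col_missing` participants,
#' then participants missing at least `max_row_missing_frac` of the
#' remaining features, and imputes surviving missing cells with -1 (all
#' real feature values are non-negative, so -1 marks missingness).
#'
#' @param mat participant x feature matrix with NA missing markers
#' @param max_col_missing,max_row_missing_frac thresholds
#' @return list: `matrix` (imputed), `dropped_features`,
#'   `dropped_participants`
#' @export
apply_missing_policy <- function(mat, max_col_missing = 30L,
                                 max_row_missing_frac = 0.2) {
  col_na <- colSums(is.na(mat))
  keep_col <- col_na <= max_col_missing
  m <- mat[, keep_col, drop = FALSE]
  row_na <- rowMeans(is.na(m))
  keep_row <- row_na < max_row_missing_frac
  m <- m[keep_row, , drop = FALSE]
  if (nrow(m) == 0) stop("missing-data policy removed every participant")
  m[is.na(m)] <- -1
  list(matrix = m,
       dropped_features = colnames(mat)[!keep_col],
       dropped_participants = rownames(mat)[!keep_row])
}

# one stability-selection pass of randomized logistic regression:
# L1 logistic fits on random row subsamples with random per-feature penalty
# scaling; returns the selection frequency of every column.
randomized_lr_frequency <- function(X, y, n_subsamples, subsample_frac,
                                    weakness, target_df = NULL) {
  p <- ncol(X)
  if (p == 0) return(numeric(0))
  keep <- apply(X, 2, function(col) sd(col) > 0)
  freq <- stats::setNames(numeric(p), colnames(X))
  if (!any(keep)) return(freq)
  Xk <- X[, keep, drop = FALSE]
  pk <- ncol(Xk)
  if (is.null(target_df)) target_df <- max(3, ceiling(sqrt(pk)))
  yb <- as.integer(factor(y)) - 1L
  n <- nrow(Xk)
  m <- max(2, floor(subsample_frac * n))
  counts <- numeric(pk)
  for (b in seq_len(n_subsamples)) {
    repeat {
      idx <- sample.int(n, m)
      if (length(unique(yb[idx])) > 1) break
    }
    pf <- runif(pk, weakness, 1)
    fit <- tryCatch(suppressWarnings(
      glmnet::glmnet(Xk[idx, , drop = FALSE], yb[idx], family = "binomial",
                     alpha = 1, penalty.factor = pf, nlambda = 30,
                     standardize = TRUE)),
      error = function(e) NULL)
    if (is.null(fit)) next
    df <- fit$df
    ix <- if (any(df <= target_df)) max(which(df <= target_df)) else 1L
    beta <- fit$beta[, ix]
    counts <- counts + (abs(beta) > 0)
  }
  freq[colnames(Xk)] <- counts / n_subsamples
  freq
}

# binary ovr-style frequency for a multiclass label: max over one-vs-rest
rlr_frequency_multiclass <- function(X, y, ...) {
  lv <- levels(factor(y))
  if (length(lv) == 2) return(randomized_lr_frequency(X, y, ...))
  freqs <- vapply(lv, function(l)
    randomized_lr_frequency(X, factor(y == l), ...), numeric(ncol(X)))
  apply(freqs, 1, max)
}

#' Nested randomized logistic regression feature selection
#'
#' Stage 1 runs randomized logistic regression (stability selection over
#' random subsamples of the training rows with randomly scaled L1
#' penalties) independently within each time-segment group of columns;
#' stage 2 pools all stage-1 selections and runs the same procedure once
#' more. For multiclass labels the per-class one-vs-rest selection
#' frequencies are combined by their maximum.
#'
#' @param X training feature matrix
#' @param y training labels (2 or 3 classes present)
#' @param groups segment group of each column (see
#'   [feature_segment_groups()]); a single group reduces the procedure to
#'   one randomized-LR pass
#' @param seed RNG seed for the subsampling
#' @param config an [pipeline_config()]
#' @return character vector of selected column names (possibly empty)
#' @export
nrlr_select <- function(X, y, groups = feature_segment_groups(colnames(X)),
                        seed = 1L, config = pipeline_config()) {
  if (length(unique(y)) < 2) stop("labels must contain at least 2 classes")
  stopifnot(length(groups) == ncol(X))
  set.seed(seed)
  args <- list(n_subsamples = config$n_subsamples,
               subsample_frac = config$subsample_frac,
               weakness = config$weakness, target_df = config$target_df)
  stage1 <- unlist(lapply(unique(groups), function(g) {
    Xg <- X[, groups == g, drop = FALSE]
    freq <- do.call(rlr_frequency_multiclass, c(list(Xg, y), args))
    names(freq)[freq >= config$selection_threshold]
  }))
  if (length(unique(groups)) == 1) return(stage1)
  if (length(stage1) == 0) return(character(0))
  X2 <- X[, stage1, drop = FALSE]
  freq2 <- do.call(rlr_frequency_multiclass, c(list(X2, y), args))
  names(freq2)[freq2 >= config$selection_threshold]
}

# majority-prior fallback model (used when no features survive selection)
prior_model <- function(y) {
  lv <- levels(factor(y))
  pr <- as.numeric(table(factor(y, levels = lv))) / length(y)
  structure(list(levels = lv, prior = pr, algorithm = "prior"),
            class = "ls_prior_model")
}

predict_prob <- function(model, newX) UseMethod("predict_prob")

#' @export
predict_prob.ls_prior_model <- function(model, newX) {
  matrix(model$prior, nrow = nrow(newX), ncol = length(model$levels),
         byrow = TRUE, dimnames = list(NULL, model$levels))
}

#' @export
predict_prob.ls_lr_model <- function(model, newX) {
  newX <- newX[, model$features, drop = FALSE]
  lv <- model$levels
  if (length(lv) == 2) {
    p <- as.numeric(predict(model$fit, newX, s = model$lambda, type = "response"))
    m <- cbind(1 - p, p); colnames(m) <- lv
    m
  } else {
    p <- predict(model$fit, newX, s = model$lambda, type = "response")[, , 1]
    if (is.null(dim(p))) p <- matrix(p, nrow = 1, dimnames = list(NULL, names(p)))
    p[, lv, drop = FALSE]
  }
}

as_prob_matrix <- function(p, lv) {
  if (is.matrix(p) && ncol(p) == length(lv)) {
    colnames(p) <- lv
    return(p)
  }
  m <- matrix(p, ncol = length(lv), byrow = TRUE)
  colnames(m) <- lv
  m
}

#' @export
predict_prob.ls_gb_model <- function(model, newX) {
  newX <- newX[, model$features, drop = FALSE]
  lv <- model$levels
  p <- predict(model$fit, xgboost::xgb.DMatrix(newX))
  if (length(lv) == 2) {
    m <- cbind(1 - p, p); colnames(m) <- lv
    m
  } else {
    as_prob_matrix(p, lv)
  }
}

fit_lr <- function(X, y, lambda = 1e-3) {
  lv <- levels(factor(y))
  fam <- if (length(lv) == 2) "binomial" else "multinomial"
  yb <- factor(y, levels = lv)
  if (min(table(yb)) < 2) stop("a class has fewer than 2 training samples")
  fit <- suppressWarnings(
    glmnet::glmnet(X, yb, family = fam, alpha = 0,
                   lambda = c(1, 0.1, lambda), standardize = TRUE))
  structure(list(fit = fit, lambda = lambda, levels = lv,
                 features = colnames(X), algorithm = "logistic_regression"),
            class = "ls_lr_model")
}

fit_gb <- function(X, y, nrounds = 30L, seed = 1L) {
  lv <- levels(factor(y))
  yb <- as.integer(factor(y, levels = lv)) - 1L
  params <- list(max_depth = 3, eta = 0.3, nthread = 1,
                 verbosity = 0, seed = seed)
  if (length(lv) == 2) {
    params$objective <- "binary:logistic"
  } else {
    params$objective <- "multi:softprob"
    params$num_class <- length(lv)
  }
  fit <- xgboost::xgb.train(params, xgboost::xgb.DMatrix(X, label = yb),
                            nrounds = nrounds)
  structure(list(fit = fit, levels = lv, features = colnames(X),
                 algorithm = "gradient_boosting"),
            class = "ls_gb_model")
}

inner_cv_accuracy <- function(fitter, X, y, k, seed) {
  set.seed(seed)
  y <- factor(y)
  folds <- integer(length(y))
  for (lv in levels(y)) { # stratified fold assignment
    idx <- which(y == lv)
    folds[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
  }
  correct <- 0L; total <- 0L
  for (f in seq_len(k)) {
    tr <- folds != f; te <- !tr
    if (length(unique(y[tr])) < 2 || !any(te)) next
    model <- tryCatch(fitter(X[tr, , drop = FALSE], y[tr]),
                      error = function(e) prior_model(y[tr]))
    pr <- predict_prob(model, X[te, , drop = FALSE])
    pred <- colnames(pr)[max.col(pr, ties.method = "first")]
    correct <- correct + sum(pred == as.character(y[te]))
    total <- total + sum(te)
  }
  if (total == 0) return(0)
  correct / total
}

#' Train the better of logistic regression and gradient boosting
#'
#' Fits both algorithms on the selected features and keeps the one with the
#' higher inner cross-validation accuracy (ties go to logistic regression,
#' the simpler model). An empty feature set falls back to the training
#' majority-class prior.
#'
#' @param X training matrix restricted to the selected features
#' @param y training labels
#' @param seed RNG seed (inner fold assignment, boosting)
#' @param config an [pipeline_config()]
#' @return fitted model object with an `algorithm` field; class
#'   probabilities for new rows via the internal `predict_prob()` generic
#' @export
train_feature_set_model <- function(X, y, seed = 1L,
                                    config = pipeline_config()) {
  if (length(unique(y)) < 2) stop("labels must contain at least 2 classes")
  if (is.null(X) || ncol(X) == 0) return(prior_model(y))
  lr_fitter <- function(Xt, yt) fit_lr(Xt, yt)
  gb_fitter <- function(Xt, yt) fit_gb(Xt, yt, nrounds = config$xgb_nrounds,
                                       seed = seed)
  acc_lr <- inner_cv_accuracy(lr_fitter, X, y, config$inner_folds, seed)
  acc_gb <- inner_cv_accuracy(gb_fitter, X, y, config$inner_folds, seed)
  model <- tryCatch(
    if (acc_gb > acc_lr) gb_fitter(X, y) else lr_fitter(X, y),
    error = function(e) prior_model(y))
  attr(model, "inner_accuracy") <- max(acc_lr, acc_gb)
  model
}

#' Leave-one-subject-out cross-validation of the per-feature-set models
#'
#' For every held-out participant and every feature set, runs NRLR feature
#' selection and model training on the remaining participants only and
#' records the held-out class probabilities. Participants absent from a
#' feature-set matrix get missing probabilities there.
#'
#' @param matrices named list of imputed per-feature-set matrices (rownames
#'   = participant ids)
#' @param labels named character vector (participant id -> class)
#' @param seed top-level seed; each fold derives its own seed
#' @param config an [pipeline_config()]
#' @param verbose print fold progress
#' @return list of class `ls_loso`: `probs` (data.table participant_id,
#'   feature_set, class, prob), `folds` (per fold and set: selected
#'   features, chosen algorithm, training ids), `levels`
#' @export
loso_cross_validate <- function(matrices, labels, seed = 1L,
                                config = pipeline_config(), verbose = FALSE) {
  ids <- sort(unique(unlist(lapply(matrices, rownames))))
  if (length(ids) < 3) stop("need at least 3 participants")
  stopifnot(all(ids %in% names(labels)))
  lv <- levels(factor(labels[ids]))
  probs <- list(); folds <- list()
  for (fi in seq_along(ids)) {
    id <- ids[fi]
    if (verbose) message("fold ", fi, "/", length(ids))
    for (s in names(matrices)) {
      m <- matrices[[s]]
      if (!(id %in% rownames(m))) next
      tr_ids <- setdiff(rownames(m), id)
      Xtr <- m[tr_ids, , drop = FALSE]
      ytr <- labels[tr_ids]
      if (length(unique(ytr)) < 2) next
      fold_seed <- (seed * 1000L + fi * 7L + match(s, names(matrices))) %% .Machine$integer.max
      sel <- nrlr_select(Xtr, ytr, feature_segment_groups(colnames(Xtr)),
                         seed = fold_seed, config = config)
      model <- train_feature_set_model(Xtr[, sel, drop = FALSE], ytr,
                                       seed = fold_seed, config = config)
      pr <- predict_prob(model, m[id, sel, drop = FALSE])
      probs[[length(probs) + 1L]] <- data.table::data.table(
        participant_id = id, feature_set = s, class = colnames(pr),
        prob = as.numeric(pr[1, ]))
      folds[[length(folds) + 1L]] <- data.table::data.table(
        participant_id = id, feature_set = s,
        algorithm = model$algorithm,
        n_selected = length(sel), selected = list(sel),
        training_ids = list(tr_ids))
    }
  }
  structure(list(probs = data.table::rbindlist(probs),
                 folds = data.table::rbindlist(folds),
                 levels = lv),
            class = "ls_loso")
}

# SAMME AdaBoost with gradient-boosting base estimators
adaboost_gb <- function(X, y, n_rounds = 10L, base_nrounds = 20L, seed = 1L) {
  lv <- levels(factor(y))
  K <- length(lv)
  yi <- as.integer(factor(y, levels = lv))
  n <- nrow(X)
  w <- rep(1 / n, n)
  learners <- list(); alphas <- numeric(0)
  for (r in seq_len(n_rounds)) {
    params <- list(max_depth = 2, eta = 0.5, nthread = 1, verbosity = 0,
                   seed = seed + r)
    if (K == 2) params$objective <- "binary:logistic"
    else { params$objective <- "multi:softprob"; params$num_class <- K }
    dm <- xgboost::xgb.DMatrix(X, label = yi - 1L, weight = w * n)
    fit <- xgboost::xgb.train(params, dm, nrounds = base_nrounds)
    pr <- predict(fit, xgboost::xgb.DMatrix(X))
    pred <- if (K == 2) as.integer(pr > 0.5) + 1L
            else max.col(as_prob_matrix(pr, lv), ties.method = "first")
    miss <- pred != yi
    err <- sum(w * miss)
    if (err <= 0) { learners[[r]] <- fit; alphas[r] <- 10; break }
    if (err >= 1 - 1 / K) { if (r == 1) { learners[[r]] <- fit; alphas[r] <- 1e-6 }; break }
    alpha <- log((1 - err) / err) + log(K - 1)
    learners[[r]] <- fit; alphas[r] <- alpha
    w <- w * exp(alpha * miss)
    w <- w / sum(w)
  }
  structure(list(learners = learners, alphas = alphas, levels = lv, K = K),
            class = "ls_adaboost")
}

predict_adaboost <- function(model, newX) {
  K <- model$K
  votes <- matrix(0, nrow = nrow(newX), ncol = K,
                  dimnames = list(NULL, model$levels))
  for (r in seq_along(model$learners)) {
    pr <- predict(model$learners[[r]], xgboost::xgb.DMatrix(newX))
    pred <- if (K == 2) as.integer(pr > 0.5) + 1L
            else max.col(as_prob_matrix(pr, model$levels), ties.method = "first")
    for (k in seq_len(K)) votes[pred == k, k] <- votes[pred == k, k] + model$alphas[r]
  }
  model$levels[max.col(votes, ties.method = "first")]
}

# meta-feature table from LOSO probabilities: binary keeps one class's
# probability per set, multiclass keeps all classes per set
meta_features <- function(probs, feature_sets, levels) {
  keep_classes <- if (length(levels) == 2) levels[2] else levels
  dt <- probs[feature_set %in% feature_sets & class %in% keep_classes]
  dt[, col := paste(feature_set, class, sep = ":")]
  wide <- data.table::dcast(dt, participant_id ~ col, value.var = "prob")
  wide <- wide[complete.cases(wide)] # intersection of participants
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$participant_id
  m
}

#' Fuse per-feature-set probabilities with the AdaBoost ensemble
#'
#' Concatenates the LOSO detection probabilities of the included feature
#' sets into meta-features (one class per set for the binary level task,
#' all classes per set for the 3-class change task), then trains and
#' evaluates AdaBoost with gradient-boosting base estimators leave-one-out
#' on the meta-features. Participants must be present in every included
#' set (row intersection).
#'
#' @param loso an `ls_loso` (or its `probs` table)
#' @param labels named class vector
#' @param feature_sets which sets to fuse (default: all in the table)
#' @param seed RNG seed
#' @param config an [pipeline_config()]
#' @return list: `predictions` (data.table), `metrics`, `meta_n`
#' @export
ensemble_combine <- function(loso, labels, feature_sets = NULL, seed = 1L,
                             config = pipeline_config()) {
  probs <- if (inherits(loso, "ls_loso")) loso$probs else loso
  lv <- levels(factor(labels))
  feature_sets <- feature_sets %||% sort(unique(probs$feature_set))
  M <- meta_features(probs, feature_sets, lv)
  ids <- rownames(M)
  if (length(ids) < 3) stop("too few participants with complete probabilities")
  y <- factor(labels[ids], levels = lv)
  preds <- character(length(ids))
  for (i in seq_along(ids)) {
    tr <- setdiff(seq_along(ids), i)
    model <- adaboost_gb(M[tr, , drop = FALSE], y[tr],
                         n_rounds = config$ada_rounds,
                         base_nrounds = config$ada_xgb_nrounds,
                         seed = seed + i)
    preds[i] <- predict_adaboost(model, M[i, , drop = FALSE])
  }
  list(predictions = data.table::data.table(
         participant_id = ids, true = as.character(y), predicted = preds),
       metrics = compute_metrics(as.character(y), preds),
       meta_n = length(ids))
}

#' Ablation study over feature-set combinations
#'
#' Evaluates [ensemble_combine()] on every subset of 2..k feature sets
#' (7 sets give 120 combinations) and reports each subset's accuracy.
#'
#' @param loso an `ls_loso`
#' @param labels named class vector
#' @param seed RNG seed
#' @param config an [pipeline_config()]
#' @return list: `results` (data.table combo/size/accuracy/n), `best`
#' @export
ablate_feature_sets <- function(loso, labels, seed = 1L,
                                config = pipeline_config()) {
  probs <- if (inherits(loso, "ls_loso")) loso$probs else loso
  sets <- sort(unique(probs$feature_set))
  if (length(sets) < 2) stop("need at least 2 feature sets")
  rows <- list()
  for (k in 2:length(sets)) {
    for (combo in utils::combn(sets, k, simplify = FALSE)) {
      res <- ensemble_combine(probs, labels, feature_sets = combo,
                              seed = seed, config = config)
      rows[[length(rows) + 1L]] <- data.table::data.table(
        combo = paste(combo, collapse = "+"), size = k,
        accuracy = res$metrics$accuracy, n = res$meta_n)
    }
  }
  results <- data.table::rbindlist(rows)
  list(results = results, best = results[which.max(accuracy)])
}

#' Classification metrics
#'
#' Accuracy, per-class precision/recall/F1 (percent), macro averages, the
#' Matthews correlation coefficient (multiclass generalization; reduces to
#' the usual binary formula) and the majority-class baseline accuracy.
#'
#' @param truth,predicted equal-length class vectors
#' @return list of metrics
#' @export
compute_metrics <- function(truth, predicted) {
  if (length(truth) != length(predicted)) stop("length mismatch")
  if (length(truth) == 0) stop("empty input")
  lv <- sort(unique(c(truth, predicted)))
  tf <- factor(truth, levels = lv); pf <- factor(predicted, levels = lv)
  cm <- table(true = tf, predicted = pf)
  n <- length(truth)
  per_class <- lapply(lv, function(l) {
    tp <- cm[l, l]; fp <- sum(cm[, l]) - tp; fn <- sum(cm[l, ]) - tp
    precision <- if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
    recall <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
    f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
      2 * precision * recall / (precision + recall) else NA_real_
    list(precision = precision, recall = recall, f1 = f1)
  })
  names(per_class) <- lv
  # multiclass MCC (covariance form); equals the binary formula for 2 classes
  c_ok <- sum(diag(cm))
  t_k <- rowSums(cm); p_k <- colSums(cm)
  num <- c_ok * n - sum(p_k * t_k)
  den <- sqrt(n^2 - sum(p_k^2)) * sqrt(n^2 - sum(t_k^2))
  mcc <- if (den > 0) num / den else 0
  list(
    accuracy = 100 * mean(truth == predicted),
    per_class = per_class,
    macro_precision = mean(vapply(per_class, `[[`, numeric(1), "precision"), na.rm = TRUE),
    macro_recall = mean(vapply(per_class, `[[`, numeric(1), "recall"), na.rm = TRUE),
    macro_f1 = mean(vapply(per_class, `[[`, numeric(1), "f1"), na.rm = TRUE),
    mcc = mcc,
    baseline_accuracy = 100 * max(table(tf)) / n,
    confusion = cm
  )
}
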