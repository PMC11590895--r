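.model_label_col <- function(modelTag) {
  switch(modelTag, model1 = "action_label", model2 = "state_label",
         model3 = "label", stop("unknown model tag: ", modelTag))
}

.model_classes <- function(modelTag) {
  switch(modelTag, model1 = ACTION_CLASSES, model2 = STATE_CLASSES,
         model3 = EVENT_CLASSES)
}

#' Individual-wise train/test split
#'
#' Assigns whole calves to the test set so that no individual contributes
#' windows to both sides — the model must generalise to unseen animals.
#' \code{nTest} calf ids are drawn uniformly without replacement (e.g. 6 of
#' 48, leaving 42 for training); within the training rows a row-level
#' validation subset of \code{valFraction} (default 0.2, the 8:2 split used
#' for tuning and early stopping) is sampled.
#'
#' @param ft a \linkS4class{FeatureTable} with a \code{calf_id} column.
#' @param nTest number of test calves (1 <= nTest < number of calves).
#' @param valFraction fraction of training rows held out for validation.
#' @param seed integer seed.
#' @return A \code{SplitPlan}: list(train_ids, test_ids, train_rows,
#'   val_rows, test_rows, seed) with row indices into the table.
#' @export
splitByIndividual <- function(ft, nTest, valFraction = 0.2, seed = 1) {
  stopifnot(valFraction > 0, valFraction < 1)
  d <- tableData(ft)
  ids <- unique(d$calf_id)
  if (nTest < 1 || nTest >= length(ids))
    stop("argument error: need 1 <= nTest < number of calves", call. = FALSE)
  set.seed(seed)
  test_ids <- sort(sample(ids, nTest))
  train_ids <- sort(setdiff(ids, test_ids))
  tr <- which(d$calf_id %in% train_ids)
  val <- sort(sample(tr, round(valFraction * length(tr))))
  structure(list(train_ids = train_ids, test_ids = test_ids,
                 train_rows = setdiff(tr, val), val_rows = val,
                 test_rows = which(d$calf_id %in% test_ids),
                 seed = as.integer(seed)),
            class = "SplitPlan")
}

.subset_ft <- function(ft, rows) {
  featureTable(ft@data[rows, , drop = FALSE], ft@featureNames, ft@modelTag)
}

#' SMOTE oversampling of the minority class
#'
#' Balances a binary training set by synthesising minority-class rows:
#' each synthetic row lies on the segment between a random minority row and
#' one of its \code{kNeighbors} nearest minority neighbours (Euclidean),
#' with a uniform interpolation factor. Originals are preserved and the
#' majority class is never touched; rows are added until the classes are
#' equal-sized. Apply to training data only.
#'
#' @param x numeric matrix of feature rows.
#' @param labels binary label vector (character or factor).
#' @param seed integer seed.
#' @param kNeighbors number of nearest neighbours (minority count must
#'   exceed it).
#' @return list(x, labels) with synthetic rows appended.
#' @export
oversampleMinority <- function(x, labels, seed = 1, kNeighbors = 5) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  tab <- table(labels)
  if (length(tab) != 2)
    stop("argument error: labels must be binary", call. = FALSE)
  minority <- names(tab)[which.min(tab)]
  n_new <- max(tab) - min(tab)
  if (n_new == 0) return(list(x = x, labels = labels))
  mi <- which(labels == minority)
  if (length(mi) <= kNeighbors)
    stop("parameter error: minority count (", length(mi),
         ") must exceed kNeighbors (", kNeighbors,
         "); lower kNeighbors", call. = FALSE)
  set.seed(seed)
  xm <- x[mi, , drop = FALSE]
  D <- as.matrix(stats::dist(xm))
  diag(D) <- Inf
  nn <- t(apply(D, 1, function(r) order(r)[seq_len(kNeighbors)]))
  base <- sample.int(nrow(xm), n_new, replace = TRUE)
  pick <- nn[cbind(base, sample.int(kNeighbors, n_new, replace = TRUE))]
  gamma <- stats::runif(n_new)
  synth <- xm[base, , drop = FALSE] +
    gamma * (xm[pick, , drop = FALSE] - xm[base, , drop = FALSE])
  list(x = rbind(x, synth), labels = c(labels, rep(minority, n_new)))
}

.default_hyper <- list(learning_rate = 0.1, n_estimators = 400,
                       max_depth = 0, max_leaves = 31,
                       min_child_weight = 1, subsample = 1)

.xgb_train <- function(x, y_int, n_class, hyper, seed, valx = NULL,
                       valy = NULL, early_stop = 50) {
  h <- utils::modifyList(.default_hyper, hyper)
  params <- list(objective = "multi:softprob", num_class = n_class,
                 eta = h$learning_rate, max_depth = h$max_depth,
                 max_leaves = h$max_leaves, tree_method = "hist",
                 grow_policy = "lossguide",            # leaf-wise growth
                 min_child_weight = h$min_child_weight,
                 subsample = h$subsample,
                 eval_metric = "mlogloss", nthread = 1, seed = seed)
  dtrain <- xgboost::xgb.DMatrix(x, label = y_int)
  watch <- list(train = dtrain)
  if (!is.null(valx)) watch$val <- xgboost::xgb.DMatrix(valx, label = valy)
  xgboost::xgb.train(params = params, data = dtrain,
                     nrounds = h$n_estimators, evals = watch,
                     early_stopping_rounds = if (!is.null(valx)) early_stop else NULL,
                     verbose = 0)
}

#' Train one of the three behavior classifiers
#'
#' Fits a leaf-wise gradient-boosted tree ensemble for the given model tag:
#' \code{model1} (4-class feeding-related actions), \code{model2} (2-class
#' posture) or \code{model3} (2-class cough events). When a validation
#' table is supplied, training stops early after 50 rounds without
#' improvement of the validation log-loss. Deterministic given the seed at
#' single-threaded settings.
#'
#' @param trainFt training \linkS4class{FeatureTable}.
#' @param valFt validation \linkS4class{FeatureTable} (same features), or
#'   NULL for a fixed number of rounds.
#' @param modelTag \code{"model1"}, \code{"model2"} or \code{"model3"}.
#' @param hyperparameters named list overriding the defaults
#'   (\code{learning_rate}, \code{n_estimators}, \code{max_depth},
#'   \code{max_leaves}, ...).
#' @param seed integer seed.
#' @return A \code{TrainedModel} (classed list with the fitted booster,
#'   class list, feature names and metadata).
#' @export
trainModel <- function(trainFt, valFt = NULL, modelTag = modelTag(trainFt),
                       hyperparameters = list(), seed = 1) {
  labcol <- .model_label_col(modelTag)
  classes <- .model_classes(modelTag)
  y <- tableData(trainFt)[[labcol]]
  if (length(unique(y)) < 2)
    stop("argument error: training labels contain a single class", call. = FALSE)
  if (!all(y %in% classes))
    stop("vocabulary error: unexpected label(s) ",
         paste(setdiff(y, classes), collapse = ", "), call. = FALSE)
  x <- featureMatrix(trainFt)
  valx <- valy <- NULL
  if (!is.null(valFt)) {
    if (!identical(featureNames(valFt), featureNames(trainFt)))
      stop("shape error: train/validation feature names differ", call. = FALSE)
    valx <- featureMatrix(valFt)
    valy <- match(tableData(valFt)[[labcol]], classes) - 1L
  }
  booster <- .xgb_train(x, match(y, classes) - 1L, length(classes),
                        hyperparameters, seed, valx, valy)
  structure(list(modelTag = modelTag, booster = booster, classes = classes,
                 featureNames = featureNames(trainFt),
                 hyperparameters = utils::modifyList(.default_hyper, hyperparameters),
                 seed = seed,
                 bestIteration = booster$best_iteration),
            class = "TrainedModel")
}

#' Predict labels and class probabilities
#'
#' @param model a \code{TrainedModel}.
#' @param newdata a \linkS4class{FeatureTable} or numeric matrix whose
#'   feature columns match the training features exactly.
#' @return data.frame with \code{label} and one \code{prob_<class>} column
#'   per class; probabilities sum to 1 per row; the label is the argmax
#'   (ties resolved in class-list order).
#' @export
predictModel <- function(model, newdata) {
  x <- if (is(newdata, "FeatureTable")) {
    if (!setequal(featureNames(newdata), model$featureNames))
      stop("shape error: feature columns do not match the training features",
           call. = FALSE)
    featureMatrix(newdata)[, model$featureNames, drop = FALSE]
  } else {
    x <- as.matrix(newdata)
    if (!setequal(colnames(x), model$featureNames))
      stop("shape error: feature columns do not match the training features",
           call. = FALSE)
    x[, model$featureNames, drop = FALSE]
  }
  k <- length(model$classes)
  if (nrow(x) == 0) {
    out <- data.frame(label = character())
    for (cl in model$classes) out[[paste0("prob_", cl)]] <- numeric()
    return(out)
  }
  p <- matrix(predict(model$booster, xgboost::xgb.DMatrix(x)), ncol = k)
  out <- data.frame(label = model$classes[max.col(p, ties.method = "first")])
  for (j in seq_len(k)) out[[paste0("prob_", model$classes[j])]] <- p[, j]
  out
}

#' Stratified k-fold cross-validation
#'
#' Splits rows into k label-stratified folds; each fold serves once as the
#' validation fold while the model trains on the remainder. With
#' \code{oversample = TRUE} (binary tags only) SMOTE is applied inside each
#' training fold only — validation folds always keep their original class
#' ratio, guarding against oversampling leakage.
#'
#' @param ft a \linkS4class{FeatureTable}.
#' @param modelTag model tag (defaults to the table's).
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @param oversample apply SMOTE inside training folds.
#' @param hyperparameters passed to \code{\link{trainModel}}.
#' @return list(metrics = per-fold data.frame(fold, accuracy, macro_f1),
#'   folds = fold assignment per row).
#' @export
crossValidate <- function(ft, modelTag = modelTag(ft), k = 5, seed = 1,
                          oversample = FALSE, hyperparameters = list()) {
  stopifnot(k >= 2)
  labcol <- .model_label_col(modelTag)
  classes <- .model_classes(modelTag)
  d <- tableData(ft)
  y <- d[[labcol]]
  if (any(table(y) < k))
    stop("stratification error: every class needs at least k members",
         call. = FALSE)
  set.seed(seed)
  fold <- integer(nrow(d))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  hp <- utils::modifyList(list(n_estimators = 100), hyperparameters)
  metrics <- lapply(seq_len(k), function(f) {
    tr <- which(fold != f); va <- which(fold == f)
    xtr <- featureMatrix(ft)[tr, , drop = FALSE]
    ytr <- y[tr]
    if (oversample) {
      os <- oversampleMinority(xtr, ytr, seed = seed + f)
      xtr <- os$x; ytr <- os$labels
    }
    booster <- .xgb_train(xtr, match(ytr, classes) - 1L, length(classes),
                          hp, seed + f)
    p <- matrix(predict(booster,
                        xgboost::xgb.DMatrix(featureMatrix(ft)[va, , drop = FALSE])),
                ncol = length(classes))
    pred <- classes[max.col(p, ties.method = "first")]
    ms <- classMetrics(confusion(y[va], pred, classes))
    data.frame(fold = f,
               accuracy = mean(pred == y[va]),
               macro_f1 = ms$f1[ms$class == "Overall"] / 100)
  })
  list(metrics = do.call(rbind, metrics), folds = fold)
}

#' Specification of a hyperparameter search
#'
#' @param nTrials number of sampled configurations (>= 1).
#' @param seed integer seed.
#' @param learningRate range for the learning rate (sampled log-uniformly).
#' @param nEstimators integer range for the number of boosting rounds.
#' @param maxDepth integer range for the tree depth (0 = unlimited,
#'   leaf-wise).
#' @param objective validation objective; \code{"macro_f1"} (maximised).
#' @return A \code{TuningSpec} (classed list).
#' @export
tuningSpec <- function(nTrials = 20, seed = 1,
                       learningRate = c(0.01, 0.3),
                       nEstimators = c(50L, 400L),
                       maxDepth = c(0L, 10L),
                       objective = "macro_f1") {
  stopifnot(nTrials >= 1, all(is.finite(learningRate)),
            all(is.finite(nEstimators)), all(is.finite(maxDepth)))
  structure(list(nTrials = nTrials, seed = seed,
                 learningRate = learningRate, nEstimators = nEstimators,
                 maxDepth = maxDepth, objective = objective),
            class = "TuningSpec")
}

#' Random-search hyperparameter tuning
#'
#' Samples \code{nTrials} configurations from the spec's search space
#' (learning rate, number of estimators, max depth), trains each on the
#' training table and scores it on the validation table with the spec's
#' objective (macro F1). Returns the best configuration and the full trial
#' log; seeded and reproducible.
#'
#' @param trainFt,valFt training and validation \linkS4class{FeatureTable}s.
#' @param spec a \code{\link{tuningSpec}}.
#' @param modelTag model tag (defaults to the training table's).
#' @return list(best = hyperparameter list, best_objective, trials =
#'   data.frame log).
#' @export
tuneHyperparameters <- function(trainFt, valFt, spec = tuningSpec(),
                                modelTag = modelTag(trainFt)) {
  labcol <- .model_label_col(modelTag)
  classes <- .model_classes(modelTag)
  set.seed(spec$seed)
  lr <- exp(stats::runif(spec$nTrials, log(spec$learningRate[1]),
                         log(spec$learningRate[2])))
  ne <- sample(seq(spec$nEstimators[1], spec$nEstimators[2]), spec$nTrials,
               replace = TRUE)
  md <- sample(seq(spec$maxDepth[1], spec$maxDepth[2]), spec$nTrials,
               replace = TRUE)
  yval <- tableData(valFt)[[labcol]]
  trials <- lapply(seq_len(spec$nTrials), function(i) {
    hp <- list(learning_rate = lr[i], n_estimators = ne[i], max_depth = md[i])
    m <- trainModel(trainFt, NULL, modelTag, hp, seed = spec$seed)
    pred <- predictModel(m, valFt)$label
    ms <- classMetrics(confusion(yval, pred, classes))
    data.frame(trial = i, learning_rate = lr[i], n_estimators = ne[i],
               max_depth = md[i],
               objective = ms$f1[ms$class == "Overall"] / 100)
  })
  log <- do.call(rbind, trials)
  best <- log[which.max(log$objective), ]
  list(best = list(learning_rate = best$learning_rate,
                   n_estimators = best$n_estimators,
                   max_depth = best$max_depth),
       best_objective = best$objective, trials = log)
}
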