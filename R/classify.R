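# Uniform training/prediction contract over the five-classifier suite:
# KNN (caret::knn3), decision tree (rpart), random forest
# (randomForest), and two gradient-boosted tree models backed by
# xgboost — GB with zero regularization (the plain boosting update) and
# XGB with the regularized objective. Adapters expose class-posterior
# matrices whose rows sum to 1.

MODEL_NAMES <- c("KNN", "DT", "RF", "GB", "XGB")

#' Default hyperparameter grid per model
#' @param name one of `"KNN"`, `"DT"`, `"RF"`, `"GB"`, `"XGB"`.
#' @return named list of candidate value vectors.
#' @export
default_grid <- function(name) {
  switch(match.arg(name, MODEL_NAMES),
    KNN = list(k = c(3, 5, 7, 11)),
    DT = list(maxdepth = c(3, 5, 10, 30)),
    RF = list(ntree = c(100, 300), mtry_mode = c("sqrt", "all")),
    GB = list(eta = c(0.05, 0.1, 0.3), nrounds = c(100, 300),
              max_depth = c(2, 3, 5)),
    XGB = list(eta = c(0.05, 0.1, 0.3), nrounds = c(100, 300),
               max_depth = c(2, 3, 5), lambda = c(0, 1)))
}

# Sensible single defaults used when tuning is switched off.
default_params <- function(name) {
  switch(match.arg(name, MODEL_NAMES),
    KNN = list(k = 5),
    DT = list(maxdepth = 30),
    RF = list(ntree = 100, mtry_mode = "sqrt"),
    GB = list(eta = 0.1, nrounds = 100, max_depth = 3),
    XGB = list(eta = 0.1, nrounds = 100, max_depth = 3, lambda = 1))
}

#' Specify a classifier and its hyperparameter grid
#'
#' @param name one of `"KNN"`, `"DT"`, `"RF"`, `"GB"`, `"XGB"`.
#' @param grid named list of candidate values (default [default_grid()]).
#' @param tuned named list of chosen values (filled by [grid_search()];
#'   defaults to [default_params()] so an untuned spec is usable).
#' @param seed integer seed for stochastic backends.
#' @return list of class `classifier_spec`.
#' @export
classifier_spec <- function(name, grid = default_grid(name), tuned = NULL,
                            seed = 1) {
  name <- match.arg(name, MODEL_NAMES)
  validate_grid(name, grid)
  structure(list(name = name, grid = grid,
                 tuned = tuned %||% default_params(name), seed = seed),
            class = "classifier_spec")
}

validate_grid <- function(name, grid) {
  if (!length(grid)) stop_crisp("crisp_validation_error", "empty grid")
  chk <- function(key, ok) {
    if (!is.null(grid[[key]]) && !all(ok(grid[[key]])))
      stop_crisp("crisp_validation_error",
                 "invalid %s grid value for %s", key, name)
  }
  chk("k", function(v) is.numeric(v) & v >= 1 & v == round(v))
  chk("maxdepth", function(v) is.numeric(v) & v >= 1)
  chk("ntree", function(v) is.numeric(v) & v >= 1)
  chk("mtry_mode", function(v) v %in% c("sqrt", "all"))
  chk("eta", function(v) is.numeric(v) & v > 0 & v <= 1)
  chk("nrounds", function(v) is.numeric(v) & v >= 1)
  chk("max_depth", function(v) is.numeric(v) & v >= 1)
  chk("lambda", function(v) is.numeric(v) & v >= 0)
  invisible(TRUE)
}

#' Fit a classifier from its spec
#'
#' @param spec a [classifier_spec()] (its `tuned` values parameterize the
#'   backend).
#' @param x training feature matrix/data.frame.
#' @param y training class labels.
#' @return object of class `crisp_model` with the backend fit, the
#'   ordered class levels, and the feature-name contract enforced at
#'   prediction.
#' @export
fit_classifier <- function(spec, x, y) {
  x <- as.data.frame(x)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2)
    stop_crisp("crisp_fit_error", "single-class training labels")
  p <- spec$tuned
  set.seed(spec$seed)
  fit <- switch(spec$name,
    KNN = caret::knn3(as.matrix(x), y, k = p$k),
    DT = rpart::rpart(label ~ ., data = cbind(x, label = y),
                      method = "class",
                      control = rpart::rpart.control(
                        maxdepth = min(p$maxdepth, 30), cp = 0,
                        minsplit = 2, minbucket = 1, xval = 0)),
    RF = randomForest::randomForest(
      x = x, y = y, ntree = p$ntree,
      mtry = if (identical(p$mtry_mode, "all")) ncol(x)
             else max(1, floor(sqrt(ncol(x))))),
    GB = fit_xgb(x, y, eta = p$eta, nrounds = p$nrounds,
                 max_depth = p$max_depth, lambda = 0, alpha = 0,
                 seed = spec$seed),
    XGB = fit_xgb(x, y, eta = p$eta, nrounds = p$nrounds,
                  max_depth = p$max_depth, lambda = p$lambda %||% 1,
                  alpha = 0, seed = spec$seed))
  structure(list(spec = spec, fit = fit, levels = levels(y),
                 feature_names = colnames(x)), class = "crisp_model")
}

fit_xgb <- function(x, y, eta, nrounds, max_depth, lambda, alpha, seed) {
  k <- nlevels(y)
  params <- list(eta = eta, max_depth = max_depth, lambda = lambda,
                 alpha = alpha, nthread = 1, seed = seed)
  if (k == 2) {
    params$objective <- "binary:logistic"
  } else {
    params$objective <- "multi:softprob"
    params$num_class <- k
  }
  xgboost::xgb.train(
    params = params,
    data = xgboost::xgb.DMatrix(as.matrix(x),
                                label = as.integer(y) - 1L),
    nrounds = nrounds, verbose = 0)
}

#' Class-posterior probabilities for new rows
#'
#' Rows sum to 1 (within 1e-9); the column order is the model's class
#' level order. KNN posteriors are neighbor vote fractions, DT posteriors
#' leaf class frequencies.
#'
#' @param model a fitted `crisp_model`.
#' @param newdata rows with exactly the model's feature columns.
#' @return numeric matrix, one row per input row, one column per class.
#' @export
predict_proba <- function(model, newdata) {
  newdata <- as.data.frame(newdata)
  if (!identical(colnames(newdata), model$feature_names))
    stop_crisp("crisp_schema_error",
               "feature columns do not match model: expected [%s], got [%s]",
               paste(model$feature_names, collapse = ", "),
               paste(colnames(newdata), collapse = ", "))
  k <- length(model$levels)
  pr <- switch(model$spec$name,
    KNN = predict(model$fit, as.matrix(newdata), type = "prob"),
    DT = predict(model$fit, newdata, type = "prob"),
    RF = predict(model$fit, newdata, type = "prob"),
    GB = ,
    XGB = {
      raw <- predict(model$fit, xgboost::xgb.DMatrix(as.matrix(newdata)))
      if (k == 2) cbind(1 - raw, raw) else matrix(raw, ncol = k)
    })
  pr <- as.matrix(pr)
  colnames(pr) <- model$levels
  pr / rowSums(pr)
}

#' Predicted class labels (argmax of the posterior, first level on ties)
#' @param model a fitted `crisp_model`.
#' @param newdata rows with the model's feature columns.
#' @return factor of predicted labels over the model's class levels.
#' @export
predict_label <- function(model, newdata) {
  pr <- predict_proba(model, newdata)
  factor(model$levels[max.col(pr, ties.method = "first")],
         levels = model$levels)
}

#' Exhaustive grid search by stratified inner cross-validation
#'
#' Every grid point is scored by mean accuracy over `inner_folds`
#' stratified folds of the training rows; the best point wins, with ties
#' going to the earlier point in grid order. A single-point grid is
#' returned without fitting anything.
#'
#' @param spec a [classifier_spec()].
#' @param x,y training rows and labels (inner CV happens inside the
#'   caller's outer training fold only).
#' @param inner_folds number of inner folds (default 5).
#' @param seed integer seed for fold assignment and fits.
#' @return the spec with `tuned` set to the winning grid point and
#'   `tuning` holding the per-point mean accuracies.
#' @export
grid_search <- function(spec, x, y, inner_folds = 5, seed = 1) {
  validate_grid(spec$name, spec$grid)
  grid <- expand.grid(spec$grid, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  if (nrow(grid) == 1L) {
    spec$tuned <- as.list(grid[1L, , drop = FALSE])
    return(spec)
  }
  x <- as.data.frame(x)
  y <- droplevels(as.factor(y))
  if (min(table(y)) < inner_folds)
    stop_crisp("crisp_stratification_error",
               "a class has fewer members (%d) than inner folds (%d)",
               min(table(y)), inner_folds)
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(inner_folds), length(idx))
  }
  scores <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    cand <- spec
    cand$tuned <- as.list(grid[g, , drop = FALSE])
    acc <- numeric(inner_folds)
    for (f in seq_len(inner_folds)) {
      cand$seed <- stage_seed(seed, g * inner_folds + f)
      m <- fit_classifier(cand, x[fold != f, , drop = FALSE], y[fold != f])
      acc[f] <- mean(predict_label(m, x[fold == f, , drop = FALSE]) ==
                       y[fold == f])
    }
    scores[g] <- mean(acc)
  }
  best <- which.max(scores)  # which.max takes the first maximum: grid order
  spec$tuned <- as.list(grid[best, , drop = FALSE])
  spec$tuning <- cbind(grid, mean_accuracy = scores)
  spec
}
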