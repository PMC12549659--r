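# Cross-validated evaluation of baseline vs CRISP configurations under
# the cycle-level ("overall") and subject-wise protocols, with a leakage
# guard around held-out labels, majority/modal subject voting with
# mean-posterior tie-breaks, the six standard metrics, and paired t-tests
# across folds.

METRIC_NAMES <- c("accuracy", "precision", "recall", "specificity", "f1",
                  "roc_auc")

#' Cross-validation fold plan
#'
#' @param n_folds number of outer folds (default 5).
#' @param split_unit `"subject_grouped"` (no subject straddles train and
#'   test; the default for both protocols) or `"cycle_stratified"`
#'   (label-stratified over cycles, provided to emulate per-cycle
#'   splitting).
#' @param seed integer seed for fold assignment.
#' @return list of class `fold_plan`.
#' @export
fold_plan <- function(n_folds = 5, split_unit = c("subject_grouped",
                                                  "cycle_stratified"),
                      seed = 1) {
  structure(list(n_folds = n_folds, split_unit = match.arg(split_unit),
                 seed = seed), class = "fold_plan")
}

#' Assign feature-matrix rows to cross-validation test folds
#'
#' Subject-grouped splits stratify subjects by label and keep all of a
#' subject's cycles in one fold; cycle-stratified splits stratify rows by
#' label directly.
#'
#' @param features a feature matrix from [build_feature_matrix()].
#' @param plan a [fold_plan()].
#' @return list of `n_folds` integer vectors of test-row indices (a
#'   partition of the rows).
#' @export
make_folds <- function(features, plan = fold_plan()) {
  set.seed(plan$seed)
  k <- plan$n_folds
  fold <- integer(nrow(features))
  if (plan$split_unit == "subject_grouped") {
    subj <- unique(features[, c("subject_id", "label")])
    cnt <- table(subj$label)
    if (any(cnt < k))
      stop_crisp("crisp_split_error",
                 "a class has fewer subjects (%d) than folds (%d)",
                 min(cnt), k)
    sfold <- integer(nrow(subj))
    for (cl in levels(subj$label)) {
      idx <- sample(which(subj$label == cl))
      sfold[idx] <- rep_len(seq_len(k), length(idx))
    }
    map <- setNames(sfold, subj$subject_id)
    fold <- map[features$subject_id]
  } else {
    for (cl in levels(features$label)) {
      idx <- sample(which(features$label == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  }
  lapply(seq_len(k), function(f) which(fold == f))
}

#' Create a leakage guard over the label column
#'
#' During the fit phase, any request for a held-out row's label raises an
#' audit error; after `unseal()` (called once fitting is complete and
#' predictions exist) labels may be read for scoring.
#'
#' @param labels full label vector.
#' @param test_idx indices of held-out rows.
#' @return list with `get_labels(idx)`, `unseal()`, and `phase()`.
#' @export
make_label_guard <- function(labels, test_idx) {
  phase <- "fit"
  list(
    get_labels = function(idx) {
      if (phase == "fit" && any(idx %in% test_idx))
        stop_crisp("crisp_leakage_error",
                   "audit failure: held-out labels requested during fitting")
      labels[idx]
    },
    unseal = function() phase <<- "score",
    phase = function() phase
  )
}

#' Run one cross-validation fold of the pipeline
#'
#' CRISP configuration: correlation pruning, RFE, and SMOTE are fitted on
#' training rows only, then the classifier is (optionally grid-search
#' tuned and) fitted on the balanced training set and applied to the
#' held-out rows restricted to the selected columns. Baseline: the
#' classifier is fitted on the full feature panel with no curation or
#' balancing. Held-out labels are sealed behind a leakage guard until
#' prediction is complete.
#'
#' @param features feature matrix from [build_feature_matrix()].
#' @param train_idx,test_idx disjoint row index vectors.
#' @param configuration `"crisp"` or `"baseline"`.
#' @param spec a [classifier_spec()].
#' @param r_threshold,n_keep,n_trees,smote_k curation/balancing
#'   parameters (defaults 0.80, 10, 100, 5).
#' @param tune run [grid_search()] inside the fold (default `FALSE`:
#'   use the spec's tuned values).
#' @param inner_folds inner folds for tuning.
#' @param seed integer seed for the fold's stochastic stages.
#' @param guard optional pre-made [make_label_guard()].
#' @return list: `test_idx`, `pred` (factor), `proba` (matrix),
#'   `artifacts` (prune/RFE/SMOTE provenance/tuned values — all fitted on
#'   training rows only), `selected` columns.
#' @export
run_pipeline_fold <- function(features, train_idx, test_idx,
                              configuration = c("crisp", "baseline"),
                              spec = classifier_spec("XGB"),
                              r_threshold = 0.80, n_keep = 10,
                              n_trees = 100, smote_k = 5, tune = FALSE,
                              inner_folds = 5, seed = 1, guard = NULL) {
  configuration <- match.arg(configuration)
  if (length(intersect(train_idx, test_idx)))
    stop_crisp("crisp_split_error", "train and test rows overlap")
  fc <- attr(features, "feature_cols") %||% feature_columns()
  guard <- guard %||% make_label_guard(features$label, test_idx)
  y_train <- guard$get_labels(train_idx)
  x_train <- features[train_idx, fc, drop = FALSE]

  artifacts <- list(configuration = configuration)
  if (configuration == "crisp") {
    prune <- suppressWarnings(
      correlation_prune(x_train, y_train, r_threshold))
    rfe <- rfe_select(x_train[, prune$retained, drop = FALSE], y_train,
                      n_keep = min(n_keep, length(prune$retained)),
                      n_trees = n_trees, seed = stage_seed(seed, 1))
    sm <- smote_oversample(x_train[, rfe$selected, drop = FALSE], y_train,
                           smote_config(smote_k, seed = stage_seed(seed, 2)))
    x_fit <- as.data.frame(sm$x)
    y_fit <- sm$labels
    cols <- rfe$selected
    artifacts$prune <- prune
    artifacts$rfe <- rfe
    artifacts$smote_provenance <- sm$provenance
  } else {
    x_fit <- x_train
    y_fit <- y_train
    cols <- fc
  }
  if (tune)
    spec <- grid_search(spec, x_fit, y_fit, inner_folds,
                        seed = stage_seed(seed, 3))
  spec$seed <- stage_seed(seed, 4)
  model <- fit_classifier(spec, x_fit, y_fit)
  artifacts$tuned <- spec$tuned

  proba <- predict_proba(model, features[test_idx, cols, drop = FALSE])
  pred <- factor(model$levels[max.col(proba, ties.method = "first")],
                 levels = model$levels)
  guard$unseal()
  list(test_idx = test_idx, pred = pred, proba = proba,
       artifacts = artifacts, selected = cols, model = model)
}

#' Collapse cycle-level predictions into one decision per subject
#'
#' Majority vote (binary) / modal class (multiclass) over each subject's
#' cycle predictions; exact vote ties are broken by the class with the
#' highest mean posterior over the subject's cycles.
#'
#' @param pred factor of cycle-level predicted labels.
#' @param proba posterior matrix aligned with `pred` (columns = classes).
#' @param subject_ids subject id per cycle row.
#' @return data.frame: `subject_id`, `decision`, `n_cycles`, `tie`;
#'   attribute `n_ties` counts tie-broken subjects; `mean_proba`
#'   attribute holds per-subject mean posteriors (for subject-level AUC).
#' @export
subject_vote <- function(pred, proba, subject_ids) {
  classes <- levels(pred)
  subs <- unique(subject_ids)
  mean_pr <- matrix(0, length(subs), length(classes),
                    dimnames = list(subs, classes))
  out <- data.frame(subject_id = subs, decision = NA_character_,
                    n_cycles = 0L, tie = FALSE)
  for (i in seq_along(subs)) {
    rows <- which(subject_ids == subs[i])
    tab <- table(factor(pred[rows], levels = classes))
    mp <- colMeans(proba[rows, , drop = FALSE])
    mean_pr[i, ] <- mp
    winners <- names(tab)[tab == max(tab)]
    if (length(winners) > 1L) {
      out$tie[i] <- TRUE
      winners <- winners[which.max(mp[winners])]
    }
    out$decision[i] <- winners
    out$n_cycles[i] <- length(rows)
  }
  out$decision <- factor(out$decision, levels = classes)
  attr(out, "n_ties") <- sum(out$tie)
  attr(out, "mean_proba") <- mean_pr
  out
}

binary_confusion_metrics <- function(y_true, y_pred, positive) {
  tp <- sum(y_pred == positive & y_true == positive)
  fp <- sum(y_pred == positive & y_true != positive)
  fn <- sum(y_pred != positive & y_true == positive)
  tn <- sum(y_pred != positive & y_true != positive)
  safe <- function(num, den) if (den == 0) 0 else num / den
  prec <- safe(tp, tp + fp)
  rec <- safe(tp, tp + fn)
  c(accuracy = (tp + tn) / (tp + fp + fn + tn),
    precision = prec, recall = rec,
    specificity = safe(tn, tn + fp),
    f1 = if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec))
}

auc_one_class <- function(is_pos, score) {
  if (all(is_pos) || !any(is_pos)) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(response = is_pos, predictor = score,
                                 levels = c(FALSE, TRUE), direction = "<",
                                 quiet = TRUE)))
}

#' The six evaluation metrics
#'
#' Binary: metrics from the 2x2 confusion matrix with `positive` (PD) as
#' the positive class. Multiclass: accuracy is overall, and precision,
#' recall, specificity, and F1 are macro-averaged one-vs-rest; ROC-AUC is
#' the macro mean of per-class one-vs-rest AUCs on the posteriors.
#' Percentages are on the 0--100 scale; AUC on `[0, 1]`. Zero
#' denominators yield 0.
#'
#' @param y_true true labels (factor).
#' @param y_pred predicted labels.
#' @param proba posterior matrix (needed for `roc_auc`; `NA` otherwise).
#' @param positive positive class for the binary task (default `"PD"`).
#' @return named numeric vector `accuracy`, `precision`, `recall`,
#'   `specificity`, `f1` (percent), `roc_auc` (0--1).
#' @export
compute_metrics <- function(y_true, y_pred, proba = NULL,
                            positive = "PD") {
  y_true <- as.factor(y_true)
  classes <- levels(y_true)
  y_pred <- factor(as.character(y_pred), levels = classes)
  if (any(is.na(y_pred)))
    stop_crisp("crisp_schema_error",
               "predicted label outside the true label set")
  if (length(classes) == 2L) {
    if (!positive %in% classes) positive <- classes[2L]
    m <- binary_confusion_metrics(y_true, y_pred, positive)
    auc <- if (is.null(proba)) NA_real_ else
      auc_one_class(y_true == positive, proba[, positive])
  } else {
    per <- vapply(classes, function(cl)
      binary_confusion_metrics(y_true, y_pred, cl), numeric(5))
    m <- c(accuracy = mean(y_pred == y_true), rowMeans(per)[-1])
    auc <- if (is.null(proba)) NA_real_ else
      mean(vapply(classes, function(cl)
        auc_one_class(y_true == cl, proba[, cl]), numeric(1)),
        na.rm = TRUE)
  }
  out <- c(m * 100, roc_auc = auc)
  names(out) <- METRIC_NAMES
  out
}

#' Paired two-sided t-tests of CRISP vs baseline across folds
#'
#' Classic paired t on per-fold metric differences (df = folds - 1).
#' Degenerate cases are flagged: identical samples give p = 1; a
#' constant nonzero difference has zero variance and no finite t.
#'
#' @param baseline,crisp data.frames of per-fold metrics (rows = folds,
#'   columns = metrics), paired by row.
#' @param metrics metric columns to test.
#' @return data.frame: `metric`, `mean_diff` (crisp - baseline), `t`,
#'   `p`, `flag`.
#' @export
paired_compare <- function(baseline, crisp,
                           metrics = setdiff(METRIC_NAMES, "roc_auc")) {
  if (nrow(baseline) != nrow(crisp))
    stop_crisp("crisp_test_error", "fold counts differ")
  if (nrow(baseline) < 2)
    stop_crisp("crisp_test_error", "need >= 2 folds for a paired t-test")
  do.call(rbind, lapply(metrics, function(mt) {
    d <- crisp[[mt]] - baseline[[mt]]
    if (sd(d) == 0) {
      if (all(d == 0))
        return(data.frame(metric = mt, mean_diff = 0, t = 0, p = 1,
                          flag = "identical"))
      return(data.frame(metric = mt, mean_diff = mean(d), t = NA_real_,
                        p = NA_real_, flag = "zero_variance"))
    }
    tt <- t.test(crisp[[mt]], baseline[[mt]], paired = TRUE)
    data.frame(metric = mt, mean_diff = mean(d),
               t = unname(tt$statistic), p = tt$p.value, flag = "")
  }))
}

#' Aggregate per-fold metrics into mean and SD per cell
#'
#' @param per_fold long data.frame with columns `model`, `configuration`,
#'   `protocol`, `fold`, and the metric columns.
#' @return data.frame with one row per (model, configuration, protocol,
#'   metric): `mean`, `sd`, `n_folds`.
#' @export
aggregate_report <- function(per_fold) {
  cells <- unique(per_fold[, c("model", "configuration", "protocol")])
  do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- per_fold$model == cells$model[i] &
      per_fold$configuration == cells$configuration[i] &
      per_fold$protocol == cells$protocol[i]
    do.call(rbind, lapply(METRIC_NAMES, function(mt) {
      v <- per_fold[[mt]][sel]
      data.frame(model = cells$model[i],
                 configuration = cells$configuration[i],
                 protocol = cells$protocol[i], metric = mt,
                 mean = mean(v), sd = sd(v), n_folds = sum(sel))
    }))
  }))
}

#' Cross-validated evaluation of the full pipeline
#'
#' Runs every (model, configuration) combination over the same outer
#' folds and scores each fold under both protocols: `overall` (metrics on
#' pooled test cycles) and `subject_wise` (metrics on voted per-subject
#' decisions, with per-subject mean posteriors for AUC).
#'
#' @param features feature matrix from [build_feature_matrix()].
#' @param models character vector of model names (subset of
#'   `KNN, DT, RF, GB, XGB`).
#' @param configurations subset of `c("baseline", "crisp")`.
#' @param plan a [fold_plan()].
#' @param tune grid-search inside each training fold (default `FALSE`).
#' @param r_threshold,n_keep,n_trees,smote_k,inner_folds pipeline
#'   parameters (paper defaults).
#' @param seed master seed (fans out per fold/stage).
#' @return object of class `evaluation_report`: `per_fold` (long metric
#'   data.frame), `aggregate`, `paired` (per model/protocol t-tests when
#'   both configurations ran), `fold_sizes`, `settings`.
#' @export
run_experiment <- function(features, models = MODEL_NAMES,
                           configurations = c("baseline", "crisp"),
                           plan = fold_plan(), tune = FALSE,
                           r_threshold = 0.80, n_keep = 10, n_trees = 100,
                           smote_k = 5, inner_folds = 5, seed = 1) {
  plan$seed <- stage_seed(seed, 100)
  folds <- make_folds(features, plan)
  all_idx <- seq_len(nrow(features))
  per_fold <- NULL
  for (model in models) {
    for (cfg in configurations) {
      for (f in seq_along(folds)) {
        test_idx <- folds[[f]]
        train_idx <- setdiff(all_idx, test_idx)
        res <- run_pipeline_fold(
          features, train_idx, test_idx, configuration = cfg,
          spec = classifier_spec(model), r_threshold = r_threshold,
          n_keep = n_keep, n_trees = n_trees, smote_k = smote_k,
          tune = tune, inner_folds = inner_folds,
          seed = stage_seed(seed, f))
        y_test <- features$label[test_idx]
        overall <- compute_metrics(y_test, res$pred, res$proba)
        vote <- subject_vote(res$pred, res$proba,
                             features$subject_id[test_idx])
        subj_truth <- features$label[test_idx][
          match(vote$subject_id, features$subject_id[test_idx])]
        subject <- compute_metrics(subj_truth, vote$decision,
                                   attr(vote, "mean_proba"))
        per_fold <- rbind(per_fold,
          data.frame(model = model, configuration = cfg,
                     protocol = "overall", fold = f, t(overall)),
          data.frame(model = model, configuration = cfg,
                     protocol = "subject_wise", fold = f, t(subject)))
      }
    }
  }
  paired <- NULL
  if (all(c("baseline", "crisp") %in% configurations)) {
    for (model in models) for (proto in c("overall", "subject_wise")) {
      sel <- per_fold$model == model & per_fold$protocol == proto
      base <- per_fold[sel & per_fold$configuration == "baseline", ]
      cri <- per_fold[sel & per_fold$configuration == "crisp", ]
      pc <- paired_compare(base[order(base$fold), ], cri[order(cri$fold), ])
      pc$model <- model; pc$protocol <- proto
      paired <- rbind(paired, pc)
    }
  }
  structure(list(per_fold = per_fold, aggregate = aggregate_report(per_fold),
                 paired = paired,
                 fold_sizes = lengths(folds),
                 settings = list(models = models,
                                 configurations = configurations,
                                 plan = plan, tune = tune,
                                 r_threshold = r_threshold,
                                 n_keep = n_keep, n_trees = n_trees,
                                 smote_k = smote_k, seed = seed)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  agg <- x$aggregate[x$aggregate$metric == "accuracy", ]
  for (i in seq_len(nrow(agg)))
    cat(sprintf("  %-4s %-8s %-12s accuracy %5.1f +/- %.2f\n",
                agg$model[i], agg$configuration[i], agg$protocol[i],
                agg$mean[i], agg$sd[i]))
  invisible(x)
}
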