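test_that("subject-grouped folds partition subjects with per-class balance", {
  fm <- small_feature_matrix(n_per_class = 5, seed = 17)
  folds <- make_folds(fm, fold_plan(5, "subject_grouped", seed = 2))
  expect_length(folds, 5)
  expect_setequal(unlist(folds), seq_len(nrow(fm)))
  for (f in folds) {
    subs <- unique(fm$subject_id[f])
    expect_length(subs, 2)
    expect_setequal(as.character(unique(fm$label[f])), c("HC", "PD"))
    # grouping: all of a subject's rows land in exactly this fold
    for (s in subs)
      expect_true(all(which(fm$subject_id == s) %in% f))
  }
  expect_error(
    make_folds(fm[fm$subject_id %in% unique(fm$subject_id)[1:4], ],
               fold_plan(5, "subject_grouped")),
    class = "crisp_split_error")
})

test_that("cycle-stratified folds keep label proportions within 2%", {
  fm <- small_feature_matrix(n_per_class = 5, seed = 17)
  folds <- make_folds(fm, fold_plan(5, "cycle_stratified", seed = 3))
  global <- mean(fm$label == "PD")
  for (f in folds)
    expect_lt(abs(mean(fm$label[f] == "PD") - global), 0.02)
})

test_that("the leakage guard seals held-out labels during fitting", {
  labels <- factor(rep(c("HC", "PD"), 10))
  guard <- make_label_guard(labels, test_idx = 11:20)
  expect_equal(guard$get_labels(1:10), labels[1:10])
  expect_error(guard$get_labels(11:20), class = "crisp_leakage_error")
  expect_error(guard$get_labels(c(5, 15)), class = "crisp_leakage_error")
  guard$unseal()
  expect_equal(guard$get_labels(11:20), labels[11:20])
})

test_that("fold artifacts are invariant to perturbation of held-out rows", {
  fm <- small_feature_matrix(n_per_class = 5, seed = 23)
  folds <- make_folds(fm, fold_plan(5, seed = 4))
  test_idx <- folds[[1]]
  train_idx <- setdiff(seq_len(nrow(fm)), test_idx)
  run <- function(features)
    run_pipeline_fold(features, train_idx, test_idx, "crisp",
                      spec = classifier_spec("RF"), seed = 7)
  a <- run(fm)
  fm2 <- fm
  fc <- attr(fm, "feature_cols")
  fm2[test_idx, fc] <- fm2[test_idx, fc] * 3 + 17  # arbitrary mutation
  attr(fm2, "feature_cols") <- fc
  b <- run(fm2)
  expect_identical(a$artifacts$prune$retained, b$artifacts$prune$retained)
  expect_identical(a$artifacts$rfe$selected, b$artifacts$rfe$selected)
  expect_identical(a$artifacts$smote_provenance, b$artifacts$smote_provenance)
  expect_identical(a$artifacts$tuned, b$artifacts$tuned)
  # predictions of course differ; the baseline stores no curation artifacts
  base <- run_pipeline_fold(fm, train_idx, test_idx, "baseline", seed = 7)
  expect_null(base$artifacts$prune)
  expect_null(base$artifacts$rfe)
})

test_that("a CRISP fold predicts from exactly ten columns on uncorrelated panels", {
  # planted-signal design: no correlated pairs, so pruning retains all 30
  # and RFE must cut to exactly the configured ten
  pm <- make_planted_matrix(n = 300, effect = 1, seed = 23)
  fm <- cbind(data.frame(subject_id = sprintf("s%02d", rep(1:30, each = 10)),
                         label = pm$y), pm$x)
  attr(fm, "feature_cols") <- colnames(pm$x)
  res <- run_pipeline_fold(fm, train_idx = 1:240, test_idx = 241:300,
                           "crisp", spec = classifier_spec("RF"), seed = 7)
  expect_length(res$selected, 10)
  expect_identical(res$selected, res$artifacts$rfe$selected)
  expect_identical(res$model$feature_names, res$selected)
  expect_length(res$artifacts$prune$retained, 30)

  # on the correlated gait panel pruning may leave fewer than ten, and the
  # model still sees exactly the RFE-selected set
  gm <- small_feature_matrix(n_per_class = 5, seed = 23)
  folds <- make_folds(gm, fold_plan(5, seed = 4))
  res2 <- run_pipeline_fold(gm, setdiff(seq_len(nrow(gm)), folds[[1]]),
                            folds[[1]], "crisp", seed = 7)
  expect_lte(length(res2$selected), 10)
  expect_identical(res2$model$feature_names, res2$artifacts$rfe$selected)
})

test_that("subject voting follows majority rule with posterior tie-breaks", {
  pred <- factor(c("PD", "PD", "HC"), levels = c("HC", "PD"))
  proba <- matrix(c(0.2, 0.3, 0.9, 0.8, 0.7, 0.1), ncol = 2,
                  dimnames = list(NULL, c("HC", "PD")))
  v <- subject_vote(pred, proba, rep("s1", 3))
  expect_equal(as.character(v$decision), "PD")
  expect_false(v$tie)

  pred2 <- factor(c("PD", "HC"), levels = c("HC", "PD"))
  proba2 <- matrix(c(0.3, 0.3, 0.7, 0.7), ncol = 2,
                   dimnames = list(NULL, c("HC", "PD")))
  v2 <- subject_vote(pred2, proba2, rep("s1", 2))
  expect_true(v2$tie)
  expect_equal(as.character(v2$decision), "PD")  # mean posterior 0.7 vs 0.3
})

test_that("subject voting matches a brute-force recount on random instances", {
  set.seed(31)
  for (i in 1:200) {
    classes <- if (runif(1) < 0.5) c("HC", "PD") else c("1", "2", "3")
    n_sub <- sample(2:6, 1)
    ids <- unlist(lapply(seq_len(n_sub), function(s)
      rep(sprintf("s%d", s), sample(1:7, 1))))
    pred <- factor(sample(classes, length(ids), replace = TRUE),
                   levels = classes)
    proba <- matrix(runif(length(ids) * length(classes)),
                    ncol = length(classes),
                    dimnames = list(NULL, classes))
    proba <- proba / rowSums(proba)
    v <- subject_vote(pred, proba, ids)
    expect_equal(as.character(v$decision), unname(brute_vote(pred, proba, ids)))
  }
})

test_that("metrics reproduce the hand confusion-matrix example exactly", {
  y_true <- factor(c(1, 1, 1, 0, 0), levels = c(0, 1))
  y_pred <- factor(c(1, 1, 0, 0, 1), levels = c(0, 1))
  m <- compute_metrics(y_true, y_pred, positive = "1")
  expect_equal(unname(m["accuracy"]), 60)
  expect_equal(unname(m["precision"]), 200 / 3, tolerance = 1e-9)
  expect_equal(unname(m["recall"]), 200 / 3, tolerance = 1e-9)
  expect_equal(unname(m["specificity"]), 50)
  expect_equal(unname(m["f1"]), 200 / 3, tolerance = 1e-9)
})

test_that("metrics handle perfect and uninformative predictions", {
  y <- factor(rep(c("HC", "PD"), 5))
  pr <- cbind(HC = 1 - c(1:10) / 11, PD = c(1:10) / 11)
  perfect <- compute_metrics(y, y, proba = NULL)
  expect_equal(unname(perfect[1:5]), rep(100, 5))
  flat <- matrix(0.5, 10, 2, dimnames = list(NULL, c("HC", "PD")))
  m <- compute_metrics(y, y, proba = flat)
  expect_equal(unname(m["roc_auc"]), 0.5)
})

test_that("metrics match brute-force counting and a rank-based AUC oracle", {
  set.seed(37)
  for (i in 1:200) {
    n <- sample(5:40, 1)
    y <- factor(sample(c("HC", "PD"), n, replace = TRUE,
                       prob = c(0.4, 0.6)), levels = c("HC", "PD"))
    if (nlevels(droplevels(y)) < 2) next
    p <- factor(sample(c("HC", "PD"), n, replace = TRUE),
                levels = c("HC", "PD"))
    score <- runif(n)
    proba <- cbind(HC = 1 - score, PD = score)
    m <- compute_metrics(y, p, proba)
    expect_equal(unname(m[1:5]), unname(brute_binary_metrics(y, p, "PD")),
                 tolerance = 1e-9)
    # Mann-Whitney rank AUC oracle
    pos <- score[y == "PD"]; neg <- score[y == "HC"]
    auc <- (sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))) /
      (length(pos) * length(neg))
    expect_equal(unname(m["roc_auc"]), auc, tolerance = 1e-9)
  }
})

test_that("macro one-vs-rest multiclass metrics average the per-class tables", {
  y <- factor(c("1", "1", "2", "2", "3", "3"))
  p <- factor(c("1", "2", "2", "2", "3", "1"), levels = levels(y))
  m <- compute_metrics(y, p)
  per <- sapply(c("1", "2", "3"), function(cl)
    brute_binary_metrics(y, p, cl))
  expect_equal(unname(m["accuracy"]), 400 / 6, tolerance = 1e-9)
  expect_equal(unname(m["precision"]), mean(per["precision", ]),
               tolerance = 1e-9)
  expect_equal(unname(m["recall"]), mean(per["recall", ]), tolerance = 1e-9)
  expect_equal(unname(m["specificity"]), mean(per["specificity", ]),
               tolerance = 1e-9)
})

test_that("paired t-tests match the closed form and flag degenerate cases", {
  base <- data.frame(accuracy = c(90, 93, 89, 92, 91))
  crisp <- data.frame(accuracy = base$accuracy + c(2, -1, 3, 0, 1))
  out <- paired_compare(base, crisp, metrics = "accuracy")
  d <- c(2, -1, 3, 0, 1)
  t_hand <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(out$t, t_hand, tolerance = 1e-9)
  expect_equal(out$p, 2 * pt(-abs(t_hand), df = 4), tolerance = 1e-9)

  same <- paired_compare(base, base, metrics = "accuracy")
  expect_equal(same$p, 1)
  expect_equal(same$flag, "identical")

  const <- paired_compare(base, data.frame(accuracy = base$accuracy + 1),
                          metrics = "accuracy")
  expect_equal(const$flag, "zero_variance")
  expect_error(paired_compare(base, crisp[1:4, , drop = FALSE],
                              metrics = "accuracy"),
               class = "crisp_test_error")
})

test_that("aggregation reproduces hand mean +/- sd per cell", {
  pf <- data.frame(model = "XGB", configuration = "crisp",
                   protocol = "overall", fold = 1:5,
                   accuracy = c(90, 92, 94, 91, 93), precision = 90,
                   recall = 90, specificity = 90, f1 = 90, roc_auc = 0.9)
  agg <- aggregate_report(pf)
  acc <- agg[agg$metric == "accuracy", ]
  expect_equal(acc$mean, 92)
  expect_equal(acc$sd, sqrt(2.5), tolerance = 1e-9)
  expect_equal(agg[agg$metric == "precision", ]$sd, 0)
})

test_that("a small experiment produces one decision per test subject and complete cells", {
  fm <- small_feature_matrix(n_per_class = 5, seed = 41)
  rep <- run_experiment(fm, models = "RF",
                        plan = fold_plan(5), seed = 2)
  expect_s3_class(rep, "evaluation_report")
  pf <- rep$per_fold
  expect_equal(nrow(pf), 2 * 2 * 5)  # configs x protocols x folds
  expect_true(all(pf$accuracy >= 0 & pf$accuracy <= 100))
  expect_true(all(pf$roc_auc >= 0 & pf$roc_auc <= 1))
  expect_equal(nrow(rep$aggregate), 2 * 2 * 6)
  expect_true(all(c("overall", "subject_wise") %in% rep$paired$protocol))
  # mean +/- sd recomputable from stored per-fold values
  cell <- pf[pf$configuration == "crisp" & pf$protocol == "overall", ]
  agg <- rep$aggregate
  expect_equal(agg[agg$configuration == "crisp" & agg$protocol == "overall" &
                     agg$metric == "accuracy", "mean"],
               mean(cell$accuracy))
})
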