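sep_toy <- function(n = 60, seed = 1) {
  set.seed(seed)
  y <- factor(rep(c("HC", "PD"), each = n / 2))
  x <- data.frame(f1 = rnorm(n) + 4 * (y == "PD"), f2 = rnorm(n))
  list(x = x, y = y)
}

test_that("posterior rows sum to one and argmax equals the predicted label", {
  toy <- sep_toy(80)
  for (name in c("KNN", "DT", "RF", "GB", "XGB")) {
    m <- fit_classifier(classifier_spec(name, seed = 2), toy$x, toy$y)
    pr <- predict_proba(m, toy$x)
    expect_equal(unname(rowSums(pr)), rep(1, nrow(pr)), tolerance = 1e-9)
    expect_true(all(pr >= 0 & pr <= 1))
    lab <- predict_label(m, toy$x)
    expect_equal(as.character(lab),
                 colnames(pr)[max.col(pr, ties.method = "first")])
  }
})

test_that("KNN with k=1 interpolates the training set; k=4 posteriors are vote fractions", {
  toy <- sep_toy(40)
  m1 <- fit_classifier(classifier_spec("KNN", tuned = list(k = 1)),
                       toy$x, toy$y)
  expect_equal(predict_label(m1, toy$x), toy$y, ignore_attr = TRUE)

  x4 <- data.frame(f1 = c(0, 0.1, 0.2, 0.3))
  y4 <- factor(c("PD", "PD", "PD", "HC"), levels = c("HC", "PD"))
  m4 <- fit_classifier(classifier_spec("KNN", tuned = list(k = 4)), x4, y4)
  pr <- predict_proba(m4, data.frame(f1 = 0.15))
  expect_equal(unname(pr[1, "PD"]), 0.75)
  expect_equal(unname(pr[1, "HC"]), 0.25)
})

test_that("an unlimited-depth tree separates separable toy data exactly", {
  toy <- sep_toy(60, seed = 3)
  m <- fit_classifier(classifier_spec("DT"), toy$x, toy$y)
  expect_equal(mean(predict_label(m, toy$x) == toy$y), 1.0)
})

test_that("ensemble models recover planted signal on holdout data", {
  pm <- make_planted_matrix(n = 600, effect = 1, seed = 5)
  train <- 1:400; test <- 401:600
  for (name in c("RF", "GB", "XGB")) {
    m <- fit_classifier(classifier_spec(name, seed = 4),
                        pm$x[train, ], pm$y[train])
    acc <- mean(predict_label(m, pm$x[test, ]) == pm$y[test])
    expect_gt(acc, 0.9)
  }
})

test_that("fitting demands two classes and matching prediction columns", {
  toy <- sep_toy(20)
  expect_error(fit_classifier(classifier_spec("RF"), toy$x,
                              rep("PD", 20)),
               class = "crisp_fit_error")
  m <- fit_classifier(classifier_spec("RF"), toy$x, toy$y)
  expect_error(predict_proba(m, toy$x[, c("f2", "f1")]),
               class = "crisp_schema_error")
})

test_that("grid search returns single-point grids untouched and validates values", {
  toy <- sep_toy(40)
  sp <- grid_search(classifier_spec("KNN", grid = list(k = 7)),
                    toy$x, toy$y)
  expect_equal(sp$tuned$k, 7)
  expect_error(classifier_spec("KNN", grid = list(k = c(0, 5))),
               class = "crisp_validation_error")
  expect_error(classifier_spec("GB", grid = list(eta = c(0.1, 2))),
               class = "crisp_validation_error")
  expect_error(
    grid_search(classifier_spec("KNN", grid = list(k = c(3, 5))),
                data.frame(f = rnorm(8)),
                factor(rep(c("a", "b"), each = 4))),
    class = "crisp_stratification_error")
})

test_that("grid search is deterministic and picks the accuracy winner", {
  pm <- make_planted_matrix(n = 300, effect = 1.5, seed = 9)
  sp1 <- grid_search(classifier_spec("DT", grid = list(maxdepth = c(1, 10))),
                     pm$x, pm$y, seed = 2)
  sp2 <- grid_search(classifier_spec("DT", grid = list(maxdepth = c(1, 10))),
                     pm$x, pm$y, seed = 2)
  expect_identical(sp1$tuned, sp2$tuned)
  # a depth-1 stump cannot use 10 informative features: deeper must win
  expect_equal(sp1$tuned$maxdepth, 10)
})

test_that("KNN tuning prefers a moderate k on a curved two-class boundary", {
  wins <- vapply(1:10, function(rep) {
    set.seed(100 + rep)
    n <- 500
    r <- c(sqrt(runif(n / 2, 0, 0.85)), sqrt(runif(n / 2, 0.7, 2)))
    th <- runif(n, 0, 2 * pi)
    x <- data.frame(u = r * cos(th), v = r * sin(th))
    y <- factor(rep(c("in", "out"), each = n / 2))
    sp <- grid_search(classifier_spec("KNN", grid = list(k = c(1, 5, 50))),
                      x, y, seed = rep)
    sp$tuned$k
  }, numeric(1))
  expect_gt(sum(wins == 5), 5)
})
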