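test_that("regression metrics follow their closed forms", {
  expect_equal(evaluate_regression(1:5, 1:5), list(rmse = 0, mae = 0))
  e <- evaluate_regression(c(3, 4, 5), c(1, 2, 3))
  expect_equal(e$rmse, 2)
  expect_equal(e$mae, 2)
  # rmse >= mae for arbitrary errors
  set.seed(6)
  for (i in 1:20) {
    e <- evaluate_regression(rnorm(30), rnorm(30))
    expect_gte(e$rmse, e$mae)
  }
})

test_that("classification metrics reconcile with their confusion matrix", {
  set.seed(12)
  lev <- c("normal", "abnormal")
  truth <- factor(sample(lev, 60, replace = TRUE, prob = c(0.7, 0.3)), lev)
  pred <- factor(sample(lev, 60, replace = TRUE), lev)
  m <- evaluate_classification(pred, truth, positive = "abnormal")
  expect_equal(m$accuracy, sum(diag(m$confusion)) / sum(m$confusion),
               tolerance = 1e-12)
  expect_equal(rowSums(m$confusion), table(truth = truth)[lev],
               ignore_attr = TRUE)
  expect_equal(m$sensitivity,
               m$confusion["abnormal", "abnormal"] /
                 sum(m$confusion["abnormal", ]))
  expect_equal(m$specificity,
               m$confusion["normal", "normal"] / sum(m$confusion["normal", ]))
  w <- as.numeric(table(truth)[m$per_class$class])
  expect_equal(m$f1_weighted, sum(m$per_class$f1 * w) / sum(w))
})

test_that("AUC agrees between trapezoid, pair counting and pROC", {
  perfect <- roc_auc(c(0.9, 0.8, 0.1, 0.2),
                     c("abnormal", "abnormal", "normal", "normal"))
  expect_equal(perfect$auc, 1.0)
  mixed <- roc_auc(c(0.8, 0.4, 0.6, 0.2),
                   c("abnormal", "abnormal", "normal", "normal"))
  expect_equal(mixed$auc, 0.75)             # 3 of 4 concordant pairs
  expect_equal(mixed$auc_pairs, 0.75)

  set.seed(21)
  for (i in 1:20) {
    truth <- c(rep("abnormal", 8), rep("normal", 12))
    scores <- round(rnorm(20), 1)           # rounding forces ties
    r <- roc_auc(scores, truth)
    expect_equal(r$auc, r$auc_pairs, tolerance = 1e-9)
    if (requireNamespace("pROC", quietly = TRUE)) {
      ref <- suppressMessages(pROC::auc(
        pROC::roc(truth, scores, levels = c("normal", "abnormal"),
                  direction = "<")))
      expect_equal(r$auc, as.numeric(ref), tolerance = 1e-9)
    }
  }
  expect_error(roc_auc(c(1, 2), c("normal", "normal")), "both classes")
})

test_that("degenerate and exact fits behave as expected", {
  set.seed(31)
  x <- data.frame(a = rnorm(30), b = rnorm(30))
  # constant target -> constant predictions
  for (alg in c("linear", "random_forest")) {
    m <- fit_model(x, rep(5, 30), task = "regression", algorithm = alg)
    expect_equal(predict_model(m, x), rep(5, 30), tolerance = 1e-9)
  }
  # noiseless linear data -> exact coefficient recovery
  y <- 2 + 3 * x$a - 1.5 * x$b
  m <- fit_model(x, y, task = "regression", algorithm = "linear")
  expect_equal(unname(coef(m$fit)), c(2, 3, -1.5), tolerance = 1e-6)
  # separable classes -> RF interpolates the training set
  cls <- factor(ifelse(x$a > 0, "abnormal", "normal"),
                c("normal", "abnormal"))
  mrf <- fit_model(x, cls, task = "binary", algorithm = "random_forest",
                   seed = 2)
  expect_equal(mean(predict_model(mrf, x)$class == cls), 1.0)
  expect_error(fit_model(x, factor(rep("normal", 30)), task = "binary",
                         algorithm = "linear"), "single class")
  expect_error(fit_model(x[1, , drop = FALSE], 1, task = "regression",
                         algorithm = "linear"), "at least 2")
})

test_that("binary scores rank the positive class for every algorithm", {
  set.seed(41)
  x <- data.frame(a = c(rnorm(40, 2), rnorm(40, -2)), b = rnorm(80))
  y <- factor(rep(c("abnormal", "normal"), each = 40),
              c("normal", "abnormal"))
  for (alg in c("linear", "random_forest", "svm_rbf")) {
    m <- fit_model(x, y, task = "binary", algorithm = alg, seed = 3)
    p <- predict_model(m, x)
    expect_gt(roc_auc(p$score, y)$auc, 0.95)
  }
})

test_that("10-fold cross-validation partitions and scores sensibly", {
  set.seed(51)
  x <- data.frame(a = rnorm(70), b = rnorm(70))
  y <- 1 + 0.5 * x$a - 2 * x$b + rnorm(70, sd = 0.1)
  cv <- cross_validate(x, y, task = "regression", algorithm = "linear",
                       seed = 4)
  expect_length(cv, 10)
  expect_lte(mean(cv), 2 * 0.1)             # near the generative noise floor
  cv2 <- cross_validate(x, y, task = "regression", algorithm = "linear",
                        seed = 4)
  expect_identical(cv, cv2)
  expect_error(cross_validate(x[1:5, ], y[1:5], task = "regression",
                              algorithm = "linear"), "10-fold")

  cls <- factor(ifelse(x$b + rnorm(70, sd = 0.2) > 0, "abnormal", "normal"),
                c("normal", "abnormal"))
  cvc <- cross_validate(x, cls, task = "binary", algorithm = "random_forest",
                        seed = 5)
  expect_length(cvc, 10)
  expect_true(all(cvc >= 0 & cvc <= 1))
  expect_gt(mean(cvc), 0.8)
})

test_that("multiclass models fit and predict all severity grades", {
  set.seed(61)
  n <- 90
  x <- data.frame(a = rnorm(n), b = rnorm(n))
  y <- label_ats_grade(60 + 30 * (x$a > 0) + runif(n, 0, 10))
  for (alg in c("linear", "random_forest", "svm_rbf")) {
    m <- fit_model(x, y, task = "multiclass", algorithm = alg, seed = 6)
    p <- predict_model(m, x)$class
    expect_gt(mean(as.character(p) == as.character(y)), 0.7)
  }
  # literal least-squares-on-class-codes mode stays available
  mlsq <- fit_model(x, y, task = "multiclass", algorithm = "linear",
                    linear_multiclass = "lsq")
  expect_s3_class(predict_model(mlsq, x)$class, "factor")
})
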