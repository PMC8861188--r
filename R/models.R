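#' Fit one predictive model for one task
#'
#' Three algorithm families over three tasks. `"linear"` means ordinary
#' least squares for regression, logistic regression for the binary task
#' and multinomial logistic regression for the multi-class task (a literal
#' least-squares-on-class-codes mode is available via
#' `linear_multiclass = "lsq"` for comparison). Hyperparameters are pinned
#' defaults — 500 trees, SVM cost 1 with RBF `gamma = 1/p` — so "default
#' settings" stay reproducible across library versions; features are
#' expected min-max normalised, hence `scale = FALSE` for the SVM.
#'
#' @param x Data frame of (normalised) numeric features.
#' @param y Target: numeric for `"regression"`, factor otherwise.
#' @param task `"regression"`, `"binary"` or `"multiclass"`.
#' @param algorithm `"linear"`, `"random_forest"` or `"svm_rbf"`.
#' @param seed Integer seed applied before any stochastic fit.
#' @param linear_multiclass `"multinomial"` (default) or `"lsq"`.
#' @return A `vf_model` object usable with [predict_model()].
#' @export
fit_model <- function(x, y,
                      task = c("regression", "binary", "multiclass"),
                      algorithm = c("linear", "random_forest", "svm_rbf"),
                      seed = 1L,
                      linear_multiclass = c("multinomial", "lsq")) {
  task <- match.arg(task)
  algorithm <- match.arg(algorithm)
  linear_multiclass <- match.arg(linear_multiclass)
  x <- as.data.frame(x)
  if (nrow(x) < 2) stop("need at least 2 training rows")
  if (task == "regression") {
    y <- as.numeric(y)
  } else {
    y <- droplevels(factor(y))
    if (nlevels(y) < 2) stop("training target has a single class")
  }
  d <- cbind(x, .y = y)
  fit <- withr::with_seed(seed, switch(algorithm,
    linear = {
      if (task == "regression") stats::lm(.y ~ ., data = d)
      else if (task == "binary") stats::glm(.y ~ ., data = d, family = stats::binomial())
      else if (linear_multiclass == "lsq")
        stats::lm(.codes ~ ., data = cbind(x, .codes = as.numeric(y)))
      else nnet::multinom(.y ~ ., data = d, trace = FALSE, maxit = 200)
    },
    random_forest = randomForest::randomForest(x, y, ntree = 500),
    svm_rbf = e1071::svm(x, y, kernel = "radial", cost = 1,
                         gamma = 1 / ncol(x), scale = FALSE,
                         probability = task != "regression")))
  structure(list(fit = fit, task = task, algorithm = algorithm,
                 linear_multiclass = linear_multiclass,
                 levels = if (task != "regression") levels(y)),
            class = "vf_model")
}

#' Predictions (and class scores) from a fitted model
#'
#' For classification, `score` is the positive-class score for the binary
#' task: a probability for linear and random-forest models and the signed
#' decision value (oriented so larger means the positive class) for the
#' SVM, which ranks without probability calibration.
#'
#' @param model A `vf_model` from [fit_model()].
#' @param newdata Feature data frame on the same schema/normalisation.
#' @param positive Positive class for the binary score.
#' @return Regression: numeric predictions. Classification: list with
#'   `class` (factor) and, for binary, `score`.
#' @export
predict_model <- function(model, newdata, positive = "abnormal") {
  newdata <- as.data.frame(newdata)
  fit <- model$fit
  if (model$task == "regression") {
    return(as.numeric(switch(model$algorithm,
      linear = stats::predict(fit, newdata = newdata),
      random_forest = stats::predict(fit, newdata = newdata),
      svm_rbf = stats::predict(fit, newdata = newdata))))
  }
  lv <- model$levels
  if (model$task == "multiclass" && model$algorithm == "linear" &&
      model$linear_multiclass == "lsq") {
    codes <- pmin(pmax(round(stats::predict(fit, newdata = newdata)), 1),
                  length(lv))
    return(list(class = factor(lv[codes], levels = lv)))
  }
  out <- switch(model$algorithm,
    linear = {
      if (model$task == "binary") {
        p <- stats::predict(fit, newdata = newdata, type = "response")
        # glm models P(second level); orient score toward `positive`
        sc <- if (lv[2] == positive) p else 1 - p
        list(class = factor(lv[1 + (p > 0.5)], levels = lv), score = sc)
      } else {
        list(class = factor(stats::predict(fit, newdata = newdata), levels = lv))
      }
    },
    random_forest = {
      cl <- stats::predict(fit, newdata = newdata)
      if (model$task == "binary") {
        pr <- stats::predict(fit, newdata = newdata, type = "prob")
        list(class = factor(cl, levels = lv), score = pr[, positive])
      } else list(class = factor(cl, levels = lv))
    },
    svm_rbf = {
      pr <- stats::predict(fit, newdata = newdata, decision.values = TRUE)
      if (model$task == "binary") {
        dv <- attr(pr, "decision.values")[, 1]
        # column name "a/b" means positive decision values favour class a
        first <- strsplit(colnames(attr(pr, "decision.values"))[1], "/")[[1]][1]
        list(class = factor(pr, levels = lv),
             score = if (first == positive) dv else -dv)
      } else list(class = factor(pr, levels = lv))
    })
  out
}

#' Seeded k-fold cross-validation on the training split
#'
#' Folds are a seeded disjoint cover of the rows. The per-fold metric is
#' RMSE for regression and accuracy for classification.
#'
#' @param x,y Training features and target.
#' @inheritParams fit_model
#' @param k Number of folds (default 10); requires `nrow(x) >= k`.
#' @return Numeric vector of k per-fold metric values.
#' @export
cross_validate <- function(x, y, task, algorithm, k = 10L, seed = 1L, ...) {
  x <- as.data.frame(x)
  n <- nrow(x)
  if (n < k) stop("need at least ", k, " training rows for ", k, "-fold CV")
  folds <- withr::with_seed(seed, sample(rep(seq_len(k), length.out = n)))
  vapply(seq_len(k), function(f) {
    tr <- folds != f
    m <- fit_model(x[tr, , drop = FALSE],
                   if (task == "regression") y[tr] else droplevels(factor(y)[tr]),
                   task = task, algorithm = algorithm, seed = seed + f, ...)
    if (task == "regression") {
      evaluate_regression(predict_model(m, x[!tr, , drop = FALSE]), y[!tr])$rmse
    } else {
      pred <- predict_model(m, x[!tr, , drop = FALSE])$class
      mean(as.character(pred) == as.character(y[!tr]))
    }
  }, numeric(1))
}
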