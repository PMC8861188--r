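#' Run the full 18-report prediction suite
#'
#' For each task (FEV1% regression; severity multi-class; normal/abnormal
#' binary), each algorithm family (linear, random forest, RBF-kernel SVM)
#' and each covariate setting (acoustic features only, or with sex, height
#' and weight appended), the suite: imputes missing values and fits min-max
#' normalisation on the training rows, runs seeded 10-fold
#' cross-validation on the training split, refits on the whole training
#' split and evaluates on the held-out test rows. All 18 reports share the
#' same partition and seed.
#'
#' @param features Tibble containing the [feature_schema()] columns
#'   (acoustic + biological) plus `fev1_pct`.
#' @param partition A `partition_spec` from [make_partition()]; its ids
#'   must index rows of `features`.
#' @param seed Integer seed for CV folds and stochastic fits.
#' @param tasks,algorithms Subsets to run (defaults: all).
#' @param cv_folds Folds for cross-validation (skipped when the training
#'   split is smaller).
#' @return List of `evaluation_report` lists; see [summarise_reports()].
#' @export
run_task_suite <- function(features, partition, seed = 1L,
                           tasks = c("regression", "multiclass", "binary"),
                           algorithms = c("linear", "random_forest", "svm_rbf"),
                           cv_folds = 10L) {
  stopifnot(all(feature_schema(biological = TRUE) %in% names(features)),
            "fev1_pct" %in% names(features))
  tr <- partition$train_ids
  te <- partition$test_ids
  fev1 <- features$fev1_pct
  targets <- list(regression = fev1,
                  multiclass = label_ats_grade(fev1),
                  binary = label_binary(fev1))
  prep <- function(biological) {
    x <- features[, feature_schema(biological)]
    x <- impute_from_train(x, tr)$x
    fit <- minmax_fit(x[tr, ])
    minmax_apply(x, fit)
  }
  xs <- list(`FALSE` = prep(FALSE), `TRUE` = prep(TRUE))
  reports <- list()
  for (task in tasks) for (algorithm in algorithms)
    for (bio in c(FALSE, TRUE)) {
      x <- xs[[as.character(bio)]]
      y <- targets[[task]]
      rep <- list(task = task, algorithm = algorithm, use_biological = bio,
                  partition_mode = partition$mode,
                  partition_seed = partition$seed, seed = seed,
                  n_train = length(tr), n_test = length(te), flagged = FALSE)
      y_tr <- if (task == "regression") y[tr] else droplevels(factor(y[tr]))
      if (task != "regression" &&
          (nlevels(y_tr) < 2 ||
           !all(as.character(unique(y[te])) %in% levels(y_tr)))) {
        rep$flagged <- TRUE
        rep$note <- "train or test split lacks a class"
        reports[[length(reports) + 1L]] <- rep
        next
      }
      rep$cv_scores <- if (cv_folds >= 2L && length(tr) >= cv_folds)
        cross_validate(x[tr, ], y_tr, task, algorithm, k = cv_folds,
                       seed = seed) else NULL
      m <- fit_model(x[tr, ], y_tr, task = task, algorithm = algorithm,
                     seed = seed)
      if (task == "regression") {
        pred <- predict_model(m, x[te, ])
        rep$metrics <- evaluate_regression(pred, y[te])
        rep$predictions <- pred
      } else {
        pred <- predict_model(m, x[te, ])
        cls <- evaluate_classification(pred$class, y[te],
                                       positive = "abnormal")
        if (task == "binary" && length(unique(y[te])) == 2) {
          r <- roc_auc(pred$score, y[te], positive = "abnormal")
          cls$auc <- r$auc
          cls$auc_pairs <- r$auc_pairs
          rep$roc <- r$roc
        }
        rep$metrics <- cls
        rep$predictions <- pred$class
      }
      reports[[length(reports) + 1L]] <- rep
    }
  reports
}

#' One-row-per-report summary of a suite run
#' @param reports List from [run_task_suite()].
#' @return Tibble with task/algorithm identifiers and headline metrics
#'   (RMSE/MAE for regression; accuracy, weighted F1, sensitivity,
#'   specificity, AUC for classification).
#' @export
summarise_reports <- function(reports) {
  rows <- lapply(reports, function(r) {
    base <- tibble::tibble(
      task = r$task, algorithm = r$algorithm,
      use_biological = r$use_biological, flagged = r$flagged,
      cv_mean = if (!is.null(r$cv_scores)) mean(r$cv_scores) else NA_real_,
      rmse = NA_real_, mae = NA_real_, accuracy = NA_real_,
      f1_weighted = NA_real_, f1_macro = NA_real_,
      sensitivity = NA_real_, specificity = NA_real_, auc = NA_real_)
    if (r$flagged) return(base)
    m <- r$metrics
    if (r$task == "regression") {
      base$rmse <- m$rmse; base$mae <- m$mae
    } else {
      base$accuracy <- m$accuracy
      base$f1_weighted <- m$f1_weighted
      base$f1_macro <- m$f1_macro
      if (!is.null(m$sensitivity)) base$sensitivity <- m$sensitivity
      if (!is.null(m$specificity)) base$specificity <- m$specificity
      if (!is.null(m$auc)) base$auc <- m$auc
    }
    base
  })
  do.call(rbind, rows)
}

#' Compare breath-only, speech-only and combined feature sets
#'
#' Refits the FEV1% regression (one algorithm) on three acoustic feature
#' subsets — breath-derived, speech-derived, and all 23 — under the same
#' partition, reporting held-out RMSE and MAE for each. Mirrors the
#' question of whether combining breath and speech information beats
#' either alone.
#'
#' @inheritParams run_task_suite
#' @param algorithm Algorithm family to use (default random forest).
#' @return Tibble: `feature_set`, `n_features`, `rmse`, `mae`.
#' @export
compare_feature_sets <- function(features, partition, seed = 1L,
                                 algorithm = "random_forest") {
  sets <- list(
    breath = grep("^breath_|^mean_breath", feature_schema(), value = TRUE),
    speech = grep("^speech_", feature_schema(), value = TRUE),
    combined = feature_schema())
  tr <- partition$train_ids
  te <- partition$test_ids
  rows <- lapply(names(sets), function(nm) {
    x <- features[, sets[[nm]]]
    x <- impute_from_train(x, tr)$x
    x <- minmax_apply(x, minmax_fit(x[tr, ]))
    m <- fit_model(x[tr, ], features$fev1_pct[tr], task = "regression",
                   algorithm = algorithm, seed = seed)
    e <- evaluate_regression(predict_model(m, x[te, ]),
                             features$fev1_pct[te])
    tibble::tibble(feature_set = nm, n_features = length(sets[[nm]]),
                   rmse = e$rmse, mae = e$mae)
  })
  do.call(rbind, rows)
}
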