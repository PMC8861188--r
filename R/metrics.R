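#' Regression error metrics
#' @param predictions,truth Equal-length numeric vectors.
#' @return List with `rmse` and `mae`.
#' @export
evaluate_regression <- function(predictions, truth) {
  stopifnot(length(predictions) == length(truth), length(truth) > 0)
  list(rmse = sqrt(mean((predictions - truth)^2)),
       mae = mean(abs(predictions - truth)))
}

#' Classification metrics from predicted and true classes
#'
#' Computes the confusion matrix (rows = truth, columns = prediction, over
#' the union of levels), accuracy, per-class precision/recall/F1, and
#' macro- and class-weighted F1. When `positive` names a class present in
#' the level set, sensitivity (recall of `positive`) and specificity
#' (recall of the rest) are included, matching the binary normal/abnormal
#' task with abnormal as the positive class.
#'
#' @param predictions,truth Factors or character vectors of classes.
#' @param positive Optional positive class for sensitivity/specificity.
#' @return List: `confusion`, `accuracy`, `per_class` (tibble), `f1_macro`,
#'   `f1_weighted`, and optionally `sensitivity`, `specificity`.
#' @export
evaluate_classification <- function(predictions, truth, positive = NULL) {
  stopifnot(length(predictions) == length(truth), length(truth) > 0)
  lev <- union(levels(factor(truth)), levels(factor(predictions)))
  truth <- factor(truth, levels = lev)
  predictions <- factor(predictions, levels = lev)
  cm <- table(truth = truth, prediction = predictions)
  acc <- sum(diag(cm)) / sum(cm)
  per <- lapply(lev, function(cl) {
    tp <- cm[cl, cl]
    prec <- if (sum(cm[, cl]) > 0) tp / sum(cm[, cl]) else NA_real_
    rec <- if (sum(cm[cl, ]) > 0) tp / sum(cm[cl, ]) else NA_real_
    f1 <- if (isTRUE(prec + rec > 0)) 2 * prec * rec / (prec + rec) else 0
    tibble::tibble(class = cl, n = sum(cm[cl, ]), precision = prec,
                   recall = rec, f1 = f1)
  })
  per <- do.call(rbind, per)
  present <- per$n > 0
  out <- list(confusion = cm, accuracy = acc, per_class = per,
              f1_macro = mean(per$f1[present]),
              f1_weighted = sum(per$f1[present] * per$n[present]) /
                sum(per$n[present]))
  if (!is.null(positive) && positive %in% lev) {
    neg <- setdiff(lev, positive)
    out$sensitivity <- per$recall[per$class == positive]
    out$specificity <- sum(vapply(neg, function(cl) cm[cl, cl], numeric(1))) /
      max(sum(cm[neg, ]), 1)
  }
  out
}

#' ROC curve and AUC for binary scores
#'
#' AUC is computed two ways and both returned: as the trapezoidal area
#' under the ROC curve built over the distinct score thresholds, and by
#' pair counting (the probability that a random positive outscores a
#' random negative, ties counting one half). The two agree to numerical
#' precision by construction of the tie-handling.
#'
#' @param scores Numeric scores, larger = more likely positive.
#' @param truth Class vector.
#' @param positive The positive class label.
#' @return List: `roc` (tibble `threshold`, `fpr`, `tpr`), `auc`
#'   (trapezoidal), `auc_pairs`.
#' @export
roc_auc <- function(scores, truth, positive = "abnormal") {
  stopifnot(length(scores) == length(truth), all(is.finite(scores)))
  pos <- truth == positive
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) stop("roc_auc needs both classes in truth")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  last <- c(s[-1] != s[-length(s)], TRUE)      # last index of each tie group
  tpr <- c(0, cumsum(p)[last] / n_pos)
  fpr <- c(0, cumsum(!p)[last] / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  r <- rank(scores)                            # midranks handle ties
  auc_pairs <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  list(roc = tibble::tibble(threshold = c(Inf, s[last]), fpr = fpr, tpr = tpr),
       auc = auc, auc_pairs = auc_pairs)
}
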