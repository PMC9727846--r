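# Evaluation metrics: imputation RMSE (two denominator conventions),
# correct-classification accuracy, and rank-based AUC.

#' RMSE between imputed and true predictor values
#'
#' Squared errors are computed on predictor cells only and, for multiple
#' imputations, averaged across the completed datasets before taking the
#' root. Two denominators are reported: `rmse_per_missing` divides by the
#' number of amputed cells (the statistically standard choice), while
#' `rmse_pooled` divides by the number of all predictor cells, so observed
#' cells contribute zero error and the value scales like the square root of
#' the missing fraction.
#'
#' @param truth a `complete_dataset` (or its values matrix).
#' @param completed list of completed matrices (or a single matrix).
#' @param mask logical matrix over predictor cells, `TRUE` = was missing.
#' @param outcome_index outcome column in the value matrices (default 6).
#' @return list with `rmse_pooled`, `rmse_per_missing` (`NA` when no cell is
#'   missing), and `n_missing_cells`.
#' @export
imputation_rmse <- function(truth, completed, mask, outcome_index = 6L) {
  tv <- if (inherits(truth, "complete_dataset")) truth$values else as.matrix(truth)
  if (inherits(truth, "complete_dataset")) outcome_index <- truth$spec$outcome_index
  if (is.matrix(completed)) completed <- list(completed)
  tp <- tv[, -outcome_index, drop = FALSE]
  if (!all(dim(mask) == dim(tp))) stop_param("mask shape does not match predictors")
  n_mis <- sum(mask)
  if (n_mis == 0L) {
    return(list(rmse_pooled = 0, rmse_per_missing = NA_real_, n_missing_cells = 0L))
  }
  e2 <- matrix(0, nrow(tp), ncol(tp))
  for (comp in completed) {
    cp <- comp[, -outcome_index, drop = FALSE]
    e2 <- e2 + (cp - tp)^2
  }
  e2 <- e2 / length(completed)
  sse <- sum(e2[mask])
  list(rmse_pooled = sqrt(sse / length(tp)),
       rmse_per_missing = sqrt(sse / n_mis),
       n_missing_cells = n_mis)
}

#' Correct-classification accuracy in percent
#'
#' @param pred_classes predicted 0/1 classes.
#' @param true_classes observed 0/1 classes.
#' @return percentage of agreement, in `[0, 100]`.
#' @export
classification_accuracy <- function(pred_classes, true_classes) {
  if (length(pred_classes) != length(true_classes) || length(true_classes) == 0L) {
    stop_param("class vectors must be nonempty and of equal length")
  }
  100 * mean(pred_classes == true_classes)
}

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation: the probability that a randomly chosen
#' positive case scores above a randomly chosen negative case, with half
#' credit for ties. Equivalent to the trapezoidal area under the empirical
#' ROC curve.
#'
#' @param probabilities numeric scores (higher = more positive).
#' @param labels 0/1 labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(probabilities, labels) {
  if (length(probabilities) != length(labels)) stop_param("length mismatch")
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop_param("both classes must be present")
  r <- rank(probabilities)                   # midranks give the tie half-credit
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
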