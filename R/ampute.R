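# Amputation: turning a complete dataset into a controlled incomplete one
# under MCAR or MAR, at a target proportion of incomplete rows. Follows the
# multivariate-amputation approach: each row is assigned one missingness
# pattern; candidate rows become incomplete with probability `proportion`
# (MCAR) or with a logistic probability driven by a weighted-sum score of
# their observed variables (MAR), so that missingness never depends on the
# values that get blanked.

default_patterns <- function(n_pred = 5L) {
  # one pattern per predictor, each missing exactly that predictor
  diag(TRUE, n_pred)
}

#' Specify an amputation
#'
#' @param mechanism "MCAR" or "MAR".
#' @param proportion target fraction of incomplete rows, in `[0, 1)`. The
#'   study grid uses 0.15, 0.30, 0.45, 0.60.
#' @param patterns logical matrix, one row per pattern, `TRUE` = predictor
#'   missing in that pattern. Default: five patterns, each missing exactly
#'   one predictor.
#' @param pattern_freq probability of each pattern; must sum to 1. Default
#'   uniform.
#' @param mar_weights numeric matrix (pattern x predictor) of weights for the
#'   MAR score. Default: weight 1 on every predictor observed in the pattern,
#'   0 on the amputed one, so selection depends only on observed values.
#' @param mar_type which tail of the score distribution is made missing;
#'   "RIGHT" (default) makes high-score rows more likely incomplete.
#' @return object of class `ampute_spec`.
#' @export
ampute_spec <- function(mechanism = c("MCAR", "MAR"),
                        proportion = 0.3,
                        patterns = default_patterns(),
                        pattern_freq = NULL,
                        mar_weights = NULL,
                        mar_type = c("RIGHT", "LEFT")) {
  mechanism <- match.arg(mechanism)
  mar_type <- match.arg(mar_type)
  if (!is.numeric(proportion) || proportion < 0 || proportion >= 1) {
    stop_param("`proportion` must lie in [0, 1)")
  }
  patterns <- as.matrix(patterns)
  storage.mode(patterns) <- "logical"
  if (any(rowSums(patterns) == ncol(patterns))) {
    stop_param("every pattern must leave at least one predictor observed")
  }
  if (any(rowSums(patterns) == 0L)) {
    stop_param("every pattern must blank at least one predictor")
  }
  if (is.null(pattern_freq)) pattern_freq <- rep(1 / nrow(patterns), nrow(patterns))
  if (abs(sum(pattern_freq) - 1) > 1e-9 || any(pattern_freq < 0)) {
    stop_param("`pattern_freq` must be non-negative and sum to 1")
  }
  if (is.null(mar_weights)) {
    mar_weights <- (!patterns) * 1.0
  }
  mar_weights <- as.matrix(mar_weights)
  if (!all(dim(mar_weights) == dim(patterns))) {
    stop_param("`mar_weights` must have one row per pattern, one column per predictor")
  }
  structure(list(mechanism = mechanism, proportion = proportion,
                 patterns = patterns, pattern_freq = pattern_freq,
                 mar_weights = mar_weights, mar_type = mar_type),
            class = "ampute_spec")
}

# Solve for the logistic intercept so mean(plogis(shift + score)) == target.
logistic_shift <- function(score, target, tol = 1e-6) {
  lo <- -50; hi <- 50
  f <- function(s) mean(stats::plogis(s + score)) - target
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Ampute a complete dataset
#'
#' @param data a `complete_dataset`.
#' @param spec an [ampute_spec()].
#' @param seed integer RNG seed.
#' @return object of class `incomplete_dataset`: `values` (matrix with `NA`
#'   in amputed predictor cells; the outcome column is never amputed), `mask`
#'   (`n x n_pred` logical, `TRUE` = missing), `source`, `spec`.
#' @export
ampute <- function(data, spec, seed = 1L) {
  stopifnot(inherits(data, "complete_dataset"), inherits(spec, "ampute_spec"))
  set.seed(as.integer(seed))
  values <- data$values
  oc <- data$spec$outcome_index
  pred <- values[, -oc, drop = FALSE]
  n <- nrow(pred)
  n_pred <- ncol(pred)
  if (ncol(spec$patterns) != n_pred) {
    stop_param("pattern width does not match the number of predictors")
  }
  mask <- matrix(FALSE, n, n_pred, dimnames = list(NULL, colnames(pred)))

  if (spec$proportion > 0) {
    pat_id <- sample.int(nrow(spec$patterns), n, replace = TRUE,
                         prob = spec$pattern_freq)
    if (spec$mechanism == "MCAR") {
      prob <- rep(spec$proportion, n)
    } else {
      z <- scale(pred)                       # standardized on the full data
      raw <- rowSums(z * spec$mar_weights[pat_id, , drop = FALSE])
      score <- as.numeric(scale(raw))
      if (spec$mar_type == "LEFT") score <- -score
      shift <- logistic_shift(score, spec$proportion)
      prob <- stats::plogis(shift + score)
    }
    hit <- stats::runif(n) < prob
    mask[hit, ] <- spec$patterns[pat_id[hit], , drop = FALSE]
  }

  pred[mask] <- NA_real_
  out <- values
  out[, -oc] <- pred
  structure(list(values = out, mask = mask, source = data, spec = spec,
                 seed = as.integer(seed)),
            class = "incomplete_dataset")
}

#' @export
print.incomplete_dataset <- function(x, ...) {
  cat(sprintf("Incomplete dataset: %d x %d, %s, %.1f%% incomplete rows (%.1f%% cells)\n",
              nrow(x$values), ncol(x$values), x$spec$mechanism,
              100 * mean(rowSums(x$mask) > 0), 100 * mean(x$mask)))
  invisible(x)
}

#' Diagnostics for the realized missingness mechanism
#'
#' Reports realized row-wise and cell-wise missing rates and tests whether
#' row incompleteness is associated with the observed data values. The
#' headline test is a one-sided Welch t-test comparing, between incomplete
#' and complete rows, each row's mean standardized observed predictor value
#' (one-sided towards high scores, matching a RIGHT-tail MAR mechanism).
#' Under MCAR it rejects at the nominal rate; under MAR it has high power.
#' Per-predictor t-tests (restricted to rows where that predictor is
#' observed) are reported alongside.
#'
#' @param inc an `incomplete_dataset`.
#' @param alpha significance level for the reported reject flags.
#' @return list of class `mechanism_diagnostics` with realized rates,
#'   p-values and reject indicators; tests are `NA` when every row is
#'   complete or every row is incomplete.
#' @export
mechanism_diagnostics <- function(inc, alpha = 0.05) {
  stopifnot(inherits(inc, "incomplete_dataset"))
  mask <- inc$mask
  row_inc <- rowSums(mask) > 0
  out <- list(row_rate = mean(row_inc), cell_rate = mean(mask), alpha = alpha,
              score_p = NA_real_, score_reject = NA,
              variable_p = rep(NA_real_, ncol(mask)))
  names(out$variable_p) <- colnames(mask)
  if (any(row_inc) && any(!row_inc)) {
    oc <- inc$source$spec$outcome_index
    pred <- inc$source$values[, -oc, drop = FALSE]
    z <- scale(pred)
    z[mask] <- NA                            # only values still observed
    score <- rowMeans(z, na.rm = TRUE)
    tt <- stats::t.test(score[row_inc], score[!row_inc], alternative = "greater")
    out$score_p <- tt$p.value
    out$score_reject <- tt$p.value < alpha
    for (k in seq_len(ncol(mask))) {
      obs_k <- !mask[, k]
      g1 <- pred[obs_k & row_inc, k]
      g0 <- pred[obs_k & !row_inc, k]
      if (length(g1) > 1 && length(g0) > 1) {
        out$variable_p[k] <- stats::t.test(g1, g0)$p.value
      }
    }
  }
  out$variable_reject <- out$variable_p < alpha
  class(out) <- "mechanism_diagnostics"
  out
}

#' @export
print.mechanism_diagnostics <- function(x, ...) {
  cat(sprintf("Missingness: %.1f%% of rows, %.1f%% of cells\n",
              100 * x$row_rate, 100 * x$cell_rate))
  if (is.na(x$score_p)) {
    cat("Association tests skipped (no contrast between complete and incomplete rows)\n")
  } else {
    cat(sprintf("Score association test: p = %.4g (%s at alpha = %.2f)\n",
                x$score_p, if (x$score_reject) "reject MCAR" else "retain MCAR",
                x$alpha))
  }
  invisible(x)
}

#' Write the missingness mask as a 0/1 CSV parallel to the dataset
#' @param inc an `incomplete_dataset`.
#' @param path output file path.
#' @export
write_mask_csv <- function(inc, path) {
  utils::write.table(1L * inc$mask, path, sep = ",", row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}
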