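# Three classifiers for the binary recurrence outcome: binary logistic
# regression fitted by iteratively reweighted least squares, and linear /
# quadratic discriminant analysis fitted from class means, covariances and
# empirical priors. All use the same stratified 70/30 train/test split and
# the 0.5 probability cut-off (strictly greater than 0.5 -> recurrence).

#' Specify a train/test split
#'
#' @param train_fraction fraction of rows used for training (default 0.70).
#' @param stratified stratify by outcome class so each class's train share is
#'   within one observation of `train_fraction` (default `TRUE`).
#' @return object of class `split_spec`.
#' @export
split_spec <- function(train_fraction = 0.7, stratified = TRUE) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop_param("`train_fraction` must lie strictly between 0 and 1")
  }
  structure(list(train_fraction = train_fraction, stratified = isTRUE(stratified)),
            class = "split_spec")
}

#' Split observations into train and test sets
#'
#' The train set has exactly `floor(train_fraction * n)` rows. Under
#' stratification the per-class allocation follows the largest-remainder
#' rule, so each class's train share is within one observation of the target
#' fraction.
#'
#' @param outcome 0/1 outcome vector (both classes must be present).
#' @param spec a [split_spec()].
#' @param seed integer RNG seed.
#' @return list with integer index vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
split_train_test <- function(outcome, spec = split_spec(), seed = 1L) {
  stopifnot(inherits(spec, "split_spec"))
  n <- length(outcome)
  classes <- sort(unique(outcome))
  if (length(classes) < 2L) stop_param("both outcome classes must be present")
  n_train <- floor(spec$train_fraction * n)
  set.seed(as.integer(seed))
  if (!spec$stratified) {
    train <- sort(sample.int(n, n_train))
  } else {
    sizes <- vapply(classes, function(cl) sum(outcome == cl), 0)
    tgt <- spec$train_fraction * sizes
    base <- floor(tgt)
    extra <- n_train - sum(base)
    if (extra > 0) {
      give <- order(tgt - base, decreasing = TRUE)[seq_len(extra)]
      base[give] <- base[give] + 1
    }
    train <- sort(unlist(lapply(seq_along(classes), function(i) {
      rows <- which(outcome == classes[i])
      rows[sample.int(length(rows), base[i])]
    })))
  }
  test <- setdiff(seq_len(n), train)
  if (length(unique(outcome[train])) < 2L) {
    stop_param("a class is absent from the training set; use a stratified split")
  }
  list(train = train, test = test)
}

## ---- binary logistic regression -------------------------------------------

#' Fit binary logistic regression by iteratively reweighted least squares
#'
#' Maximizes the Bernoulli log-likelihood of
#' `logit(p_i) = beta0 + beta1 x_1i + ... + beta5 x_5i`.
#' Convergence is declared when the maximum absolute score
#' `|X'(y - p)|` falls below `tol`. Near-singular designs get a small ridge;
#' diverging coefficients (complete separation) are capped with
#' `converged = FALSE`.
#'
#' @param x numeric predictor matrix (no intercept column).
#' @param y 0/1 outcome vector.
#' @param cutoff classification cut-off on the predicted probability
#'   (default 0.5; strictly greater means class 1).
#' @param tol score convergence tolerance (default 1e-8).
#' @param max_iter IRLS iteration cap (default 50).
#' @return object of class `blr_model` with `beta0`, `beta`, `coefficients`,
#'   `cutoff`, `converged`, `n_iter`.
#' @export
fit_blr <- function(x, y, cutoff = 0.5, tol = 1e-8, max_iter = 50L) {
  x <- as.matrix(x)
  X <- cbind("(Intercept)" = 1, x)
  q <- ncol(X)
  beta <- numeric(q)
  beta[1] <- stats::qlogis(min(max(mean(y), 1e-3), 1 - 1e-3))
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    eta <- as.numeric(X %*% beta)
    p <- stats::plogis(eta)
    score <- crossprod(X, y - p)
    if (max(abs(score)) < tol) {
      converged <- TRUE
      break
    }
    w <- pmax(p * (1 - p), 1e-10)
    XtWX <- crossprod(X * w, X)
    step <- tryCatch(solve(XtWX, score), error = function(e) {
      warning("near-singular logistic design; applying ridge")
      solve(XtWX + diag(1e-8 * pmax(diag(XtWX), 1), q), score)
    })
    beta <- beta + as.numeric(step)
    if (max(abs(beta)) > 1e4) {
      warning("logistic coefficients diverging (separation?); capping")
      beta <- pmin(pmax(beta, -1e4), 1e4)
      break
    }
  }
  if (!converged && iter >= max_iter) {
    warning("IRLS did not converge in ", max_iter, " iterations")
  }
  names(beta) <- colnames(X)
  structure(list(beta0 = beta[1], beta = beta[-1], coefficients = beta,
                 cutoff = cutoff, converged = converged, n_iter = iter),
            class = "blr_model")
}

#' @export
coef.blr_model <- function(object, ...) object$coefficients

#' @export
print.blr_model <- function(x, ...) {
  cat(sprintf("Binary logistic regression (%s, %d IRLS iterations)\n",
              if (x$converged) "converged" else "not converged", x$n_iter))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Predict from a fitted logistic regression
#'
#' @param object a `blr_model`.
#' @param newdata predictor matrix matching the training columns.
#' @param ... unused.
#' @return list with `prob` (inverse-logit probabilities) and `class`
#'   (1 iff `prob` strictly exceeds the cut-off).
#' @export
predict.blr_model <- function(object, newdata, ...) {
  eta <- object$beta0 + as.numeric(as.matrix(newdata) %*% object$beta)
  prob <- stats::plogis(eta)
  list(prob = prob, class = as.numeric(prob > object$cutoff))
}

## ---- discriminant analysis -------------------------------------------------

#' Fit a linear or quadratic discriminant classifier
#'
#' Group means are class means; LDA uses the pooled within-class covariance
#' (divisor `n - 2`), QDA per-class covariances (divisor `n_k - 1`); priors
#' are the empirical class proportions. A case `x` is allocated to the class
#' with the largest discriminant score: for LDA
#' `delta_k(x) = x' S^-1 mu_k - mu_k' S^-1 mu_k / 2 + log pi_k`, for QDA
#' `delta_k(x) = -(x - mu_k)' S_k^-1 (x - mu_k) / 2 - log|S_k| / 2 + log pi_k`.
#' Singular covariances are repaired by an eigenvalue floor with a warning.
#'
#' @param x numeric predictor matrix.
#' @param y 0/1 outcome vector.
#' @param kind `"lda"` or `"qda"`.
#' @return object of class `discriminant_model`.
#' @export
fit_discriminant <- function(x, y, kind = c("lda", "qda")) {
  kind <- match.arg(kind)
  x <- as.matrix(x)
  classes <- sort(unique(y))
  if (length(classes) != 2L) stop_param("exactly two outcome classes required")
  pdim <- ncol(x)
  n <- nrow(x)
  nk <- vapply(classes, function(cl) sum(y == cl), 0)
  if (kind == "qda" && any(nk < pdim + 2L)) {
    stop_param("QDA needs at least p + 2 rows per class")
  }
  if (n < pdim + 2L) stop_param("LDA needs at least p + 2 rows")
  means <- matrix(vapply(classes, function(cl) colMeans(x[y == cl, , drop = FALSE]),
                         numeric(pdim)),
                  nrow = length(classes), byrow = TRUE)
  priors <- nk / n
  check <- function(S, what) {
    r <- repair_spd(S)
    if (r$repaired) warning(what, " covariance repaired to positive definite")
    r$sigma
  }
  if (kind == "lda") {
    pooled <- matrix(0, pdim, pdim)
    for (i in seq_along(classes)) {
      xc <- sweep(x[y == classes[i], , drop = FALSE], 2, means[i, ])
      pooled <- pooled + crossprod(xc)
    }
    pooled <- check(pooled / (n - 2), "pooled")
    covs <- NULL
  } else {
    pooled <- NULL
    covs <- lapply(seq_along(classes), function(i)
      check(stats::cov(x[y == classes[i], , drop = FALSE]), "class"))
  }
  structure(list(kind = kind, classes = classes, means = means,
                 pooled_cov = pooled, group_covs = covs, priors = priors),
            class = "discriminant_model")
}

#' @export
print.discriminant_model <- function(x, ...) {
  cat(sprintf("%s classifier: priors %s\n", toupper(x$kind),
              paste(sprintf("%.3f", x$priors), collapse = " / ")))
  invisible(x)
}

#' Predict from a fitted discriminant model
#'
#' @param object a `discriminant_model`.
#' @param newdata predictor matrix.
#' @param ... unused.
#' @return list with `delta` (discriminant scores, one column per class),
#'   `posterior` (class posteriors via Bayes' theorem; rows sum to 1),
#'   `prob` (posterior of the second = recurrence class), and `class`
#'   (argmax of `delta`).
#' @export
predict.discriminant_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  n <- nrow(x)
  delta <- matrix(0, n, 2)
  if (object$kind == "lda") {
    Sinv_mu <- solve_spd(object$pooled_cov, t(object$means))   # p x 2
    for (i in 1:2) {
      mu <- object$means[i, ]
      delta[, i] <- x %*% Sinv_mu[, i] -
        0.5 * sum(mu * Sinv_mu[, i]) + log(object$priors[i])
    }
  } else {
    for (i in 1:2) {
      S <- object$group_covs[[i]]
      ch <- chol(S)
      dev <- sweep(x, 2, object$means[i, ])
      sol <- forwardsolve(t(ch), t(dev))
      delta[, i] <- -0.5 * colSums(sol^2) - sum(log(diag(ch))) +
        log(object$priors[i])
    }
  }
  # posterior via softmax of the discriminant scores (shared terms cancel)
  mx <- pmax(delta[, 1], delta[, 2])
  ed <- exp(delta - mx)
  posterior <- ed / rowSums(ed)
  colnames(posterior) <- as.character(object$classes)
  cls <- object$classes[max.col(delta, ties.method = "first")]
  list(delta = delta, posterior = posterior,
       prob = posterior[, 2], class = cls)
}
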