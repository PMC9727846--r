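# Classifier unit tests. Oracles: explicit likelihood maximization via
# optim() with analytic gradient for the logistic model, direct evaluation
# of the discriminant formulas via solve(), and MASS::lda / MASS::qda as an
# independent implementation.

test_that("the 70/30 split has the stated sizes, stratification, and determinism", {
  d <- generate_complete(cohort_spec(), seed = 2)
  s <- split_train_test(d$outcome, split_spec(), seed = 3)
  expect_length(s$train, 485)               # floor(693 * 0.7)
  expect_length(s$test, 208)
  expect_identical(sort(c(s$train, s$test)), 1:693)
  # each class's train share within one observation of 70%
  for (cl in 0:1) {
    n_cl <- sum(d$outcome == cl)
    expect_lt(abs(sum(d$outcome[s$train] == cl) - 0.7 * n_cl), 1 + 1e-9)
  }
  s2 <- split_train_test(d$outcome, split_spec(), seed = 3)
  expect_identical(s, s2)

  # 10 balanced rows at fraction 0.5: 5/5 with class balance preserved
  y <- rep(0:1, 5)
  sb <- split_train_test(y, split_spec(0.5), seed = 4)
  expect_length(sb$train, 5)
  expect_true(abs(sum(y[sb$train]) - 2.5) <= 0.5 + 1e-9)

  expect_error(split_train_test(rep(1, 10), split_spec(), seed = 1),
               "both outcome classes")
})

test_that("IRLS coefficients maximize the Bernoulli log-likelihood", {
  # fixed 20-row set; oracle: BFGS on the explicit log-likelihood with
  # analytic gradient
  set.seed(77)
  x <- matrix(rnorm(20 * 3), 20, 3)
  y <- rbinom(20, 1, plogis(0.3 + x %*% c(0.8, -0.5, 0.2)))
  fit <- fit_blr(x, y)
  X <- cbind(1, x)
  nll <- function(b) -sum(y * (X %*% b) - log1p(exp(X %*% b)))
  gr <- function(b) -as.numeric(crossprod(X, y - plogis(X %*% b)))
  opt <- optim(rep(0, 4), nll, gr, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-15))
  expect_lt(max(abs(coef(fit) - opt$par)), 1e-6)
  # score equations satisfied at convergence
  expect_lt(max(abs(crossprod(X, y - plogis(X %*% coef(fit))))), 1e-6)
  expect_true(fit$converged)
})

test_that("logistic fit approaches the null model when predictors carry no signal", {
  set.seed(88)
  n <- 4000
  x <- matrix(rnorm(n * 5), n, 5)
  y <- rbinom(n, 1, 0.3)
  fit <- fit_blr(x, y)
  expect_lt(abs(fit$beta0 - qlogis(mean(y))), 0.01)
  expect_true(all(abs(fit$beta) < 4 / sqrt(n)))
  p <- predict(fit, x)$prob
  expect_true(all(p > 0 & p < 1))
})

test_that("logistic predictions follow the inverse logit and the strict 0.5 cut", {
  null_model <- structure(list(beta0 = 0, beta = rep(0, 2), cutoff = 0.5),
                          class = "blr_model")
  pr <- predict(null_model, matrix(rnorm(10), 5, 2))
  expect_equal(pr$prob, rep(0.5, 5))
  expect_equal(pr$class, rep(0, 5))          # not greater than 0.5 -> class 0

  icpt <- structure(list(beta0 = 1, beta = rep(0, 2), cutoff = 0.5),
                    class = "blr_model")
  pr <- predict(icpt, matrix(rnorm(6), 3, 2))
  expect_equal(pr$prob, rep(exp(1) / (1 + exp(1)), 3))
  expect_equal(pr$class, rep(1, 3))          # 0.731 > 0.5 -> recurrence
})

test_that("discriminant scores match direct evaluation of the formulas", {
  set.seed(99)
  x <- matrix(rnorm(10 * 2, sd = 2), 10, 2)
  y <- c(0, 0, 0, 0, 1, 1, 1, 1, 1, 0)
  for (kind in c("lda", "qda")) {
    fit <- fit_discriminant(x, y, kind)
    pred <- predict(fit, x)
    n <- nrow(x)
    mu0 <- colMeans(x[y == 0, ]); mu1 <- colMeans(x[y == 1, ])
    pi0 <- mean(y == 0); pi1 <- mean(y == 1)
    if (kind == "lda") {
      S <- (crossprod(sweep(x[y == 0, ], 2, mu0)) +
              crossprod(sweep(x[y == 1, ], 2, mu1))) / (n - 2)
      Si <- solve(S)
      d0 <- x %*% Si %*% mu0 - 0.5 * drop(mu0 %*% Si %*% mu0) + log(pi0)
      d1 <- x %*% Si %*% mu1 - 0.5 * drop(mu1 %*% Si %*% mu1) + log(pi1)
    } else {
      S0 <- cov(x[y == 0, ]); S1 <- cov(x[y == 1, ])
      qf <- function(xx, mu, S) apply(xx, 1, function(r)
        drop(t(r - mu) %*% solve(S) %*% (r - mu)))
      d0 <- -0.5 * qf(x, mu0, S0) - 0.5 * log(det(S0)) + log(pi0)
      d1 <- -0.5 * qf(x, mu1, S1) - 0.5 * log(det(S1)) + log(pi1)
    }
    expect_equal(pred$delta[, 1], drop(d0), tolerance = 1e-10)
    expect_equal(pred$delta[, 2], drop(d1), tolerance = 1e-10)
    expect_equal(pred$class, as.numeric(d1 > d0))
    # posteriors normalize and are monotone in delta
    expect_equal(rowSums(pred$posterior), rep(1, n), tolerance = 1e-12)
    expect_identical(max.col(pred$posterior), max.col(pred$delta))
  }
})

test_that("discriminant predictions agree with the MASS implementations", {
  d <- generate_complete(cohort_spec(400), seed = 13)
  x <- d$values[, 1:5]; y <- d$outcome
  for (kind in c("lda", "qda")) {
    fit <- fit_discriminant(x, y, kind)
    mine <- predict(fit, x)
    ref <- if (kind == "lda") MASS::lda(x, grouping = y) else MASS::qda(x, grouping = y)
    rp <- predict(ref, x)
    expect_equal(unname(mine$posterior[, 2]), unname(rp$posterior[, 2]),
                 tolerance = 1e-8)
    expect_equal(mine$class, as.numeric(as.character(rp$class)))
  }
})

test_that("QDA reduces to LDA when the class covariances are forced equal", {
  d <- generate_complete(cohort_spec(300), seed = 14)
  x <- d$values[, 1:5]; y <- d$outcome
  lda_fit <- fit_discriminant(x, y, "lda")
  qda_fit <- fit_discriminant(x, y, "qda")
  qda_fit$group_covs <- list(lda_fit$pooled_cov, lda_fit$pooled_cov)
  set.seed(15)
  new_x <- MASS::mvrnorm(200, colMeans(x), cov(x))
  expect_identical(predict(qda_fit, new_x)$class, predict(lda_fit, new_x)$class)
})

test_that("the LDA decision is invariant to affine rescaling of a predictor", {
  d <- generate_complete(cohort_spec(300), seed = 16)
  x <- d$values[, 1:5]; y <- d$outcome
  x2 <- x; x2[, 1] <- 10 * x2[, 1] + 3
  c1 <- predict(fit_discriminant(x, y, "lda"), x)$class
  c2 <- predict(fit_discriminant(x2, y, "lda"), x2)$class
  expect_identical(c1, c2)
})

test_that("a symmetric 1-D two-class problem has its boundary at the midpoint", {
  x <- matrix(c(-1.5, -1, -0.5, 0.5, 1, 1.5), ncol = 1)
  y <- c(0, 0, 0, 1, 1, 1)
  fit <- fit_discriminant(x, y, "lda")
  pr <- predict(fit, matrix(c(0, 0.5, -0.5), ncol = 1))
  expect_equal(pr$posterior[1, ], c("0" = 0.5, "1" = 0.5), tolerance = 1e-12)
  expect_equal(pr$class[2:3], c(1, 0))       # allocated to the nearer mean
})

test_that("all classifiers beat the majority class on separated data and match it on shuffled labels", {
  set.seed(123)
  n <- 600
  y <- rep(0:1, each = n / 2)
  x <- matrix(rnorm(n * 3), n, 3)
  x[, 1] <- x[, 1] + 3 * y                   # 3-SD separation on one axis
  idx <- split_train_test(y, split_spec(), seed = 5)
  majority <- 100 * max(mean(y[idx$test]), 1 - mean(y[idx$test]))
  for (clf in c("blr", "lda", "qda")) {
    fit_fun <- function(yy) {
      if (clf == "blr") predict(fit_blr(x[idx$train, ], yy[idx$train]),
                                x[idx$test, ])$class
      else predict(fit_discriminant(x[idx$train, ], yy[idx$train], clf),
                   x[idx$test, ])$class
    }
    acc <- classification_accuracy(fit_fun(y), y[idx$test])
    expect_gt(acc, majority + 10)
    set.seed(321)
    y_shuf <- sample(y)
    maj_shuf <- 100 * max(mean(y_shuf[idx$test]), 1 - mean(y_shuf[idx$test]))
    acc_shuf <- classification_accuracy(fit_fun(y_shuf), y_shuf[idx$test])
    expect_lt(abs(acc_shuf - maj_shuf), 100 * 4 * sqrt(0.25 / length(idx$test)))
  }
})
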