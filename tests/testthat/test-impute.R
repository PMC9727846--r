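# Unit tests for the six imputers. Hand oracles are re-derived inline from
# the method definitions (brute-force scans, closed forms), independent of
# the implementation code paths.

no_missing_identity <- function(method) {
  d <- small_complete(60, seed = 7)
  inc <- toy_incomplete(d$values[, 1:5], d$outcome,
                        matrix(FALSE, nrow(d$values), 5))
  res <- impute_missing(inc, imputer_config(method), seed = 1)
  for (comp in res$completed) expect_identical(comp, inc$values)
}

test_that("every imputer is the identity on data without missing cells", {
  for (m in c("smean", "hd", "knn", "mice", "pmm", "emb")) no_missing_identity(m)
})

test_that("series mean fills with the observed variable means", {
  pred <- cbind(x1 = c(1, 2, 3, 10), x2 = c(5, 6, 7, 8))
  mask <- rbind(c(FALSE, FALSE), c(FALSE, FALSE), c(FALSE, TRUE), c(TRUE, FALSE))
  inc <- toy_incomplete(pred, c(0, 1, 0, 1), mask)
  res <- impute_mean(inc)
  comp <- res$completed[[1]]
  expect_equal(unname(comp[4, "x1"]), mean(c(1, 2, 3)))   # observed values {1,2,3}
  expect_equal(unname(comp[3, "x2"]), mean(c(5, 6, 8)))
  expect_identical(comp[, 1:2][!mask], pred[!mask])

  all_na <- toy_incomplete(cbind(x1 = c(NA, NA), x2 = c(1, 2)),
                           c(0, 1), cbind(c(TRUE, TRUE), c(FALSE, FALSE)))
  expect_error(impute_mean(all_na), "no observed values")
})

test_that("hot deck picks the donor with minimal maximum standardized deviation", {
  for (case in 1:15) {
    inc <- random_incomplete(n = 30, p = 4, frac = 0.15, seed = 100 + case)
    res <- impute_hotdeck(inc)
    comp <- res$completed[[1]]
    pred <- inc$values[, 1:4]
    mask <- inc$mask
    # oracle: standardize on observed moments, scan complete rows
    z <- scale(pred, center = colMeans(pred, na.rm = TRUE),
               scale = apply(pred, 2, sd, na.rm = TRUE))
    complete_rows <- which(rowSums(mask) == 0)
    for (i in which(rowSums(mask) > 0)) {
      obs <- which(!mask[i, ])
      dist <- vapply(complete_rows, function(j)
        max(abs(z[i, obs] - z[j, obs])), 0)
      donor <- complete_rows[which.min(dist)]   # which.min takes lowest index
      expect_equal(unname(comp[i, which(mask[i, ])]),
                   unname(pred[donor, which(mask[i, ])]))
    }
  }
})

test_that("KNN averages the k nearest donors under the range-normalized distance", {
  for (case in 1:15) {
    inc <- random_incomplete(n = 30, p = 4, frac = 0.15, seed = 200 + case)
    k <- 3L
    res <- impute_knn(inc, imputer_config("knn", k_neighbours = k))
    comp <- res$completed[[1]]
    pred <- inc$values[, 1:4]
    mask <- inc$mask
    rng <- apply(pred, 2, function(x) diff(range(x, na.rm = TRUE)))
    for (i in which(rowSums(mask) > 0)) {
      obs <- which(!mask[i, ])
      for (t in which(mask[i, ])) {
        donors <- which(!mask[, t])
        D <- vapply(donors, function(j) {
          shared <- obs[!mask[j, obs]]
          if (length(shared) == 0) return(Inf)
          mean(abs(pred[i, shared] - pred[j, shared]) / rng[shared])
        }, 0)
        nearest <- donors[order(D, donors)][seq_len(min(k, length(donors)))]
        expect_equal(unname(comp[i, t]), mean(pred[nearest, t]))
      }
    }
  }
})

test_that("a duplicate observed profile is the 1-nearest neighbour", {
  pred <- cbind(x1 = c(1, 1, 5, 9), x2 = c(2, 2, 6, 1), x3 = c(4, 7, 8, 2))
  mask <- matrix(FALSE, 4, 3); mask[1, 3] <- TRUE
  inc <- toy_incomplete(pred, c(0, 1, 0, 1), mask)
  res <- impute_knn(inc, imputer_config("knn", k_neighbours = 1))
  expect_equal(unname(res$completed[[1]][1, "x3"]), 7)   # row 2 duplicates (x1, x2)
})

test_that("donor-based imputers only emit observed values and never alter observed cells", {
  for (case in 1:25) {
    inc <- random_incomplete(n = 35, p = 4, frac = 0.2, seed = 300 + case)
    pred <- inc$values[, 1:4]
    for (m in c("hd", "pmm")) {
      cfg <- imputer_config(m, m_imputations = 2, chain_iterations = 3)
      res <- impute_missing(inc, cfg, seed = case)
      for (comp in res$completed) {
        for (t in 1:4) {
          mis <- inc$mask[, t]
          if (!any(mis)) next
          expect_true(all(comp[mis, t] %in% pred[!mis, t]))
          expect_identical(comp[!mis, t], pred[!mis, t])
        }
      }
    }
  }
})

test_that("pmm_match agrees with the brute-force nearest-predictive-mean scan", {
  for (case in 1:40) {
    set.seed(400 + case)
    yobs <- rnorm(30)
    ymis <- rnorm(8)
    pool <- sample(c(1L, 3L, 5L), 1)
    sel <- imputeclass:::pmm_match(yobs, ymis, pool)
    for (i in seq_along(ymis)) {
      brute <- order(abs(yobs - ymis[i]), seq_along(yobs))[seq_len(pool)]
      expect_setequal(sel[i, ], brute)
      if (pool == 1L) expect_identical(sel[i, 1], brute[1])
    }
  }
})

test_that("chained-equations imputation is reproducible, stochastic across m, and unbiased under MCAR", {
  inc <- random_incomplete(n = 60, p = 4, frac = 0.2, seed = 17)
  cfg <- imputer_config("mice", m_imputations = 3, chain_iterations = 4)
  r1 <- impute_missing(inc, cfg, seed = 5)
  r2 <- impute_missing(inc, cfg, seed = 5)
  expect_identical(r1$completed, r2$completed)
  # distinct sub-seeds: imputed cells differ between completions
  mis_cells <- which(cbind(inc$mask, FALSE))
  expect_gt(var(c(r1$completed[[1]][mis_cells][1],
                  r1$completed[[2]][mis_cells][1],
                  r1$completed[[3]][mis_cells][1])), 0)

  # MCAR unbiasedness: replicate-averaged imputed-cell means close to truth
  spec <- cohort_spec(1200)
  reps <- 10
  dev <- matrix(NA_real_, reps, 5)
  for (r in seq_len(reps)) {
    d <- generate_complete(spec, seed = 700 + r)
    inc_r <- ampute(d, ampute_spec("MCAR", 0.30), seed = 800 + r)
    res <- impute_missing(inc_r, imputer_config("mice"), seed = 900 + r)
    for (k in 1:5) {
      mis <- inc_r$mask[, k]
      imp <- rowMeans(vapply(res$completed, function(cm) cm[mis, k],
                             numeric(sum(mis))))
      dev[r, k] <- mean(imp) - spec$mu[k]
    }
  }
  grand <- colMeans(dev)
  se <- apply(dev, 2, sd) / sqrt(reps)
  expect_true(all(abs(grand) < 4 * se))
})

test_that("EM recovers the ML estimate on complete data in one pass", {
  d <- small_complete(200, seed = 31)
  x <- d$values
  fit <- em_mvnorm(x)
  expect_true(fit$converged)
  expect_equal(unname(fit$mu), unname(colMeans(x)), tolerance = 1e-10)
  expect_equal(unname(fit$sigma),
               unname(cov(x) * (nrow(x) - 1) / nrow(x)), tolerance = 1e-8)
})

test_that("EM log-likelihood trace is monotone non-decreasing", {
  d <- generate_complete(cohort_spec(400), seed = 33)
  inc <- ampute(d, ampute_spec("MCAR", 0.45), seed = 34)
  fit <- em_mvnorm(inc)
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
  expect_true(fit$converged)
})

test_that("conditional draws match the closed-form bivariate conditional normal", {
  mu <- c(1, -2)
  sigma <- matrix(c(2, 1.2, 1.2, 1.5), 2)
  n <- 20000
  set.seed(44)
  x1 <- rnorm(n, mu[1], sqrt(sigma[1, 1]))
  X <- cbind(x1, NA_real_)
  set.seed(45)
  out <- imputeclass:::conditional_draw(X, mu, sigma)
  b <- sigma[2, 1] / sigma[1, 1]
  cmean <- mu[2] + b * (x1 - mu[1])
  cvar <- sigma[2, 2] - b * sigma[1, 2]
  resid <- out[, 2] - cmean
  expect_lt(abs(mean(resid)), 4 * sqrt(cvar / n))
  expect_equal(var(resid), cvar, tolerance = 0.05)
})

test_that("bootstrap-EM propagates parameter uncertainty across completions", {
  d <- generate_complete(cohort_spec(250), seed = 51)
  inc <- ampute(d, ampute_spec("MCAR", 0.15), seed = 52)
  res <- impute_missing(inc, imputer_config("emb"), seed = 53)
  expect_length(res$completed, 5)
  mis_cells <- which(cbind(inc$mask, FALSE))
  means <- vapply(res$completed, function(cm) mean(cm[mis_cells]), 0)
  expect_gt(var(means), 0)
  for (comp in res$completed) expect_false(anyNA(comp))
})
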