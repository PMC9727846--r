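# Six imputation algorithms sharing one contract: an incomplete dataset in,
# a list of completed datasets out (one for the single-imputation methods,
# m for the multiple-imputation ones). Observed cells are never altered.

#' Configure an imputation method
#'
#' @param method one of `"smean"` (series mean), `"hd"` (hot deck), `"knn"`
#'   (k-nearest neighbour), `"mice"` (multiple imputation by chained
#'   equations), `"pmm"` (predictive mean matching), `"emb"` (bootstrap
#'   expectation-maximisation).
#' @param m_imputations number of completed datasets. Defaults to 1 for the
#'   single-imputation methods and 5 for mice/pmm/emb.
#' @param k_neighbours donors averaged by KNN (default 5).
#' @param knn_weights positive per-predictor weights for the KNN distance
#'   (default uniform).
#' @param donor_pool PMM draws its donor uniformly from this many nearest
#'   candidates (default 5).
#' @param chain_iterations sweeps of the chained-equations loop for mice/pmm
#'   (default 10).
#' @param em_tol convergence tolerance on the relative change of the
#'   observed-data log-likelihood (default 1e-6).
#' @param em_max_iter maximum EM iterations (default 500).
#' @param outcome_in_model should the (always observed) binary outcome enter
#'   the mice/pmm conditional models as a regressor? Default `TRUE`.
#' @return object of class `imputer_config`.
#' @export
imputer_config <- function(method = c("smean", "hd", "knn", "mice", "pmm", "emb"),
                           m_imputations = NULL,
                           k_neighbours = 5L,
                           knn_weights = NULL,
                           donor_pool = 5L,
                           chain_iterations = 10L,
                           em_tol = 1e-6,
                           em_max_iter = 500L,
                           outcome_in_model = TRUE) {
  method <- match.arg(method)
  if (is.null(m_imputations)) {
    m_imputations <- if (method %in% c("mice", "pmm", "emb")) 5L else 1L
  }
  m_imputations <- as.integer(m_imputations)
  if (m_imputations < 1L) stop_param("`m_imputations` must be >= 1")
  if (k_neighbours < 1L) stop_param("`k_neighbours` must be >= 1")
  if (donor_pool < 1L) stop_param("`donor_pool` must be >= 1")
  if (em_tol <= 0) stop_param("`em_tol` must be > 0")
  structure(list(method = method, m_imputations = m_imputations,
                 k_neighbours = as.integer(k_neighbours),
                 knn_weights = knn_weights,
                 donor_pool = as.integer(donor_pool),
                 chain_iterations = as.integer(chain_iterations),
                 em_tol = em_tol, em_max_iter = as.integer(em_max_iter),
                 outcome_in_model = isTRUE(outcome_in_model)),
            class = "imputer_config")
}

method_label <- function(method) {
  c(smean = "SMEAN", hd = "HD", knn = "KNN",
    mice = "MICE", pmm = "PMM", emb = "EMB")[[method]]
}

#' Impute an incomplete dataset
#'
#' Dispatches to the configured method. All methods leave observed cells
#' untouched and return completed matrices with no missing entries.
#'
#' @param inc an `incomplete_dataset` (see [ampute()]).
#' @param config an [imputer_config()].
#' @param seed integer RNG seed (used by the stochastic methods; the
#'   deterministic ones ignore it).
#' @return object of class `imputation_result`: `completed` (list of
#'   completed matrices), `method` (label), `mask`, `m`, `diagnostics`.
#' @export
impute_missing <- function(inc, config = imputer_config("smean"), seed = 1L) {
  stopifnot(inherits(inc, "incomplete_dataset"), inherits(config, "imputer_config"))
  switch(config$method,
         smean = impute_mean(inc),
         hd    = impute_hotdeck(inc),
         knn   = impute_knn(inc, config),
         mice  = impute_chained(inc, config, seed, matching = FALSE),
         pmm   = impute_chained(inc, config, seed, matching = TRUE),
         emb   = impute_emb(inc, config, seed))
}

#' @export
print.imputation_result <- function(x, ...) {
  cat(sprintf("%s imputation: %d completed dataset%s, %d cells imputed\n",
              x$method, x$m, if (x$m > 1) "s" else "", sum(x$mask)))
  invisible(x)
}

new_imputation_result <- function(completed, method, inc, diagnostics = NULL) {
  structure(list(completed = completed, method = method_label(method),
                 mask = inc$mask, m = length(completed),
                 diagnostics = diagnostics),
            class = "imputation_result")
}

# Split an incomplete dataset into the pieces every imputer needs.
impute_parts <- function(inc) {
  oc <- inc$source$spec$outcome_index
  pred_idx <- setdiff(seq_len(ncol(inc$values)), oc)
  list(values = inc$values, mask = inc$mask, oc = oc, pred_idx = pred_idx,
       pred = inc$values[, pred_idx, drop = FALSE], n = nrow(inc$values))
}

put_pred <- function(values, pred, pred_idx) {
  values[, pred_idx] <- pred
  values
}

# Group rows by missingness pattern; returns list of (rows, miss, obs) over
# predictor indices, skipping the fully observed group unless keep_complete.
pattern_groups <- function(mask, keep_complete = FALSE) {
  key <- as.vector(mask %*% 2^(seq_len(ncol(mask)) - 1))
  out <- list()
  for (k in unique(key)) {
    rows <- which(key == k)
    miss <- which(mask[rows[1], ])
    if (length(miss) == 0L && !keep_complete) next
    out[[length(out) + 1L]] <- list(rows = rows, miss = miss,
                                    obs = which(!mask[rows[1], ]))
  }
  out
}

## ---- series mean ----------------------------------------------------------

#' @describeIn impute_missing series-mean imputation: each missing cell is
#'   replaced by its variable's mean over observed values.
#' @export
impute_mean <- function(inc) {
  p <- impute_parts(inc)
  pred <- p$pred
  for (k in seq_len(ncol(pred))) {
    mis <- p$mask[, k]
    if (!any(mis)) next
    obs <- pred[!mis, k]
    if (length(obs) == 0L) stop_param("variable ", k, " has no observed values")
    pred[mis, k] <- mean(obs)
  }
  new_imputation_result(list(put_pred(p$values, pred, p$pred_idx)), "smean", inc)
}

## ---- hot deck -------------------------------------------------------------

# Nearest-donor hot deck under the maximum-deviation metric
# D(i, j) = max_k |z_ik - z_jk| on predictors standardized to the observed
# mean and SD, so deviations are comparable across scales. The donor with
# minimal D supplies all of the recipient's missing values; ties go to the
# lowest row index.

#' @describeIn impute_missing hot-deck imputation by minimal maximum
#'   standardized deviation.
#' @export
impute_hotdeck <- function(inc) {
  p <- impute_parts(inc)
  pred <- p$pred
  np <- ncol(pred)
  mu <- colMeans(pred, na.rm = TRUE)
  sd_ <- apply(pred, 2, stats::sd, na.rm = TRUE)
  sd_[!is.finite(sd_) | sd_ <= 0] <- 1
  z <- sweep(sweep(pred, 2, mu), 2, sd_, "/")
  donor_of <- rep(NA_integer_, p$n)

  for (g in pattern_groups(p$mask)) {
    # strict donors: observed on everything the recipient is missing AND on
    # every matching variable; with the default patterns these are the
    # complete rows
    need <- c(g$miss, g$obs)
    strict <- which(rowSums(p$mask[, need, drop = FALSE]) == 0L)
    donors <- strict
    if (length(donors) == 0L) {
      # fallback: donors observed on the missing variables, matched on
      # whatever observed variables they share with the recipient
      donors <- setdiff(which(rowSums(p$mask[, g$miss, drop = FALSE]) == 0L),
                        g$rows)
    }
    if (length(donors) == 0L) stop_param("no eligible hot-deck donor for a pattern")
    D <- matrix(-Inf, length(g$rows), length(donors))
    for (v in g$obs) {
      dv <- abs(outer(z[g$rows, v], z[donors, v], "-"))
      dv[is.na(dv)] <- -Inf                 # donor missing this matching var
      D <- pmax(D, dv)
    }
    D[!is.finite(D) & D < 0] <- Inf         # donors sharing no observed var
    best <- donors[max.col(-D, ties.method = "first")]
    pred[g$rows, g$miss] <- pred[best, g$miss, drop = FALSE]
    donor_of[g$rows] <- best
  }
  new_imputation_result(list(put_pred(p$values, pred, p$pred_idx)), "hd", inc,
                        diagnostics = list(donor = donor_of))
}

## ---- k-nearest neighbour --------------------------------------------------

# KNN distance: D_ij = sum_k w_k tau_ijk / sum_k w_k with
# tau_ijk = |x_ik - x_jk| / r_k, the absolute deviation scaled by the
# variable's observed range, summed over variables observed in both rows.

#' @describeIn impute_missing k-nearest-neighbour imputation with
#'   range-normalized weighted distances; the imputed value is the unweighted
#'   mean of the k nearest donors' values.
#' @export
impute_knn <- function(inc, config = imputer_config("knn")) {
  p <- impute_parts(inc)
  orig <- p$pred                             # distances use original cells only
  pred <- p$pred
  np <- ncol(orig)
  w <- config$knn_weights %||% rep(1, np)
  if (length(w) != np || any(w < 0)) {
    stop_param("`knn_weights` must be ", np, " non-negative values")
  }
  rng <- apply(orig, 2, function(x) diff(range(x, na.rm = TRUE)))
  bad <- !is.finite(rng) | rng <= 0
  if (any(bad & w > 0)) {
    warning("dropping zero-range variable(s) from KNN distances: ",
            paste(colnames(orig)[bad], collapse = ", "))
    w[bad] <- 0
  }
  donor_idx <- list()

  for (g in pattern_groups(p$mask)) {
    for (t in g$miss) {
      donors <- which(!p$mask[, t])
      if (length(donors) == 0L) stop_param("no observed donor values for variable ", t)
      num <- matrix(0, length(g$rows), length(donors))
      den <- matrix(0, length(g$rows), length(donors))
      for (v in g$obs) {
        if (w[v] <= 0) next
        dv <- abs(outer(orig[g$rows, v], orig[donors, v], "-")) / rng[v]
        ok <- !is.na(dv)
        dv[!ok] <- 0
        num <- num + w[v] * dv
        den <- den + w[v] * ok
      }
      D <- ifelse(den > 0, num / den, Inf)
      k <- min(config$k_neighbours, length(donors))
      vals <- matrix(0, length(g$rows), k)
      sel <- matrix(NA_integer_, length(g$rows), k)
      for (j in seq_len(k)) {
        a <- max.col(-D, ties.method = "first")
        sel[, j] <- donors[a]
        vals[, j] <- orig[donors[a], t]
        D[cbind(seq_along(g$rows), a)] <- Inf
      }
      pred[g$rows, t] <- rowMeans(vals)
      donor_idx[[length(donor_idx) + 1L]] <-
        list(variable = t, rows = g$rows, donors = sel)
    }
  }
  new_imputation_result(list(put_pred(p$values, pred, p$pred_idx)), "knn", inc,
                        diagnostics = list(donors = donor_idx))
}

## ---- chained equations (MICE and PMM) -------------------------------------

# Draw from the posterior of a normal linear regression with the standard
# noninformative prior: sigma^2* = RSS / chi^2_{n-q}, beta* ~ N(betahat,
# sigma^2* (X'X)^-1). Singular designs get a small ridge on the diagonal.
bayes_lm_draw <- function(X, y, ridge = 1e-5) {
  q <- ncol(X)
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  ch <- tryCatch(chol(XtX), error = function(e) NULL)
  if (is.null(ch)) {
    warning("singular conditional-model design; applying ridge inflation")
    XtX <- XtX + diag(ridge * pmax(diag(XtX), 1), q)
    ch <- chol(XtX)
  }
  betahat <- backsolve(ch, forwardsolve(t(ch), Xty))
  resid <- y - X %*% betahat
  df <- max(length(y) - q, 1L)
  sigma2 <- sum(resid^2) / stats::rchisq(1L, df)
  # chol of (X'X)^-1 via the inverse of the upper factor
  Rinv <- backsolve(ch, diag(q))
  betastar <- betahat + Rinv %*% stats::rnorm(q) * sqrt(sigma2)
  list(betahat = betahat, betastar = betastar, sigma = sqrt(sigma2))
}

# For each recipient predictive mean, indices (into yhat_obs) of the `pool`
# nearest donors, ties broken by lowest donor position. Vectorized via a
# sorted candidate window of `pool` donors on each side.
pmm_match <- function(yhat_obs, yhat_mis, pool) {
  n_obs <- length(yhat_obs)
  n_mis <- length(yhat_mis)
  pool <- min(pool, n_obs)
  o <- order(yhat_obs, seq_len(n_obs))
  ys <- yhat_obs[o]
  pos <- findInterval(yhat_mis, ys)
  offs <- seq.int(-pool + 1L, pool)
  C <- outer(pos, offs, "+")
  C[C < 1L] <- 1L
  C[C > n_obs] <- n_obs
  D <- abs(matrix(ys[C], n_mis) - yhat_mis)
  # clamping duplicates edge candidates; keep only the first copy of each
  dup <- matrix(C, n_mis)
  dup[, -1][dup[, -1] == dup[, -ncol(dup)]] <- NA
  D[is.na(dup)] <- Inf
  sel <- matrix(NA_integer_, n_mis, pool)
  idx <- seq_len(n_mis)
  for (j in seq_len(pool)) {
    a <- max.col(-D, ties.method = "first")
    sel[, j] <- o[C[cbind(idx, a)]]
    D[cbind(idx, a)] <- Inf
  }
  sel
}

impute_chained <- function(inc, config, seed, matching) {
  p <- impute_parts(inc)
  any_mis <- which(colSums(p$mask) > 0L)
  completed <- vector("list", config$m_imputations)
  oc_col <- if (config$outcome_in_model) p$values[, p$oc] else NULL

  for (imp in seq_len(config$m_imputations)) {
    set.seed(derive_seed(seed, 101L, imp))
    pred <- p$pred
    # initialize missing cells by random draws from the observed values
    for (k in any_mis) {
      mis <- p$mask[, k]
      obs <- pred[!mis, k]
      if (length(obs) == 0L) stop_param("variable ", k, " has no observed values")
      pred[mis, k] <- sample(obs, sum(mis), replace = TRUE)
    }
    n_sweeps <- if (length(any_mis) > 0L) config$chain_iterations else 0L
    for (it in seq_len(n_sweeps)) {
      for (k in any_mis) {
        mis <- p$mask[, k]
        X <- cbind(1, pred[, -k, drop = FALSE], oc_col)
        draw <- bayes_lm_draw(X[!mis, , drop = FALSE], pred[!mis, k])
        if (matching) {
          # Type-1 matching: least-squares means for donors, posterior-draw
          # means for recipients; donor drawn uniformly from the pool
          yhat_obs <- as.numeric(X[!mis, , drop = FALSE] %*% draw$betahat)
          yhat_mis <- as.numeric(X[mis, , drop = FALSE] %*% draw$betastar)
          sel <- pmm_match(yhat_obs, yhat_mis, config$donor_pool)
          pick <- sel[cbind(seq_len(nrow(sel)),
                            sample.int(ncol(sel), nrow(sel), replace = TRUE))]
          pred[mis, k] <- pred[!mis, k][pick]
        } else {
          mu_mis <- as.numeric(X[mis, , drop = FALSE] %*% draw$betastar)
          pred[mis, k] <- mu_mis + stats::rnorm(sum(mis)) * draw$sigma
        }
      }
    }
    completed[[imp]] <- put_pred(p$values, pred, p$pred_idx)
  }
  new_imputation_result(completed, if (matching) "pmm" else "mice", inc)
}

## ---- EM for the incomplete multivariate normal ----------------------------

#' Maximum-likelihood multivariate-normal parameters from incomplete data
#'
#' Standard EM: the E-step fills in conditional expectations of the missing
#' cells (and their second moments) given the observed cells under the
#' current `(mu, Sigma)`; the M-step re-estimates `(mu, Sigma)` from the
#' completed sufficient statistics. The observed-data log-likelihood is
#' non-decreasing across iterations; convergence is declared when its
#' relative change falls below `em_tol`.
#'
#' @param inc an `incomplete_dataset`, or a numeric matrix with `NA`s.
#' @param em_tol relative log-likelihood tolerance (default 1e-6).
#' @param em_max_iter iteration cap (default 500); non-convergence warns and
#'   returns the trace.
#' @return list with `mu`, `sigma` (maximum-likelihood, divisor n),
#'   `loglik_trace`, `iterations`, `converged`.
#' @export
em_mvnorm <- function(inc, em_tol = 1e-6, em_max_iter = 500L) {
  X <- if (inherits(inc, "incomplete_dataset")) inc$values else as.matrix(inc)
  n <- nrow(X); pdim <- ncol(X)
  if (n <= pdim) stop_param("need more rows than variables")
  miss <- is.na(X)
  key <- as.vector(miss %*% 2^(seq_len(pdim) - 1))
  groups <- lapply(unique(key), function(k) {
    rows <- which(key == k)
    list(rows = rows, m = which(miss[rows[1], ]), o = which(!miss[rows[1], ]))
  })
  if (any(vapply(groups, function(g) length(g$o) == 0L, TRUE))) {
    stop_param("rows with every variable missing cannot be handled")
  }

  mu <- colMeans(X, na.rm = TRUE)
  cc <- stats::complete.cases(X)
  if (sum(cc) >= pdim + 2L) {
    sigma <- stats::cov(X[cc, , drop = FALSE]) * (sum(cc) - 1) / sum(cc)
    sigma <- repair_spd(sigma)$sigma
  } else {
    v <- apply(X, 2, stats::var, na.rm = TRUE)
    v[!is.finite(v) | v <= 0] <- 1
    sigma <- diag(v, pdim)
  }

  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < em_max_iter) {
    iter <- iter + 1L
    T1 <- numeric(pdim)
    T2 <- matrix(0, pdim, pdim)
    ll <- 0
    for (g in groups) {
      Xg <- X[g$rows, , drop = FALSE]
      o <- g$o; m <- g$m
      ng <- length(g$rows)
      cho <- safe_chol(sigma[o, o, drop = FALSE])
      dev <- sweep(Xg[, o, drop = FALSE], 2, mu[o])
      sol <- forwardsolve(t(cho), t(dev))       # |o| x ng
      ll <- ll - 0.5 * (ng * (length(o) * log(2 * pi) +
                                2 * sum(log(diag(cho)))) + sum(sol^2))
      if (length(m) > 0L) {
        B <- backsolve(cho, forwardsolve(t(cho), sigma[o, m, drop = FALSE]))
        Xg[, m] <- sweep(dev %*% B, 2, mu[m], "+")
        Cm <- sigma[m, m, drop = FALSE] - sigma[m, o, drop = FALSE] %*% B
        T2[m, m] <- T2[m, m] + ng * Cm
      }
      T1 <- T1 + colSums(Xg)
      T2 <- T2 + crossprod(Xg)
    }
    trace <- c(trace, ll)
    if (iter > 1L) {
      prev <- trace[iter - 1L]
      if (abs(ll - prev) < em_tol * (abs(prev) + em_tol)) {
        converged <- TRUE
        break
      }
    }
    mu <- T1 / n
    sigma_new <- T2 / n - tcrossprod(mu)
    rep_ <- repair_spd(sigma_new)
    if (rep_$repaired) warning("EM covariance update repaired to positive definite")
    sigma <- rep_$sigma
  }
  if (!converged) warning("EM did not converge within ", em_max_iter, " iterations")
  names(mu) <- colnames(X)
  dimnames(sigma) <- list(colnames(X), colnames(X))
  list(mu = mu, sigma = sigma, loglik_trace = trace,
       iterations = iter, converged = converged)
}

# Draw missing cells of X from their conditional normal given the observed
# cells under (mu, sigma).
conditional_draw <- function(X, mu, sigma) {
  miss <- is.na(X)
  if (!any(miss)) return(X)
  key <- as.vector(miss %*% 2^(seq_len(ncol(X)) - 1))
  for (k in setdiff(unique(key), 0)) {
    rows <- which(key == k)
    m <- which(miss[rows[1], ]); o <- which(!miss[rows[1], ])
    cho <- safe_chol(sigma[o, o, drop = FALSE])
    B <- backsolve(cho, forwardsolve(t(cho), sigma[o, m, drop = FALSE]))
    dev <- sweep(X[rows, o, drop = FALSE], 2, mu[o])
    cmean <- sweep(dev %*% B, 2, mu[m], "+")
    Cm <- sigma[m, m, drop = FALSE] - sigma[m, o, drop = FALSE] %*% B
    Lc <- safe_chol(Cm)
    z <- matrix(stats::rnorm(length(rows) * length(m)), length(rows))
    X[rows, m] <- cmean + z %*% Lc
  }
  X
}

#' @describeIn impute_missing bootstrap-EM multiple imputation: M bootstrap
#'   resamples of the incomplete rows each get their own EM parameter
#'   estimates, and the original missing cells are drawn from the conditional
#'   normal under each estimate, propagating parameter uncertainty.
#' @export
impute_emb <- function(inc, config = imputer_config("emb"), seed = 1L) {
  p <- impute_parts(inc)
  M <- config$m_imputations
  completed <- vector("list", M)
  fits <- vector("list", M)
  for (b in seq_len(M)) {
    set.seed(derive_seed(seed, 202L, b))
    fit <- NULL
    for (attempt in seq_len(10L)) {
      idx <- sample.int(p$n, p$n, replace = TRUE)
      Xb <- p$values[idx, , drop = FALSE]
      n_distinct <- apply(Xb, 2, function(x) length(unique(x[!is.na(x)])))
      if (any(n_distinct < 2L)) next
      fit <- em_mvnorm(Xb, em_tol = config$em_tol,
                       em_max_iter = config$em_max_iter)
      break
    }
    if (is.null(fit)) stop_param("could not draw a non-degenerate bootstrap resample")
    completed[[b]] <- conditional_draw(p$values, fit$mu, fit$sigma)
    fits[[b]] <- fit[c("mu", "iterations", "converged")]
  }
  new_imputation_result(completed, "emb", inc, diagnostics = list(fits = fits))
}
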