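# Orchestration of the full simulation grid: missingness percentage x
# mechanism x imputer, each evaluated with all classifiers, replicated, and
# aggregated into the study's three result tables (mean RMSE, BLR AUC,
# classification accuracy).

default_imputers <- function() {
  lapply(c("smean", "hd", "knn", "mice", "pmm", "emb"), imputer_config)
}

#' Configure a simulation grid
#'
#' The default grid is 4 missingness percentages x 2 mechanisms x 6 imputers
#' = 48 conditions, each classified with BLR, LDA and QDA.
#'
#' @param sim a [simulation_spec()].
#' @param percentages missingness proportions (default 0.15, 0.30, 0.45, 0.60).
#' @param mechanisms subset of `c("MCAR", "MAR")`.
#' @param imputers list of [imputer_config()]s (default all six methods).
#' @param classifiers subset of `c("blr", "lda", "qda")`.
#' @param split a [split_spec()].
#' @param replicates independent replicates per condition (default 100;
#'   use 1 to mimic a single-realization study).
#' @param master_seed integer; every RNG stream in the run derives from it.
#' @return object of class `grid_config`.
#' @export
grid_config <- function(sim = simulation_spec(),
                        percentages = c(0.15, 0.30, 0.45, 0.60),
                        mechanisms = c("MCAR", "MAR"),
                        imputers = default_imputers(),
                        classifiers = c("blr", "lda", "qda"),
                        split = split_spec(),
                        replicates = 100L,
                        master_seed = 1L) {
  if (any(percentages <= 0 | percentages >= 1)) {
    stop_param("`percentages` must lie strictly in (0, 1)")
  }
  mechanisms <- match.arg(mechanisms, c("MCAR", "MAR"), several.ok = TRUE)
  classifiers <- match.arg(classifiers, c("blr", "lda", "qda"), several.ok = TRUE)
  replicates <- as.integer(replicates)
  if (replicates < 1L) stop_param("`replicates` must be >= 1")
  stopifnot(inherits(sim, "simulation_spec"), inherits(split, "split_spec"),
            all(vapply(imputers, inherits, TRUE, "imputer_config")))
  structure(list(sim = sim, percentages = percentages, mechanisms = mechanisms,
                 imputers = imputers, classifiers = classifiers, split = split,
                 replicates = replicates, master_seed = as.integer(master_seed)),
            class = "grid_config")
}

# Fit every classifier on each completed dataset's train rows, average the m
# predicted test probabilities (multiple-imputation pooling), threshold at
# the cut-off, and score accuracy/AUC on the test outcome.
classify_completions <- function(completed, outcome, split_idx, classifiers,
                                 outcome_index, cutoff = 0.5) {
  y_tr <- outcome[split_idx$train]
  y_te <- outcome[split_idx$test]
  out <- list()
  for (clf in classifiers) {
    probs <- 0
    for (comp in completed) {
      x <- comp[, -outcome_index, drop = FALSE]
      x_tr <- x[split_idx$train, , drop = FALSE]
      x_te <- x[split_idx$test, , drop = FALSE]
      pr <- if (clf == "blr") {
        predict(fit_blr(x_tr, y_tr, cutoff = cutoff), x_te)$prob
      } else {
        predict(fit_discriminant(x_tr, y_tr, kind = clf), x_te)$prob
      }
      probs <- probs + pr
    }
    probs <- probs / length(completed)
    out[[clf]] <- list(prob = probs,
                       class = as.numeric(probs > cutoff),
                       accuracy = classification_accuracy(
                         as.numeric(probs > cutoff), y_te),
                       auc = roc_auc(probs, y_te))
  }
  out
}

#' Run one grid condition on a given complete dataset
#'
#' Amputes, imputes, scores imputation RMSE against the truth, then fits and
#' evaluates each classifier on a stratified train/test split with
#' multiple-imputation pooling of predicted probabilities. Fully determined
#' by `seed`.
#'
#' @param truth a `complete_dataset`.
#' @param pct missingness proportion in `[0, 1)`.
#' @param mechanism `"MCAR"` or `"MAR"`.
#' @param imputer_cfg an [imputer_config()].
#' @param classifiers character vector of classifiers to evaluate.
#' @param split a [split_spec()].
#' @param seed integer; amputation, imputation and split seeds derive from it.
#' @return data.frame with one row per classifier: missing_pct, mechanism,
#'   imputer, classifier, rmse_pooled, rmse_per_missing, accuracy, auc,
#'   n_missing_cells.
#' @export
run_condition <- function(truth, pct, mechanism, imputer_cfg,
                          classifiers = c("blr", "lda", "qda"),
                          split = split_spec(), seed = 1L) {
  amp_seed <- derive_seed(seed, 1L)
  imp_seed <- derive_seed(seed, 2L)
  split_seed <- derive_seed(seed, 3L)
  inc <- ampute(truth, ampute_spec(mechanism, pct), seed = amp_seed)
  res <- impute_missing(inc, imputer_cfg, seed = imp_seed)
  rm_ <- imputation_rmse(truth, res$completed, inc$mask)
  split_idx <- split_train_test(truth$outcome, split, seed = split_seed)
  scored <- classify_completions(res$completed, truth$outcome, split_idx,
                                 classifiers, truth$spec$outcome_index)
  data.frame(missing_pct = pct, mechanism = mechanism, imputer = res$method,
             classifier = toupper(classifiers),
             rmse_pooled = rm_$rmse_pooled,
             rmse_per_missing = rm_$rmse_per_missing,
             accuracy = unname(vapply(scored, `[[`, 0, "accuracy")[classifiers]),
             auc = unname(vapply(scored, `[[`, 0, "auc")[classifiers]),
             n_missing_cells = rm_$n_missing_cells,
             row.names = NULL)
}

#' Run the full simulation grid
#'
#' For each replicate a fresh complete dataset is generated and shared by
#' every condition (so comparisons across imputers and mechanisms are
#' paired); the amputation of a given (percentage, mechanism) cell is also
#' shared across imputers within a replicate. Child seeds derive
#' deterministically from `master_seed`, so condition results do not depend
#' on the order in which conditions are run.
#'
#' @param cfg a [grid_config()].
#' @param verbose print a progress line per replicate (default `FALSE`).
#' @return object of class `imputation_grid`: `results` (long per-replicate
#'   data.frame), `conditions` (replicate-averaged means and standard
#'   errors), `tables` (wide analogues of the study's three tables), and
#'   `config`.
#' @export
run_grid <- function(cfg = grid_config(), verbose = FALSE) {
  stopifnot(inherits(cfg, "grid_config"))
  rows <- vector("list", 0L)
  for (rep_i in seq_len(cfg$replicates)) {
    truth <- generate_complete(cfg$sim, seed = derive_seed(cfg$master_seed, rep_i, 0L))
    split_seed <- derive_seed(cfg$master_seed, rep_i, 1L)
    split_idx <- split_train_test(truth$outcome, cfg$split, seed = split_seed)
    for (pct in cfg$percentages) {
      for (mech in cfg$mechanisms) {
        # seeds keyed by condition value, not loop position, so results do
        # not depend on the order conditions are listed or run
        p_id <- as.integer(round(1000 * pct))
        m_id <- match(mech, c("MCAR", "MAR"))
        amp_seed <- derive_seed(cfg$master_seed, rep_i, 2L, p_id, m_id)
        inc <- ampute(truth, ampute_spec(mech, pct), seed = amp_seed)
        for (icfg in cfg$imputers) {
          i_id <- match(icfg$method, c("smean", "hd", "knn", "mice", "pmm", "emb"))
          imp_seed <- derive_seed(cfg$master_seed, rep_i, 3L, p_id, m_id, i_id)
          res <- impute_missing(inc, icfg, seed = imp_seed)
          rm_ <- imputation_rmse(truth, res$completed, inc$mask)
          scored <- classify_completions(res$completed, truth$outcome,
                                         split_idx, cfg$classifiers,
                                         truth$spec$outcome_index)
          rows[[length(rows) + 1L]] <- data.frame(
            replicate = rep_i, missing_pct = pct, mechanism = mech,
            imputer = res$method, classifier = toupper(cfg$classifiers),
            rmse_pooled = rm_$rmse_pooled,
            rmse_per_missing = rm_$rmse_per_missing,
            accuracy = unname(vapply(scored, `[[`, 0, "accuracy")[cfg$classifiers]),
            auc = unname(vapply(scored, `[[`, 0, "auc")[cfg$classifiers]),
            n_missing_cells = rm_$n_missing_cells,
            row.names = NULL)
        }
      }
    }
    if (verbose) {
      message(sprintf("replicate %d/%d done", rep_i, cfg$replicates))
    }
  }
  results <- do.call(rbind, rows)
  structure(list(results = results,
                 conditions = aggregate_conditions(results),
                 tables = result_tables(results),
                 config = cfg),
            class = "imputation_grid")
}

aggregate_conditions <- function(results) {
  key <- c("missing_pct", "mechanism", "imputer", "classifier")
  se <- function(x) stats::sd(x) / sqrt(length(x))
  means <- stats::aggregate(results[c("rmse_pooled", "rmse_per_missing",
                                      "accuracy", "auc")],
                            results[key], mean)
  ses <- stats::aggregate(results[c("rmse_pooled", "accuracy", "auc")],
                          results[key], se)
  names(ses)[-(1:4)] <- paste0(names(ses)[-(1:4)], "_se")
  out <- merge(means, ses, by = key)
  out$n_replicates <- max(results$replicate)
  out[order(out$mechanism, out$missing_pct, out$imputer, out$classifier), ]
}

wide_by_imputer <- function(df, value) {
  out <- stats::reshape(df[c("missing_pct", "mechanism", "imputer", value)],
                        idvar = c("mechanism", "missing_pct"),
                        timevar = "imputer", direction = "wide")
  names(out) <- sub(paste0("^", value, "\\."), "", names(out))
  rownames(out) <- NULL
  out[order(out$mechanism, out$missing_pct), ]
}

#' Replicate-averaged wide tables of the three study metrics
#'
#' @param results long per-replicate data.frame from [run_grid()].
#' @return list with `rmse` (mean pooled RMSE by missingness and imputer,
#'   one block per mechanism), `auc_blr` (BLR AUC by imputer and condition),
#'   and `accuracy` (by imputer, classifier and condition).
#' @export
result_tables <- function(results) {
  key <- c("missing_pct", "mechanism", "imputer")
  rmse_m <- stats::aggregate(results[results$classifier == results$classifier[1],
                                     "rmse_pooled", drop = FALSE],
                             results[results$classifier == results$classifier[1], key],
                             mean)
  blr <- results[results$classifier == "BLR", , drop = FALSE]
  acc <- stats::aggregate(results["accuracy"],
                          results[c(key, "classifier")], mean)
  list(rmse = wide_by_imputer(rmse_m, "rmse_pooled"),
       auc_blr = if (nrow(blr)) {
         wide_by_imputer(stats::aggregate(blr["auc"], blr[key], mean), "auc")
       } else NULL,
       accuracy = {
         w <- stats::reshape(acc, idvar = c("mechanism", "missing_pct", "imputer"),
                             timevar = "classifier", direction = "wide")
         names(w) <- sub("^accuracy\\.", "", names(w))
         rownames(w) <- NULL
         w[order(w$mechanism, w$missing_pct, w$imputer), ]
       })
}

#' @export
print.imputation_grid <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Simulation grid: %d pct x %d mechanisms x %d imputers = %d conditions, %d replicate(s)\n",
              length(cfg$percentages), length(cfg$mechanisms),
              length(cfg$imputers),
              length(cfg$percentages) * length(cfg$mechanisms) * length(cfg$imputers),
              cfg$replicates))
  cat("\nMean pooled RMSE by condition:\n")
  print(format_table(x$tables$rmse, 2))
  if (!is.null(x$tables$auc_blr)) {
    cat("\nMean BLR AUC by condition:\n")
    print(format_table(x$tables$auc_blr, 4))
  }
  invisible(x)
}

format_table <- function(df, digits) {
  num <- vapply(df, is.numeric, TRUE) & names(df) != "missing_pct"
  df[num] <- lapply(df[num], round, digits)
  df
}

#' Summarize a simulation grid
#'
#' Reports, with replicate standard errors: the best and worst imputer by
#' mean pooled RMSE within each mechanism, the best classifier-imputer cell
#' by accuracy, and the maximum BLR AUC cell.
#'
#' @param object an `imputation_grid`.
#' @param ... unused.
#' @return list of class `imputation_grid_summary`.
#' @export
summary.imputation_grid <- function(object, ...) {
  cond <- object$conditions
  if (nrow(cond) == 0L) stop_param("empty results")
  rmse <- unique(cond[c("missing_pct", "mechanism", "imputer",
                        "rmse_pooled", "rmse_pooled_se")])
  by_mech <- lapply(split(rmse, rmse$mechanism), function(d) {
    list(best = d[which.min(d$rmse_pooled), ],
         worst = d[which.max(d$rmse_pooled), ])
  })
  best_acc <- cond[which.max(cond$accuracy), ]
  min_acc <- cond[which.min(cond$accuracy), ]
  blr <- cond[cond$classifier == "BLR", , drop = FALSE]
  max_auc <- if (nrow(blr)) blr[which.max(blr$auc), ] else NULL
  structure(list(rmse_by_mechanism = by_mech, best_accuracy = best_acc,
                 min_accuracy = min_acc, max_auc = max_auc),
            class = "imputation_grid_summary")
}

#' @export
print.imputation_grid_summary <- function(x, ...) {
  for (m in names(x$rmse_by_mechanism)) {
    b <- x$rmse_by_mechanism[[m]]$best
    w <- x$rmse_by_mechanism[[m]]$worst
    cat(sprintf("%s: best imputer by RMSE %s (%.2f +/- %.2f at %.0f%%), worst %s (%.2f +/- %.2f at %.0f%%)\n",
                m, b$imputer, b$rmse_pooled, b$rmse_pooled_se, 100 * b$missing_pct,
                w$imputer, w$rmse_pooled, w$rmse_pooled_se, 100 * w$missing_pct))
  }
  a <- x$best_accuracy
  cat(sprintf("Best accuracy: %.1f%% +/- %.1f (%s on %s, %.0f%% %s)\n",
              a$accuracy, a$accuracy_se, a$classifier, a$imputer,
              100 * a$missing_pct, a$mechanism))
  a <- x$min_accuracy
  cat(sprintf("Minimum accuracy: %.1f%% +/- %.1f (%s on %s, %.0f%% %s)\n",
              a$accuracy, a$accuracy_se, a$classifier, a$imputer,
              100 * a$missing_pct, a$mechanism))
  if (!is.null(x$max_auc)) {
    a <- x$max_auc
    cat(sprintf("Max BLR AUC: %.4f +/- %.4f (%s, %.0f%% %s)\n",
                a$auc, a$auc_se, a$imputer, 100 * a$missing_pct, a$mechanism))
  }
  invisible(x)
}

#' Plot replicate-averaged metrics against missingness percentage
#'
#' One panel per metric (pooled RMSE and BLR AUC), one line per imputer,
#' solid/dashed by mechanism.
#'
#' @param x an `imputation_grid`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.imputation_grid <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  cond <- x$conditions
  imputers <- sort(unique(cond$imputer))
  cols <- seq_along(imputers)
  for (metric in c("rmse_pooled", "auc")) {
    d <- if (metric == "auc") cond[cond$classifier == "BLR", ] else
      cond[cond$classifier == cond$classifier[1], ]
    if (nrow(d) == 0L) next
    pcts <- sort(unique(d$missing_pct))
    graphics::plot(NULL, xlim = range(pcts), ylim = range(d[[metric]]),
                   xlab = "missing fraction",
                   ylab = if (metric == "auc") "BLR AUC" else "pooled RMSE",
                   main = if (metric == "auc") "Discrimination" else "Imputation error")
    for (i in seq_along(imputers)) {
      for (m in unique(d$mechanism)) {
        dd <- d[d$imputer == imputers[i] & d$mechanism == m, ]
        dd <- dd[order(dd$missing_pct), ]
        graphics::lines(dd$missing_pct, dd[[metric]], col = cols[i],
                        lty = if (m == "MCAR") 1 else 2)
      }
    }
    graphics::legend("topleft", legend = imputers, col = cols, lty = 1,
                     cex = 0.7, bty = "n")
  }
  invisible(x)
}

#' Write grid outputs as CSV files
#'
#' Long per-replicate results plus the three wide tables, full precision.
#'
#' @param grid an `imputation_grid`.
#' @param dir output directory (created if absent).
#' @return the directory, invisibly.
#' @export
write_grid_csv <- function(grid, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(grid$results, file.path(dir, "results_long.csv"),
                   row.names = FALSE)
  utils::write.csv(grid$tables$rmse, file.path(dir, "table_rmse.csv"),
                   row.names = FALSE)
  if (!is.null(grid$tables$auc_blr)) {
    utils::write.csv(grid$tables$auc_blr, file.path(dir, "table_auc_blr.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(grid$tables$accuracy, file.path(dir, "table_accuracy.csv"),
                   row.names = FALSE)
  invisible(dir)
}
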