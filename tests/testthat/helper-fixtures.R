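# Shared fixtures: small datasets built in code at test time.

cohort_spec <- function(n = 693L) simulation_spec(n_obs = n)

small_complete <- function(n = 150L, seed = 42L) {
  generate_complete(cohort_spec(n), seed = seed)
}

# A complete dataset wrapper around an arbitrary predictor matrix + outcome,
# for toy examples where we control the values exactly.
toy_dataset <- function(pred, outcome) {
  pred <- as.matrix(pred)
  values <- cbind(pred, recurrence = outcome)
  spec <- list(n_obs = nrow(pred), outcome_index = ncol(values),
               outcome_threshold = 0.5,
               column_names = colnames(values))
  class(spec) <- "simulation_spec"
  structure(list(values = values, column_names = colnames(values),
                 outcome = outcome, spec = spec),
            class = "complete_dataset")
}

# Incomplete dataset built directly from a values matrix and mask, bypassing
# ampute(), for imputer unit tests with hand-placed missing cells.
toy_incomplete <- function(pred, outcome, mask) {
  full <- toy_dataset(pred, outcome)
  mask <- matrix(as.logical(mask), nrow(pred), ncol(pred))
  vals <- full$values
  pr <- vals[, seq_len(ncol(pred)), drop = FALSE]
  pr[mask] <- NA_real_
  vals[, seq_len(ncol(pred))] <- pr
  structure(list(values = vals, mask = mask, source = full,
                 spec = ampute_spec("MCAR", 0.1), seed = 0L),
            class = "incomplete_dataset")
}

# Random toy imputation problems for property-style loops.
random_incomplete <- function(n = 40L, p = 4L, frac = 0.2, seed = 1L) {
  set.seed(seed)
  pred <- matrix(rnorm(n * p, sd = rep(c(1, 10, 0.5, 3), length.out = p)),
                 n, p, dimnames = list(NULL, paste0("x", seq_len(p))))
  outcome <- rbinom(n, 1, 0.4)
  if (all(outcome == outcome[1])) outcome[1:2] <- c(0, 1)
  mask <- matrix(runif(n * p) < frac, n, p)
  mask[rowSums(mask) == p, 1] <- FALSE       # keep at least one observed per row
  for (k in seq_len(p)) if (all(mask[, k])) mask[1, k] <- FALSE
  toy_incomplete(pred, outcome, mask)
}
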