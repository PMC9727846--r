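# Synthetic data generation: draws from a 6-variate normal whose mean vector
# and covariance matrix summarise a breast-cancer cohort (age, heart rate,
# respiratory rate, body mass index, body surface area, recurrence), with the
# sixth variable dichotomized into the binary recurrence outcome.

#' Default variable names for the recurrence study
#' @return character vector of the six column names.
#' @export
recurrence_variables <- function() {
  c("age", "heart_rate", "respiratory_rate", "bmi", "bsa", "recurrence")
}

#' Mean vector of the breast-cancer recurrence cohort
#'
#' Summary means of age (years), heart rate (beats/min), respiratory rate
#' (breaths/min), body mass index (kg/m^2), body surface area (m^2), and the
#' latent recurrence score.
#' @return named numeric vector of length 6.
#' @export
recurrence_mu <- function() {
  stats::setNames(c(51.00, 97.89, 20.84, 27.71, 1.69, 0.31),
                  recurrence_variables())
}

#' Covariance matrix of the breast-cancer recurrence cohort
#' @return 6x6 symmetric positive definite matrix with dimnames.
#' @export
recurrence_sigma <- function() {
  s <- matrix(c(
    169.3,   1.8,   3.0,   2.0, -0.2,  0.1,
      1.8, 486.7,   9.7,  -4.7, -0.2,  1.1,
      3.0,   9.7,  37.5,  -0.5, -0.01, 0.2,
      2.0,  -4.7,  -0.5,  43.6,  0.9, -0.2,
     -0.2,  -0.2,  -0.01,  0.9,  0.1,  0.01,
      0.1,   1.1,   0.2,  -0.2,  0.01, 0.2
  ), nrow = 6, byrow = TRUE)
  dimnames(s) <- list(recurrence_variables(), recurrence_variables())
  s
}

#' Validate (and if necessary repair) a covariance matrix
#'
#' Symmetrizes by averaging with the transpose; if the smallest eigenvalue is
#' non-positive, clips all eigenvalues to a small positive floor
#' (`1e-8 *` largest eigenvalue) — the minimal eigenvalue-clipping repair in
#' Frobenius distance — and reports the repair.
#'
#' @param sigma square numeric matrix with finite entries.
#' @return list with elements `sigma` (validated matrix), `repaired`
#'   (logical), `min_eigenvalue`, and `report` (character).
#' @export
validate_covariance <- function(sigma) {
  if (!is.matrix(sigma) || nrow(sigma) != ncol(sigma)) {
    stop_param("`sigma` must be a square matrix")
  }
  if (!all(is.finite(sigma))) {
    stop_param("`sigma` must have finite entries")
  }
  asym <- max(abs(sigma - t(sigma)))
  rep_ <- repair_spd(sigma)
  report <- if (rep_$repaired) {
    sprintf("eigenvalues clipped to positive floor (max asymmetry %.3g)", asym)
  } else {
    "no repair"
  }
  list(sigma = rep_$sigma, repaired = rep_$repaired,
       min_eigenvalue = rep_$min_eigenvalue, report = report)
}

#' Specify a simulation of the recurrence cohort
#'
#' @param n_obs number of observations (default 693, the cohort size).
#' @param mu length-6 mean vector.
#' @param sigma 6x6 covariance matrix (validated, repaired if needed).
#' @param outcome_index column holding the latent outcome variable (6).
#' @param outcome_threshold dichotomization cut: a latent draw strictly above
#'   it is coded recurrence = 1. The default 0.5 gives outcome prevalence
#'   `1 - pnorm((0.5 - mu[6]) / sqrt(sigma[6, 6]))`, about 0.335 under the
#'   default parameters.
#' @param column_names names for the six variables.
#' @return object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_obs = 693L,
                            mu = recurrence_mu(),
                            sigma = recurrence_sigma(),
                            outcome_index = 6L,
                            outcome_threshold = 0.5,
                            column_names = recurrence_variables()) {
  n_obs <- as.integer(n_obs)
  if (is.na(n_obs) || n_obs < 2L) stop_param("`n_obs` must be at least 2")
  mu <- as.numeric(mu)
  p <- length(mu)
  if (!is.matrix(sigma) || !all(dim(sigma) == p)) {
    stop_param("`sigma` must be a ", p, "x", p, " matrix matching `mu`")
  }
  val <- validate_covariance(sigma)
  if (val$min_eigenvalue <= 0) stop_param("`sigma` could not be repaired to positive definite")
  if (length(column_names) != p) stop_param("`column_names` must match `mu` in length")
  structure(list(n_obs = n_obs, mu = mu, sigma = val$sigma,
                 outcome_index = as.integer(outcome_index),
                 outcome_threshold = outcome_threshold,
                 column_names = column_names,
                 covariance_report = val$report),
            class = "simulation_spec")
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat(sprintf("Simulation spec: %d obs, %d variables, outcome '%s' (> %.3g -> 1)\n",
              x$n_obs, length(x$mu), x$column_names[x$outcome_index],
              x$outcome_threshold))
  cat("Covariance check:", x$covariance_report, "\n")
  invisible(x)
}

#' Generate a complete dataset from a simulation spec
#'
#' Draws `n_obs` rows from the multivariate normal with the spec's mean and
#' covariance, then dichotomizes the outcome column at the spec's threshold.
#' The same `(spec, seed)` pair always yields an identical dataset.
#'
#' @param spec a [simulation_spec()].
#' @param seed integer RNG seed.
#' @return object of class `complete_dataset`: a list with `values`
#'   (`n_obs x 6` matrix; outcome column already binary), `column_names`,
#'   `outcome` (0/1 vector), and `spec`.
#' @export
generate_complete <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(as.integer(seed))
  x <- MASS::mvrnorm(spec$n_obs, mu = spec$mu, Sigma = spec$sigma)
  colnames(x) <- spec$column_names
  oc <- spec$outcome_index
  outcome <- as.numeric(x[, oc] > spec$outcome_threshold)
  x[, oc] <- outcome
  structure(list(values = x, column_names = spec$column_names,
                 outcome = outcome, spec = spec, seed = as.integer(seed)),
            class = "complete_dataset")
}

#' @export
print.complete_dataset <- function(x, ...) {
  cat(sprintf("Complete dataset: %d x %d, outcome prevalence %.3f\n",
              nrow(x$values), ncol(x$values), mean(x$outcome)))
  invisible(x)
}

predictor_matrix <- function(data) {
  oc <- data$spec$outcome_index %||% ncol(data$values)
  data$values[, -oc, drop = FALSE]
}

#' Write a dataset to CSV
#'
#' Plain UTF-8 CSV with a header row; missing cells are written as empty
#' fields so that incomplete datasets round-trip.
#'
#' @param data a `complete_dataset`, `incomplete_dataset`, or numeric matrix.
#' @param path output file path.
#' @export
write_dataset_csv <- function(data, path) {
  values <- if (is.matrix(data)) data else data$values
  utils::write.table(values, path, sep = ",", na = "", row.names = FALSE,
                     col.names = TRUE, qmethod = "double")
  invisible(path)
}

#' Read a dataset written by [write_dataset_csv()]
#'
#' @param path CSV path; empty fields become `NA`.
#' @return numeric matrix with column names.
#' @export
read_dataset_csv <- function(path) {
  df <- utils::read.csv(path, header = TRUE,
                        na.strings = "", check.names = FALSE)
  as.matrix(df)
}
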