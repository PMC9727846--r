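# Internal helpers shared across modules.

#' Derive a child seed from a master seed and an index path
#'
#' Deterministic integer hash so that every (replicate, condition, stage)
#' combination gets its own reproducible RNG stream. Results stay strictly
#' below 2^31 - 1 so they are valid R integer seeds.
#'
#' @param master integer master seed.
#' @param ... integer indices identifying the stream (replicate, condition,
#'   stage, ...).
#' @return a single integer seed.
#' @export
derive_seed <- function(master, ...) {
  idx <- c(...)
  s <- as.double(master) %% 2147483647
  for (k in idx) {
    # LCG-style mixing; doubles are exact well beyond 69069 * 2^31
    s <- (s * 69069 + as.double(k) + 1) %% 2147483647
  }
  as.integer(s)
}

# Eigenvalue-floor repair for symmetric matrices that should be positive
# definite. Returns the repaired matrix plus a flag; floor is relative to the
# largest eigenvalue.
repair_spd <- function(sigma, floor_frac = 1e-8) {
  sigma <- (sigma + t(sigma)) / 2
  ev <- eigen(sigma, symmetric = TRUE)
  if (min(ev$values) > 0) {
    return(list(sigma = sigma, repaired = FALSE, min_eigenvalue = min(ev$values)))
  }
  floor_val <- floor_frac * max(ev$values)
  vals <- pmax(ev$values, floor_val)
  out <- ev$vectors %*% (vals * t(ev$vectors))
  out <- (out + t(out)) / 2
  list(sigma = out, repaired = TRUE, min_eigenvalue = min(vals))
}

# Cholesky with escalating safeguards: plain chol, then an eigenvalue-floor
# repair, then growing diagonal jitter. Degenerate matrices arise routinely
# in bootstrap resamples of small incomplete datasets.
safe_chol <- function(A) {
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (!is.null(ch)) return(ch)
  A <- repair_spd(A, floor_frac = 1e-6)$sigma
  scale_ <- mean(diag(A))
  for (jit in c(0, 1e-8, 1e-6, 1e-4) * max(scale_, 1e-12)) {
    ch <- tryCatch(chol(A + diag(jit, nrow(A))), error = function(e) NULL)
    if (!is.null(ch)) return(ch)
  }
  stop_param("matrix could not be made positive definite")
}

# Solve a symmetric positive definite system, falling back to an
# eigenvalue-floor repair when the Cholesky fails.
solve_spd <- function(A, b) {
  ch <- safe_chol(A)
  backsolve(ch, forwardsolve(t(ch), b))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_param <- function(...) stop(..., call. = FALSE)
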