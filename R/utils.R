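#' @keywords internal
"_PACKAGE"

# Classed error helper so callers can distinguish failure modes
# (grid mismatch, non-convergence, insufficient design, ...) without
# parsing message text.
abort <- function(message, class, ...) {
  stop(errorCondition(message, ..., class = c(class, "cyclofit_error")))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

check_positive_scalar <- function(x, name) {
  if (!is_scalar_number(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive finite number", name),
          "cyclofit_validation_error")
  }
  invisible(x)
}

# Deterministic child-seed derivation: mixes a master seed with small
# integer indices through fixed primes, reduced mod 2^31 - 1 so the
# result is always a valid 32-bit seed. Documented so any single trace
# or titration can be regenerated in isolation.
child_seed <- function(master_seed, ...) {
  idx <- c(...)
  s <- as.double(master_seed)
  primes <- c(7919, 104729, 1299709, 15485863)
  for (i in seq_along(idx)) {
    s <- (s * 31 + as.double(idx[i]) * primes[((i - 1L) %% 4L) + 1L]) %%
      2147483647
  }
  as.integer(s %% 2147483647)
}

# Evaluate code under a temporary RNG state so library functions that
# draw random numbers do not perturb the caller's stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Gas constant in kJ mol-1 K-1
#'
#' Universal gas constant on the kJ scale used throughout the two-state
#' unfolding model.
#' @keywords internal
R_GAS_KJ <- 8.314e-3
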