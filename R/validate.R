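# Internal validation helpers. Validation failures signal a condition of
# class "pupildyn_validation_error" so callers (and the CLI, which maps it
# to exit status 2) can distinguish bad input from programming errors.

stop_validation <- function(..., call. = FALSE) {
  msg <- paste0(...)
  cond <- structure(
    class = c("pupildyn_validation_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  )
  stop(cond)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_validation(name, " must be a single non-missing number")
  }
  if (x < lower || x > upper) {
    stop_validation(name, " must be in [", lower, ", ", upper, "], got ", x)
  }
  invisible(x)
}

assert_count <- function(x, name, min = 0L) {
  assert_scalar_number(x, name, lower = min)
  if (x != round(x)) stop_validation(name, " must be an integer, got ", x)
  invisible(as.integer(x))
}

# Row-stochastic matrix check; names the offending row in the error.
assert_stochastic <- function(m, name, n_states, tol = 1e-9) {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop_validation(name, " must be a numeric matrix")
  }
  if (nrow(m) != n_states || ncol(m) != n_states) {
    stop_validation(name, " must be ", n_states, "x", n_states,
                    ", got ", nrow(m), "x", ncol(m))
  }
  if (any(is.na(m)) || any(m < 0) || any(m > 1)) {
    stop_validation(name, " entries must all lie in [0, 1]")
  }
  rs <- rowSums(m)
  bad <- which(abs(rs - 1) > tol)
  if (length(bad)) {
    stop_validation(name, " is not row-stochastic: row ", bad[1],
                    " sums to ", format(rs[bad[1]], digits = 12))
  }
  invisible(m)
}

assert_distribution <- function(p, name, n_states, tol = 1e-9) {
  if (!is.numeric(p) || length(p) != n_states) {
    stop_validation(name, " must be a numeric vector of length ", n_states)
  }
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop_validation(name, " entries must all lie in [0, 1]")
  }
  if (abs(sum(p) - 1) > tol) {
    stop_validation(name, " must sum to 1, sums to ",
                    format(sum(p), digits = 12))
  }
  invisible(p)
}
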