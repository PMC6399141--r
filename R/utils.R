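# Small internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Classed errors so callers/tests can dispatch on failure mode.
te_stop <- function(class, msg, call. = FALSE) {
  stop(structure(
    class = c(class, "tankecgi_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

te_warn <- function(class, msg) {
  warning(structure(
    class = c(class, "tankecgi_warning", "warning", "condition"),
    list(message = msg, call = NULL)
  ))
}

vnorm <- function(x) sqrt(sum(x^2))

row_norms <- function(m) sqrt(rowSums(m^2))

normalize_rows <- function(m) m / pmax(row_norms(m), .Machine$double.eps)

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Row-wise cross product for n x 3 matrices.
cross3_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Derive a reproducible child seed (kept below 2^31; double arithmetic is
# exact here, integer would overflow)
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k)) %% 2147480009)
}
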