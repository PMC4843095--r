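# Internal helpers shared across modules.

# Gauss-Hermite nodes/weights (physicists' convention, weight e^{-x^2})
# via Golub-Welsch on the Jacobi matrix of the Hermite recurrence.
gauss_hermite <- function(n) {
  stopifnot(n >= 1)
  if (n == 1L) return(list(x = 0, w = sqrt(pi)))
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- sqrt(i / 2)
  J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(x = e$values[ord], w = sqrt(pi) * e$vectors[1, ord]^2)
}

.gh_cache <- new.env(parent = emptyenv())

gh_rule <- function(n) {
  key <- as.character(n)
  if (is.null(.gh_cache[[key]])) .gh_cache[[key]] <- gauss_hermite(n)
  .gh_cache[[key]]
}

# fail with a consistent condition class so callers/tests can target it
abort_validation <- function(msg) {
  stop(structure(class = c("rootheat_validation_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort_validation(msg)
  invisible(TRUE)
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min &&
    x == round(x)
}

is_prop <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

# deterministic child seeds below 2^31 derived from a master seed
derive_seed <- function(seed, k) {
  (as.integer(seed) + 1664525L * as.integer(k)) %% 2147483647L
}
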