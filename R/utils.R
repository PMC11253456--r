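#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

## Central-difference Jacobian of a vector-valued function. Step scales with
## the magnitude of each coordinate so derivatives stay accurate for
## coefficients spanning orders of magnitude.
num_jacobian <- function(f, x, eps = 1e-6) {
  f0 <- f(x)
  J <- matrix(0, nrow = length(f0), ncol = length(x),
              dimnames = list(names(f0), names(x)))
  for (j in seq_along(x)) {
    h <- eps * max(1, abs(x[j]))
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

block_diag <- function(A, B) {
  out <- matrix(0, nrow(A) + nrow(B), ncol(A) + ncol(B))
  out[seq_len(nrow(A)), seq_len(ncol(A))] <- A
  out[nrow(A) + seq_len(nrow(B)), ncol(A) + seq_len(ncol(B))] <- B
  out
}

## round() prints 2 dp the way the study tables do
fmt_pct <- function(x, digits = 2) round(100 * x, digits)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
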