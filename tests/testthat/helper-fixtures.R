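# Shared fixtures for the test suite.  Everything is generated in code;
# seeds are fixed so expected values frozen in the tests stay valid.

# Random symmetric positive-definite matrix with eigenvalues bounded
# away from zero.
rand_spd <- function(n, seed) {
  set.seed(seed)
  A <- matrix(rnorm(n * n), n)
  crossprod(A) / n + diag(n)
}

# Direct generalized-least-squares estimate, the independent oracle for
# whitened OLS.
gls_beta <- function(Y, X, V) {
  solve(crossprod(X, solve(V, X)), crossprod(X, solve(V, Y)))
}

# Intercept-only design of length n (TR in seconds).
intercept_design <- function(n, TR = 1) {
  design_matrix(matrix(1, n, 1), "intercept", "intercept", TR)
}

# Penalized restricted log-likelihood evaluated from scratch (no reuse
# of package internals): the brute-force objective for grid searches.
reml_objective_oracle <- function(lambda, S, basis, X, v) {
  n <- nrow(S)
  qrX <- qr(X)
  K <- qr.Q(qrX, complete = TRUE)[, (qrX$rank + 1L):n, drop = FALSE]
  Vr <- matrix(0, ncol(K), ncol(K))
  for (i in seq_along(basis$components))
    Vr <- Vr + lambda[i] * crossprod(K, basis$components[[i]]$matrix %*% K)
  ch <- tryCatch(chol(Vr), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  iV <- chol2inv(ch)
  Sr <- crossprod(K, S %*% K)
  nr <- nrow(Sr)
  k <- length(lambda)
  -v / 2 * (2 * sum(log(diag(ch))) + sum(iV * Sr) + nr * log(2 * pi)) -
    0.5 * exp(-8) * sum(lambda^2) - k / 2 * (log(2 * pi) + 8)
}
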