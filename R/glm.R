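#' Whitening matrix from an autocorrelation matrix
#'
#' Computes the symmetric principal inverse square root \eqn{W = V^{-1/2}},
#' which satisfies the defining relation \eqn{W'W = V^{-1}}.  The inverse
#' square root is non-unique; the symmetric root is the conventional,
#' deterministic choice.  Eigenvalues of `V` are floored at
#' `floor_tol * max(eigenvalue)` so that mixtures with small negative
#' weights remain usable.
#'
#' @param V Symmetric positive (semi-)definite matrix.
#' @param floor_tol Relative eigenvalue floor (default `1e-8`).
#' @return A symmetric matrix `W` with `t(W) %*% W` equal to `solve(V)` up
#'   to the floor.
#' @export
whitening_matrix <- function(V, floor_tol = 1e-8) {
  if (!is.matrix(V) || nrow(V) != ncol(V))
    stop("`V` must be a square matrix", call. = FALSE)
  if (max(abs(V - t(V))) > 1e-8 * max(1, max(abs(V))))
    stop("`V` must be symmetric", call. = FALSE)
  es <- eigen((V + t(V)) / 2, symmetric = TRUE)
  vals <- pmax(es$values, floor_tol * max(es$values))
  es$vectors %*% (t(es$vectors) / sqrt(vals))
}

#' Label and partition a design matrix
#'
#' Bundles the design matrix with column labels, a partition map
#' (task / drift / nuisance / intercept) and the sampling interval, as
#' required by the fitting and sensitivity routines.
#'
#' @param X Numeric matrix, one row per acquired volume.
#' @param labels Character vector of column labels.
#' @param partition Character vector, one of `"task"`, `"drift"`,
#'   `"nuisance"`, `"intercept"` per column.
#' @param TR Sampling interval (volume repetition time) in seconds.
#' @return A `design_matrix` object.
#' @export
design_matrix <- function(X, labels, partition, TR) {
  X <- as.matrix(X)
  if (length(labels) != ncol(X) || length(partition) != ncol(X))
    stop("labels and partition must have one entry per design column",
         call. = FALSE)
  bad <- !partition %in% c("task", "drift", "nuisance", "intercept")
  if (any(bad))
    stop("unknown partition class: ", paste(unique(partition[bad]),
         collapse = ", "), call. = FALSE)
  if (any(colSums(abs(X)) == 0))
    stop("design contains an all-zero column", call. = FALSE)
  colnames(X) <- labels
  structure(list(X = X, labels = labels, partition = partition, TR = TR),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix: %d x %d, TR = %g s>\n",
              nrow(x$X), ncol(x$X), x$TR))
  print(table(x$partition))
  invisible(x)
}

design_mat <- function(X) if (inherits(X, "design_matrix")) X$X else as.matrix(X)

intercept_column <- function(X) {
  if (inherits(X, "design_matrix")) {
    idx <- which(X$partition == "intercept")
    if (length(idx) != 1L)
      stop("design must contain exactly one intercept column", call. = FALSE)
    return(idx)
  }
  M <- as.matrix(X)
  const <- which(apply(M, 2, function(col) max(abs(col - col[1])) == 0 &&
                         col[1] != 0))
  if (length(const) != 1L)
    stop("design must contain exactly one intercept (constant) column",
         call. = FALSE)
  const
}

# Moore-Penrose pseudoinverse via SVD with a relative rank tolerance.
pseudoinverse <- function(A, tol = 1e-10) {
  s <- svd(A)
  keep <- s$d > tol * max(s$d, 0)
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Fit the general linear model to (optionally whitened) data
#'
#' Fits `W Y = W X beta + W eps` by least squares using the pseudoinverse
#' of `W X`.  The per-voxel error variance is estimated from the residuals
#' as \eqn{\hat\sigma^2 = e'e / \mathrm{trace}(R V_w)} with
#' \eqn{e = R W Y}, \eqn{R = I - WX (WX)^-} the residual-forming matrix,
#' and \eqn{V_w = I} (the error is taken to be white after prewhitening).
#'
#' @param Y Numeric matrix, `n` time points x `v` voxels.
#' @param X A `design_matrix` or plain numeric matrix (`n` x `k`).
#' @param W Whitening matrix (`n` x `n`); `NULL` or missing means no
#'   whitening (identity), the "no model" condition.
#' @return A `glm_fit` object with elements `beta` (`k` x `v`),
#'   `residuals` (`n` x `v`), `sigma2` (length `v`), `df` (residual trace,
#'   i.e. `trace(R)`), `W`, `WX`, `pinv_WX` and the design.
#' @export
fit_glm <- function(Y, X, W = NULL) {
  Y <- as.matrix(Y)
  M <- design_mat(X)
  n <- nrow(M)
  if (nrow(Y) != n)
    stop("`Y` must have one row per design row (time points)", call. = FALSE)
  if (ncol(M) >= n)
    stop("design must have fewer columns than time points", call. = FALSE)
  if (is.null(W)) {
    WY <- Y
    WX <- M
  } else {
    if (!is.matrix(W) || any(dim(W) != n))
      stop("`W` must be an n x n matrix", call. = FALSE)
    WY <- W %*% Y
    WX <- W %*% M
  }
  pinv_WX <- pseudoinverse(WX)
  beta <- pinv_WX %*% WY
  fitted <- WX %*% beta
  e <- WY - fitted
  # trace(R) = n - trace(WX %*% pinv_WX) = n - rank(WX); V_w = I
  df <- n - sum(WX * t(pinv_WX))
  if (df <= 1e-8)
    stop("no residual degrees of freedom (trace of residual-forming matrix",
         " is zero)", call. = FALSE)
  sigma2 <- colSums(e^2) / df
  # residuals at the level of round-off (data exactly in the column
  # space) count as an exact fit, so t-scores are flagged infinite
  # rather than blowing up on noise of order machine epsilon
  yss <- colSums(WY^2)
  sigma2[yss > 0 & sigma2 <= 1e-24 * yss] <- 0
  structure(
    list(beta = beta, residuals = e, sigma2 = sigma2, df = df,
         W = W, WX = WX, pinv_WX = pinv_WX, design = X,
         n = n, v = ncol(Y)),
    class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("<glm_fit: n = %d, k = %d, voxels = %d, trace(R) = %.2f>\n",
              x$n, ncol(x$WX), x$v, x$df))
  invisible(x)
}

#' t-score for a contrast of GLM parameters
#'
#' Computes \eqn{t = c'\hat\beta / (\hat\sigma \eta)} per voxel, where the
#' effective precision \eqn{\eta = \sqrt{c' (WX)^- (WX)^{-T} c}} carries
#' the dependence of the standard error on the design and on the
#' correlation model through `W`.
#'
#' @param fit A `glm_fit` object.
#' @param contrast Numeric contrast vector of length `k`.
#' @return A `contrast_result` with per-voxel `effect` (`c'beta`), `t`,
#'   the scalar `eta`, and a logical `infinite` flag marking voxels with
#'   zero residual variance (reported as `Inf` rather than an error, so
#'   noiseless fixtures pass through).
#' @export
contrast_t <- function(fit, contrast) {
  stopifnot(inherits(fit, "glm_fit"))
  k <- ncol(fit$WX)
  if (!is.numeric(contrast) || length(contrast) != k)
    stop(sprintf("`contrast` must have length %d", k), call. = FALSE)
  if (all(contrast == 0)) stop("`contrast` must be non-zero", call. = FALSE)
  g <- crossprod(fit$pinv_WX, contrast)   # (WX)^-T c, length n
  eta <- sqrt(sum(g^2))
  effect <- drop(crossprod(contrast, fit$beta))
  sigma <- sqrt(fit$sigma2)
  t <- effect / (sigma * eta)
  inf <- sigma == 0
  t[inf] <- sign(effect[inf]) * Inf
  structure(list(contrast = contrast, effect = effect, t = t, eta = eta,
                 df = fit$df, infinite = inf),
            class = "contrast_result")
}

#' t-score testing for the mean signal
#'
#' The t-score of the intercept contrast, proposed as a functional
#' sensitivity metric: unlike the weighted tSNR it accounts for serial
#' correlations through the effective precision \eqn{\eta_0}.  For an
#' intercept-only design with white errors (`W = I`), \eqn{\eta_0}
#' reduces to \eqn{1/\sqrt{N}} and the score equals the weighted tSNR.
#'
#' @param fit A `glm_fit` object whose design has an intercept column.
#' @return A `contrast_result` (the `eta` element is \eqn{\eta_0}).
#' @export
mean_t <- function(fit) {
  stopifnot(inherits(fit, "glm_fit"))
  i0 <- intercept_column(fit$design)
  c0 <- numeric(ncol(fit$WX))
  c0[i0] <- 1
  contrast_t(fit, c0)
}

#' Weighted temporal signal-to-noise ratio
#'
#' The conventional sensitivity metric: mean signal over residual standard
#' deviation, weighted by the square root of the number of samples,
#' \eqn{tSNR_w = c_0'\hat\beta / \hat\sigma \cdot \sqrt{N}}.  Computed
#' within the GLM so that task-related variance is removed by the design
#' regressors, but ignoring serial correlations (it substitutes
#' \eqn{1/\sqrt{N}} for \eqn{\eta_0}).
#'
#' @param fit A `glm_fit` object whose design has an intercept column.
#' @return A `contrast_result` whose `t` element holds the weighted tSNR.
#' @export
weighted_tsnr <- function(fit) {
  stopifnot(inherits(fit, "glm_fit"))
  i0 <- intercept_column(fit$design)
  c0 <- numeric(ncol(fit$WX))
  c0[i0] <- 1
  effect <- drop(crossprod(c0, fit$beta))
  sigma <- sqrt(fit$sigma2)
  tsnr <- effect / sigma * sqrt(fit$n)
  inf <- sigma == 0
  tsnr[inf] <- sign(effect[inf]) * Inf
  structure(list(contrast = c0, effect = effect, t = tsnr,
                 eta = 1 / sqrt(fit$n), df = fit$df, infinite = inf),
            class = "contrast_result")
}
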