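#' Restricted maximum likelihood estimation of covariance mixtures
#'
#' The serial-correlation matrix is expressed as a mixture
#' \eqn{V(\lambda) = \sum_i \lambda_i C_i} over a component dictionary and
#' the hyperparameters \eqn{\lambda} are estimated by Fisher scoring on
#' the variational (Laplace) free energy, from a sample covariance pooled
#' over task-responsive voxels.  The restriction is implemented by
#' projecting the sample covariance and the components onto the orthogonal
#' complement of the design's column space, so the estimate is unaffected
#' by uncertainty in the fixed-effect parameters.
#'
#' @name reml-engine
#' @keywords internal
NULL

#' Select task-responsive voxels by an omnibus F-test
#'
#' Ordinary-least-squares F-test of the joint null that all task
#' regressors have zero effect, per voxel.  Voxels with `p < alpha` form
#' the pool over which the sample covariance of serial correlations is
#' estimated.  If no voxel survives, all voxels are returned with a
#' warning rather than an empty pool.
#'
#' @param Y Numeric matrix, voxels x time.
#' @param X A `design_matrix` or plain matrix (time x regressors).
#' @param task_columns Integer indices of the task columns; defaults to
#'   the columns labelled `"task"` in the design partition.
#' @param alpha Per-voxel significance level (default 0.001, the
#'   conventional uncorrected threshold for pooling masks).
#' @return Logical vector, one entry per voxel.
#' @export
omnibus_voxel_selection <- function(Y, X, task_columns = NULL,
                                    alpha = 0.001) {
  Y <- as.matrix(Y)
  M <- design_mat(X)
  n <- nrow(M)
  if (ncol(Y) != n)
    stop("`Y` must be voxels x time with one column per design row",
         call. = FALSE)
  if (is.null(task_columns) && inherits(X, "design_matrix"))
    task_columns <- which(X$partition == "task")
  if (length(task_columns) == 0L)
    stop("`task_columns` must be a non-empty set of design columns",
         call. = FALSE)
  if (any(task_columns < 1L | task_columns > ncol(M)))
    stop("`task_columns` out of range", call. = FALSE)

  Yt <- t(Y)                                   # n x v
  rank_full <- qr(M)$rank
  df2 <- n - rank_full
  if (df2 <= 0)
    stop("zero residual degrees of freedom in the omnibus F-test",
         call. = FALSE)
  RSS1 <- colSums((Yt - M %*% (pseudoinverse(M) %*% Yt))^2)
  M0 <- M[, -task_columns, drop = FALSE]
  if (ncol(M0) == 0L) {
    RSS0 <- colSums(Yt^2)
    rank_red <- 0L
  } else {
    rank_red <- qr(M0)$rank
    RSS0 <- colSums((Yt - M0 %*% (pseudoinverse(M0) %*% Yt))^2)
  }
  q <- rank_full - rank_red
  Fstat <- ((RSS0 - RSS1) / q) / (RSS1 / df2)
  Fstat[RSS1 == 0 & RSS0 > 0] <- Inf
  pval <- stats::pf(Fstat, q, df2, lower.tail = FALSE)
  pval[is.infinite(Fstat)] <- 0
  mask <- pval < alpha
  if (!any(mask)) {
    warning("no voxel survived the omnibus F-test at alpha = ", alpha,
            "; pooling over all voxels", call. = FALSE)
    mask <- rep(TRUE, length(mask))
  }
  mask
}

#' Pool the sample covariance of serial correlations over voxels
#'
#' Averages the outer product `y y'` over the selected voxels.  By
#' default each voxel's series is first scaled to unit mean square so
#' that voxels contribute on a common scale; the unscaled variant is
#' available for simulation studies where the generating weights are
#' known on the raw scale.
#'
#' @param Y Numeric matrix, voxels x time.
#' @param mask Logical or integer voxel selector; default all voxels.
#' @param scale `"unit-mean-square"` (default) or `"none"`.
#' @return A `sample_cov` object: `matrix` (time x time),
#'   `n_voxels_pooled`, `scaling`.
#' @export
pooled_sample_covariance <- function(Y, mask = NULL,
                                     scale = c("unit-mean-square", "none")) {
  scale <- match.arg(scale)
  Y <- as.matrix(Y)
  if (is.null(mask)) mask <- rep(TRUE, nrow(Y))
  Ys <- t(Y[mask, , drop = FALSE])             # n x v
  v <- ncol(Ys)
  if (v < 1L) stop("`mask` selects no voxels", call. = FALSE)
  if (scale == "unit-mean-square") {
    ms <- colMeans(Ys^2)
    if (any(ms == 0))
      stop("cannot scale all-zero voxel series to unit mean square",
           call. = FALSE)
    Ys <- sweep(Ys, 2, sqrt(ms), "/")
  }
  structure(list(matrix = tcrossprod(Ys) / v, n_voxels_pooled = v,
                 scaling = scale),
            class = "sample_cov")
}

#' Options for the ReML Fisher-scoring ascent
#'
#' @param max_iter Maximum number of scoring iterations (default 64).
#' @param tol Convergence tolerance on the predicted free-energy
#'   improvement, in nats (default 1e-2).
#' @param prior_var Hyperprior variance of each mixture weight; the
#'   weights carry a Gaussian prior with mean zero and variance `exp(8)`
#'   (effectively uninformative).
#' @param cond_warn Condition-number threshold of the Fisher information
#'   above which an ill-conditioning warning is issued (default 1e10).
#' @param verbose Print the free-energy trajectory.
#' @return A list of options for [reml_fit()].
#' @export
reml_options <- function(max_iter = 64L, tol = 1e-2, prior_var = exp(8),
                         cond_warn = 1e10, verbose = FALSE) {
  list(max_iter = as.integer(max_iter), tol = tol, prior_var = prior_var,
       cond_warn = cond_warn, verbose = verbose)
}

# Penalized restricted log-likelihood of projected matrices.
# Returns -Inf when V(lambda) is not positive definite on the projected
# space, which drives the step-halving in the ascent.
reml_objective <- function(lambda, Cr, Sr, v, prior_prec) {
  nr <- nrow(Sr)
  Vr <- matrix(0, nr, nr)
  for (i in seq_along(Cr)) Vr <- Vr + lambda[i] * Cr[[i]]
  ch <- tryCatch(chol(Vr), error = function(e) NULL)
  if (is.null(ch)) return(list(value = -Inf))
  logdet <- 2 * sum(log(diag(ch)))
  iVr <- chol2inv(ch)
  ll <- -v / 2 * (logdet + sum(iVr * Sr) + nr * log(2 * pi))
  k <- length(lambda)
  logprior <- -0.5 * prior_prec * sum(lambda^2) -
    k / 2 * (log(2 * pi) + log(1 / prior_prec))
  list(value = ll + logprior, iVr = iVr)
}

#' Fit mixture hyperparameters by ReML Fisher scoring
#'
#' Maximizes the restricted likelihood of a pooled sample covariance
#' under \eqn{V(\lambda) = \sum_i \lambda_i C_i}, with a Gaussian
#' hyperprior of variance `exp(8)` on each weight, by Fisher scoring with
#' step-halving to enforce monotone ascent.  The weights are
#' unconstrained (they may go negative, with positive definiteness of the
#' fitted matrix enforced downstream by eigenvalue flooring at whitening
#' time).  The reported free energy is the Laplace approximation to the
#' log model evidence at the posterior mode: penalized likelihood plus
#' the Gaussian posterior entropy, so that free-energy differences
#' between dictionaries implement Bayesian model comparison with an
#' automatic complexity penalty.
#'
#' @param S A `sample_cov` object, or a plain symmetric matrix (then
#'   `n_voxels` gives the pooled count).
#' @param basis A `cov_basis` dictionary of matching dimension.
#' @param X A `design_matrix` or plain matrix; the estimate is restricted
#'   to the orthogonal complement of its column space.
#' @param options See [reml_options()].
#' @param n_voxels Pooled voxel count when `S` is a plain matrix.
#' @return A `reml_fit` object: `lambda`, `V` (trace-normalized to `n`),
#'   `free_energy`, `posterior_cov`, `n_iterations`, `converged`,
#'   `condition_number`, `basis_label`, `n_voxels_pooled`, and the
#'   free-energy trajectory `F_trace`.
#' @export
reml_fit <- function(S, basis, X, options = reml_options(), n_voxels = 1L) {
  if (inherits(S, "sample_cov")) {
    v <- S$n_voxels_pooled
    Smat <- S$matrix
  } else {
    v <- n_voxels
    Smat <- as.matrix(S)
  }
  stopifnot(inherits(basis, "cov_basis"))
  M <- design_mat(X)
  n <- nrow(Smat)
  if (ncol(Smat) != n || basis$n_samples != n || nrow(M) != n)
    stop("`S`, `basis` and `X` must share the sample dimension",
         call. = FALSE)

  # Restriction: orthonormal basis K of the null space of X'
  qrX <- qr(M)
  r <- qrX$rank
  if (n - r < 2L)
    stop("fewer than two residual dimensions after removing the design",
         call. = FALSE)
  K <- qr.Q(qrX, complete = TRUE)[, (r + 1L):n, drop = FALSE]
  Sr <- crossprod(K, Smat %*% K)
  Sr <- (Sr + t(Sr)) / 2
  Cr <- lapply(basis$components, function(comp)
    crossprod(K, comp$matrix %*% K))
  k <- length(Cr)
  prior_prec <- 1 / options$prior_var

  # Initialization: spread the projected sample variance over the
  # components that carry a diagonal; keeps V(lambda) positive definite.
  diag_comps <- which(vapply(Cr, function(C) mean(diag(C)) > 0.5, TRUE))
  if (length(diag_comps) == 0L) diag_comps <- 1L
  lambda <- numeric(k)
  lambda[diag_comps] <- mean(diag(Sr)) / length(diag_comps)

  obj <- reml_objective(lambda, Cr, Sr, v, prior_prec)
  if (!is.finite(obj$value))
    stop("initialization failed: mixture not positive definite",
         call. = FALSE)

  F_trace <- obj$value
  converged <- FALSE
  cond_number <- NA_real_
  iter <- 0L
  Fisher <- diag(k)
  for (iter in seq_len(options$max_iter)) {
    iVr <- obj$iVr
    A <- lapply(Cr, function(C) iVr %*% C)     # iV C_i
    B <- iVr %*% Sr
    tB <- t(B)
    grad <- vapply(seq_len(k), function(i)
      v / 2 * (sum(A[[i]] * tB) - sum(diag(A[[i]]))), 0) -
      prior_prec * lambda
    Fisher <- matrix(0, k, k)
    for (i in seq_len(k)) {
      tAi <- t(A[[i]])
      for (j in i:k) {
        Fisher[i, j] <- v / 2 * sum(tAi * A[[j]])
        Fisher[j, i] <- Fisher[i, j]
      }
    }
    H <- Fisher + prior_prec * diag(k)
    cond_number <- kappa(H, exact = FALSE)
    dlambda <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(dlambda)) {
      # Levenberg fallback for a numerically singular information matrix
      dlambda <- solve(H + diag(diag(H) * 1e-6 + 1e-12, k), grad)
    }
    predicted <- sum(grad * dlambda)

    # Step-halving: accept only steps that do not decrease the objective
    step <- 1
    accepted <- FALSE
    for (half in 1:16) {
      cand <- lambda + step * dlambda
      obj_new <- reml_objective(cand, Cr, Sr, v, prior_prec)
      if (is.finite(obj_new$value) && obj_new$value >= obj$value - 1e-10) {
        lambda <- cand
        obj <- obj_new
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    F_trace <- c(F_trace, obj$value)
    if (options$verbose)
      message(sprintf("iter %2d  F = %.6f  predicted dF = %.3g",
                      iter, obj$value, predicted))
    if (!accepted) break
    if (predicted < options$tol) {
      converged <- TRUE
      break
    }
  }

  if (is.finite(cond_number) && cond_number > options$cond_warn)
    warning(sprintf(paste0("Fisher information is ill-conditioned ",
                           "(condition number %.3g): the dictionary is ",
                           "likely over-parameterized"), cond_number),
            call. = FALSE)

  posterior_cov <- tryCatch(solve(Fisher + prior_prec * diag(k)),
                            error = function(e) matrix(NA_real_, k, k))
  # Laplace free energy: penalized likelihood at the mode plus the
  # posterior entropy (the 2*pi terms of prior and entropy cancel).
  logdet_post <- tryCatch(determinant(posterior_cov, logarithm = TRUE),
                          error = function(e) NULL)
  F <- obj$value + k / 2 * log(2 * pi) +
    (if (!is.null(logdet_post) && logdet_post$sign > 0)
      0.5 * as.numeric(logdet_post$modulus) else NA_real_)

  Vfull <- mix_components(basis, lambda)
  Vhat <- Vfull * n / sum(diag(Vfull))

  structure(
    list(lambda = lambda, V = Vhat, free_energy = F,
         objective = obj$value, posterior_cov = posterior_cov,
         n_iterations = iter, converged = converged,
         condition_number = cond_number, basis_label = basis$label,
         n_voxels_pooled = v, F_trace = F_trace, n = n),
    class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf("<reml_fit '%s': F = %.3f, %d iterations, converged = %s>\n",
              x$basis_label, x$free_energy, x$n_iterations, x$converged))
  cat("lambda:", format(x$lambda, digits = 4), "\n")
  invisible(x)
}

#' Compare component dictionaries by free energy
#'
#' Runs [reml_fit()] for each dictionary with identical options and
#' tabulates free-energy differences against the first (reference)
#' dictionary.  A difference above 3 nats is flagged as strong evidence,
#' the conventional threshold (log odds of about 20:1).
#'
#' @param S Pooled sample covariance (see [reml_fit()]).
#' @param X Design matrix.
#' @param bases List of at least two `cov_basis` objects.
#' @param options See [reml_options()].
#' @param n_voxels Pooled count when `S` is a plain matrix.
#' @return A `model_comparison` object with a `table` data frame (label,
#'   p, free energy, delta F, strong evidence, convergence), the winner's
#'   label, and the list of fits.
#' @export
compare_models <- function(S, X, bases, options = reml_options(),
                           n_voxels = 1L) {
  if (!is.list(bases) || length(bases) < 2L)
    stop("`bases` must list at least two component dictionaries",
         call. = FALSE)
  fits <- lapply(bases, function(b)
    reml_fit(S, b, X, options = options, n_voxels = n_voxels))
  F <- vapply(fits, function(f) f$free_energy, 0)
  labels <- vapply(fits, function(f) f$basis_label, "")
  dF <- F - F[1L]
  tab <- data.frame(
    label = labels,
    p = vapply(bases, function(b) b$p, 0L),
    free_energy = F,
    delta_F = dF,
    strong_evidence = abs(dF) > 3,
    converged = vapply(fits, function(f) f$converged, TRUE),
    stringsAsFactors = FALSE)
  tab$strong_evidence[1L] <- FALSE
  structure(list(table = tab, reference_label = labels[1L],
                 winner = labels[which.max(F)], fits = fits),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("<model_comparison: reference '%s', winner '%s'>\n",
              x$reference_label, x$winner))
  print(x$table, row.names = FALSE)
  invisible(x)
}
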