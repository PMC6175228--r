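#' Residual whiteness and estimator stability diagnostics
#'
#' Three instruments for judging whether a serial-correlation model has
#' done its job: a Ljung-Box portmanteau screen of the residuals with
#' false-discovery-rate control across voxels and lags, averaged
#' residual power spectra, and the stability of the intercept precision
#' against the square root of the sample count.
#'
#' @name diagnostics
#' @keywords internal
NULL

# Ljung-Box Q at every lag 1..max_lag from a single pass over the
# autocorrelation function.  Series are demeaned by stats::acf.
ljung_box_all <- function(x, max_lag) {
  m <- length(x)
  if (max_lag >= m) stop("`lag` must be smaller than the series length",
                         call. = FALSE)
  if (stats::sd(x) == 0)
    stop("autocorrelations are undefined for a constant series",
         call. = FALSE)
  rho <- drop(stats::acf(x, lag.max = max_lag, plot = FALSE,
                         demean = TRUE)$acf)[-1]
  Q <- m * (m + 2) * cumsum(rho^2 / (m - seq_len(max_lag)))
  p <- stats::pchisq(Q, df = seq_len(max_lag), lower.tail = FALSE)
  list(Q = Q, p = p)
}

#' Ljung-Box portmanteau test of residual autocorrelation
#'
#' Computes \eqn{Q = m (m + 2) \sum_{k=1}^{h} \hat\rho_k^2 / (m - k)}
#' on the demeaned series and the upper-tail p-value from a chi-square
#' distribution with `h` degrees of freedom.  No degrees-of-freedom
#' adjustment is made for fitted GLM parameters; the null calibration of
#' the screen is verified empirically instead.
#'
#' @param series Numeric vector.
#' @param lag Maximum lag `h` tested (must be below the series length).
#' @return A list with elements `Q` and `p` (scalars for the given lag).
#' @export
ljung_box_q <- function(series, lag) {
  lb <- ljung_box_all(as.numeric(series), as.integer(lag))
  list(Q = lb$Q[lag], p = lb$p[lag])
}

#' Benjamini-Hochberg step-up rejection mask
#'
#' Standard step-up false-discovery-rate procedure at level `q`.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @param q FDR level.
#' @return Logical rejection mask of the same length (empty input gives
#'   an empty mask).
#' @export
benjamini_hochberg <- function(pvals, q) {
  if (length(pvals) == 0L) return(logical(0))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvals, method = "BH") <= q
}

#' Whiteness screen of GLM residuals
#'
#' For each voxel, truncates the residual series to its first `n_points`
#' samples and computes the Ljung-Box Q statistic at every lag
#' `1..max_lag`.  The false-discovery-rate correction is applied jointly
#' across all voxel-by-lag p-values (the conservative reading of
#' "corrected for multiple comparison"), and a voxel is flagged as
#' showing residual serial correlation if any of its lags is rejected.
#' The headline number is the proportion of flagged voxels.
#'
#' @param residuals Numeric matrix, voxels x time.
#' @param n_points Number of initial residual samples tested (default
#'   100).
#' @param max_lag Largest lag tested (default 20).
#' @param fdr_q FDR level (default 0.05).
#' @return A `whiteness_report`: `per_voxel_p` (voxels x lags),
#'   `rejected`, `proportion_rejected`, `n_excluded` (voxels whose
#'   autocorrelations were undefined), and the screen parameters.
#' @export
whiteness_screen <- function(residuals, n_points = 100L, max_lag = 20L,
                             fdr_q = 0.05) {
  residuals <- as.matrix(residuals)
  n_points <- as.integer(n_points)
  max_lag <- as.integer(max_lag)
  if (ncol(residuals) < n_points)
    stop("residual series shorter than `n_points`", call. = FALSE)
  if (n_points <= max_lag)
    stop("`n_points` must exceed `max_lag`", call. = FALSE)
  R <- residuals[, seq_len(n_points), drop = FALSE]
  v <- nrow(R)
  P <- matrix(NA_real_, v, max_lag)
  for (i in seq_len(v)) {
    lb <- tryCatch(ljung_box_all(R[i, ], max_lag), error = function(e) NULL)
    if (!is.null(lb)) P[i, ] <- lb$p
  }
  included <- !is.na(P[, 1])
  n_excluded <- sum(!included)
  if (n_excluded > 0)
    warning(n_excluded, " voxel(s) excluded from the whiteness screen ",
            "(undefined autocorrelations)", call. = FALSE)
  flat <- as.vector(P[included, , drop = FALSE])
  rej_flat <- benjamini_hochberg(flat, fdr_q)
  rej_mat <- matrix(rej_flat, nrow = sum(included), ncol = max_lag)
  rejected <- rep(NA, v)
  rejected[included] <- rowSums(rej_mat) > 0
  structure(
    list(per_voxel_p = P, rejected = rejected,
         proportion_rejected = mean(rejected[included]),
         n_points = n_points, max_lag = max_lag, fdr_q = fdr_q,
         n_excluded = n_excluded),
    class = "whiteness_report")
}

#' @export
print.whiteness_report <- function(x, ...) {
  cat(sprintf(paste0("<whiteness_report: %.1f%% of voxels show residual ",
                     "serial correlation (n_points = %d, max_lag = %d, ",
                     "FDR q = %g)>\n"),
              100 * x$proportion_rejected, x$n_points, x$max_lag, x$fdr_q))
  invisible(x)
}

#' Averaged residual power spectrum
#'
#' Segment-averaged periodogram (50% overlap, mean-detrended segments)
#' averaged over voxels; segment length is the largest power of two not
#' exceeding half the series (at least 8 samples).
#'
#' @param residuals Numeric matrix, voxels x time (at least 8 points).
#' @param TR Sampling interval in seconds.
#' @return A list with `frequencies` (Hz, up to Nyquist) and `power`.
#' @export
residual_power_spectrum <- function(residuals, TR) {
  residuals <- as.matrix(residuals)
  n <- ncol(residuals)
  if (n < 8) stop("at least 8 time points are required", call. = FALSE)
  L <- 2^floor(log2(n / 2))
  L <- max(8L, min(L, n))
  hop <- L %/% 2L
  starts <- seq(1L, n - L + 1L, by = hop)
  acc <- numeric(L %/% 2L)
  n_seg <- 0L
  for (s in starts) {
    seg <- residuals[, s:(s + L - 1L), drop = FALSE]
    seg <- seg - rowMeans(seg)
    ft <- stats::mvfft(t(seg))
    pw <- rowMeans(Mod(ft)^2) * TR / L
    acc <- acc + pw[2:(L %/% 2L + 1L)]
    n_seg <- n_seg + 1L
  }
  list(frequencies = seq_len(L %/% 2L) / (L * TR), power = acc / n_seg)
}

#' Stability of the intercept precision against sample count
#'
#' The precision (inverse standard error) of the intercept estimate is
#' expected to grow linearly with the square root of the number of
#' samples when the serial-correlation model is stable.  The time series
#' and design are truncated to 5 equally spaced sample counts between
#' `n_min` and `n_total`; at each point the correlation matrix is
#' re-estimated by ReML, the GLM refitted, and the voxel-average
#' precision recorded; a linear fit of precision on sqrt(n) summarizes
#' the relationship by its R-squared.
#'
#' @param Y Numeric matrix, voxels x time.
#' @param X A `design_matrix` spanning the full series.
#' @param model Model specification string (see [parse_model_spec()]).
#' @param n_total Largest sample count (default: full series).
#' @param n_min Smallest sample count (default 100; `n_total` must be
#'   large enough that the 5-point grid is strictly increasing).
#' @param options ReML options.
#' @param mask Optional pooling mask; default: omnibus selection when
#'   the design has task columns, otherwise all voxels.
#' @return A `stability_result`: `sample_grid`, `precision`,
#'   `r_squared`, `slope`, `intercept`, `converged` flags.
#' @export
precision_stability <- function(Y, X, model, n_total = ncol(Y),
                                n_min = 100L, options = reml_options(),
                                mask = NULL) {
  Y <- as.matrix(Y)
  grid <- round(seq(n_min, n_total, length.out = 5))
  if (any(diff(grid) <= 0))
    stop("`n_total` too close to `n_min`: the 5-point grid must be ",
         "strictly increasing", call. = FALSE)
  precision <- numeric(5)
  converged <- logical(5)
  for (i in seq_along(grid)) {
    n <- grid[i]
    Yn <- Y[, seq_len(n), drop = FALSE]
    Xn <- truncate_design(X, n)
    m <- mask
    if (is.null(m)) {
      has_task <- inherits(Xn, "design_matrix") &&
        any(Xn$partition == "task")
      m <- if (has_task) omnibus_voxel_selection(Yn, Xn)
           else rep(TRUE, nrow(Yn))
    }
    S <- pooled_sample_covariance(Yn, m)
    basis <- parse_model_spec(model, n)
    if (is.null(basis)) {
      W <- NULL
      converged[i] <- TRUE
    } else {
      fit <- reml_fit(S, basis, Xn, options = options)
      converged[i] <- fit$converged
      if (!fit$converged)
        warning("ReML did not converge at n = ", n,
                "; grid point retained", call. = FALSE)
      W <- whitening_matrix(fit$V)
    }
    g <- fit_glm(t(Yn), Xn, W)
    t0 <- mean_t(g)
    se <- sqrt(g$sigma2) * t0$eta
    precision[i] <- mean(1 / se[se > 0])
  }
  lf <- stats::lm(precision ~ sqrt(grid))
  structure(
    list(sample_grid = grid, precision = precision,
         r_squared = summary(lf)$r.squared,
         slope = unname(stats::coef(lf)[2]),
         intercept = unname(stats::coef(lf)[1]),
         converged = converged),
    class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("<stability_result: R^2 = %.3f over n = %s>\n",
              x$r_squared, paste(x$sample_grid, collapse = ", ")))
  invisible(x)
}
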