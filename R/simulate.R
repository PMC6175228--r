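#' Synthetic block-design BOLD series
#'
#' Ground-truth generator for calibration and parameter-recovery
#' studies: a block design convolved with the canonical HRF, riding on a
#' constant baseline, with stationary AR(1) noise; a decimation scheme
#' derives series with longer sampling intervals from a common
#' fine-grained truth, emulating a fixed scan duration acquired at
#' different rates.
#'
#' @name synthetic-data
#' @keywords internal
NULL

#' Simulation configuration
#'
#' Defaults reproduce the reference simulation: 100 voxels by 1,024
#' samples at a base sampling interval of 1 s (forced by 16 blocks of
#' 32 s on + 32 s off spanning 1,024 s), baseline 100, task effect 1% of
#' baseline, AR(1) noise with coefficient 0.4 and marginal standard
#' deviation 1.
#'
#' @param n_voxels Number of voxels.
#' @param n_samples Number of time points at the base sampling interval.
#' @param baseline Mean signal level (signal units).
#' @param effect_pct Task effect size as a percentage of baseline.
#' @param block_on,block_off Block on/off durations in seconds.
#' @param n_blocks Number of task blocks.
#' @param ar_coef AR(1) coefficient of the noise, in `[0, 1)`.
#' @param noise_sd Noise standard deviation (see `sd_scale` of
#'   [simulate_block_series()]).
#' @param base_dt Base sampling interval in seconds.
#' @param seed Integer seed for reproducibility.
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(n_voxels = 100L, n_samples = 1024L,
                              baseline = 100, effect_pct = 1,
                              block_on = 32, block_off = 32,
                              n_blocks = 16L, ar_coef = 0.4,
                              noise_sd = 1, base_dt = 1, seed = 1L) {
  if (effect_pct < 0) stop("`effect_pct` must be non-negative",
                           call. = FALSE)
  if (ar_coef < 0 || ar_coef >= 1)
    stop("`ar_coef` must lie in [0, 1)", call. = FALSE)
  if (n_blocks * (block_on + block_off) / base_dt > n_samples)
    stop("block schedule does not fit within `n_samples`", call. = FALSE)
  structure(list(n_voxels = as.integer(n_voxels),
                 n_samples = as.integer(n_samples), baseline = baseline,
                 effect_pct = effect_pct, block_on = block_on,
                 block_off = block_off, n_blocks = as.integer(n_blocks),
                 ar_coef = ar_coef, noise_sd = noise_sd,
                 base_dt = base_dt, seed = as.integer(seed)),
            class = "simulation_config")
}

# Stationary AR(1) noise matrix (voxels x time): initialized from the
# stationary distribution, no burn-in transient.
ar1_noise <- function(n_voxels, n_samples, phi, marginal_sd) {
  E <- matrix(stats::rnorm(n_voxels * n_samples), n_voxels, n_samples)
  innov_sd <- marginal_sd * sqrt(1 - phi^2)
  X <- matrix(0, n_voxels, n_samples)
  X[, 1] <- E[, 1] * marginal_sd
  if (n_samples > 1)
    for (t in 2:n_samples)
      X[, t] <- phi * X[, t - 1] + E[, t] * innov_sd
  X
}

#' Simulate a block-design series with AR(1) noise
#'
#' Generates `Y = baseline + (effect_pct/100 * baseline) * s + noise`
#' per voxel, where `s` is the HRF-convolved block regressor scaled to
#' unit peak and the noise is an independent stationary AR(1) process
#' per voxel.
#'
#' @param cfg A `simulation_config`.
#' @param sd_scale Whether `noise_sd` is the marginal (stationary)
#'   standard deviation of the AR(1) process (default) or the innovation
#'   standard deviation.
#' @return A `sim_series` object: `Y` (voxels x time), `truth` (task
#'   regressor, true effect amplitude, AR coefficient, noise sd,
#'   baseline), `dt`, `seed`, and the config.
#' @export
simulate_block_series <- function(cfg,
                                  sd_scale = c("marginal", "innovation")) {
  stopifnot(inherits(cfg, "simulation_config"))
  sd_scale <- match.arg(sd_scale)
  set.seed(cfg$seed)
  onsets <- (seq_len(cfg$n_blocks) - 1) * (cfg$block_on + cfg$block_off)
  sched <- event_schedule(onsets, cfg$block_on)
  s <- block_regressor(sched, cfg$n_samples, cfg$base_dt)
  if (max(s) > 0) s <- s / max(s)
  amp <- cfg$effect_pct / 100 * cfg$baseline
  marginal_sd <- switch(sd_scale,
    marginal = cfg$noise_sd,
    innovation = cfg$noise_sd / sqrt(1 - cfg$ar_coef^2))
  noise <- ar1_noise(cfg$n_voxels, cfg$n_samples, cfg$ar_coef, marginal_sd)
  Y <- matrix(cfg$baseline + amp * s, cfg$n_voxels, cfg$n_samples,
              byrow = TRUE) + noise
  structure(
    list(Y = Y,
         truth = list(task = s, beta = amp, ar_coef = cfg$ar_coef,
                      noise_sd = cfg$noise_sd, baseline = cfg$baseline),
         dt = cfg$base_dt, seed = cfg$seed, config = cfg),
    class = "sim_series")
}

#' @export
print.sim_series <- function(x, ...) {
  cat(sprintf("<sim_series: %d voxels x %d samples, dt = %g s, seed = %d>\n",
              nrow(x$Y), ncol(x$Y), x$dt, x$seed))
  invisible(x)
}

#' Decimate a simulated series
#'
#' Keeps samples `1, 1+d, 1+2d, ...` of the series and of the truth
#' regressor, multiplying the sampling interval by `d`.  Emulates
#' acquiring the same scan duration with a `d`-fold longer volume TR.
#'
#' @param series A `sim_series`.
#' @param d Decimation factor (integer >= 1; values above 6 are accepted
#'   with a warning).
#' @return A `sim_series` on the coarser grid.
#' @export
decimate_series <- function(series, d) {
  stopifnot(inherits(series, "sim_series"))
  d <- as.integer(d)
  if (is.na(d) || d < 1L) stop("`d` must be a positive integer",
                               call. = FALSE)
  if (d > 6L) warning("decimation factor above 6 is outside the usual ",
                      "range", call. = FALSE)
  idx <- seq(1L, ncol(series$Y), by = d)
  out <- series
  out$Y <- series$Y[, idx, drop = FALSE]
  out$truth$task <- series$truth$task[idx]
  out$dt <- series$dt * d
  out
}

#' Draw Gaussian noise with a prescribed component-mixture covariance
#'
#' Rows are independent multivariate normal draws with covariance
#' `mix_components(basis, lambda)`.  Small negative eigenvalues (within
#' `-1e-8` of the largest) are floored at zero; an indefinite mixture
#' beyond that tolerance is an error.
#'
#' @param basis A `cov_basis`.
#' @param lambda Mixture weights.
#' @param n_voxels Number of rows to draw.
#' @param seed Optional integer seed.
#' @return A `n_voxels` x `n_samples` matrix.
#' @export
sample_noise_with_covariance <- function(basis, lambda, n_voxels,
                                         seed = NULL) {
  V <- mix_components(basis, lambda)
  es <- eigen((V + t(V)) / 2, symmetric = TRUE)
  if (min(es$values) < -1e-8 * max(abs(es$values)))
    stop("mixture covariance is indefinite", call. = FALSE)
  L <- es$vectors %*% diag(sqrt(pmax(es$values, 0)), nrow(V))
  if (!is.null(seed)) set.seed(seed)
  Z <- matrix(stats::rnorm(n_voxels * nrow(V)), n_voxels, nrow(V))
  Z %*% t(L)
}

#' Sensitivity of t-scores to the sampling interval
#'
#' Runs the full decimation experiment: for each decimation factor `d`,
#' the series is decimated, a task + intercept design is built on the
#' coarser grid, the serial-correlation matrix is estimated by ReML from
#' the pooled sample covariance of task-responsive voxels, the data are
#' whitened, the GLM is fitted, and the voxel-average task t-score,
#' mean-signal t-score and weighted tSNR are recorded.
#'
#' @param cfg A `simulation_config`.
#' @param model Model specification string (see [parse_model_spec()]),
#'   default `"ar1"`.
#' @param d_values Decimation factors (default `1:6`).
#' @param alpha Omnibus selection level for the pooling mask.
#' @param options ReML options.
#' @return A data frame with one row per `d`: `d`, `N`, `dt`,
#'   `n_pooled`, `t_task`, `t0`, `tsnr_w` (voxel means), `eta0`, and
#'   `converged`.
#' @export
sensitivity_experiment <- function(cfg, model = "ar1", d_values = 1:6,
                                   alpha = 0.001,
                                   options = reml_options()) {
  stopifnot(inherits(cfg, "simulation_config"))
  base <- simulate_block_series(cfg)
  rows <- lapply(d_values, function(d) {
    dec <- decimate_series(base, d)
    n <- ncol(dec$Y)
    X <- assemble_design(task = dec$truth$task, n = n, TR = dec$dt,
                         task_labels = "task")
    mask <- omnibus_voxel_selection(dec$Y, X, alpha = alpha)
    S <- pooled_sample_covariance(dec$Y, mask)
    basis <- parse_model_spec(model, n)
    fit <- if (is.null(basis)) NULL else
      reml_fit(S, basis, X, options = options)
    W <- if (is.null(fit)) NULL else whitening_matrix(fit$V)
    g <- fit_glm(t(dec$Y), X, W)
    ct <- contrast_t(g, c(1, 0))
    t0 <- mean_t(g)
    ts <- weighted_tsnr(g)
    data.frame(d = d, N = n, dt = dec$dt, n_pooled = sum(mask),
               t_task = mean(ct$t[is.finite(ct$t)]),
               t0 = mean(t0$t[is.finite(t0$t)]),
               tsnr_w = mean(ts$t[is.finite(ts$t)]),
               eta0 = t0$eta,
               converged = if (is.null(fit)) NA else fit$converged)
  })
  do.call(rbind, rows)
}

#' Synthesize a physiological phase/amplitude trace
#'
#' Sinusoidal cardiac (~1 Hz) and respiratory (~0.3 Hz) cycles with slow
#' random frequency drift, sampled at mid-volume, plus slowly varying
#' respiration-amplitude and heart-rate streams.  Intended for
#' exercising the physiological regressor builders and the residual
#' spectrum diagnostics; it makes no claim to biophysical realism.
#'
#' @param n Number of volumes.
#' @param TR Sampling interval in seconds.
#' @param cardiac_hz,resp_hz Base frequencies in Hz.
#' @param seed Optional integer seed.
#' @return A `physio_trace`.
#' @export
simulate_physio_trace <- function(n, TR, cardiac_hz = 1, resp_hz = 0.3,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t_mid <- (seq_len(n) - 0.5) * TR
  drift <- function(scale) cumsum(stats::rnorm(n, 0, scale)) * TR
  card_phase <- 2 * pi * (cardiac_hz * t_mid + drift(0.01))
  resp_phase <- 2 * pi * (resp_hz * t_mid + drift(0.005))
  rv <- 1 + 0.2 * sin(2 * pi * 0.01 * t_mid) + stats::rnorm(n, 0, 0.02)
  hr <- 60 * cardiac_hz + 3 * sin(2 * pi * 0.008 * t_mid) +
    stats::rnorm(n, 0, 0.5)
  physio_trace(t_mid, card_phase, resp_phase,
               respiration_amplitude = rv, cardiac_rate = hr)
}
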