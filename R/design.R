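#' Design-matrix construction
#'
#' Builders for the regressors of a block-design BOLD analysis: the
#' canonical double-gamma haemodynamic response, HRF-convolved task
#' boxcars, a discrete-cosine high-pass drift basis (128 s cutoff), and
#' cardiac/respiratory nuisance regressors (Fourier phase expansion to
#' the third harmonic plus amplitude regressors convolved with
#' respiratory and cardiac response kernels).
#'
#' @name design-builder
#' @keywords internal
NULL

# Double-gamma HRF density (unnormalized): response gamma with shape 6,
# rate 1 (mode at 5 s) minus an undershoot gamma with shape 16, rate 1
# (mode at 15 s) scaled by the conventional 1/6 ratio.
hrf_density <- function(t) {
  stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
}

# Running integral of the double-gamma density, available in closed form
# through the regularized incomplete gamma function.  Exact convolution
# of boxcars with the HRF uses differences of this integral, which makes
# the convolution independent of any microtime grid.
hrf_integral <- function(t) {
  stats::pgamma(t, shape = 6, rate = 1) -
    stats::pgamma(t, shape = 16, rate = 1) / 6
}

hrf_peak_value <- function() {
  # mode of the response gamma is at t = 5; refine the peak of the
  # difference of gammas around it once
  stats::optimize(hrf_density, c(3, 8), maximum = TRUE)$objective
}

#' Canonical haemodynamic response kernel
#'
#' Samples the canonical double-gamma HRF on a regular grid over 32 s,
#' scaled to unit peak.  Response peak delay 6 s (gamma shape 6, rate 1,
#' mode at 5 s), undershoot delay 16 s, dispersions 1 s, and a
#' peak-to-undershoot ratio of 6 -- the convention of standard fMRI
#' analysis software.
#'
#' @param dt Sampling interval of the kernel in seconds, in `(0, 4]`.
#' @return Numeric vector of kernel values at `t = 0, dt, 2 dt, ..., 32`.
#' @export
canonical_hrf <- function(dt) {
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0 || dt > 4)
    stop("`dt` must be a single value in (0, 4] seconds", call. = FALSE)
  t <- seq(0, 32, by = dt)
  hrf_density(t) / hrf_peak_value()
}

#' Event schedule for a task run
#'
#' @param onsets Event onsets in seconds (non-negative, sorted).
#' @param durations Event durations in seconds (positive; recycled).
#' @param condition Condition labels (recycled; default `"task"`).
#' @return An `event_schedule` object.
#' @export
event_schedule <- function(onsets, durations, condition = "task") {
  if (length(onsets) > 0) {
    if (any(onsets < 0)) stop("onsets must be non-negative", call. = FALSE)
    if (is.unsorted(onsets)) stop("onsets must be sorted", call. = FALSE)
  }
  durations <- rep_len(durations, length(onsets))
  condition <- rep_len(condition, length(onsets))
  if (length(onsets) > 0 && any(durations <= 0))
    stop("durations must be positive", call. = FALSE)
  structure(list(onsets = as.numeric(onsets),
                 durations = as.numeric(durations),
                 condition = as.character(condition)),
            class = "event_schedule")
}

#' HRF-convolved task regressor for a block or event schedule
#'
#' Convolves the schedule's boxcar with the canonical HRF and samples the
#' result at the volume acquisition times `t = 0, TR, ..., (n-1) TR`.
#' The convolution is evaluated exactly through the closed-form running
#' integral of the double-gamma kernel, so regressors built on a
#' decimated time grid coincide exactly with decimated regressors.
#'
#' @param schedule An `event_schedule`.
#' @param n Number of volumes.
#' @param TR Sampling interval in seconds.
#' @return Numeric vector of length `n` (unit-peak HRF units; a long
#'   block plateaus at the kernel integral, not at 1).
#' @export
block_regressor <- function(schedule, n, TR) {
  stopifnot(inherits(schedule, "event_schedule"), n >= 1, TR > 0)
  times <- (seq_len(n) - 1) * TR
  r <- numeric(n)
  if (length(schedule$onsets) == 0L) return(r)
  run_end <- n * TR
  beyond <- schedule$onsets >= run_end
  if (any(beyond))
    warning(sum(beyond), " event(s) beyond the series end were dropped",
            call. = FALSE)
  peak <- hrf_peak_value()
  for (i in which(!beyond)) {
    on <- schedule$onsets[i]
    off <- on + schedule$durations[i]
    r <- r + (hrf_integral(times - on) - hrf_integral(times - off)) / peak
  }
  r
}

#' Discrete-cosine high-pass drift basis
#'
#' Returns the low-frequency discrete cosine columns modelling drifts
#' slower than the cutoff period.  The retained column count follows the
#' convention `k = floor(2 n TR / cutoff + 1) - 1` (the constant term is
#' handled by the intercept and excluded here).  Columns have zero mean,
#' unit norm, and are mutually orthogonal.
#'
#' @param n Number of volumes.
#' @param TR Sampling interval in seconds.
#' @param cutoff High-pass cutoff period in seconds (default 128).
#' @return An `n` x `k` matrix (zero columns with a warning when the run
#'   is shorter than the cutoff).
#' @export
dct_drift_basis <- function(n, TR, cutoff = 128) {
  stopifnot(n >= 2, TR > 0, cutoff > 0)
  if (n * TR <= cutoff) {
    warning("run duration does not exceed the cutoff period; ",
            "no drift columns generated", call. = FALSE)
    return(matrix(numeric(0), n, 0))
  }
  k <- floor(2 * n * TR / cutoff + 1) - 1
  if (k < 1) return(matrix(numeric(0), n, 0))
  i <- seq_len(n)
  X <- vapply(seq_len(k), function(j)
    sqrt(2 / n) * cos(pi * (2 * i - 1) * j / (2 * n)), numeric(n))
  colnames(X) <- sprintf("dct_%03d", seq_len(k))
  X
}

#' Per-volume physiological phase trace
#'
#' Cardiac and respiratory phases sampled at the middle of each volume
#' acquisition, plus optional amplitude streams (respiration amplitude,
#' cardiac rate) used by [amplitude_regressors()].
#'
#' @param time Volume mid-acquisition times in seconds (strictly
#'   increasing).
#' @param cardiac_phase,respiratory_phase Phases in radians, wrapped to
#'   `[0, 2 pi)`.
#' @param respiration_amplitude Optional respiration amplitude stream
#'   (arbitrary units).
#' @param cardiac_rate Optional heart-rate stream (beats per minute).
#' @return A `physio_trace` object.
#' @export
physio_trace <- function(time, cardiac_phase, respiratory_phase,
                         respiration_amplitude = NULL,
                         cardiac_rate = NULL) {
  if (any(diff(time) <= 0))
    stop("`time` must be strictly increasing", call. = FALSE)
  n <- length(time)
  if (length(cardiac_phase) != n || length(respiratory_phase) != n)
    stop("phase streams must have one sample per volume", call. = FALSE)
  structure(
    list(time = as.numeric(time),
         cardiac_phase = cardiac_phase %% (2 * pi),
         respiratory_phase = respiratory_phase %% (2 * pi),
         respiration_amplitude = respiration_amplitude,
         cardiac_rate = cardiac_rate),
    class = "physio_trace")
}

#' Fourier phase expansion of cardiac and respiratory cycles
#'
#' Builds the 12 phase regressors: sine and cosine of the cardiac and
#' respiratory phases up to the third harmonic (`order = 3`, giving
#' `4 * order = 12` columns).  Other orders are accepted but reported as
#' a deviation from the standard 14-regressor physiological set.
#'
#' @param trace A `physio_trace`.
#' @param order Number of harmonics (default 3).
#' @return An `n` x `4 * order` matrix with labelled columns.
#' @export
physio_fourier_regressors <- function(trace, order = 3L) {
  stopifnot(inherits(trace, "physio_trace"))
  order <- as.integer(order)
  if (order < 1L) stop("`order` must be at least 1", call. = FALSE)
  if (order != 3L)
    message("note: harmonic order ", order,
            " deviates from the standard third-harmonic expansion")
  cols <- list()
  for (m in seq_len(order)) {
    cols[[sprintf("cardiac_sin%d", m)]] <- sin(m * trace$cardiac_phase)
    cols[[sprintf("cardiac_cos%d", m)]] <- cos(m * trace$cardiac_phase)
    cols[[sprintf("resp_sin%d", m)]] <- sin(m * trace$respiratory_phase)
    cols[[sprintf("resp_cos%d", m)]] <- cos(m * trace$respiratory_phase)
  }
  do.call(cbind, cols)
}

# Respiration response function (Birn-style): slow overshoot/undershoot
# impulse response to respiration-volume changes.
respiration_response <- function(t) {
  0.6 * t^2.1 * exp(-t / 1.6) - 0.0023 * t^3.54 * exp(-t / 4.25)
}

# Cardiac response function (Chang-style): early gamma peak followed by
# a Gaussian dip around 12 s.
cardiac_response <- function(t) {
  0.6 * t^2.7 * exp(-t / 1.6) -
    16 / sqrt(2 * pi * 9) * exp(-(t - 12)^2 / 18)
}

#' Respiration-volume and heart-rate amplitude regressors
#'
#' Interpolates the trace's amplitude streams onto the volume times,
#' mean-centres them, and convolves each with its response kernel
#' (respiration response function and cardiac response function,
#' evaluated over 32 s).  Completes the 12 + 2 = 14 physiological
#' regressor set.
#'
#' @param trace A `physio_trace` carrying `respiration_amplitude` and/or
#'   `cardiac_rate`.
#' @param volume_times Volume mid-acquisition times in seconds.
#' @return An `n` x 2 matrix (columns `rvt`, `hr`); missing streams are
#'   omitted with a warning.
#' @export
amplitude_regressors <- function(trace, volume_times) {
  stopifnot(inherits(trace, "physio_trace"))
  n <- length(volume_times)
  dt <- mean(diff(volume_times))
  kern_t <- seq(0, 32, by = dt)
  out <- list()
  one <- function(stream, kernel_fun, label) {
    y <- stats::approx(trace$time, stream, xout = volume_times,
                       rule = 2)$y
    y <- y - mean(y)
    kern <- kernel_fun(kern_t)
    full <- stats::convolve(y, rev(kern), type = "open") * dt
    out[[label]] <<- full[seq_len(n)]
  }
  if (!is.null(trace$respiration_amplitude))
    one(trace$respiration_amplitude, respiration_response, "rvt")
  else warning("no respiration amplitude stream; `rvt` column omitted",
               call. = FALSE)
  if (!is.null(trace$cardiac_rate))
    one(trace$cardiac_rate, cardiac_response, "hr")
  else warning("no cardiac rate stream; `hr` column omitted",
               call. = FALSE)
  if (length(out) == 0L) return(matrix(numeric(0), n, 0))
  do.call(cbind, out)
}

#' Assemble a labelled, partitioned design matrix
#'
#' Concatenates task, drift and nuisance regressors, appends the
#' intercept last, checks the rank, and records the partition map used
#' by the fitting and selection routines.
#'
#' @param task Numeric vector, matrix, or list of task regressors.
#' @param drift Optional drift matrix (e.g. from [dct_drift_basis()]).
#' @param nuisance Optional nuisance matrix (physiological or motion
#'   regressors, pass-through).
#' @param n Number of volumes.
#' @param TR Sampling interval in seconds.
#' @param task_labels Optional labels for the task columns.
#' @return A `design_matrix`.
#' @export
assemble_design <- function(task, drift = NULL, nuisance = NULL, n, TR,
                            task_labels = NULL) {
  if (is.list(task) && !is.matrix(task)) task <- do.call(cbind, task)
  task <- as.matrix(task)
  if (nrow(task) != n)
    stop("task regressors must have `n` rows", call. = FALSE)
  if (qr(task)$rank < ncol(task))
    stop("task regressors are rank deficient", call. = FALSE)
  if (is.null(task_labels))
    task_labels <- if (!is.null(colnames(task))) colnames(task)
      else sprintf("task_%d", seq_len(ncol(task)))
  blocks <- list(task)
  labels <- task_labels
  partition <- rep("task", ncol(task))
  add_block <- function(M, kind, prefix) {
    if (is.null(M) || ncol(as.matrix(M)) == 0L) return()
    M <- as.matrix(M)
    if (nrow(M) != n) stop(kind, " regressors must have `n` rows",
                           call. = FALSE)
    blocks[[length(blocks) + 1L]] <<- M
    labels <<- c(labels, if (!is.null(colnames(M))) colnames(M)
                 else sprintf("%s_%d", prefix, seq_len(ncol(M))))
    partition <<- c(partition, rep(kind, ncol(M)))
  }
  add_block(drift, "drift", "drift")
  add_block(nuisance, "nuisance", "nuisance")
  blocks[[length(blocks) + 1L]] <- matrix(1, n, 1)
  labels <- c(labels, "intercept")
  partition <- c(partition, "intercept")
  X <- do.call(cbind, blocks)
  if (qr(X)$rank < ncol(X))
    warning("assembled design is rank deficient; downstream fits use ",
            "the pseudoinverse", call. = FALSE)
  design_matrix(X, labels, partition, TR)
}

# Truncate a design to its first n rows (used by the stability analysis).
truncate_design <- function(X, n) {
  if (inherits(X, "design_matrix")) {
    M <- X$X[seq_len(n), , drop = FALSE]
    keep <- colSums(abs(M)) > 0
    design_matrix(M[, keep, drop = FALSE], X$labels[keep],
                  X$partition[keep], X$TR)
  } else {
    as.matrix(X)[seq_len(n), , drop = FALSE]
  }
}
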