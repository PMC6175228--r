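#' Readers, writers and pipeline orchestration
#'
#' On-disk interchange is plain delimited text (TSV) with JSON sidecars;
#' NIfTI-1 volumes are supported as an optional input/output route when
#' the RNifti package is available.
#'
#' @name io-cli
#' @keywords internal
NULL

sidecar_path <- function(path) paste0(sub("\\.[^.]+$", "", path), ".json")

#' Read a voxels-by-time series table
#'
#' Reads a tab-delimited voxels x time matrix (no header).  The sampling
#' interval is taken from `tr`, or from a JSON sidecar (same path with a
#' `.json` extension, field `TR`) when present.
#'
#' @param path Path to the TSV file.
#' @param tr Optional sampling interval in seconds (overrides sidecar).
#' @return A list with `Y` (matrix) and `TR` (possibly `NULL`).
#' @export
read_timeseries <- function(path, tr = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  Y <- as.matrix(utils::read.table(path, header = FALSE, sep = "\t"))
  dimnames(Y) <- NULL
  if (is.null(tr)) {
    sc <- sidecar_path(path)
    if (file.exists(sc)) tr <- jsonlite::read_json(sc)$TR
  }
  list(Y = Y, TR = if (is.null(tr)) NULL else as.numeric(tr))
}

#' Write a voxels-by-time series table
#'
#' @param Y Numeric matrix, voxels x time.
#' @param path Output TSV path.
#' @param TR Optional sampling interval, recorded in a JSON sidecar.
#' @return Invisibly, `path`.
#' @export
write_timeseries <- function(Y, path, TR = NULL) {
  utils::write.table(Y, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  if (!is.null(TR))
    jsonlite::write_json(list(TR = TR), sidecar_path(path),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a 4D NIfTI series with a 3D mask
#'
#' Extracts the voxels inside the mask as a voxels x time matrix; the
#' sampling interval is taken from the time dimension of `pixdim`.
#' Requires the RNifti package.
#'
#' @param path Path to a 4D NIfTI-1 image.
#' @param mask_path Path to a 3D mask image (non-zero = included).
#' @return A list with `Y`, `TR`, and `voxel_index` (positions inside
#'   the mask, for writing maps back).
#' @export
read_timeseries_nifti <- function(path, mask_path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("NIfTI support requires the RNifti package", call. = FALSE)
  img <- RNifti::readNifti(path)
  msk <- RNifti::readNifti(mask_path)
  d <- dim(img)
  if (length(d) != 4L) stop("expected a 4D image", call. = FALSE)
  if (!all(dim(msk) == d[1:3]))
    stop("mask dimensions do not match the image", call. = FALSE)
  idx <- which(msk != 0)
  if (length(idx) == 0L) stop("mask selects no voxels", call. = FALSE)
  mat <- matrix(img, prod(d[1:3]), d[4])
  list(Y = mat[idx, , drop = FALSE],
       TR = RNifti::pixdim(img)[4], voxel_index = idx)
}

#' Read a BIDS-style events table
#'
#' Tab-delimited with a header containing at least `onset` and
#' `duration` (seconds); `trial_type` is optional.
#'
#' @param path Path to the events TSV.
#' @return An `event_schedule`.
#' @export
read_events <- function(path) {
  ev <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("onset", "duration") %in% names(ev)))
    stop("events table must have `onset` and `duration` columns",
         call. = FALSE)
  cond <- if ("trial_type" %in% names(ev)) ev$trial_type else "task"
  o <- order(ev$onset)
  event_schedule(ev$onset[o], ev$duration[o],
                 if (length(cond) > 1) cond[o] else cond)
}

#' Write a design matrix with its JSON sidecar
#'
#' The matrix is written as TSV with a header row of labels; the sidecar
#' records labels, partition and TR.
#'
#' @param design A `design_matrix`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "design_matrix"))
  utils::write.table(design$X, path, sep = "\t", row.names = FALSE,
                     col.names = design$labels, quote = FALSE)
  jsonlite::write_json(
    list(labels = design$labels, partition = design$partition,
         TR = design$TR),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a design matrix written by [write_design()]
#'
#' @param path Path to the design TSV (sidecar expected alongside).
#' @return A `design_matrix`.
#' @export
read_design <- function(path) {
  X <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   check.names = FALSE))
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop("design sidecar not found: ", sc, call. = FALSE)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  design_matrix(X, meta$labels, meta$partition, meta$TR)
}

#' Serialize a ReML fit to JSON
#'
#' @param fit A `reml_fit`.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_reml_json <- function(fit, path) {
  stopifnot(inherits(fit, "reml_fit"))
  jsonlite::write_json(
    list(basis = fit$basis_label, lambda = fit$lambda,
         free_energy = fit$free_energy, n_iterations = fit$n_iterations,
         converged = fit$converged,
         condition_number = fit$condition_number,
         n_voxels_pooled = fit$n_voxels_pooled),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run the simulate / fit / diagnose pipeline
#'
#' Orchestrates the package's analyses from a single configuration.
#' When `series` is `NULL` a block-design series is simulated from the
#' built-in defaults with the supplied seed.  Outputs (per-voxel
#' statistics table, ReML fit JSON, whiteness report JSON, fitted
#' autocorrelation matrix, log) are written under `out_dir`.
#'
#' @param cfg A list with fields: `out_dir` (required), `seed` (integer,
#'   default 1), `model` (spec string, default `"ar1"`), `series`
#'   (optional path to a voxels x time TSV), `TR` (required with
#'   `series`), `events` (optional events TSV used to build the task
#'   regressor), `diagnostics` (list with `n_points`, `max_lag`,
#'   `fdr_q`), `models` (optional character vector; when at least two
#'   are given a free-energy comparison is also written), `simulation`
#'   (optional `simulation_config` overriding the built-in defaults).
#' @return Invisibly, a list with the fit, whiteness report and paths.
#' @export
run_pipeline <- function(cfg) {
  if (is.null(cfg$out_dir)) stop("`out_dir` is required", call. = FALSE)
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  model <- if (is.null(cfg$model)) "ar1" else cfg$model
  log_lines <- character(0)
  note <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  note("fastwhiten pipeline: model = %s, seed = %d", model, seed)

  if (is.null(cfg$series)) {
    sim_cfg <- if (!is.null(cfg$simulation)) cfg$simulation
               else simulation_config(seed = seed)
    sim <- simulate_block_series(sim_cfg)
    Y <- sim$Y
    TR <- sim$dt
    task <- sim$truth$task
    note("simulated %d voxels x %d samples (block design, AR(1) noise)",
         nrow(Y), ncol(Y))
  } else {
    ts <- read_timeseries(cfg$series, tr = cfg$TR)
    Y <- ts$Y
    TR <- ts$TR
    if (is.null(TR)) stop("`TR` is required with an external series",
                          call. = FALSE)
    n <- ncol(Y)
    task <- if (!is.null(cfg$events))
      block_regressor(read_events(cfg$events), n, TR) else NULL
  }
  n <- ncol(Y)
  X <- if (!is.null(task)) {
    tk <- if (max(abs(task)) > 0) task / max(abs(task)) else task
    assemble_design(task = tk, n = n, TR = TR, task_labels = "task")
  } else {
    design_matrix(matrix(1, n, 1), "intercept", "intercept", TR)
  }

  mask <- if (!is.null(task)) omnibus_voxel_selection(Y, X)
          else rep(TRUE, nrow(Y))
  S <- pooled_sample_covariance(Y, mask)
  basis <- parse_model_spec(model, n)
  if (is.null(basis)) {
    fit <- NULL
    W <- NULL
    note("no serial-correlation model: identity whitening")
  } else {
    fit <- reml_fit(S, basis, X)
    W <- whitening_matrix(fit$V)
    note("ReML '%s': free energy %.3f, %d iterations, converged = %s",
         fit$basis_label, fit$free_energy, fit$n_iterations,
         fit$converged)
    write_reml_json(fit, file.path(cfg$out_dir, "reml.json"))
    utils::write.table(fit$V, file.path(cfg$out_dir, "V_hat.tsv"),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  }

  g <- fit_glm(t(Y), X, W)
  t0 <- mean_t(g)
  ts_w <- weighted_tsnr(g)
  stats_tab <- data.frame(voxel = seq_len(nrow(Y)),
                          sigma2 = g$sigma2, t0 = t0$t, tsnr_w = ts_w$t)
  if (!is.null(task)) {
    ct <- contrast_t(g, c(1, rep(0, ncol(g$WX) - 1)))
    stats_tab$t_task <- ct$t
    stats_tab$beta_task <- ct$effect
  }
  utils::write.table(stats_tab, file.path(cfg$out_dir, "stats.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  dopt <- cfg$diagnostics
  wr <- whiteness_screen(
    t(g$residuals),
    n_points = if (is.null(dopt$n_points)) 100L else dopt$n_points,
    max_lag = if (is.null(dopt$max_lag)) 20L else dopt$max_lag,
    fdr_q = if (is.null(dopt$fdr_q)) 0.05 else dopt$fdr_q)
  note("whiteness screen: %.1f%% of voxels show residual correlation",
       100 * wr$proportion_rejected)
  jsonlite::write_json(
    list(proportion_rejected = wr$proportion_rejected,
         n_points = wr$n_points, max_lag = wr$max_lag,
         fdr_q = wr$fdr_q, n_excluded = wr$n_excluded),
    file.path(cfg$out_dir, "whiteness.json"), auto_unbox = TRUE,
    digits = NA)

  cmp <- NULL
  if (!is.null(cfg$models) && length(cfg$models) >= 2) {
    bases <- lapply(cfg$models, parse_model_spec, n_samples = n)
    if (any(vapply(bases, is.null, TRUE)))
      stop("'none' cannot take part in a free-energy comparison",
           call. = FALSE)
    cmp <- compare_models(S, X, bases)
    note("model comparison winner: %s", cmp$winner)
    jsonlite::write_json(cmp$table,
                         file.path(cfg$out_dir, "comparison.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  writeLines(log_lines, file.path(cfg$out_dir, "log.txt"))
  invisible(list(fit = fit, whiteness = wr, comparison = cmp,
                 stats = stats_tab, out_dir = cfg$out_dir))
}
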