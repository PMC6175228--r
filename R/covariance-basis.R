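#' Covariance-component dictionaries for serial-correlation modelling
#'
#' Serial correlations in a stationary time series of length \eqn{n} are
#' modelled as a linear mixture \eqn{V = \sum_i \lambda_i C_i} over a fixed
#' dictionary of symmetric Toeplitz components \eqn{C_i}.  Two dictionaries
#' are provided: the extended multi-timescale family of exponential decays
#' and their first two derivative shapes (known as the FAST model), and the
#' classical pair of white noise plus a first-order autoregressive process.
#'
#' @name covariance-basis
#' @keywords internal
NULL

new_cov_component <- function(matrix, kind, order = NA_integer_,
                              alpha = NA_real_, q = NA_integer_,
                              decay = NA_real_) {
  structure(
    list(matrix = matrix, kind = kind, order = order,
         alpha = alpha, q = q, decay = decay),
    class = "cov_component"
  )
}

new_cov_basis <- function(components, n_samples, p, label) {
  structure(
    list(components = components, n_samples = n_samples, p = p,
         label = label),
    class = "cov_basis"
  )
}

#' Build the multi-timescale (FAST) covariance-component dictionary
#'
#' Constructs the dictionary of `3 * p` symmetric Toeplitz components used
#' to model serial correlations at `p` exponential timescales.  For each
#' timescale index `q = 1, ..., p` the decay rate is `alpha = 8 / 2^q`
#' (per sample), and three shapes are generated, indexed by the derivative
#' order `n = 0, 1, 2`:
#' \deqn{C^{n\alpha}_{ij} = 1 \textrm{ if } j = i, n = 0; \quad
#'       |j - i|^n e^{-\alpha |j - i|} \textrm{ otherwise.}}
#' The `n = 0` member of each timescale is an AR(1)-like correlation shape
#' (unit diagonal); the `n = 1, 2` members have zero diagonal and capture
#' departures from a pure exponential decay.
#'
#' Components are ordered by timescale `q` ascending and derivative order
#' `n` ascending within each timescale, so the dictionary for `p - 1`
#' timescales is a prefix of the dictionary for `p`.
#'
#' @param n_samples Number of time points (matrix dimension), at least 2.
#' @param p Number of exponential timescales, an integer in `[1, 9]`.
#' @return A `cov_basis` object holding `3 * p` `cov_component`s.
#' @seealso [build_ar1_plus_white()], [mix_components()]
#' @export
#' @examples
#' b <- build_fast_components(64, p = 3)
#' length(b$components)  # 9
build_fast_components <- function(n_samples, p) {
  n_samples <- as.integer(n_samples)
  p <- as.integer(p)
  if (is.na(n_samples) || n_samples < 2L)
    stop("`n_samples` must be an integer >= 2", call. = FALSE)
  if (is.na(p) || p < 1L || p > 9L)
    stop("`p` must be an integer in [1, 9]", call. = FALSE)
  lag <- abs(outer(seq_len(n_samples), seq_len(n_samples), "-"))
  components <- vector("list", 3L * p)
  idx <- 1L
  for (q in seq_len(p)) {
    alpha <- 8 / 2^q
    decay <- exp(-alpha * lag)
    for (n_ord in 0:2) {
      # 0^0 = 1 in R, so the two-case rule (unit diagonal for n = 0, zero
      # diagonal for n >= 1) falls out of the single expression.
      M <- lag^n_ord * decay
      components[[idx]] <- new_cov_component(M, kind = "fast",
                                             order = n_ord, alpha = alpha,
                                             q = q)
      idx <- idx + 1L
    }
  }
  new_cov_basis(components, n_samples, p = p,
                label = sprintf("fast:p=%d", p))
}

#' Build the AR(1) + white noise covariance-component pair
#'
#' The conventional two-component dictionary: an identity (white noise)
#' component and a Toeplitz AR(1) correlation shape with entries
#' `decay^|i - j|`.  The decay is a fixed shape parameter of the component,
#' not a fitted quantity; only the two mixture weights are estimated.
#'
#' @param n_samples Number of time points, at least 2.
#' @param decay AR(1) lag-one correlation of the component shape, in
#'   `[0, 1)`.  Defaults to 0.2, the conventional fixed value.
#' @return A `cov_basis` object holding 2 `cov_component`s.
#' @export
build_ar1_plus_white <- function(n_samples, decay = 0.2) {
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 2L)
    stop("`n_samples` must be an integer >= 2", call. = FALSE)
  if (!is.numeric(decay) || length(decay) != 1L || decay < 0 || decay >= 1)
    stop("`decay` must lie in [0, 1): the AR(1) shape must be stationary",
         call. = FALSE)
  lag <- abs(outer(seq_len(n_samples), seq_len(n_samples), "-"))
  white <- diag(n_samples)
  ar1 <- decay^lag  # 0^0 = 1 keeps the diagonal at 1 even for decay = 0
  components <- list(
    new_cov_component(white, kind = "white"),
    new_cov_component(ar1, kind = "ar1", decay = decay)
  )
  new_cov_basis(components, n_samples, p = 0L, label = "ar1+white")
}

#' Evaluate a mixture of covariance components
#'
#' Returns \eqn{V = \sum_i \lambda_i C_i} for a dictionary and a weight
#' vector.  The result is symmetric Toeplitz by construction; positive
#' definiteness is not enforced here (weights from ReML may be negative)
#' and is handled at whitening time by eigenvalue flooring.
#'
#' @param basis A `cov_basis` object.
#' @param weights Numeric vector of mixture weights, one per component.
#' @return A symmetric `n_samples` x `n_samples` matrix.
#' @export
mix_components <- function(basis, weights) {
  stopifnot(inherits(basis, "cov_basis"))
  k <- length(basis$components)
  if (!is.numeric(weights) || length(weights) != k)
    stop(sprintf("`weights` must be a numeric vector of length %d", k),
         call. = FALSE)
  n <- basis$n_samples
  V <- matrix(0, n, n)
  for (i in seq_len(k))
    V <- V + weights[i] * basis$components[[i]]$matrix
  V
}

#' Parse a model specification string into a component dictionary
#'
#' Accepts `"none"` (no correlation model: identity), `"ar1"` or
#' `"ar1:<decay>"`, and `"fast:p=<K>"`.
#'
#' @param spec Model specification string.
#' @param n_samples Number of time points.
#' @return A `cov_basis` object, or `NULL` for `"none"`.
#' @export
parse_model_spec <- function(spec, n_samples) {
  spec <- tolower(trimws(spec))
  if (spec == "none") return(NULL)
  if (spec == "ar1") return(build_ar1_plus_white(n_samples))
  if (grepl("^ar1:", spec)) {
    decay <- suppressWarnings(as.numeric(sub("^ar1:", "", spec)))
    if (is.na(decay)) stop("cannot parse AR(1) decay in '", spec, "'",
                           call. = FALSE)
    return(build_ar1_plus_white(n_samples, decay = decay))
  }
  if (grepl("^fast:p=", spec)) {
    p <- suppressWarnings(as.integer(sub("^fast:p=", "", spec)))
    if (is.na(p)) stop("cannot parse timescale count in '", spec, "'",
                       call. = FALSE)
    return(build_fast_components(n_samples, p = p))
  }
  stop("unknown model specification '", spec,
       "' (expected none | ar1[:decay] | fast:p=K)", call. = FALSE)
}

#' Export a component dictionary to delimited text plus a JSON manifest
#'
#' Writes each component matrix as a tab-delimited file
#' (`component_<i>.tsv`) and a `manifest.json` recording kind, dimension,
#' decay rate and timescale index per component, for inspection and
#' cross-implementation comparison.
#'
#' @param basis A `cov_basis` object.
#' @param dir Output directory, created if absent.
#' @return Invisibly, the manifest as a list.
#' @export
export_components <- function(basis, dir) {
  stopifnot(inherits(basis, "cov_basis"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest <- list(label = basis$label, n_samples = basis$n_samples,
                   p = basis$p, components = list())
  for (i in seq_along(basis$components)) {
    comp <- basis$components[[i]]
    file <- sprintf("component_%02d.tsv", i)
    utils::write.table(comp$matrix, file.path(dir, file), sep = "\t",
                       row.names = FALSE, col.names = FALSE)
    manifest$components[[i]] <- list(
      file = file, kind = comp$kind,
      order = if (is.na(comp$order)) NULL else comp$order,
      alpha = if (is.na(comp$alpha)) NULL else comp$alpha,
      q = if (is.na(comp$q)) NULL else comp$q,
      decay = if (is.na(comp$decay)) NULL else comp$decay)
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' @export
print.cov_basis <- function(x, ...) {
  cat(sprintf("<cov_basis '%s': %d components, n = %d>\n",
              x$label, length(x$components), x$n_samples))
  invisible(x)
}
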