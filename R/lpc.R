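# Latent principal components (LPCs) of a selected waveband: PCA of the
# calibration samples restricted to the window's channels, components sorted
# by descending explained variance. Validation and testing spectra are always
# projected with the calibration-fitted basis, never refit.

#' Fit the latent-principal-component basis of a waveband
#'
#' Principal components of the mean-centered calibration matrix restricted
#' to one waveband, computed by singular-value decomposition. Components are
#' ordered by descending explained variance and each loading's sign is fixed
#' so that its largest-magnitude entry is positive. All components whose
#' singular value exceeds `1e-10` times the largest are kept, so with more
#' samples than channels the LPC count equals the waveband's variable count.
#'
#' @param X numeric calibration matrix restricted to the waveband
#'   (samples x N), at least 2 rows.
#' @param window optional list with `S` and `N` recorded for provenance.
#' @return An object of class `lpc_basis`: `column_means` (length N),
#'   `loadings` (N x m, orthonormal columns), `explained_variance`
#'   (length m, non-increasing, denominator n - 1), `m`, `window`.
#' @export
fit_lpc <- function(X, window = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 calibration samples to fit LPCs")
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  sv <- svd(Xc)
  keep <- sv$d > 1e-10 * sv$d[1L]
  m <- sum(keep)
  V <- sv$v[, seq_len(m), drop = FALSE]
  # deterministic sign: largest-magnitude loading entry positive
  for (j in seq_len(m)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  structure(list(window = window,
                 column_means = mu,
                 loadings = V,
                 explained_variance = sv$d[seq_len(m)]^2 / (n - 1L),
                 m = m),
            class = "lpc_basis")
}

#' @export
print.lpc_basis <- function(x, ...) {
  cat(sprintf("<lpc_basis> %d LPCs over %d variables\n",
              x$m, length(x$column_means)))
  ev <- x$explained_variance
  cat(sprintf("  leading share of variance: %.1f%%\n",
              100 * ev[1L] / sum(ev)))
  invisible(x)
}

#' Project spectra onto an LPC basis
#'
#' Centers by the calibration column means stored in the basis, then maps
#' onto the loadings. Use this for calibration, validation and testing rows
#' alike; the basis is never refit on new samples.
#'
#' @param basis an [fit_lpc()] basis.
#' @param X numeric matrix (samples x N) restricted to the same waveband
#'   (a vector is taken as one spectrum).
#' @return Score matrix, samples x m.
#' @export
project_lpc <- function(basis, X) {
  stopifnot(inherits(basis, "lpc_basis"))
  X <- if (is.null(dim(X))) matrix(X, nrow = 1L) else as.matrix(X)
  if (ncol(X) != length(basis$column_means)) {
    stop(sprintf("`X` has %d columns; basis expects %d",
                 ncol(X), length(basis$column_means)))
  }
  out <- sweep(X, 2L, basis$column_means) %*% basis$loadings
  dimnames(out) <- NULL
  out
}

#' Serialize an LPC basis to CSV
#'
#' Writes a long-format audit table: one row per (variable, component)
#' loading entry plus the per-variable means and per-component variances.
#'
#' @param basis an [fit_lpc()] basis.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_lpc_basis <- function(basis, path) {
  stopifnot(inherits(basis, "lpc_basis"))
  N <- length(basis$column_means)
  df <- data.frame(
    variable = rep(seq_len(N), basis$m),
    component = rep(seq_len(basis$m), each = N),
    loading = as.vector(basis$loadings),
    column_mean = rep(basis$column_means, basis$m),
    explained_variance = rep(basis$explained_variance, each = N))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
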