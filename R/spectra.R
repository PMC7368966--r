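#' Wavelength axis of a spectral dataset
#'
#' A uniformly spaced wavelength axis is defined by its first wavelength, the
#' channel spacing, and the number of channels `P`. Channel `S` (1-based)
#' sits at `start_nm + (S - 1) * step_nm`; both endpoints of a waveband are
#' counted, so a band from `a` to `b` nm holds `(b - a)/step_nm + 1`
#' variables. The default instrument-style axis used throughout the package
#' is 1100 nm start, 2 nm step, 700 channels (last channel 2498 nm).
#'
#' @param start_nm first wavelength in nm.
#' @param step_nm channel spacing in nm, strictly positive.
#' @param count number of channels `P`, integer, at least 1.
#' @return An object of class `wl_axis`.
#' @examples
#' ax <- wl_axis(1100, 2, 700)
#' wavelength_of_index(ax, 441) # 1980
#' @export
wl_axis <- function(start_nm, step_nm, count) {
  stopifnot(is.numeric(start_nm), length(start_nm) == 1L, is.finite(start_nm))
  if (!is.numeric(step_nm) || length(step_nm) != 1L || !is.finite(step_nm) ||
      step_nm <= 0) {
    stop("`step_nm` must be a single positive number")
  }
  count <- as.integer(count)
  if (is.na(count) || count < 1L) stop("`count` must be an integer >= 1")
  structure(list(start_nm = as.numeric(start_nm),
                 step_nm = as.numeric(step_nm),
                 count = count),
            class = "wl_axis")
}

#' @export
print.wl_axis <- function(x, ...) {
  cat(sprintf("<wl_axis> %g-%g nm, step %g nm, %d channels\n",
              x$start_nm, x$start_nm + (x$count - 1L) * x$step_nm,
              x$step_nm, x$count))
  invisible(x)
}

#' Wavelength at a 1-based channel index
#'
#' @param axis a [wl_axis()].
#' @param S 1-based channel index (vectorized).
#' @return Wavelength(s) in nm: `start_nm + (S - 1) * step_nm`.
#' @export
wavelength_of_index <- function(axis, S) {
  stopifnot(inherits(axis, "wl_axis"))
  S <- as.integer(S)
  if (any(is.na(S)) || any(S < 1L) || any(S > axis$count)) {
    stop(sprintf("channel index out of range 1..%d", axis$count))
  }
  axis$start_nm + (S - 1L) * axis$step_nm
}

#' 1-based channel index of a wavelength
#'
#' Inverse of [wavelength_of_index()]; the wavelength must lie on the axis
#' grid (within a small tolerance of a channel position).
#'
#' @param axis a [wl_axis()].
#' @param nm wavelength(s) in nm.
#' @return Integer index/indices in `1..count`.
#' @export
index_of_wavelength <- function(axis, nm) {
  stopifnot(inherits(axis, "wl_axis"), is.numeric(nm))
  idx <- (nm - axis$start_nm) / axis$step_nm + 1
  r <- round(idx)
  if (any(abs(idx - r) > 1e-6)) {
    stop("wavelength not on the axis grid")
  }
  r <- as.integer(r)
  if (any(r < 1L) || any(r > axis$count)) {
    stop(sprintf("wavelength outside the axis range (index 1..%d)",
                 axis$count))
  }
  r
}

#' All wavelengths of an axis
#' @param axis a [wl_axis()].
#' @return Numeric vector of length `count`.
#' @export
axis_wavelengths <- function(axis) {
  stopifnot(inherits(axis, "wl_axis"))
  axis$start_nm + (seq_len(axis$count) - 1L) * axis$step_nm
}

#' Number of variables in a closed waveband
#'
#' Counts the channels of a closed interval `[start_nm, end_nm]` on a grid
#' with the given spacing; both endpoints are included, so 1446-1520 nm at
#' 2 nm spacing holds 38 variables.
#'
#' @param start_nm,end_nm interval endpoints in nm, `end_nm >= start_nm`.
#' @param step_nm channel spacing in nm.
#' @return Integer variable count `(end_nm - start_nm)/step_nm + 1`.
#' @export
span_variable_count <- function(start_nm, end_nm, step_nm) {
  stopifnot(is.numeric(start_nm), is.numeric(end_nm), is.numeric(step_nm),
            step_nm > 0)
  if (end_nm < start_nm) stop("`end_nm` must be >= `start_nm`")
  k <- (end_nm - start_nm) / step_nm
  if (abs(k - round(k)) > 1e-6) {
    stop("interval span is not a multiple of `step_nm`")
  }
  as.integer(round(k)) + 1L
}

#' Spectral dataset container
#'
#' Bundles a wavelength axis, an absorbance matrix (samples in rows, channels
#' in columns), one reference value per sample (the analyte content, e.g.
#' protein in wt.%), and sample identifiers.
#'
#' @param axis a [wl_axis()] whose `count` equals `ncol(absorbance)`.
#' @param absorbance numeric matrix, samples x channels, no missing values.
#' @param y numeric reference values, one per sample.
#' @param sample_ids optional character labels; defaults to `s1, s2, ...`.
#' @return An object of class `spectral_dataset`.
#' @export
spectral_dataset <- function(axis, absorbance, y, sample_ids = NULL) {
  stopifnot(inherits(axis, "wl_axis"))
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  if (ncol(absorbance) != axis$count) {
    stop(sprintf("absorbance has %d columns but the axis has %d channels",
                 ncol(absorbance), axis$count))
  }
  if (anyNA(absorbance)) stop("absorbance contains missing values")
  y <- as.numeric(y)
  if (length(y) != nrow(absorbance)) {
    stop("`y` length must equal the number of spectra")
  }
  if (anyNA(y)) stop("`y` contains missing values")
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(absorbance)))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(absorbance)) {
    stop("`sample_ids` length must equal the number of spectra")
  }
  if (anyDuplicated(sample_ids)) stop("`sample_ids` must be unique")
  dimnames(absorbance) <- NULL
  structure(list(axis = axis, absorbance = absorbance, y = y,
                 sample_ids = sample_ids),
            class = "spectral_dataset")
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat(sprintf("<spectral_dataset> %d samples x %d channels (%g-%g nm)\n",
              nrow(x$absorbance), x$axis$count, x$axis$start_nm,
              x$axis$start_nm + (x$axis$count - 1L) * x$axis$step_nm))
  cat(sprintf("  reference: mean %.3f, sd %.3f\n",
              mean(x$y), stats::sd(x$y)))
  invisible(x)
}

#' @export
dim.spectral_dataset <- function(x) dim(x$absorbance)

#' Subset a spectral dataset by sample
#'
#' @param dataset a [spectral_dataset()].
#' @param i sample indices (integer or logical).
#' @return A `spectral_dataset` with the selected rows.
#' @export
subset_samples <- function(dataset, i) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  spectral_dataset(dataset$axis,
                   dataset$absorbance[i, , drop = FALSE],
                   dataset$y[i],
                   dataset$sample_ids[i])
}

#' Standard normal variate (SNV) preprocessing
#'
#' Centers and scales each spectrum (row) independently to mean 0 and unit
#' standard deviation (sample SD, denominator n - 1), the usual correction
#' for multiplicative scatter differences between samples. The axis and
#' reference values are unchanged.
#'
#' @param dataset a [spectral_dataset()]; every row must have nonzero SD.
#' @return The transformed `spectral_dataset`.
#' @export
snv_transform <- function(dataset) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  X <- dataset$absorbance
  m <- rowMeans(X)
  s <- apply(X, 1L, stats::sd)
  bad <- which(s == 0 | !is.finite(s))
  if (length(bad)) {
    stop(sprintf("SNV undefined for constant spectrum of sample '%s'",
                 dataset$sample_ids[bad[1L]]))
  }
  spectral_dataset(dataset$axis, (X - m) / s, dataset$y, dataset$sample_ids)
}

#' Read a spectral dataset from delimited text
#'
#' Expects comma-separated text with a header row: first column `sample_id`,
#' second column `reference`, remaining columns headed by wavelength in nm
#' with uniform spacing.
#'
#' @param path file path.
#' @return A [spectral_dataset()].
#' @export
read_dataset <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) {
    stop("dataset file needs `sample_id`, `reference` and wavelength columns")
  }
  if (!identical(names(df)[1:2], c("sample_id", "reference"))) {
    stop("first two columns must be `sample_id` and `reference`")
  }
  wl <- suppressWarnings(as.numeric(names(df)[-(1:2)]))
  if (anyNA(wl)) stop("wavelength headers must be numeric (nm)")
  if (length(wl) > 1L) {
    steps <- diff(wl)
    if (any(steps <= 0) || diff(range(steps)) > 1e-6 * max(abs(steps))) {
      stop("wavelength headers must be strictly increasing and uniformly spaced")
    }
    step <- steps[1L]
  } else {
    step <- 1
  }
  X <- as.matrix(df[, -(1:2), drop = FALSE])
  if (!is.numeric(X) || anyNA(X)) stop("non-numeric or missing absorbance cells")
  y <- suppressWarnings(as.numeric(df$reference))
  if (anyNA(y)) stop("non-numeric reference values")
  spectral_dataset(wl_axis(wl[1L], step, length(wl)), X, y, df$sample_id)
}

#' Write a spectral dataset to delimited text
#'
#' Inverse of [read_dataset()]: comma-separated with `sample_id`,
#' `reference`, then one column per wavelength.
#'
#' @param dataset a [spectral_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  df <- data.frame(sample_id = dataset$sample_ids,
                   reference = dataset$y,
                   check.names = FALSE)
  X <- as.data.frame(dataset$absorbance)
  names(X) <- format(axis_wavelengths(dataset$axis), trim = TRUE,
                     scientific = FALSE, drop0trailing = TRUE)
  utils::write.csv(cbind(df, X), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
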