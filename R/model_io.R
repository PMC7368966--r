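# Plain-text serialization of the final calibration model, so a fitted
# pipeline result can be audited and re-applied to new spectra without
# rerunning the search. The format is line-oriented `key=values` with
# comma-separated numbers; the loadings matrix is stored one column per line.

#' Save the final calibration model of a pipeline run
#'
#' Writes everything needed to predict new spectra: the waveband location,
#' the LPC basis fitted on the calibration samples (column means and
#' loadings), the GA-selected component flags, and the least-squares
#' coefficients of the final regression. The file is plain text.
#'
#' @param report a [run_framework()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_framework_model <- function(report, path) {
  stopifnot(inherits(report, "framework_report"))
  b <- report$best
  num <- function(x) paste(format(x, digits = 17, trim = TRUE,
                                  scientific = TRUE), collapse = ",")
  lines <- c(
    sprintf("start_nm=%s", num(b$start_nm)),
    sprintf("step_nm=%s", num(report$gsmw$axis$step_nm)),
    sprintf("axis_start_nm=%s", num(report$gsmw$axis$start_nm)),
    sprintf("axis_count=%d", report$gsmw$axis$count),
    sprintf("S=%d", b$S),
    sprintf("N=%d", b$N),
    sprintf("chromosome=%s", paste(b$chromosome, collapse = ",")),
    sprintf("intercept=%s", num(b$intercept)),
    sprintf("coefficients=%s", num(b$coefficients)),
    sprintf("column_means=%s", num(b$basis$column_means)))
  for (j in seq_len(b$basis$m)) {
    lines <- c(lines, sprintf("loading_%d=%s", j, num(b$basis$loadings[, j])))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Load a saved calibration model
#'
#' @param path file written by [write_framework_model()].
#' @return An object of class `nirwaveband_model`.
#' @export
read_framework_model <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, `[[`, "", 1L)
  vals <- lapply(kv, function(p) as.numeric(strsplit(p[2L], ",")[[1L]]))
  names(vals) <- keys
  need <- c("S", "N", "chromosome", "intercept", "coefficients",
            "column_means", "axis_start_nm", "step_nm", "axis_count")
  if (!all(need %in% keys)) {
    stop("model file is missing fields: ",
         paste(setdiff(need, keys), collapse = ", "))
  }
  lk <- grep("^loading_", keys)
  loadings <- do.call(cbind, vals[lk[order(as.integer(
    sub("loading_", "", keys[lk])))]])
  structure(list(axis = wl_axis(vals$axis_start_nm, vals$step_nm,
                                vals$axis_count),
                 S = as.integer(vals$S),
                 N = as.integer(vals$N),
                 chromosome = as.integer(vals$chromosome),
                 intercept = vals$intercept,
                 coefficients = vals$coefficients,
                 column_means = vals$column_means,
                 loadings = loadings),
            class = "nirwaveband_model")
}

#' @export
print.nirwaveband_model <- function(x, ...) {
  cat(sprintf(
    "<nirwaveband_model> waveband %g-%g nm (N=%d), %d/%d LPCs selected\n",
    wavelength_of_index(x$axis, x$S),
    wavelength_of_index(x$axis, x$S + x$N - 1L),
    x$N, sum(x$chromosome), length(x$chromosome)))
  invisible(x)
}

#' Predict analyte values for new spectra with a saved model
#'
#' Applies the stored pipeline to a raw dataset: SNV preprocessing,
#' restriction to the model's waveband, projection onto the stored LPC
#' basis, and the final linear regression on the selected components.
#'
#' @param object a [read_framework_model()] model (or the same structure
#'   built in-session).
#' @param newdata a raw [spectral_dataset()] on the same wavelength axis.
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.nirwaveband_model <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "spectral_dataset"))
  if (newdata$axis$count != object$axis$count ||
      newdata$axis$start_nm != object$axis$start_nm ||
      newdata$axis$step_nm != object$axis$step_nm) {
    stop("`newdata` axis does not match the model's axis")
  }
  snv <- snv_transform(newdata)
  cols <- seq.int(object$S, object$S + object$N - 1L)
  scores <- sweep(snv$absorbance[, cols, drop = FALSE], 2L,
                  object$column_means) %*% object$loadings
  sel <- which(object$chromosome != 0)
  drop(object$intercept +
         scores[, sel, drop = FALSE] %*% object$coefficients)
}
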