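# PLS1 regression via NIPALS with X-only deflation, and the RMSE / R
# evaluation metrics used throughout the pipeline.

# Core NIPALS PLS1 decomposition on mean-centered data. For univariate y the
# weight vector per component is exact (w = E'f / ||E'f||), no inner
# iteration. Deflation of X only. Stops early if the residual covariance
# vanishes. Returns weights W, loadings Pl, y-loadings q per component.
nipals_pls1 <- function(Xc, yc, ncomp, tol = 1e-12) {
  E <- Xc
  f <- yc
  p <- ncol(Xc)
  W <- matrix(0, p, ncomp)
  Pl <- matrix(0, p, ncomp)
  q <- numeric(ncomp)
  a <- 0L
  for (k in seq_len(ncomp)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw < tol) break
    w <- w / nw
    t <- E %*% w
    tt <- sum(t^2)
    if (tt < tol) break
    Pl[, k] <- crossprod(E, t) / tt
    q[k] <- sum(f * t) / tt
    W[, k] <- w
    E <- E - tcrossprod(t, Pl[, k])
    a <- k
  }
  list(W = W[, seq_len(a), drop = FALSE],
       P = Pl[, seq_len(a), drop = FALSE],
       q = q[seq_len(a)],
       ncomp = a)
}

#' Fit a PLS1 regression model
#'
#' Partial least squares with a single response, computed by the NIPALS
#' algorithm: each latent variable is the direction of maximum covariance
#' between the (deflated) spectra and the centered response. Predictors and
#' response are mean-centered; columns are not autoscaled by default since
#' SNV-preprocessed spectra are already row-normalized.
#'
#' @param X numeric calibration matrix, samples x variables, at least 2 rows.
#' @param y numeric response, one value per row of `X`; must not be constant.
#' @param n_components number of latent variables `A`,
#'   `0 <= A <= min(nrow(X) - 1, ncol(X))`. `A = 0` gives the intercept-only
#'   model (predicting `mean(y)` everywhere).
#' @param autoscale if `TRUE`, columns of `X` are also scaled to unit SD
#'   before fitting (default `FALSE`).
#' @return An object of class `pls_model` with the centering vectors, NIPALS
#'   weights/loadings and the regression coefficient vector.
#' @export
fit_pls <- function(X, y, n_components, autoscale = FALSE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  p <- ncol(X)
  if (n < 2L) stop("need at least 2 calibration samples")
  if (length(y) != n) stop("`y` length must equal `nrow(X)`")
  A <- as.integer(n_components)
  amax <- min(n - 1L, p)
  if (is.na(A) || A < 0L || A > amax) {
    stop(sprintf("`n_components` must be between 0 and %d", amax))
  }
  if (stats::sd(y) == 0) stop("`y` has zero variance")
  x_mean <- colMeans(X)
  x_scale <- if (autoscale) {
    s <- apply(X, 2L, stats::sd)
    s[s == 0] <- 1
    s
  } else {
    rep(1, p)
  }
  Xc <- sweep(X, 2L, x_mean) / rep(x_scale, each = n)
  y_mean <- mean(y)
  if (A == 0L) {
    dec <- list(W = matrix(0, p, 0), P = matrix(0, p, 0), q = numeric(0),
                ncomp = 0L)
    beta <- numeric(p)
  } else {
    dec <- nipals_pls1(Xc, y - y_mean, A)
    if (dec$ncomp < A) {
      warning(sprintf("rank deficiency: only %d of %d components extracted",
                      dec$ncomp, A))
    }
    beta <- if (dec$ncomp > 0L) {
      # b = W (P'W)^{-1} q ; P'W is unit upper triangular in NIPALS PLS1
      drop(dec$W %*% solve(crossprod(dec$P, dec$W), dec$q))
    } else {
      numeric(p)
    }
  }
  structure(list(n_components = dec$ncomp,
                 x_mean = x_mean, x_scale = x_scale, y_mean = y_mean,
                 weights = dec$W, loadings = dec$P, y_loadings = dec$q,
                 coefficients = beta / x_scale,
                 autoscale = autoscale),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d latent variable(s), %d predictors\n",
              x$n_components, length(x$x_mean)))
  invisible(x)
}

#' Predict from a fitted PLS model
#'
#' @param object a [fit_pls()] model.
#' @param newdata numeric matrix with the same number of columns the model
#'   was fitted on (a vector is taken as one spectrum).
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  X <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1L) else
    as.matrix(newdata)
  if (ncol(X) != length(object$x_mean)) {
    stop(sprintf("`newdata` has %d columns; model expects %d",
                 ncol(X), length(object$x_mean)))
  }
  drop(object$y_mean + sweep(X, 2L, object$x_mean) %*% object$coefficients)
}

#' Evaluate predictions with RMSE and the correlation coefficient
#'
#' The root mean square error uses denominator `n` (the convention of NIR
#' calibration reporting), and `R` is the Pearson product-moment correlation
#' between measured and predicted values. If either vector has zero
#' variance, `R` is undefined: `r` is `NA` and `r_defined` is `FALSE`.
#'
#' @param y_true measured reference values.
#' @param y_pred model predictions, same length.
#' @param which_set optional label: `"calibration"`, `"validation"` or
#'   `"testing"`.
#' @return An object of class `evaluation_report`: list with `rmse`, `r`,
#'   `r_defined`, `n`, `which_set`.
#' @export
evaluate_predictions <- function(y_true, y_pred, which_set = NA_character_) {
  y_true <- as.numeric(y_true)
  y_pred <- as.numeric(y_pred)
  n <- length(y_true)
  if (n == 0L || length(y_pred) != n) {
    stop("`y_true` and `y_pred` must have equal nonzero length")
  }
  rmse <- sqrt(mean((y_true - y_pred)^2))
  st <- stats::sd(y_true)
  sp <- stats::sd(y_pred)
  if (n < 2L || st == 0 || sp == 0) {
    r <- NA_real_
    r_defined <- FALSE
  } else {
    r <- stats::cor(y_true, y_pred)
    r_defined <- TRUE
  }
  structure(list(rmse = rmse, r = r, r_defined = r_defined, n = n,
                 which_set = which_set),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report>%s n = %d, RMSE = %.4f, R = %s\n",
              if (is.na(x$which_set)) "" else paste0(" ", x$which_set, ":"),
              x$n, x$rmse,
              if (x$r_defined) sprintf("%.4f", x$r) else "undefined"))
  invisible(x)
}

# Validation-error scan over latent-variable counts, the inner loop of the
# moving-window search. One NIPALS pass extracts up to `max_lv` components;
# validation predictions are accumulated component by component, so RMSEV
# and R_V for every A = 1..max_lv come out of a single decomposition.
# Returns vectors rmsev/r_v indexed by A (length = components extracted).
pls_rmsev_scan <- function(X_cal, y_cal, X_val, y_val, max_lv,
                           tol = 1e-12) {
  n <- nrow(X_cal)
  x_mean <- colMeans(X_cal)
  y_mean <- mean(y_cal)
  E <- sweep(X_cal, 2L, x_mean)
  Ev <- sweep(X_val, 2L, x_mean)
  f <- y_cal - y_mean
  rmsev <- numeric(max_lv)
  r_v <- numeric(max_lv)
  yhat <- rep(y_mean, nrow(X_val))
  sv_y <- stats::sd(y_val)
  a <- 0L
  for (k in seq_len(max_lv)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw < tol) break
    w <- w / nw
    t <- E %*% w
    tt <- sum(t^2)
    if (tt < tol) break
    p <- crossprod(E, t) / tt
    q <- sum(f * t) / tt
    E <- E - tcrossprod(t, p)
    tv <- Ev %*% w
    Ev <- Ev - tcrossprod(tv, p)
    yhat <- yhat + q * tv
    a <- k
    rmsev[k] <- sqrt(mean((y_val - yhat)^2))
    sh <- stats::sd(yhat)
    r_v[k] <- if (sv_y > 0 && sh > 0) stats::cor(y_val, yhat) else NA_real_
  }
  list(rmsev = rmsev[seq_len(a)], r_v = r_v[seq_len(a)], ncomp = a)
}
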