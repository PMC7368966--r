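# Independent oracles used across the suite. Each re-derives the quantity
# under test by a different computational route than the package code.

# PLS1 predictions equal least squares on the Krylov space
# span{X'y, (X'X)X'y, ...}; this oracle builds that basis explicitly with
# modified Gram-Schmidt (re-orthogonalized) and regresses on it, never
# touching the NIPALS deflation path. Returns RMSEV per component count.
oracle_pls_rmsev_scan <- function(Xc, yc, Xv, yv, max_lv) {
  xm <- colMeans(Xc)
  ym <- mean(yc)
  E <- sweep(Xc, 2, xm)
  Ev <- sweep(Xv, 2, xm)
  f <- yc - ym
  C <- crossprod(E)
  v <- crossprod(E, f)
  scale0 <- sqrt(sum(v^2))
  V <- matrix(0, ncol(E), 0)
  rmse <- numeric(0)
  for (a in seq_len(max_lv)) {
    if (ncol(V) > 0) {
      v <- v - V %*% crossprod(V, v)
      v <- v - V %*% crossprod(V, v)
    }
    nv <- sqrt(sum(v^2))
    if (nv < 1e-8 * scale0) break
    v <- v / nv
    V <- cbind(V, v)
    beta <- qr.coef(qr(E %*% V), f)
    beta[is.na(beta)] <- 0
    yhat <- ym + drop(Ev %*% V %*% beta)
    rmse[a] <- sqrt(mean((yv - yhat)^2))
    v <- C %*% V[, a, drop = FALSE]
  }
  rmse
}

# Ordinary least squares with intercept by explicit normal equations.
oracle_ols_predict <- function(Xc, yc, Xv) {
  A <- cbind(1, Xc)
  beta <- solve(crossprod(A), crossprod(A, yc))
  drop(cbind(1, Xv) %*% beta)
}

# Closed-form simple linear regression on one predictor.
oracle_simple_regression_predict <- function(x, y, xnew) {
  b <- stats::cov(x, y) / stats::var(x)
  a <- mean(y) - b * mean(x)
  a + b * xnew
}

# SPXY selection re-derived with plain loops, recomputing every joint
# distance from scratch at each step (no distance matrix reuse).
oracle_spxy <- function(X, y, n_select) {
  n <- nrow(X)
  dxy <- function(i, j) {
    dx <- sqrt(sum((X[i, ] - X[j, ])^2))
    dy <- abs(y[i] - y[j])
    mx <- 0
    my <- 0
    for (a in 1:(n - 1)) {
      for (b in (a + 1):n) {
        mx <- max(mx, sqrt(sum((X[a, ] - X[b, ])^2)))
        my <- max(my, abs(y[a] - y[b]))
      }
    }
    (if (mx > 0) dx / mx else dx) + (if (my > 0) dy / my else dy)
  }
  best <- c(1L, 2L)
  bestd <- -Inf
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      d <- dxy(i, j)
      if (d > bestd) {
        bestd <- d
        best <- c(i, j)
      }
    }
  }
  sel <- best
  while (length(sel) < n_select) {
    cand <- setdiff(seq_len(n), sel)
    bi <- NA_integer_
    bd <- -Inf
    for (i in cand) {
      dmin <- Inf
      for (j in sel) dmin <- min(dmin, dxy(i, j))
      if (dmin > bd) {
        bd <- dmin
        bi <- i
      }
    }
    sel <- c(sel, bi)
  }
  sel
}

# Exhaustive search over all nonempty chromosome subsets.
oracle_best_subset <- function(scores_cal, y_cal, scores_val, y_val) {
  m <- ncol(scores_cal)
  best <- Inf
  best_chrom <- NULL
  for (code in 1:(2^m - 1)) {
    chrom <- as.integer(intToBits(code)[1:m])
    v <- ga_fitness(chrom, scores_cal, y_cal, scores_val, y_val)
    if (v < best) {
      best <- v
      best_chrom <- chrom
    }
  }
  list(rmsev = best, chromosome = best_chrom)
}

# Small seeded regression fixture: spectra-free score matrices with a known
# informative structure (first columns predictive, rest noise).
make_score_fixture <- function(seed, n_cal = 40, n_val = 25, m = 8,
                               informative = 3, noise = 0.3) {
  set.seed(seed)
  sc <- matrix(rnorm((n_cal + n_val) * m), n_cal + n_val, m)
  beta <- c(seq(2, 1, length.out = informative), rep(0, m - informative))
  y <- drop(sc %*% beta) + rnorm(n_cal + n_val, 0, noise)
  list(scores_cal = sc[1:n_cal, , drop = FALSE],
       y_cal = y[1:n_cal],
       scores_val = sc[(n_cal + 1):(n_cal + n_val), , drop = FALSE],
       y_val = y[(n_cal + 1):(n_cal + n_val)])
}

# Synthetic configuration scaled to a short axis: one analyte band at the
# axis midpoint, one interferent band in the lower third.
make_small_config <- function(P, n, seed, ...) {
  ax <- wl_axis(1100, 2, P)
  span <- (P - 1) * 2
  synthetic_config(
    axis = ax, n_samples = n,
    analyte_bands = data.frame(center_nm = 1100 + span / 2,
                               sigma_nm = max(4, span * 0.08),
                               amplitude = 0.01),
    interferents = list(
      list(bands = data.frame(center_nm = 1100 + span * 0.2,
                              sigma_nm = max(4, span * 0.1),
                              amplitude = 0.008),
           conc_mean = 8, conc_sd = 1.5, correlation = 0.3)),
    seed = seed, ...)
}

# Calibration/validation halves of the tiny synthetic fixture, shared by
# the window-search and GA tests.
tiny_cal_val <- function(seed = 1) {
  fx <- standard_fixtures(seed)
  d <- snv_transform(fx$tiny$dataset)
  list(cal = subset_samples(d, 1:18), val = subset_samples(d, 19:30))
}
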