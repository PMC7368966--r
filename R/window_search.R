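# Grid-search moving window (GSMW): exhaustive enumeration of contiguous
# wavebands (N, S) over an N grid, a PLS model with a latent-variable scan
# per window, and ranking of wavebands by validation RMSE.

#' Window width grid
#'
#' The admissible window widths `N` for a moving-window search. The default
#' grid is the dense-to-coarse design used for a 700-channel axis: every
#' width up to 100, then steps of 10 up to 300, then steps of 20 up to 700.
#' A grid can also be given as a spec string such as
#' `"1:1:100,110:10:300,320:20:700"` (`from:by:to` segments).
#'
#' @param n_values integer vector of widths, or a spec string.
#' @return Sorted unique integer vector of widths, class `window_grid`.
#' @examples
#' length(window_grid()) # 140 widths
#' @export
window_grid <- function(n_values = NULL) {
  if (is.null(n_values)) {
    n_values <- c(1:100, seq(110L, 300L, 10L), seq(320L, 700L, 20L))
  } else if (is.character(n_values)) {
    n_values <- parse_grid_spec(n_values)
  }
  n_values <- sort(unique(as.integer(n_values)))
  if (length(n_values) == 0L || anyNA(n_values) || any(n_values < 1L)) {
    stop("window widths must be positive integers")
  }
  structure(n_values, class = "window_grid")
}

parse_grid_spec <- function(spec) {
  parts <- strsplit(spec, ",", fixed = TRUE)[[1L]]
  out <- integer(0)
  for (p in parts) {
    f <- suppressWarnings(as.numeric(strsplit(trimws(p), ":", fixed = TRUE)[[1L]]))
    if (length(f) == 1L && !is.na(f)) {
      out <- c(out, as.integer(f))
    } else if (length(f) == 3L && !anyNA(f)) {
      out <- c(out, as.integer(seq(f[1L], f[3L], by = f[2L])))
    } else {
      stop(sprintf("cannot parse grid segment '%s' (use from:by:to)", p))
    }
  }
  out
}

#' Enumerate all admissible windows
#'
#' For each width `N` in the grid, every start position `S` with
#' `S + N - 1 <= P` is admissible; windows are listed with `N` ascending and
#' `S` ascending within `N`. The total count is `sum(P - N + 1)` over the
#' widths not exceeding `P`.
#'
#' @param P number of channels on the axis.
#' @param grid a [window_grid()] (or width vector / spec string).
#' @return Data frame with integer columns `N` and `S`.
#' @export
enumerate_windows <- function(P, grid = window_grid()) {
  P <- as.integer(P)
  if (is.na(P) || P < 1L) stop("`P` must be an integer >= 1")
  if (!inherits(grid, "window_grid")) grid <- window_grid(grid)
  widths <- as.integer(grid[grid <= P])
  if (length(widths) == 0L) stop("no admissible width in the grid")
  counts <- P - widths + 1L
  data.frame(N = rep(widths, counts),
             S = unlist(lapply(counts, seq_len), use.names = FALSE))
}

window_columns <- function(S, N) seq.int(S, S + N - 1L)

#' Evaluate one window with a latent-variable scan
#'
#' Restricts the calibration and validation spectra to the window's columns,
#' extracts PLS components up to the scan cap, and returns the
#' latent-variable count minimizing the validation RMSE together with its
#' metrics. The cap is `min(lv_cap, N, n_cal - 1)`.
#'
#' @param window list or one-row data frame with `S` (1-based start index)
#'   and `N` (width in variables).
#' @param cal,val calibration and validation [spectral_dataset()]s sharing
#'   one axis.
#' @param lv_cap maximum latent variables scanned (default 15).
#' @return List with `best_lv`, `rmsev`, `r_v`.
#' @export
evaluate_window <- function(window, cal, val, lv_cap = 15L) {
  stopifnot(inherits(cal, "spectral_dataset"),
            inherits(val, "spectral_dataset"))
  if (!identical(unclass(cal$axis), unclass(val$axis))) {
    stop("calibration and validation sets must share one wavelength axis")
  }
  S <- as.integer(window$S)
  N <- as.integer(window$N)
  P <- cal$axis$count
  if (S < 1L || N < 1L || S + N - 1L > P) {
    stop(sprintf("window (N=%d, S=%d) not admissible on a %d-channel axis",
                 N, S, P))
  }
  cols <- window_columns(S, N)
  sc <- pls_rmsev_scan(cal$absorbance[, cols, drop = FALSE], cal$y,
                       val$absorbance[, cols, drop = FALSE], val$y,
                       max_lv = min(lv_cap, N, nrow(cal$absorbance) - 1L))
  if (sc$ncomp == 0L) {
    # degenerate window (zero covariance): intercept-only prediction
    rep0 <- evaluate_predictions(val$y, rep(mean(cal$y), length(val$y)))
    return(list(best_lv = 0L, rmsev = rep0$rmse, r_v = NA_real_))
  }
  best <- which.min(sc$rmsev)
  list(best_lv = best, rmsev = sc$rmsev[best], r_v = sc$r_v[best])
}

#' Grid-search moving-window scan
#'
#' Evaluates every admissible window of the grid with [evaluate_window()]
#' and retains the full validation-error surface. Each window is scored
#' independently, so the result does not depend on evaluation order.
#'
#' @param cal,val calibration and validation [spectral_dataset()]s.
#' @param grid a [window_grid()].
#' @param lv_cap maximum latent variables scanned per window.
#' @return An object of class `gsmw_result`: list with `surface` (data frame
#'   `N, S, start_nm, end_nm, best_lv, rmsev, r_v`, one row per window in
#'   enumeration order), the `grid`, `lv_cap` and the axis.
#' @export
gsmw_search <- function(cal, val, grid = window_grid(), lv_cap = 15L) {
  if (!inherits(grid, "window_grid")) grid <- window_grid(grid)
  wins <- enumerate_windows(cal$axis$count, grid)
  m <- nrow(wins)
  best_lv <- integer(m)
  rmsev <- numeric(m)
  r_v <- numeric(m)
  Xc <- cal$absorbance
  Xv <- val$absorbance
  nc1 <- nrow(Xc) - 1L
  for (i in seq_len(m)) {
    cols <- window_columns(wins$S[i], wins$N[i])
    sc <- pls_rmsev_scan(Xc[, cols, drop = FALSE], cal$y,
                         Xv[, cols, drop = FALSE], val$y,
                         max_lv = min(lv_cap, wins$N[i], nc1))
    if (sc$ncomp == 0L) {
      best_lv[i] <- 0L
      rmsev[i] <- sqrt(mean((val$y - mean(cal$y))^2))
      r_v[i] <- NA_real_
    } else {
      b <- which.min(sc$rmsev)
      best_lv[i] <- b
      rmsev[i] <- sc$rmsev[b]
      r_v[i] <- sc$r_v[b]
    }
  }
  surface <- data.frame(
    N = wins$N, S = wins$S,
    start_nm = wavelength_of_index(cal$axis, wins$S),
    end_nm = wavelength_of_index(cal$axis, wins$S + wins$N - 1L),
    best_lv = best_lv, rmsev = rmsev, r_v = r_v)
  structure(list(surface = surface, grid = grid, lv_cap = lv_cap,
                 axis = cal$axis),
            class = "gsmw_result")
}

#' @export
print.gsmw_result <- function(x, ...) {
  cat(sprintf("<gsmw_result> %d windows evaluated, %d widths, LV cap %d\n",
              nrow(x$surface), length(x$grid), x$lv_cap))
  top <- x$surface[order(x$surface$rmsev, x$surface$N, x$surface$S), ][1L, ]
  cat(sprintf("  best: %g-%g nm (N=%d, S=%d), RMSEV %.4f\n",
              top$start_nm, top$end_nm, top$N, top$S, top$rmsev))
  invisible(x)
}

#' Select the top non-overlapping wavebands
#'
#' Greedy selection by ascending validation RMSE, skipping any window whose
#' channel range overlaps an already-selected window, so the chosen
#' wavebands are disjoint regions of the spectrum. Ties in RMSEV are broken
#' by smaller `N`, then smaller `S`.
#'
#' @param result a [gsmw_search()] result.
#' @param k number of wavebands to return (default 5). If fewer disjoint
#'   windows exist, returns what is available with a warning.
#' @return Data frame of selected rows of the surface, in selection order,
#'   with a `rank` column.
#' @export
select_top_windows <- function(result, k = 5L) {
  stopifnot(inherits(result, "gsmw_result"))
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("`k` must be >= 1")
  s <- result$surface[order(result$surface$rmsev, result$surface$N,
                            result$surface$S), ]
  sel <- integer(0)
  for (i in seq_len(nrow(s))) {
    lo <- s$S[i]
    hi <- s$S[i] + s$N[i] - 1L
    overlap <- FALSE
    for (j in sel) {
      lo_j <- s$S[j]
      hi_j <- s$S[j] + s$N[j] - 1L
      if (lo <= hi_j && lo_j <= hi) {
        overlap <- TRUE
        break
      }
    }
    if (!overlap) {
      sel <- c(sel, i)
      if (length(sel) == k) break
    }
  }
  if (length(sel) < k) {
    warning(sprintf("only %d disjoint windows available (requested %d)",
                    length(sel), k))
  }
  out <- s[sel, ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
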