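# Sample-set partitioning: a random testing holdout picked first, then SPXY
# (joint x-y distance, Kennard-Stone style) selection of the calibration part
# from the remaining modeling samples.

local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Random testing-set holdout
#'
#' Draws a uniformly random testing subset before any model-driven selection,
#' so the testing samples never inform calibration decisions. Deterministic
#' for a fixed seed.
#'
#' @param dataset a [spectral_dataset()].
#' @param n_test number of testing samples, `0 < n_test < n`.
#' @param seed integer RNG seed.
#' @return List with integer index vectors `modeling` and `testing`
#'   (both sorted ascending).
#' @export
random_holdout <- function(dataset, n_test, seed) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  n <- nrow(dataset$absorbance)
  n_test <- as.integer(n_test)
  if (is.na(n_test) || n_test <= 0L || n_test >= n) {
    stop(sprintf("`n_test` must satisfy 0 < n_test < %d", n))
  }
  testing <- sort(local_seed(seed, sample.int(n, n_test)))
  list(modeling = setdiff(seq_len(n), testing), testing = testing)
}

# Pairwise joint x-y distance matrix: Euclidean distances in spectral space
# and in reference-value space, each normalized by its maximum over the pool.
spxy_distance <- function(X, y) {
  dx <- as.matrix(stats::dist(X))
  dy <- abs(outer(y, y, "-"))
  mx <- max(dx)
  my <- max(dy)
  if (mx > 0) dx <- dx / mx
  if (my > 0) dy <- dy / my
  dx + dy
}

#' SPXY sample selection
#'
#' Kennard-Stone-style greedy selection on the joint distance
#' `d(i,j) = d_x(i,j)/max(d_x) + d_y(i,j)/max(d_y)`, where `d_x` is the
#' Euclidean distance between spectra and `d_y = |y_i - y_j|`. The first two
#' picks are the pair at maximum joint distance; every later pick maximizes
#' its minimum joint distance to the already-selected set. Fully
#' deterministic; ties are broken by the lowest sample index.
#'
#' @param X numeric matrix of (preprocessed) spectra, samples in rows.
#' @param y numeric reference values.
#' @param n_select how many samples to select, `2 <= n_select <= nrow(X)`.
#' @return Integer vector of selected row indices, in selection order.
#' @export
spxy_select <- function(X, y, n_select) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(y) == n)
  n_select <- as.integer(n_select)
  if (is.na(n_select) || n_select < 2L) stop("`n_select` must be >= 2")
  if (n_select > n) stop("`n_select` exceeds the number of samples")
  D <- spxy_distance(X, y)
  # seed pair: maximum joint distance, lowest (i, j) on ties
  best <- c(1L, 2L)
  bestd <- -Inf
  for (i in seq_len(n - 1L)) {
    j <- which.max(D[i, (i + 1L):n]) + i
    if (D[i, j] > bestd) {
      bestd <- D[i, j]
      best <- c(i, j)
    }
  }
  selected <- as.integer(unname(best))
  remaining <- setdiff(seq_len(n), selected)
  while (length(selected) < n_select) {
    # min distance from each remaining candidate to the selected set
    dmin <- apply(D[remaining, selected, drop = FALSE], 1L, min)
    pick <- remaining[which.max(dmin)] # which.max takes the first (lowest index) tie
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
  }
  as.integer(unname(selected))
}

#' Split a dataset into calibration, validation and testing parts
#'
#' The testing set is drawn first by [random_holdout()]; the calibration part
#' is then chosen from the modeling samples by [spxy_select()] (distances on
#' the dataset as passed in, which the pipeline supplies SNV-preprocessed);
#' the validation part is what remains.
#'
#' @param dataset a [spectral_dataset()].
#' @param n_cal,n_val,n_test part sizes; must sum to the sample count, with
#'   `n_cal >= 2`, `n_val >= 1`, `n_test >= 1`.
#' @param seed integer RNG seed for the testing holdout.
#' @return An object of class `split_indices`: list with sorted integer
#'   vectors `calibration`, `validation`, `testing`, plus
#'   `calibration_order` (SPXY selection order).
#' @export
split_dataset <- function(dataset, n_cal, n_val, n_test, seed) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  n <- nrow(dataset$absorbance)
  n_cal <- as.integer(n_cal); n_val <- as.integer(n_val)
  n_test <- as.integer(n_test)
  if (n_cal + n_val + n_test != n) {
    stop(sprintf("part sizes %d + %d + %d must sum to %d",
                 n_cal, n_val, n_test, n))
  }
  if (n_cal < 2L) stop("`n_cal` must be >= 2")
  if (n_val < 1L) stop("`n_val` must be >= 1 (validation must be nonempty)")
  hold <- random_holdout(dataset, n_test, seed)
  pool <- hold$modeling
  ord <- spxy_select(dataset$absorbance[pool, , drop = FALSE],
                     dataset$y[pool], n_cal)
  cal <- pool[ord]
  structure(list(calibration = sort(cal),
                 validation = sort(setdiff(pool, cal)),
                 testing = hold$testing,
                 calibration_order = cal),
            class = "split_indices")
}

#' @export
print.split_indices <- function(x, ...) {
  cat(sprintf("<split_indices> calibration %d, validation %d, testing %d\n",
              length(x$calibration), length(x$validation), length(x$testing)))
  invisible(x)
}
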