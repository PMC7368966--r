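# Binary genetic algorithm over LPC candidates. Chromosomes are 0/1 flag
# vectors (1 = component enters the regression); fitness is the validation
# RMSE of a least-squares fit on the flagged score columns. Tournament
# selection (size 2), single-point crossover, per-bit mutation, elitism, and
# two stopping rules: an iteration cap and a stall window on the best RMSEV.

#' Genetic-algorithm configuration
#'
#' Probabilities are given in percent, matching how GA settings are usually
#' quoted in calibration work (crossover commonly 50%, per-bit mutation
#' 1.2%, 500 iterations).
#'
#' @param p_crossover per-pair probability that crossover occurs, in percent
#'   (0, 100).
#' @param p_mutation per-bit flip probability, in percent \[0, 100).
#' @param max_iterations iteration cap (stopping condition 1), default 500.
#' @param stall_window iterations of unchanged best RMSEV that trigger the
#'   adaptive stop (stopping condition 2), default 20.
#' @param stall_tolerance change in best RMSEV below which an iteration
#'   counts as unchanged, default `1e-6`. Set negative to disable the
#'   adaptive stop entirely.
#' @param population_size even integer >= 4, or `NULL` for the default
#'   `max(20, 2 * chromosome length)` rounded up to even.
#' @param seed integer RNG seed.
#' @return An object of class `ga_config`; probabilities stored as
#'   fractions (`pc`, `pm`) alongside the percent inputs.
#' @export
ga_config <- function(p_crossover = 50, p_mutation = 1.2,
                      max_iterations = 500L, stall_window = 20L,
                      stall_tolerance = 1e-6, population_size = NULL,
                      seed = 1L) {
  pc <- p_crossover / 100
  pm <- p_mutation / 100
  if (!is.finite(pc) || pc <= 0 || pc >= 1) {
    stop("`p_crossover` must be in (0, 100) percent")
  }
  if (!is.finite(pm) || pm < 0 || pm >= 1) {
    stop("`p_mutation` must be in [0, 100) percent")
  }
  max_iterations <- as.integer(max_iterations)
  stall_window <- as.integer(stall_window)
  if (max_iterations < 1L) stop("`max_iterations` must be >= 1")
  if (stall_window < 1L) stop("`stall_window` must be >= 1")
  if (!is.null(population_size)) {
    population_size <- as.integer(population_size)
    if (population_size < 4L || population_size %% 2L != 0L) {
      stop("`population_size` must be an even integer >= 4")
    }
  }
  structure(list(p_crossover = p_crossover, p_mutation = p_mutation,
                 pc = pc, pm = pm,
                 max_iterations = max_iterations,
                 stall_window = stall_window,
                 stall_tolerance = stall_tolerance,
                 population_size = population_size,
                 seed = as.integer(seed)),
            class = "ga_config")
}

default_population_size <- function(chrom_len) {
  n <- max(20L, 2L * chrom_len)
  if (n %% 2L != 0L) n <- n + 1L
  n
}

#' Fitness of a chromosome: validation RMSE of the flagged subset
#'
#' Regresses the calibration response on the flagged score columns by least
#' squares with intercept, then scores the validation rows. The LPC scores
#' are orthogonal on the calibration set, so the least-squares fit is stable
#' and coincides with a full-rank PLS on the same columns. An all-zero
#' chromosome gets `Inf` (a sentinel that is never selected as best).
#'
#' @param chromosome 0/1 vector over the candidate columns.
#' @param scores_cal,scores_val score matrices (samples x m).
#' @param y_cal,y_val responses.
#' @return Validation RMSE (denominator n).
#' @export
ga_fitness <- function(chromosome, scores_cal, y_cal, scores_val, y_val) {
  sel <- which(chromosome != 0)
  if (length(sel) == 0L) return(Inf)
  fit <- stats::lm.fit(cbind(1, scores_cal[, sel, drop = FALSE]), y_cal)
  coefs <- fit$coefficients
  coefs[is.na(coefs)] <- 0
  pred <- drop(cbind(1, scores_val[, sel, drop = FALSE]) %*% coefs)
  sqrt(mean((y_val - pred)^2))
}

# Predictions of a chromosome's model on new score rows (used for the final
# testing evaluation). Coefficients are fit on the calibration scores.
ga_predict <- function(chromosome, scores_cal, y_cal, scores_new) {
  sel <- which(chromosome != 0)
  if (length(sel) == 0L) return(rep(mean(y_cal), nrow(scores_new)))
  fit <- stats::lm.fit(cbind(1, scores_cal[, sel, drop = FALSE]), y_cal)
  coefs <- fit$coefficients
  coefs[is.na(coefs)] <- 0
  drop(cbind(1, scores_new[, sel, drop = FALSE]) %*% coefs)
}

#' Evolve a population of LPC subsets
#'
#' Runs the binary GA: a random initial population (each flag Bernoulli
#' 1/2, all-zero rows repaired by setting one random bit), then per
#' generation fitness evaluation, tournament selection of parent pairs,
#' single-point crossover with probability `pc`, per-bit mutation with
#' probability `pm`, and elitism (the best individual is carried unchanged,
#' so the best-so-far RMSEV trace is non-increasing). One offspring is kept
#' per parent pair, and a child that duplicates an individual already placed
#' in the new generation is regenerated (with bounded retries), a standard
#' diversity safeguard for small populations. Stops at the
#' iteration cap or when the best RMSEV has been unchanged (within
#' `stall_tolerance`) for `stall_window` consecutive iterations. Fully
#' deterministic for a fixed seed.
#'
#' @param scores_cal,scores_val score matrices (samples x m).
#' @param y_cal,y_val responses.
#' @param config a [ga_config()].
#' @param initial_population optional 0/1 matrix (rows = individuals) to
#'   seed the population instead of random initialization.
#' @return An object of class `ga_trace`: `best_rmsev_per_iteration`,
#'   `stop_iteration`, `stop_reason` (`"max_iterations"` or `"stalled"`),
#'   `best_chromosome`, `best_rmsev`, `best_r_v`, `n_evaluations`, `config`.
#' @export
ga_evolve <- function(scores_cal, y_cal, scores_val, y_val, config,
                      initial_population = NULL) {
  stopifnot(inherits(config, "ga_config"))
  scores_cal <- as.matrix(scores_cal)
  scores_val <- as.matrix(scores_val)
  m <- ncol(scores_cal)
  if (m < 1L) stop("need at least one candidate column")
  if (ncol(scores_val) != m) stop("score matrices must have equal columns")
  tr <- ga_run_core(
    m,
    function(chrom) ga_fitness(chrom, scores_cal, y_cal, scores_val, y_val),
    config, initial_population)
  pred <- ga_predict(tr$best_chromosome, scores_cal, y_cal, scores_val)
  tr$best_r_v <- evaluate_predictions(y_val, pred)$r
  tr
}

# Generation loop shared by the LPC-subset GA and the full-spectrum baseline
# GA: only the fitness function differs. Memoizes fitness by chromosome.
ga_run_core <- function(m, raw_fitness, config, initial_population = NULL) {
  pop_n <- if (is.null(config$population_size)) {
    default_population_size(m)
  } else {
    config$population_size
  }
  cache <- new.env(parent = emptyenv())
  n_eval <- 0L
  fitness_of <- function(chrom) {
    key <- paste(chrom, collapse = "")
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    v <- raw_fitness(chrom)
    n_eval <<- n_eval + 1L
    cache[[key]] <- v
    v
  }
  repair <- function(chrom) {
    if (!any(chrom != 0)) chrom[sample.int(m, 1L)] <- 1L
    chrom
  }
  local_seed(config$seed, {
    if (is.null(initial_population)) {
      pop <- matrix(sample(0:1, pop_n * m, replace = TRUE), pop_n, m)
    } else {
      pop <- as.matrix(initial_population)
      if (ncol(pop) != m) stop("`initial_population` has wrong chromosome length")
      pop_n <- nrow(pop)
      if (pop_n < 2L) stop("`initial_population` needs >= 2 individuals")
    }
    for (i in seq_len(pop_n)) pop[i, ] <- repair(pop[i, ])

    best_chrom <- NULL
    best_fit <- Inf
    trace <- numeric(0)
    stall <- 0L
    stop_reason <- "max_iterations"
    iter <- 0L
    repeat {
      iter <- iter + 1L
      fits <- apply(pop, 1L, fitness_of)
      gi <- which.min(fits)
      if (fits[gi] < best_fit) {
        best_fit <- fits[gi]
        best_chrom <- pop[gi, ]
      }
      trace[iter] <- best_fit
      if (iter > 1L &&
          abs(trace[iter] - trace[iter - 1L]) <= config$stall_tolerance) {
        stall <- stall + 1L
      } else {
        stall <- 0L
      }
      if (stall >= config$stall_window) {
        stop_reason <- "stalled"
        break
      }
      if (iter >= config$max_iterations) {
        stop_reason <- "max_iterations"
        break
      }
      # next generation: elite + tournament/crossover/mutation offspring.
      # Offspring identical to an already-placed member are regenerated
      # (bounded retries): small populations otherwise fill with elite
      # copies and stop exploring well before the stall window closes.
      newpop <- matrix(0L, pop_n, m)
      newpop[1L, ] <- best_chrom
      filled <- 1L
      seen <- c(paste(best_chrom, collapse = ""))
      tournament <- function() {
        cand <- sample.int(pop_n, 2L)
        if (fits[cand[1L]] <= fits[cand[2L]]) cand[1L] else cand[2L]
      }
      while (filled < pop_n) {
        tries <- 0L
        repeat {
          tries <- tries + 1L
          pa <- pop[tournament(), ]
          pb <- pop[tournament(), ]
          if (m >= 2L && stats::runif(1L) < config$pc) {
            cut <- sample.int(m - 1L, 1L)
            child <- c(pa[seq_len(cut)], pb[(cut + 1L):m])
          } else {
            child <- pa
          }
          if (config$pm > 0) {
            flip <- stats::runif(m) < config$pm
            child[flip] <- 1L - child[flip]
          }
          child <- repair(child)
          key <- paste(child, collapse = "")
          if (!(key %in% seen) || tries >= 10L) break
        }
        seen <- c(seen, key)
        filled <- filled + 1L
        newpop[filled, ] <- child
      }
      pop <- newpop
    }
    structure(list(best_rmsev_per_iteration = trace,
                   stop_iteration = iter,
                   stop_reason = stop_reason,
                   best_chromosome = as.integer(best_chrom),
                   best_rmsev = best_fit,
                   best_r_v = NA_real_,
                   n_evaluations = n_eval,
                   config = config),
              class = "ga_trace")
  })
}

#' @export
print.ga_trace <- function(x, ...) {
  cat(sprintf(
    "<ga_trace> stopped at iteration %d (%s); best RMSEV %.4f, %d/%d LPCs\n",
    x$stop_iteration, x$stop_reason, x$best_rmsev,
    sum(x$best_chromosome), length(x$best_chromosome)))
  invisible(x)
}

#' Parametric scan over crossover and mutation probabilities
#'
#' Runs [ga_evolve()] for every (crossover, mutation) pair of the grids with
#' a per-cell derived seed, and returns the cell with the minimum best RMSEV
#' (row-major first on ties). The default grids are the usual scaling
#' design: crossover 40/50/60%, mutation 0.8/1.2/1.5%.
#'
#' @param scores_cal,scores_val score matrices.
#' @param y_cal,y_val responses.
#' @param crossover_grid crossover probabilities in percent.
#' @param mutation_grid per-bit mutation probabilities in percent.
#' @param base_config a [ga_config()] supplying the remaining settings and
#'   the base seed (cell seeds are `seed + 1000 * cell index`).
#' @return An object of class `ga_scan`: `best_config`, `best_trace`,
#'   `grid` (data frame of per-cell summaries), `traces` (list of all
#'   [ga_evolve()] results, row-major over the grids).
#' @export
ga_parametric_scan <- function(scores_cal, y_cal, scores_val, y_val,
                               crossover_grid = c(40, 50, 60),
                               mutation_grid = c(0.8, 1.2, 1.5),
                               base_config = ga_config()) {
  stopifnot(inherits(base_config, "ga_config"))
  if (length(crossover_grid) == 0L || length(mutation_grid) == 0L) {
    stop("both grids must be nonempty")
  }
  cells <- expand.grid(p_mutation = mutation_grid,
                       p_crossover = crossover_grid)[, 2:1]
  traces <- vector("list", nrow(cells))
  summ <- data.frame(p_crossover = cells$p_crossover,
                     p_mutation = cells$p_mutation,
                     seed = NA_integer_, stop_iteration = NA_integer_,
                     stop_reason = NA_character_, best_rmsev = NA_real_,
                     best_r_v = NA_real_)
  for (i in seq_len(nrow(cells))) {
    cfg <- ga_config(p_crossover = cells$p_crossover[i],
                     p_mutation = cells$p_mutation[i],
                     max_iterations = base_config$max_iterations,
                     stall_window = base_config$stall_window,
                     stall_tolerance = base_config$stall_tolerance,
                     population_size = base_config$population_size,
                     seed = base_config$seed + 1000L * i)
    tr <- ga_evolve(scores_cal, y_cal, scores_val, y_val, cfg)
    traces[[i]] <- tr
    summ$seed[i] <- cfg$seed
    summ$stop_iteration[i] <- tr$stop_iteration
    summ$stop_reason[i] <- tr$stop_reason
    summ$best_rmsev[i] <- tr$best_rmsev
    summ$best_r_v[i] <- tr$best_r_v
  }
  bi <- which.min(summ$best_rmsev)
  structure(list(best_config = traces[[bi]]$config,
                 best_trace = traces[[bi]],
                 grid = summ,
                 traces = traces),
            class = "ga_scan")
}

#' @export
print.ga_scan <- function(x, ...) {
  cat(sprintf("<ga_scan> %d cells; best RMSEV %.4f at crossover %g%%, mutation %g%%\n",
              nrow(x$grid), x$best_trace$best_rmsev,
              x$best_config$p_crossover, x$best_config$p_mutation))
  invisible(x)
}
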