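test_that("fitness is the validation RMSE of the flagged least-squares model", {
  fx <- make_score_fixture(1)
  # single-column chromosome matches the closed-form simple regression
  chrom <- c(1, rep(0, 7))
  pred <- oracle_simple_regression_predict(fx$scores_cal[, 1], fx$y_cal,
                                           fx$scores_val[, 1])
  expect_equal(ga_fitness(chrom, fx$scores_cal, fx$y_cal,
                          fx$scores_val, fx$y_val),
               sqrt(mean((fx$y_val - pred)^2)), tolerance = 1e-10)
  # full chromosome matches the least-squares oracle
  full <- rep(1, 8)
  pred_full <- oracle_ols_predict(fx$scores_cal, fx$y_cal, fx$scores_val)
  expect_equal(ga_fitness(full, fx$scores_cal, fx$y_cal,
                          fx$scores_val, fx$y_val),
               sqrt(mean((fx$y_val - pred_full)^2)), tolerance = 1e-10)
  # the all-zero chromosome is a sentinel, never a candidate best
  expect_identical(ga_fitness(rep(0, 8), fx$scores_cal, fx$y_cal,
                              fx$scores_val, fx$y_val), Inf)
})

test_that("adding a column never raises the nested calibration RMSE", {
  fx <- make_score_fixture(2)
  rmse_cal <- function(chrom) {
    pred <- nirwaveband:::ga_predict(chrom, fx$scores_cal, fx$y_cal,
                                     fx$scores_cal)
    sqrt(mean((fx$y_cal - pred)^2))
  }
  base <- c(1, 1, 0, 0, 0, 0, 0, 0)
  wider <- c(1, 1, 1, 0, 0, 0, 0, 0)
  expect_lte(rmse_cal(wider), rmse_cal(base) + 1e-12)
})

test_that("config validation rejects out-of-range settings", {
  expect_error(ga_config(p_crossover = 0), "p_crossover")
  expect_error(ga_config(p_crossover = 100), "p_crossover")
  expect_error(ga_config(p_mutation = 100), "p_mutation")
  expect_error(ga_config(population_size = 5), "even")
  expect_error(ga_config(population_size = 2), "even integer >= 4|>= 4")
  expect_silent(ga_config(p_mutation = 0))
})

test_that("evolution is elitist, reproducible, and traces non-increasing", {
  fx <- make_score_fixture(3)
  cfg <- ga_config(seed = 42, max_iterations = 60)
  tr <- ga_evolve(fx$scores_cal, fx$y_cal, fx$scores_val, fx$y_val, cfg)
  expect_true(all(diff(tr$best_rmsev_per_iteration) <= 0))
  expect_lte(tr$stop_iteration, 60)
  expect_gte(sum(tr$best_chromosome), 1)
  tr2 <- ga_evolve(fx$scores_cal, fx$y_cal, fx$scores_val, fx$y_val, cfg)
  expect_identical(tr, tr2)
  tr3 <- ga_evolve(fx$scores_cal, fx$y_cal, fx$scores_val, fx$y_val,
                   ga_config(seed = 43, max_iterations = 60))
  expect_false(identical(tr$best_rmsev_per_iteration,
                         tr3$best_rmsev_per_iteration))
})

test_that("a length-1 chromosome is solved at the first iteration", {
  fx <- make_score_fixture(4, m = 1, informative = 1)
  tr <- ga_evolve(fx$scores_cal, fx$y_cal, fx$scores_val, fx$y_val,
                  ga_config(seed = 1))
  expect_identical(tr$best_chromosome, 1L)
  # the trace is constant, so the stall rule fires at stall_window + 1
  expect_identical(tr$stop_reason, "stalled")
  expect_identical(tr$stop_iteration, 21L)
})

test_that("stopping rules terminate exactly when specified", {
  fx <- make_score_fixture(5)
  # condition 1: the stall rule disabled forces the full iteration budget
  tr_full <- ga_evolve(fx$scores_cal, fx$y_cal, fx$scores_val, fx$y_val,
                       ga_config(seed = 7, max_iterations = 500,
                                 stall_tolerance = -1))
  expect_identical(tr_full$stop_reason, "max_iterations")
  expect_identical(tr_full$stop_iteration, 500L)
  expect_length(tr_full$best_rmsev_per_iteration, 500L)
  # condition 2: seeding the population with the exhaustive optimum means
  # no later improvement is possible; the run stalls at exactly
  # stall_window unchanged iterations past iteration 1
  or <- oracle_best_subset(fx$scores_cal, fx$y_cal, fx$scores_val, fx$y_val)
  init <- matrix(rep(or$chromosome, 20), 20, byrow = TRUE)
  tr <- ga_evolve(fx$scores_cal, fx$y_cal, fx$scores_val, fx$y_val,
                  ga_config(seed = 7, stall_window = 20),
                  initial_population = init)
  expect_identical(tr$stop_reason, "stalled")
  expect_lte(tr$stop_iteration, 21L)
  expect_equal(tr$best_rmsev, or$rmsev)
})

test_that("the GA attains the exhaustive-subset optimum on small instances", {
  fx <- make_score_fixture(6)
  or <- oracle_best_subset(fx$scores_cal, fx$y_cal, fx$scores_val, fx$y_val)
  hits <- 0L
  for (seed in 1:10) {
    tr <- ga_evolve(fx$scores_cal, fx$y_cal, fx$scores_val, fx$y_val,
                    ga_config(seed = seed))
    if (abs(tr$best_rmsev - or$rmsev) <= 1e-9) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("the parametric scan equals independently re-run cells", {
  fx <- make_score_fixture(8)
  base <- ga_config(seed = 11, max_iterations = 40)
  scan <- ga_parametric_scan(fx$scores_cal, fx$y_cal, fx$scores_val,
                             fx$y_val,
                             crossover_grid = c(40, 60),
                             mutation_grid = c(0.8, 1.5),
                             base_config = base)
  expect_identical(nrow(scan$grid), 4L)
  for (i in seq_len(4)) {
    cfg <- ga_config(p_crossover = scan$grid$p_crossover[i],
                     p_mutation = scan$grid$p_mutation[i],
                     max_iterations = 40, seed = scan$grid$seed[i])
    tr <- ga_evolve(fx$scores_cal, fx$y_cal, fx$scores_val, fx$y_val, cfg)
    expect_equal(tr$best_rmsev, scan$grid$best_rmsev[i])
  }
  expect_equal(scan$best_trace$best_rmsev, min(scan$grid$best_rmsev))
  # a 1x1 grid is a single evolve call
  one <- ga_parametric_scan(fx$scores_cal, fx$y_cal, fx$scores_val,
                            fx$y_val, 50, 1.2, base)
  cfg1 <- ga_config(p_crossover = 50, p_mutation = 1.2,
                    max_iterations = 40, seed = base$seed + 1000L)
  tr1 <- ga_evolve(fx$scores_cal, fx$y_cal, fx$scores_val, fx$y_val, cfg1)
  expect_equal(one$best_trace$best_rmsev, tr1$best_rmsev)
})
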