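# Reduced-scale pipeline configuration used by the end-to-end tests: a
# 120-channel axis around the analyte band keeps a full run under a few
# seconds while exercising every stage.
small_pipeline_fixture <- function(seed) {
  cfg <- synthetic_config(
    axis = wl_axis(1900, 2, 120),
    n_samples = 60L,
    analyte_bands = data.frame(center_nm = 2015, sigma_nm = 15,
                               amplitude = 0.01),
    interferents = list(
      list(bands = data.frame(center_nm = 2120, sigma_nm = 20,
                              amplitude = 0.008),
           conc_mean = 8, conc_sd = 1.5, correlation = 0.3)),
    seed = seed)
  generate_synthetic(cfg)$dataset
}

small_framework_config <- function(seed) {
  framework_config(n_cal = 30, n_val = 18, n_test = 12, seed = seed,
                   grid = window_grid(c(5, 10, 20)), k = 2, lv_cap = 8,
                   crossover_grid = 50, mutation_grid = 1.2,
                   ga_max_iterations = 60, ga_population_size = 30)
}

test_that("the pipeline runs end to end and reports coherent metrics", {
  d <- small_pipeline_fixture(21)
  rep <- run_framework(d, small_framework_config(21))
  expect_s3_class(rep, "framework_report")
  expect_identical(nrow(rep$windows), 2L)
  expect_true(all(rep$windows$post_ga_rmsev > 0))
  expect_true(all(rep$windows$n_selected >= 1))
  expect_true(all(rep$windows$n_selected <= rep$windows$n_lpc))
  b <- rep$best
  expect_equal(rep$windows$post_ga_rmsev[b$index],
               min(rep$windows$post_ga_rmsev))
  # the reported validation metrics come from the refit best model
  expect_equal(rep$validation$rmse, rep$windows$post_ga_rmsev[b$index])
  expect_identical(rep$testing$n, 12L)
  # the best waveband covers part of the planted 1980-2050 nm band
  expect_lt(b$start_nm, 2050)
  expect_gt(b$end_nm, 1980)
})

test_that("a degenerate config (k = 1, 1x1 GA grid) yields a single row", {
  d <- small_pipeline_fixture(22)
  cfg <- small_framework_config(22)
  cfg$k <- 1L
  rep <- run_framework(d, cfg)
  expect_identical(nrow(rep$windows), 1L)
  expect_identical(rep$best$index, 1L)
})

test_that("reruns with the same config produce byte-identical artifacts", {
  d <- small_pipeline_fixture(23)
  cfg <- small_framework_config(23)
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  run_framework(d, cfg, outdir = out1)
  run_framework(d, cfg, outdir = out2)
  files <- list.files(out1)
  expect_true(length(files) >= 5)
  expect_setequal(files, list.files(out2))
  for (f in files) {
    expect_identical(readBin(file.path(out1, f), "raw", 1e6),
                     readBin(file.path(out2, f), "raw", 1e6),
                     info = f)
  }
})

test_that("stage isolation: rerunning the GA from saved scores reproduces it", {
  d <- small_pipeline_fixture(24)
  cfg <- small_framework_config(24)
  rep <- run_framework(d, cfg)
  w <- rep$best$index
  snv <- snv_transform(d)
  cal <- subset_samples(snv, rep$split$calibration)
  val <- subset_samples(snv, rep$split$validation)
  cols <- rep$best$S:(rep$best$S + rep$best$N - 1)
  sc_cal <- project_lpc(rep$best$basis, cal$absorbance[, cols])
  sc_val <- project_lpc(rep$best$basis, val$absorbance[, cols])
  scan <- ga_parametric_scan(
    sc_cal, cal$y, sc_val, val$y,
    crossover_grid = cfg$crossover_grid,
    mutation_grid = cfg$mutation_grid,
    base_config = ga_config(max_iterations = cfg$ga_max_iterations,
                            population_size = cfg$ga_population_size,
                            seed = cfg$seed + 10000L * w))
  expect_identical(scan$best_trace$best_chromosome, rep$best$chromosome)
  expect_equal(scan$best_trace$best_rmsev, rep$windows$post_ga_rmsev[w])
})

test_that("a saved model round-trips and reproduces the testing predictions", {
  d <- small_pipeline_fixture(28)
  rep <- run_framework(d, small_framework_config(28))
  path <- withr::local_tempfile(fileext = ".txt")
  write_framework_model(rep, path)
  model <- read_framework_model(path)
  test_set <- subset_samples(d, rep$split$testing)
  pred <- predict(model, test_set)
  ev <- evaluate_predictions(test_set$y, pred)
  expect_equal(ev$rmse, rep$testing$rmse, tolerance = 1e-10)
  expect_error(predict(model, subset_samples(
    generate_synthetic(make_small_config(30, 5L, 1L))$dataset, 1:5)),
    "axis")
})

test_that("the full-spectrum GA-PLS baseline runs and has chromosome length P", {
  d <- small_pipeline_fixture(25)
  cfg <- small_framework_config(25)
  cfg$ga_max_iterations <- 30L
  base <- run_baseline_ga(d, cfg)
  expect_length(base$chromosome, 120L)
  expect_gte(sum(base$chromosome), 1)
  expect_gt(base$testing$rmse, 0)
  expect_identical(base$testing$n, 12L)
})

test_that("with mutation off and a uniform population, flags never change", {
  d <- small_pipeline_fixture(26)
  cfg <- small_framework_config(26)
  cfg$ga_max_iterations <- 10L
  set.seed(99)
  chrom <- rbinom(120, 1, 0.5)
  chrom[1] <- 1L
  init <- matrix(rep(chrom, 10), 10, byrow = TRUE)
  base <- run_baseline_ga(d, cfg, p_mutation = 0,
                          initial_population = init)
  # crossover between identical parents is a no-op, so the population is
  # invariant and the best chromosome is the seeded one
  expect_identical(base$chromosome, as.integer(chrom))
})

test_that("split sizes incompatible with the dataset abort before any work", {
  d <- small_pipeline_fixture(27)
  cfg <- small_framework_config(27)
  cfg$n_test <- 13L
  expect_error(run_framework(d, cfg), "sum")
  expect_error(run_baseline_ga(d, cfg), "sum")
})
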