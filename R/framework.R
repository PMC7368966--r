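# End-to-end orchestration: SNV preprocessing, SPXY/random split, the
# grid-search moving-window scan, LPC extraction per selected waveband, the
# parametric-scaling GA over LPCs, and the final testing evaluation. Also a
# conventional full-spectrum GA-PLS baseline for comparison.

#' Pipeline configuration
#'
#' @param n_cal,n_val,n_test split sizes (defaults 90/50/54, matching a
#'   194-sample dataset).
#' @param seed master seed; the testing holdout uses it directly, each
#'   waveband's GA scan derives `seed + 10000 * waveband rank`, and cells
#'   within a scan derive `+ 1000 * cell`.
#' @param grid a [window_grid()] of admissible window widths.
#' @param k number of disjoint top wavebands carried into the GA stage.
#' @param lv_cap maximum latent variables scanned per window model.
#' @param lpc_keep optional truncation: keep only the leading `lpc_keep`
#'   LPCs per waveband (`NULL`, the default, keeps all).
#' @param crossover_grid,mutation_grid GA parametric-scan grids, in percent.
#' @param ga_max_iterations,ga_stall_window,ga_stall_tolerance,ga_population_size
#'   GA settings passed to [ga_config()] (`NULL` population = auto).
#' @return An object of class `framework_config`.
#' @export
framework_config <- function(n_cal = 90L, n_val = 50L, n_test = 54L,
                             seed = 1L,
                             grid = window_grid(),
                             k = 5L, lv_cap = 15L, lpc_keep = NULL,
                             crossover_grid = c(40, 50, 60),
                             mutation_grid = c(0.8, 1.2, 1.5),
                             ga_max_iterations = 500L,
                             ga_stall_window = 20L,
                             ga_stall_tolerance = 1e-6,
                             ga_population_size = NULL) {
  if (!inherits(grid, "window_grid")) grid <- window_grid(grid)
  structure(list(n_cal = as.integer(n_cal), n_val = as.integer(n_val),
                 n_test = as.integer(n_test), seed = as.integer(seed),
                 grid = grid, k = as.integer(k), lv_cap = as.integer(lv_cap),
                 lpc_keep = if (is.null(lpc_keep)) NULL else
                   as.integer(lpc_keep),
                 crossover_grid = crossover_grid,
                 mutation_grid = mutation_grid,
                 ga_max_iterations = as.integer(ga_max_iterations),
                 ga_stall_window = as.integer(ga_stall_window),
                 ga_stall_tolerance = ga_stall_tolerance,
                 ga_population_size = ga_population_size),
            class = "framework_config")
}

truncate_basis <- function(basis, keep) {
  if (is.null(keep) || keep >= basis$m) return(basis)
  basis$loadings <- basis$loadings[, seq_len(keep), drop = FALSE]
  basis$explained_variance <- basis$explained_variance[seq_len(keep)]
  basis$m <- as.integer(keep)
  basis
}

#' Run the full waveband-optimization pipeline
#'
#' Stages: (1) SNV preprocessing of every spectrum; (2) split into
#' testing (random holdout) and calibration/validation (SPXY on the
#' preprocessed spectra); (3) grid-search moving-window scan ranking all
#' admissible wavebands by validation RMSE of a PLS model; (4) for each of
#' the `k` top disjoint wavebands, principal-component (LPC) extraction on
#' the calibration rows and a genetic-algorithm scan over crossover and
#' mutation rates selecting the LPC subset with minimum validation RMSE;
#' (5) the waveband with the lowest post-GA validation RMSE becomes the
#' final model, which is evaluated once on the held-out testing set.
#'
#' @param dataset a raw [spectral_dataset()] (SNV is applied internally).
#' @param config a [framework_config()].
#' @param outdir optional directory; when given, stage artifacts are written
#'   (`gsmw_surface.csv`, `top_windows.csv`, `ga_best.csv`, `report.csv`,
#'   `manifest.txt`, per-cell `ga_trace_<waveband>.csv`).
#' @return An object of class `framework_report`: `windows` (one row per
#'   waveband: location, pre-GA and post-GA validation metrics, chosen GA
#'   parameters, stop iteration, selected LPC count), `best` (index and
#'   details of the winning waveband incl. the LPC basis and chromosome),
#'   `validation`/`testing` [evaluate_predictions()] reports for the final
#'   model, `split`, `gsmw`, `scans`, `config`.
#' @export
run_framework <- function(dataset, config = framework_config(),
                          outdir = NULL) {
  stopifnot(inherits(dataset, "spectral_dataset"),
            inherits(config, "framework_config"))
  n <- nrow(dataset$absorbance)
  if (config$n_cal + config$n_val + config$n_test != n) {
    stop(sprintf("split sizes (%d + %d + %d) must sum to the %d samples",
                 config$n_cal, config$n_val, config$n_test, n))
  }
  snv <- snv_transform(dataset)
  split <- split_dataset(snv, config$n_cal, config$n_val, config$n_test,
                         config$seed)
  cal <- subset_samples(snv, split$calibration)
  val <- subset_samples(snv, split$validation)
  test <- subset_samples(snv, split$testing)

  gsmw <- gsmw_search(cal, val, config$grid, config$lv_cap)
  top <- select_top_windows(gsmw, config$k)

  kk <- nrow(top)
  scans <- vector("list", kk)
  bases <- vector("list", kk)
  rows <- data.frame(rank = top$rank, S = top$S, N = top$N,
                     start_nm = top$start_nm, end_nm = top$end_nm,
                     pre_ga_lv = top$best_lv,
                     pre_ga_rmsev = top$rmsev, pre_ga_r_v = top$r_v,
                     n_lpc = NA_integer_,
                     p_crossover = NA_real_, p_mutation = NA_real_,
                     stop_iteration = NA_integer_,
                     stop_reason = NA_character_,
                     n_selected = NA_integer_,
                     post_ga_rmsev = NA_real_, post_ga_r_v = NA_real_)
  for (w in seq_len(kk)) {
    cols <- window_columns(top$S[w], top$N[w])
    basis <- truncate_basis(
      fit_lpc(cal$absorbance[, cols, drop = FALSE],
              window = list(S = top$S[w], N = top$N[w])),
      config$lpc_keep)
    bases[[w]] <- basis
    sc_cal <- project_lpc(basis, cal$absorbance[, cols, drop = FALSE])
    sc_val <- project_lpc(basis, val$absorbance[, cols, drop = FALSE])
    base_cfg <- ga_config(max_iterations = config$ga_max_iterations,
                          stall_window = config$ga_stall_window,
                          stall_tolerance = config$ga_stall_tolerance,
                          population_size = config$ga_population_size,
                          seed = config$seed + 10000L * w)
    scan <- ga_parametric_scan(sc_cal, cal$y, sc_val, val$y,
                               crossover_grid = config$crossover_grid,
                               mutation_grid = config$mutation_grid,
                               base_config = base_cfg)
    scans[[w]] <- scan
    tr <- scan$best_trace
    rows$n_lpc[w] <- basis$m
    rows$p_crossover[w] <- scan$best_config$p_crossover
    rows$p_mutation[w] <- scan$best_config$p_mutation
    rows$stop_iteration[w] <- tr$stop_iteration
    rows$stop_reason[w] <- tr$stop_reason
    rows$n_selected[w] <- sum(tr$best_chromosome)
    rows$post_ga_rmsev[w] <- tr$best_rmsev
    rows$post_ga_r_v[w] <- tr$best_r_v
  }
  bi <- which.min(rows$post_ga_rmsev)
  best_basis <- bases[[bi]]
  best_trace <- scans[[bi]]$best_trace
  cols <- window_columns(top$S[bi], top$N[bi])
  sc_cal <- project_lpc(best_basis, cal$absorbance[, cols, drop = FALSE])
  sc_val <- project_lpc(best_basis, val$absorbance[, cols, drop = FALSE])
  sc_test <- project_lpc(best_basis, test$absorbance[, cols, drop = FALSE])
  val_pred <- ga_predict(best_trace$best_chromosome, sc_cal, cal$y, sc_val)
  test_pred <- ga_predict(best_trace$best_chromosome, sc_cal, cal$y, sc_test)
  validation <- evaluate_predictions(val$y, val_pred, "validation")
  testing <- evaluate_predictions(test$y, test_pred, "testing")
  sel <- which(best_trace$best_chromosome != 0)
  cf <- stats::lm.fit(cbind(1, sc_cal[, sel, drop = FALSE]), cal$y)$coefficients
  cf[is.na(cf)] <- 0

  report <- structure(
    list(windows = rows,
         best = list(index = bi, S = top$S[bi], N = top$N[bi],
                     start_nm = top$start_nm[bi], end_nm = top$end_nm[bi],
                     basis = best_basis,
                     chromosome = best_trace$best_chromosome,
                     intercept = unname(cf[1L]),
                     coefficients = unname(cf[-1L]),
                     p_crossover = rows$p_crossover[bi],
                     p_mutation = rows$p_mutation[bi],
                     stop_iteration = rows$stop_iteration[bi]),
         validation = validation,
         testing = testing,
         split = split,
         gsmw = gsmw,
         scans = scans,
         config = config),
    class = "framework_report")
  if (!is.null(outdir)) write_framework_artifacts(report, outdir)
  report
}

#' @export
print.framework_report <- function(x, ...) {
  cat(sprintf("<framework_report> %d waveband(s) optimized\n",
              nrow(x$windows)))
  b <- x$best
  cat(sprintf("  best waveband: %g-%g nm (N=%d, S=%d), crossover %g%%, mutation %g%%\n",
              b$start_nm, b$end_nm, b$N, b$S, b$p_crossover, b$p_mutation))
  cat(sprintf("  validation: RMSEV %.4f, R_V %.4f\n",
              x$validation$rmse, x$validation$r))
  cat(sprintf("  testing:    RMSET %.4f, R_T %.4f\n",
              x$testing$rmse, x$testing$r))
  invisible(x)
}

write_framework_artifacts <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$gsmw$surface,
                   file.path(outdir, "gsmw_surface.csv"), row.names = FALSE)
  top <- report$windows[, c("rank", "N", "S", "start_nm", "end_nm",
                            "pre_ga_lv", "pre_ga_rmsev", "pre_ga_r_v")]
  utils::write.csv(top, file.path(outdir, "top_windows.csv"),
                   row.names = FALSE)
  utils::write.csv(report$windows, file.path(outdir, "report.csv"),
                   row.names = FALSE)
  ga_best <- report$windows[, c("start_nm", "end_nm", "p_crossover",
                                "p_mutation", "stop_iteration", "n_selected",
                                "post_ga_rmsev", "post_ga_r_v")]
  utils::write.csv(ga_best, file.path(outdir, "ga_best.csv"),
                   row.names = FALSE)
  for (w in seq_along(report$scans)) {
    tr <- report$scans[[w]]$best_trace
    utils::write.csv(
      data.frame(iteration = seq_along(tr$best_rmsev_per_iteration),
                 best_rmsev = tr$best_rmsev_per_iteration),
      file.path(outdir, sprintf("ga_trace_%g-%g.csv",
                                report$windows$start_nm[w],
                                report$windows$end_nm[w])),
      row.names = FALSE)
  }
  write_framework_model(report, file.path(outdir, "model.txt"))
  cfg <- report$config
  manifest <- c(
    sprintf("seed: %d", cfg$seed),
    sprintf("split: cal %d / val %d / test %d", cfg$n_cal, cfg$n_val,
            cfg$n_test),
    sprintf("window widths: %s", paste(as.integer(cfg$grid), collapse = ",")),
    sprintf("windows evaluated: %d", nrow(report$gsmw$surface)),
    sprintf("k: %d, lv_cap: %d", cfg$k, cfg$lv_cap),
    sprintf("lpc_keep: %s",
            if (is.null(cfg$lpc_keep)) "all" else cfg$lpc_keep),
    sprintf("crossover grid (%%): %s",
            paste(cfg$crossover_grid, collapse = ",")),
    sprintf("mutation grid (%%): %s",
            paste(cfg$mutation_grid, collapse = ",")),
    sprintf("ga: max_iterations %d, stall_window %d, stall_tolerance %g",
            cfg$ga_max_iterations, cfg$ga_stall_window,
            cfg$ga_stall_tolerance),
    sprintf("ga population: %s",
            if (is.null(cfg$ga_population_size)) "auto" else
              cfg$ga_population_size),
    sprintf("ga seeds: per-waveband seed + 10000*rank, per-cell + 1000*cell"),
    sprintf("best waveband: %g-%g nm", report$best$start_nm,
            report$best$end_nm),
    sprintf("validation RMSEV: %.6f", report$validation$rmse),
    sprintf("testing RMSET: %.6f", report$testing$rmse))
  writeLines(manifest, file.path(outdir, "manifest.txt"))
  invisible(outdir)
}

#' Conventional full-spectrum GA-PLS baseline
#'
#' The comparison method: a binary GA directly over the wavelength flags of
#' the full (SNV-preprocessed) spectrum — no moving-window stage, no LPC
#' transformation. Fitness of a chromosome is the validation RMSE of a PLS
#' model on the flagged wavelengths (latent variables scanned up to
#' `lv_cap`). Defaults follow common practice: 50% crossover, 1.2%
#' mutation, 500 iterations. The final model is refit on the best
#' chromosome and evaluated on the testing set.
#'
#' @param dataset a raw [spectral_dataset()].
#' @param config a [framework_config()]; the split sizes, seed, `lv_cap`
#'   and GA settings are used. Note the default population rule
#'   `max(20, 2P)` is expensive for wide spectra; set
#'   `ga_population_size` to bound it.
#' @param p_crossover,p_mutation GA probabilities in percent.
#' @param initial_population optional 0/1 matrix seeding the population.
#' @return List of class `baseline_report`: `validation` and `testing`
#'   [evaluate_predictions()] reports, `trace` (the [ga_evolve()]-style
#'   trace), `chromosome`, `best_lv`, `split`.
#' @export
run_baseline_ga <- function(dataset, config = framework_config(),
                            p_crossover = 50, p_mutation = 1.2,
                            initial_population = NULL) {
  stopifnot(inherits(dataset, "spectral_dataset"),
            inherits(config, "framework_config"))
  n <- nrow(dataset$absorbance)
  if (config$n_cal + config$n_val + config$n_test != n) {
    stop(sprintf("split sizes (%d + %d + %d) must sum to the %d samples",
                 config$n_cal, config$n_val, config$n_test, n))
  }
  snv <- snv_transform(dataset)
  split <- split_dataset(snv, config$n_cal, config$n_val, config$n_test,
                         config$seed)
  cal <- subset_samples(snv, split$calibration)
  val <- subset_samples(snv, split$validation)
  test <- subset_samples(snv, split$testing)
  P <- snv$axis$count
  nc1 <- nrow(cal$absorbance) - 1L
  wl_fitness <- function(chrom) {
    sel <- which(chrom != 0)
    if (length(sel) == 0L) return(Inf)
    sc <- pls_rmsev_scan(cal$absorbance[, sel, drop = FALSE], cal$y,
                         val$absorbance[, sel, drop = FALSE], val$y,
                         max_lv = min(config$lv_cap, length(sel), nc1))
    if (sc$ncomp == 0L) return(sqrt(mean((val$y - mean(cal$y))^2)))
    min(sc$rmsev)
  }
  ga_cfg <- ga_config(p_crossover = p_crossover, p_mutation = p_mutation,
                      max_iterations = config$ga_max_iterations,
                      stall_window = config$ga_stall_window,
                      stall_tolerance = config$ga_stall_tolerance,
                      population_size = config$ga_population_size,
                      seed = config$seed)
  trace <- ga_run_core(P, wl_fitness, ga_cfg, initial_population)
  sel <- which(trace$best_chromosome != 0)
  sc <- pls_rmsev_scan(cal$absorbance[, sel, drop = FALSE], cal$y,
                       val$absorbance[, sel, drop = FALSE], val$y,
                       max_lv = min(config$lv_cap, length(sel), nc1))
  best_lv <- if (sc$ncomp == 0L) 0L else which.min(sc$rmsev)
  if (best_lv > 0L) {
    model <- fit_pls(cal$absorbance[, sel, drop = FALSE], cal$y, best_lv)
    val_pred <- predict(model, val$absorbance[, sel, drop = FALSE])
    test_pred <- predict(model, test$absorbance[, sel, drop = FALSE])
  } else {
    val_pred <- rep(mean(cal$y), length(val$y))
    test_pred <- rep(mean(cal$y), length(test$y))
  }
  validation <- evaluate_predictions(val$y, val_pred, "validation")
  trace$best_r_v <- validation$r
  structure(list(validation = validation,
                 testing = evaluate_predictions(test$y, test_pred,
                                                "testing"),
                 trace = trace,
                 chromosome = trace$best_chromosome,
                 best_lv = best_lv,
                 split = split),
            class = "baseline_report")
}

#' @export
print.baseline_report <- function(x, ...) {
  cat(sprintf(
    "<baseline_report> GA-PLS on %d wavelengths, %d selected, %d LV\n",
    length(x$chromosome), sum(x$chromosome), x$best_lv))
  cat(sprintf("  validation: RMSEV %.4f | testing: RMSET %.4f\n",
              x$validation$rmse, x$testing$rmse))
  invisible(x)
}
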