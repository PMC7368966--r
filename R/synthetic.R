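# Synthetic NIR mixture spectra with known ground truth. Each spectrum is a
# Beer-Lambert-style superposition: component concentrations times Gaussian
# absorption bands, plus a per-sample linear baseline and additive noise.
# The defaults emulate a fishmeal-protein style dataset: 700 channels over
# 1100-2498 nm at 2 nm, 194 samples, analyte content ~ N(60.7, 4.36) wt.%
# truncated to [53, 67], one analyte band spanning roughly 1980-2050 nm and
# two interferent bands elsewhere, at signal-to-noise ratio ~ 10.

#' Configuration of the synthetic spectrum generator
#'
#' Components are described by a band table (`center_nm`, `sigma_nm`,
#' `amplitude` per row, several rows per component allowed). Interferent
#' concentrations are drawn jointly normal with the analyte at the given
#' correlation (the analyte draw is truncated by rejection first, then
#' interferents are built from its z-score), mimicking co-varying matrix
#' constituents such as moisture or ash. The signal-to-noise ratio is
#' defined as (analyte peak amplitude x concentration SD) / noise SD.
#'
#' @param axis a [wl_axis()]; default 1100 nm start, 2 nm step, 700 channels.
#' @param n_samples number of samples, default 194.
#' @param conc_mean,conc_sd target mean and SD (wt.%) of the analyte
#'   concentration after truncation, default 60.7 and 4.36. The generator
#'   solves for the parent normal whose truncated moments best match these
#'   targets; a target SD above what any normal truncated to `conc_range`
#'   can reach (the uniform limit `diff(conc_range)/sqrt(12)`) is met as
#'   closely as possible.
#' @param conc_range truncation bounds for the analyte, default `c(53, 67)`.
#' @param analyte_bands data frame of analyte absorption bands; default one
#'   Gaussian centered at 2015 nm, sigma 15 nm, amplitude 0.01.
#' @param interferents list of interferent components, each a list with
#'   `bands` (data frame as above), `conc_mean`, `conc_sd`, `correlation`
#'   (with the analyte).
#' @param background_bands optional data frame of broad matrix-absorption
#'   bands common to every sample (unit concentration). Diffuse-reflectance
#'   spectra are dominated by such common structure (water, protein and
#'   lipid combination bands); it is what makes SNV scale-correction
#'   information-preserving, since the per-spectrum SD is then nearly
#'   constant rather than proportional to the analyte content. `NULL`
#'   (default) adds none.
#' @param baseline_offset_sd,baseline_slope_sd per-sample baseline offset SD
#'   (absorbance units) and slope SD (absorbance per nm about the axis
#'   midpoint).
#' @param noise_sd additive Gaussian noise SD per channel; the default
#'   0.00436 puts the analyte band at SNR 10.
#' @param seed integer RNG seed.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(axis = wl_axis(1100, 2, 700),
                             n_samples = 194L,
                             conc_mean = 60.7, conc_sd = 4.36,
                             conc_range = c(53, 67),
                             analyte_bands = data.frame(center_nm = 2015,
                                                        sigma_nm = 15,
                                                        amplitude = 0.01),
                             interferents = list(
                               list(bands = data.frame(center_nm = 1450,
                                                       sigma_nm = 25,
                                                       amplitude = 0.012),
                                    conc_mean = 10, conc_sd = 2,
                                    correlation = 0.3),
                               list(bands = data.frame(center_nm = 2180,
                                                       sigma_nm = 30,
                                                       amplitude = 0.008),
                                    conc_mean = 8, conc_sd = 1.5,
                                    correlation = 0.3)),
                             background_bands = NULL,
                             baseline_offset_sd = 0.02,
                             baseline_slope_sd = 5e-5,
                             noise_sd = 0.00436,
                             seed = 1L) {
  stopifnot(inherits(axis, "wl_axis"))
  n_samples <- as.integer(n_samples)
  if (n_samples < 2L) stop("`n_samples` must be >= 2")
  if (conc_sd <= 0) stop("`conc_sd` must be positive")
  check_bands <- function(b, who) {
    need <- c("center_nm", "sigma_nm", "amplitude")
    if (!all(need %in% names(b))) {
      stop(sprintf("%s bands need columns %s", who,
                   paste(need, collapse = ", ")))
    }
    if (any(b$amplitude < 0)) stop(sprintf("%s amplitudes must be >= 0", who))
    if (any(b$sigma_nm <= 0)) stop(sprintf("%s band widths must be > 0", who))
    lo <- axis$start_nm
    hi <- axis$start_nm + (axis$count - 1L) * axis$step_nm
    if (any(b$center_nm < lo | b$center_nm > hi)) {
      stop(sprintf("%s band centers must lie within the axis (%g-%g nm)",
                   who, lo, hi))
    }
    invisible(b)
  }
  check_bands(analyte_bands, "analyte")
  if (!is.null(background_bands)) check_bands(background_bands, "background")
  for (k in seq_along(interferents)) {
    it <- interferents[[k]]
    check_bands(it$bands, sprintf("interferent %d", k))
    if (it$conc_sd <= 0) stop("interferent `conc_sd` must be positive")
    if (abs(it$correlation) >= 1) {
      stop("interferent `correlation` must be in (-1, 1)")
    }
  }
  if (baseline_offset_sd < 0 || baseline_slope_sd < 0 || noise_sd < 0) {
    stop("baseline and noise SDs must be >= 0")
  }
  structure(list(axis = axis, n_samples = n_samples,
                 conc_mean = conc_mean, conc_sd = conc_sd,
                 conc_range = conc_range,
                 analyte_bands = analyte_bands,
                 interferents = interferents,
                 background_bands = background_bands,
                 baseline_offset_sd = baseline_offset_sd,
                 baseline_slope_sd = baseline_slope_sd,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Moments of a normal(mu, sig) truncated to [a, b].
truncnorm_moments <- function(mu, sig, a, b) {
  al <- (a - mu) / sig
  be <- (b - mu) / sig
  Z <- stats::pnorm(be) - stats::pnorm(al)
  da <- stats::dnorm(al)
  db <- stats::dnorm(be)
  m <- mu + sig * (da - db) / Z
  v <- sig^2 * (1 + (al * da - be * db) / Z - ((da - db) / Z)^2)
  c(mean = m, sd = sqrt(v))
}

# Parent normal whose truncation to [a, b] matches the target moments as
# closely as possible. Truncation shrinks the SD, so matching the parent's
# own parameters to the targets would bias the sample; instead the parent
# mean is solved (for each candidate sigma) so the truncated mean is exact,
# and sigma is chosen to bring the truncated SD nearest the target. A
# target SD above the family's supremum on [a, b] (the uniform limit,
# (b - a)/sqrt(12)) yields the closest attainable value.
truncnorm_parent <- function(target_mean, target_sd, a, b) {
  if (target_mean <= a || target_mean >= b) {
    stop("`conc_mean` must lie strictly inside `conc_range`")
  }
  mu_for <- function(sig) {
    f <- function(mu) truncnorm_moments(mu, sig, a, b)[["mean"]] - target_mean
    lo <- a - 5 * sig
    hi <- b + 5 * sig
    k <- 0L
    while (k < 20L && is.finite(f(hi)) && f(hi) < 0) {
      hi <- hi + 5 * sig
      k <- k + 1L
    }
    while (k < 20L && is.finite(f(lo)) && f(lo) > 0) {
      lo <- lo - 5 * sig
      k <- k + 1L
    }
    stats::uniroot(f, lower = lo, upper = hi, tol = 1e-10)$root
  }
  lo_sig <- min(target_sd / 2, 0.02 * (b - a))
  hi_sig <- max(2 * (b - a), 2 * target_sd)
  opt <- stats::optimize(function(l) {
    sig <- exp(l)
    (truncnorm_moments(mu_for(sig), sig, a, b)[["sd"]] - target_sd)^2
  }, lower = log(lo_sig), upper = log(hi_sig))
  sig <- exp(opt$minimum)
  c(mu = mu_for(sig), sigma = sig)
}

# Exact inverse-CDF sampler for the truncated normal (no rejection, so it
# stays cheap and deterministic even under strong tilt).
rtruncnorm <- function(n, mu, sig, a, b) {
  pa <- stats::pnorm(a, mu, sig)
  pb <- stats::pnorm(b, mu, sig)
  stats::qnorm(stats::runif(n, pa, pb), mu, sig)
}

#' Default matrix-absorption background for the full NIR axis
#'
#' Broad common absorption structure mimicking the water, protein and lipid
#' combination bands that dominate a diffuse-reflectance feed spectrum over
#' 1100-2500 nm. Passed as `background_bands` to [synthetic_config()]; every
#' sample receives this profile at unit concentration, so the per-spectrum
#' SD that SNV divides by is dominated by composition-independent structure,
#' as in real spectra.
#'
#' @return Data frame with `center_nm`, `sigma_nm`, `amplitude`.
#' @export
nir_matrix_background <- function() {
  data.frame(
    center_nm = c(1200, 1450, 1720, 1940, 2180, 2350),
    sigma_nm = c(60, 40, 50, 45, 60, 50),
    amplitude = c(0.15, 0.50, 0.20, 0.60, 0.30, 0.25))
}

band_profile <- function(wl, bands) {
  out <- numeric(length(wl))
  for (i in seq_len(nrow(bands))) {
    out <- out + bands$amplitude[i] *
      exp(-(wl - bands$center_nm[i])^2 / (2 * bands$sigma_nm[i]^2))
  }
  out
}

#' Generate a synthetic spectral dataset
#'
#' Draws concentrations, builds each spectrum as the concentration-weighted
#' sum of the component band profiles plus baseline and noise, and returns
#' the dataset together with a ground-truth record (all concentrations,
#' band tables, baseline terms and the realized SNR) sufficient to
#' reconstruct every spectrum bit-exactly given the seed. Deterministic per
#' seed.
#'
#' @param config a [synthetic_config()].
#' @return List with `dataset` (a [spectral_dataset()]) and `truth` (list
#'   with `concentrations` data frame, `analyte_bands`, `interferent_bands`,
#'   `baseline` data frame, `noise_sd`, `snr`, `seed`).
#' @export
generate_synthetic <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  wl <- axis_wavelengths(config$axis)
  n <- config$n_samples
  parent <- truncnorm_parent(config$conc_mean, config$conc_sd,
                             config$conc_range[1L], config$conc_range[2L])
  pop <- truncnorm_moments(parent[["mu"]], parent[["sigma"]],
                           config$conc_range[1L], config$conc_range[2L])
  local_seed(config$seed, {
    y <- rtruncnorm(n, parent[["mu"]], parent[["sigma"]],
                    config$conc_range[1L], config$conc_range[2L])
    z_a <- (y - pop[["mean"]]) / pop[["sd"]]
    conc <- data.frame(analyte = y)
    profiles <- list(band_profile(wl, config$analyte_bands))
    for (k in seq_along(config$interferents)) {
      it <- config$interferents[[k]]
      z <- it$correlation * z_a +
        sqrt(1 - it$correlation^2) * stats::rnorm(n)
      conc[[paste0("interferent", k)]] <- it$conc_mean + it$conc_sd * z
      profiles[[k + 1L]] <- band_profile(wl, it$bands)
    }
    X <- matrix(0, n, config$axis$count)
    for (j in seq_along(profiles)) {
      X <- X + tcrossprod(conc[[j]], profiles[[j]])
    }
    if (!is.null(config$background_bands)) {
      X <- X + matrix(band_profile(wl, config$background_bands),
                      n, config$axis$count, byrow = TRUE)
    }
    offset <- stats::rnorm(n, 0, config$baseline_offset_sd)
    slope <- stats::rnorm(n, 0, config$baseline_slope_sd)
    X <- X + offset + tcrossprod(slope, wl - mean(wl))
    if (config$noise_sd > 0) {
      X <- X + matrix(stats::rnorm(n * config$axis$count, 0, config$noise_sd),
                      n, config$axis$count)
    }
    peak <- max(band_profile(wl, config$analyte_bands))
    snr <- if (config$noise_sd > 0) {
      peak * config$conc_sd / config$noise_sd
    } else {
      Inf
    }
    list(dataset = spectral_dataset(config$axis, X, y),
         truth = list(concentrations = conc,
                      analyte_bands = config$analyte_bands,
                      interferent_bands = lapply(config$interferents,
                                                 `[[`, "bands"),
                      background_bands = config$background_bands,
                      baseline = data.frame(offset = offset, slope = slope),
                      noise_sd = config$noise_sd,
                      snr = snr,
                      seed = config$seed))
  })
}

#' Standard synthetic fixtures
#'
#' Three seeded datasets used for testing every pipeline stage:
#' \describe{
#'   \item{planted_band}{the default full-scale configuration: 194 samples,
#'     700 channels, one analyte band spanning roughly 1980-2050 nm, two
#'     correlated interferent bands, SNR about 10.}
#'   \item{tiny}{20 channels, 30 samples, one analyte band and one
#'     interferent; small enough for brute-force oracles.}
#'   \item{rank1}{noise-free, no interferents, no baseline: spectra exactly
#'     proportional to the analyte concentration.}
#' }
#'
#' @param seed integer base seed (fixtures derive their own from it).
#' @return Named list of `list(dataset, truth, config)` entries.
#' @export
standard_fixtures <- function(seed = 1L) {
  seed <- as.integer(seed)
  planted_cfg <- synthetic_config(background_bands = nir_matrix_background(),
                                  seed = seed)
  tiny_cfg <- synthetic_config(
    axis = wl_axis(1100, 2, 20),
    n_samples = 30L,
    analyte_bands = data.frame(center_nm = 1124, sigma_nm = 4,
                               amplitude = 0.01),
    interferents = list(
      list(bands = data.frame(center_nm = 1110, sigma_nm = 5,
                              amplitude = 0.008),
           conc_mean = 10, conc_sd = 2, correlation = 0.3)),
    background_bands = data.frame(center_nm = 1118, sigma_nm = 20,
                                  amplitude = 0.4),
    baseline_offset_sd = 0.005,
    baseline_slope_sd = 1e-5,
    noise_sd = 0.002,
    seed = seed + 1L)
  rank1_cfg <- synthetic_config(
    axis = wl_axis(1100, 2, 50),
    n_samples = 40L,
    analyte_bands = data.frame(center_nm = 1150, sigma_nm = 10,
                               amplitude = 0.01),
    interferents = list(),
    baseline_offset_sd = 0,
    baseline_slope_sd = 0,
    noise_sd = 0,
    seed = seed + 2L)
  out <- list(planted_band = generate_synthetic(planted_cfg),
              tiny = generate_synthetic(tiny_cfg),
              rank1 = generate_synthetic(rank1_cfg))
  out$planted_band$config <- planted_cfg
  out$tiny$config <- tiny_cfg
  out$rank1$config <- rank1_cfg
  out
}

#' Write the ground-truth record beside a synthetic dataset
#'
#' @param truth the `truth` element of [generate_synthetic()].
#' @param path output CSV path for the per-sample table (concentrations and
#'   baseline terms); the band table and scalar settings are written beside
#'   it to `paste0(path, ".bands.csv")`.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  per_sample <- cbind(truth$concentrations, truth$baseline)
  utils::write.csv(per_sample, path, row.names = FALSE)
  bands <- truth$analyte_bands
  bands$component <- "analyte"
  for (k in seq_along(truth$interferent_bands)) {
    b <- truth$interferent_bands[[k]]
    b$component <- paste0("interferent", k)
    bands <- rbind(bands, b)
  }
  bands$noise_sd <- truth$noise_sd
  bands$snr <- truth$snr
  bands$seed <- truth$seed
  utils::write.csv(bands, paste0(path, ".bands.csv"), row.names = FALSE)
  invisible(path)
}
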