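#' Pure-component absorbance library for synthetic spectra
#'
#' Builds one smooth, strictly positive absorbance curve per compositional
#' component (moisture, oil, protein, starch) on the standard 700-point
#' 1,100-2,498 nm grid. Each curve is a small constant offset plus 3-6
#' Gaussian bands anchored at the component's characteristic near-infrared
#' absorption wavelengths (water O-H at ~1450/1940 nm, lipid C-H overtones
#' at ~1210/1725/2310 nm, protein N-H at ~1510/2050/2180 nm, carbohydrate
#' O-H/C-O at ~1540/2100/2280 nm), with seeded jitter on band position,
#' width and strength. Amplitudes are absorbance per percent of the
#' component, so Beer-Lambert mixtures of typical compositions land in an
#' O(1) absorbance range. Curves are regenerated until all pairwise
#' correlations are below 0.999, keeping the components linearly
#' distinguishable.
#'
#' @param seed integer seed; the library is reproducible per seed.
#' @param wavelengths wavelength axis in nm (default `seq(1100, 2498, 2)`).
#' @param components component names; unnamed extra components get random
#'   band placements.
#' @return object of class `component_library` with fields `wavelengths`,
#'   `curves` (channels x components matrix) and `seed`.
#' @export
make_library <- function(seed, wavelengths = seq(1100, 2498, by = 2),
                         components = c("moisture", "oil", "protein",
                                        "starch")) {
  # characteristic band centers (nm), widths (nm) and relative strengths
  band_table <- list(
    moisture = list(centers = c(1190, 1450, 1940),
                    widths = c(60, 55, 75), strength = c(0.2, 0.7, 1.0)),
    oil = list(centers = c(1210, 1725, 1760, 2310, 2350),
               widths = c(35, 35, 30, 35, 30),
               strength = c(0.5, 1.0, 0.7, 0.9, 0.6)),
    protein = list(centers = c(1510, 1690, 2055, 2180),
                   widths = c(50, 45, 55, 50),
                   strength = c(0.6, 0.4, 1.0, 0.9)),
    starch = list(centers = c(1450, 1540, 2100, 2280),
                  widths = c(70, 65, 60, 55),
                  strength = c(0.3, 0.5, 1.0, 0.7)))
  span <- range(wavelengths)
  withr::with_seed(as.integer(seed), {
    for (attempt in 1:50) {
      curves <- vapply(components, function(cmp) {
        bt <- band_table[[cmp]]
        if (is.null(bt)) {
          nb <- sample(3:6, 1)
          bt <- list(centers = stats::runif(nb, span[1] + 50, span[2] - 50),
                     widths = stats::runif(nb, 30, 80),
                     strength = stats::runif(nb, 0.3, 1))
        }
        keep <- bt$centers > span[1] & bt$centers < span[2]
        centers <- bt$centers[keep] + stats::rnorm(sum(keep), 0, 8)
        widths <- bt$widths[keep] * stats::runif(sum(keep), 0.85, 1.15)
        amps <- 0.008 * bt$strength[keep] * stats::runif(sum(keep), 0.8, 1.2)
        curve <- rep(stats::runif(1, 0.002, 0.004), length(wavelengths))
        for (b in seq_along(centers))
          curve <- curve + amps[b] * exp(-(wavelengths - centers[b])^2 /
                                           (2 * widths[b]^2))
        curve
      }, numeric(length(wavelengths)))
      cc <- stats::cor(curves)
      if (max(abs(cc[upper.tri(cc)])) < 0.999) break
    }
    structure(list(wavelengths = wavelengths, curves = curves,
                   seed = as.integer(seed)),
              class = "component_library")
  })
}

#' Configuration of the synthetic dataset generator
#'
#' Defaults mirror the composition statistics of the 80-kernel corn
#' benchmark (means/stds in percent: moisture 10.23/0.38, oil 3.50/0.18,
#' protein 8.67/0.50, starch 64.70/0.82). Scatter and baseline artifacts are
#' off by default; enable them (e.g. `scatter_sigma = 0.05`) to create the
#' distortions that SNV/MSC preprocessing exists to remove.
#'
#' @param n_samples number of samples (default 80).
#' @param composition_mean,composition_sd named numeric vectors (percent).
#' @param scatter_sigma sd of the log-normal multiplicative scatter factor.
#' @param baseline_offset_sigma,baseline_slope_sigma sds of the additive
#'   baseline `a + b * lambda_norm` (absorbance units), with `lambda_norm`
#'   the wavelength axis rescaled to [0, 1].
#' @param noise_sd sd of additive Gaussian channel noise (absorbance units).
#' @param nonlinearity coefficient of an optional mild quadratic term
#'   `nonlinearity * mixture^2`, giving nonlinear structure a convolutional
#'   encoder can exploit; 0 disables it.
#' @param seed integer seed.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_samples = 80,
                             composition_mean = c(moisture = 10.23,
                                                  oil = 3.50,
                                                  protein = 8.67,
                                                  starch = 64.70),
                             composition_sd = c(moisture = 0.38,
                                                oil = 0.18,
                                                protein = 0.50,
                                                starch = 0.82),
                             scatter_sigma = 0,
                             baseline_offset_sigma = 0,
                             baseline_slope_sigma = 0,
                             noise_sd = 2e-4,
                             nonlinearity = 0,
                             seed = 1L) {
  stopifnot(n_samples >= 1, all(composition_sd >= 0), scatter_sigma >= 0,
            baseline_offset_sigma >= 0, baseline_slope_sigma >= 0,
            noise_sd >= 0,
            identical(names(composition_mean), names(composition_sd)))
  structure(list(n_samples = as.integer(n_samples),
                 composition_mean = composition_mean,
                 composition_sd = composition_sd,
                 scatter_sigma = scatter_sigma,
                 baseline_offset_sigma = baseline_offset_sigma,
                 baseline_slope_sigma = baseline_slope_sigma,
                 noise_sd = noise_sd, nonlinearity = nonlinearity,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# positive truncated-normal draws by rejection, at most 1000 retries each
rtruncnorm_pos <- function(n, mean, sd) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    for (try in 1:1000) {
      v <- stats::rnorm(1, mean, sd)
      if (v > 0) break
      v <- NA_real_
    }
    if (is.na(v)) stop("could not draw a positive composition value for mean ",
                       mean, ", sd ", sd)
    out[i] <- v
  }
  out
}

#' Generate a synthetic NIR dataset with known composition
#'
#' Spectra follow a Beer-Lambert linear mixing model with optional
#' instrument-like artifacts:
#' `spectrum_i = m_i * (sum_k c_ik * s_k + a_i + b_i * lambda_norm) + noise`,
#' where `s_k` are the library curves, `c_ik` the drawn compositions
#' (percent, stored as targets), `m_i` a log-normal multiplicative scatter
#' factor and `a_i + b_i * lambda_norm` an additive baseline.
#'
#' @param library a [make_library()] result.
#' @param config a [synthetic_config()].
#' @return a [spectra_set] with targets.
#' @examples
#' d <- generate_dataset(make_library(1), synthetic_config(n_samples = 5))
#' dim(d$absorbance)  # 5 x 700
#' @export
generate_dataset <- function(library, config = synthetic_config()) {
  stopifnot(inherits(library, "component_library"),
            inherits(config, "synthetic_config"))
  wl <- library$wavelengths
  lam <- (wl - min(wl)) / (max(wl) - min(wl))
  comps <- colnames(library$curves)
  stopifnot(identical(comps, names(config$composition_mean)))
  withr::with_seed(config$seed, {
    n <- config$n_samples
    conc <- vapply(comps, function(k)
      rtruncnorm_pos(n, config$composition_mean[[k]], config$composition_sd[[k]]),
      numeric(n))
    conc <- matrix(conc, nrow = n,
                   dimnames = list(NULL, comps))
    mix <- conc %*% t(library$curves)               # n x channels
    if (config$nonlinearity != 0)
      mix <- mix + config$nonlinearity * mix^2
    a <- stats::rnorm(n, 0, config$baseline_offset_sigma)
    b <- stats::rnorm(n, 0, config$baseline_slope_sigma)
    m <- exp(stats::rnorm(n, 0, config$scatter_sigma))
    spectra <- m * (mix + outer(a, rep(1, length(wl))) + outer(b, lam)) +
      matrix(stats::rnorm(n * length(wl), 0, config$noise_sd), n)
    spectra_set(wl, spectra,
                sample_ids = sprintf("SYN%03d", seq_len(n)),
                targets = as.data.frame(conc))
  })
}

#' Tiny golden fixture dataset
#'
#' An 8-sample by 32-channel synthetic dataset shipped as plain text under
#' `inst/extdata/golden_spectra.csv`, small enough that preprocessing
#' outputs can be verified by hand. `golden_fixture()` reads the checked-in
#' copy; `golden_fixture_build()` regenerates the identical object from code
#' (the file is its serialization).
#'
#' @return a [spectra_set] with 8 samples, 32 channels and 4 targets.
#' @export
golden_fixture <- function() {
  path <- system.file("extdata", "golden_spectra.csv", package = "nircae",
                      mustWork = TRUE)
  suppressMessages(read_spectra(path))
}

#' @rdname golden_fixture
#' @export
golden_fixture_build <- function() {
  lib <- make_library(401, wavelengths = seq(1100, 2464, by = 44))
  generate_dataset(lib, synthetic_config(n_samples = 8, noise_sd = 2e-4,
                                         seed = 402))
}
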