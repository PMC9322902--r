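#' Gaussian band specification for the synthetic generator
#'
#' @param center band center in cm-1
#' @param width Gaussian sigma in cm-1 (> 0)
#' @param amplitude_mean mean peak absorbance in AU (>= 0)
#' @param classes character subset of c("A", "B"): classes whose spectra
#'   carry the band
#' @param amplitude_cv fractional (log-normal) inter-sample variability of
#'   the amplitude (>= 0)
#' @param assignment free-text vibrational assignment (reporting only)
#' @return a `band_spec` list
#' @export
band_spec <- function(center, width, amplitude_mean, classes = c("A", "B"),
                      amplitude_cv = 0.15, assignment = "") {
  stopifnot(width > 0, amplitude_mean >= 0, amplitude_cv >= 0,
            length(classes) >= 1, all(classes %in% c("A", "B")))
  structure(list(center = center, width = width,
                 amplitude_mean = amplitude_mean, amplitude_cv = amplitude_cv,
                 classes = classes, assignment = assignment),
            class = "band_spec")
}

#' Default mid-IR band catalogue for the two herbal classes
#'
#' Shared bands cover the O-H/saccharide, C-H/lipid, C=O, amide I, organic
#' acid and C-O fingerprint features common to both flower-bud classes;
#' class A additionally carries the amide II band at 1545 cm-1 plus
#' saccharide modes at 1400 and 930 cm-1, class B the aromatic 1528 cm-1
#' band and the saponin 781 cm-1 band. The five class-restricted bands are
#' what makes the two classes separable.
#'
#' @param amplitude_cv inter-sample amplitude variability applied to every
#'   band
#' @param discriminating_scale multiplier on the five class-restricted band
#'   amplitudes (1 = default; < 1 makes the problem harder)
#' @return list of [band_spec()] entries
#' @export
default_bands <- function(amplitude_cv = 0.15, discriminating_scale = 1) {
  b <- function(center, width, amp, classes = c("A", "B"), assign = "")
    band_spec(center, width, amp, classes, amplitude_cv, assign)
  ds <- discriminating_scale
  list(
    b(3350, 90, 0.90, assign = "O-H stretch (water/saccharides)"),
    b(2920, 14, 0.50, assign = "CH2 asym. stretch (lipids)"),
    b(2851, 11, 0.30, assign = "CH2 sym. stretch (lipids)"),
    b(1730, 12, 0.35, assign = "C=O stretch (lipids)"),
    b(1630, 18, 0.60, assign = "amide I"),
    b(1440, 11, 0.30, assign = "O-H bend (organic acids)"),
    b(1374,  9, 0.25, assign = "O-H bend (organic acids)"),
    b(1320,  9, 0.20, assign = "C-O stretch"),
    b(1260, 10, 0.25, assign = "C-O stretch"),
    b(1150, 12, 0.35, assign = "CO-O-C asym. stretch"),
    b(1050, 25, 0.70, assign = "C-O stretch (starch)"),
    b(815,   8, 0.12, assign = "C-H bend (out of plane)"),
    b(1545,  5, 0.25 * ds, "A", "amide II (proteins)"),
    b(1400,  5, 0.20 * ds, "A", "O-C-H bend (saccharides)"),
    b(930,   5, 0.14 * ds, "A", "saccharide skeletal"),
    b(1528,  5, 0.25 * ds, "B", "aromatic skeletal (flavonoids)"),
    b(781,   5, 0.15 * ds, "B", "COO- skeletal (saponins)"))
}

#' Configuration of the synthetic spectrum generator
#'
#' Defines the study conditions the generator emulates: two classes sharing
#' a fingerprint band catalogue, distinguished only by class-restricted
#' bands; smooth per-sample baseline drift; multiplicative/additive scatter
#' distortion (particle-size and thickness effects); additive white noise.
#' Output is percent transmittance on the standard descending grid.
#'
#' @param n_per_class samples per class (>= 1)
#' @param grid wavenumber grid (default [default_grid()], 851 points)
#' @param bands band catalogue (default [default_bands()])
#' @param baseline list(degree, coef_scale, hump_amplitude): random
#'   polynomial baseline (coefficients ~ N(0, coef_scale) on a [-1, 1]
#'   abscissa) plus a broad Gaussian hump with |N(0, hump_amplitude)| height
#' @param scatter_slope_sd sdlog of the per-sample log-normal multiplicative
#'   distortion
#' @param scatter_offset_sd sd of the per-sample additive offset (AU)
#' @param noise_sd additive white noise sd (AU)
#' @param seed integer RNG seed; identical config + seed gives bit-identical
#'   output
#' @return a `synthetic_config` list
#' @export
synthetic_config <- function(n_per_class = 100, grid = default_grid(),
                             bands = default_bands(),
                             baseline = list(degree = 2, coef_scale = 0.03,
                                             hump_amplitude = 0.08),
                             scatter_slope_sd = 0.1,
                             scatter_offset_sd = 0.02,
                             noise_sd = 0.005, seed = 20220720) {
  stopifnot(n_per_class >= 1, noise_sd >= 0, scatter_slope_sd >= 0,
            scatter_offset_sd >= 0)
  structure(list(n_per_class = n_per_class, grid = grid, bands = bands,
                 baseline = baseline, scatter_slope_sd = scatter_slope_sd,
                 scatter_offset_sd = scatter_offset_sd, noise_sd = noise_sd,
                 seed = seed),
            class = "synthetic_config")
}

# Sum of class-appropriate Gaussian bands for one sample; amps is the vector
# of per-sample band amplitudes (catalogue order).
band_signal <- function(grid, bands, class, amps) {
  y <- numeric(length(grid))
  for (i in seq_along(bands)) {
    bd <- bands[[i]]
    if (!(class %in% bd$classes)) next
    y <- y + amps[i] * exp(-(grid - bd$center)^2 / (2 * bd$width^2))
  }
  y
}

#' The noise-free class-mean absorbance signal
#'
#' Deterministic sum of the class-appropriate bands at their mean
#' amplitudes; used as the clean reference in band-analysis checks.
#'
#' @param cfg a [synthetic_config()]
#' @param class "A" or "B"
#' @return numeric absorbance vector on `cfg$grid`
#' @export
clean_class_signal <- function(cfg, class = c("A", "B")) {
  class <- match.arg(class)
  band_signal(cfg$grid, cfg$bands,
              class, vapply(cfg$bands, `[[`, numeric(1), "amplitude_mean"))
}

#' Generate a labeled two-class synthetic spectrum set
#'
#' For each sample: clean absorbance = sum of class-appropriate Gaussian
#' bands with log-normal per-sample amplitude jitter; plus a random smooth
#' baseline; then y <- a*y + b with a ~ LogNormal(0, scatter_slope_sd) and
#' b ~ Normal(0, scatter_offset_sd); plus white noise. Absorbance is clipped
#' to [0, 4] and converted to percent transmittance \%T = 10^(2 - A).
#' Class-A samples come first; draws occur in a fixed per-sample order, so a
#' given config and seed always reproduce the same matrix.
#'
#' @param cfg a [synthetic_config()]
#' @return a [spectrum_set()] in transmittance mode with labels "A"/"B"
#' @export
generate_spectra <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(cfg$seed)

  grid <- cfg$grid
  m <- length(grid)
  nb <- length(cfg$bands)
  amp_mean <- vapply(cfg$bands, `[[`, numeric(1), "amplitude_mean")
  amp_cv <- vapply(cfg$bands, `[[`, numeric(1), "amplitude_cv")
  # log-normal with mean = amplitude_mean and cv = amplitude_cv
  sdlog <- sqrt(log1p(amp_cv^2))
  meanlog <- ifelse(amp_mean > 0, log(amp_mean) - sdlog^2 / 2, -Inf)
  x01 <- seq(-1, 1, length.out = m)  # baseline abscissa
  rng <- range(grid)

  n <- 2L * cfg$n_per_class
  vals <- matrix(0, n, m)
  labels <- rep(c("A", "B"), each = cfg$n_per_class)
  for (i in seq_len(n)) {
    amps <- ifelse(is.finite(meanlog),
                   exp(stats::rnorm(nb, meanlog, sdlog)), 0)
    y <- band_signal(grid, cfg$bands, labels[i], amps)
    if (!is.null(cfg$baseline)) {
      bl <- cfg$baseline
      coefs <- stats::rnorm(bl$degree + 1, 0, bl$coef_scale)
      base <- drop(outer(x01, 0:bl$degree, `^`) %*% coefs)
      hump_a <- abs(stats::rnorm(1, 0, bl$hump_amplitude))
      hump_c <- stats::runif(1, rng[1], rng[2])
      base <- base + hump_a * exp(-(grid - hump_c)^2 / (2 * (diff(rng) / 4)^2))
      y <- y + base - min(base)   # keep the drift nonnegative
    }
    a <- exp(stats::rnorm(1, 0, cfg$scatter_slope_sd))
    b <- stats::rnorm(1, 0, cfg$scatter_offset_sd)
    y <- a * y + b
    if (cfg$noise_sd > 0) y <- y + stats::rnorm(m, 0, cfg$noise_sd)
    vals[i, ] <- y
  }
  vals <- pmin(pmax(vals, 0), 4)
  tvals <- 10^(2 - vals)
  ids <- paste0(labels, rep(seq_len(cfg$n_per_class), 2))
  spectrum_set(grid, tvals, "transmittance_percent", ids, labels)
}

#' Named synthetic fixtures: training + external-prediction pairs
#'
#' Registry of study conditions used throughout the tests and the worked
#' analyses:
#' \describe{
#'   \item{easy}{100 samples per class on the 851-point grid, mild noise and
#'     scatter: a clearly (but not trivially) separable problem.}
#'   \item{hard}{same size, half-amplitude discriminating bands, quadrupled
#'     amplitude variability, doubled scatter and noise: overlapping
#'     classes.}
#'   \item{prescription}{training half identical in structure to "easy"; the
#'     external half adds a shared low-variability "excipient" band set
#'     (compound formulations containing one of the two classes) at low
#'     noise, and carries labels so predictions can be scored.}
#' }
#' The external set of every pair is generated at `seed + 1`.
#'
#' @param name one of "easy", "hard", "prescription"
#' @param seed base RNG seed
#' @param n_per_class training samples per class (default 100); the external
#'   set has 20 per class
#' @return list(training =, external =) of [spectrum_set()] objects
#' @export
make_fixture <- function(name = c("easy", "hard", "prescription"),
                         seed = 20220720, n_per_class = 100) {
  name <- match.arg(name)
  ext_n <- 20
  if (name == "easy") {
    train <- generate_spectra(synthetic_config(n_per_class, seed = seed))
    ext <- generate_spectra(synthetic_config(ext_n, seed = seed + 1))
  } else if (name == "hard") {
    hard_cfg <- function(n, sd) synthetic_config(
      n, bands = default_bands(amplitude_cv = 0.6,
                               discriminating_scale = 0.3),
      scatter_slope_sd = 0.25, scatter_offset_sd = 0.05,
      noise_sd = 0.08, seed = sd)
    train <- generate_spectra(hard_cfg(n_per_class, seed))
    ext <- generate_spectra(hard_cfg(ext_n, seed + 1))
  } else {
    train <- generate_spectra(synthetic_config(n_per_class, seed = seed))
    exc <- function(center, width, amp)
      band_spec(center, width, amp, c("A", "B"), 0.1, "excipient")
    rx_bands <- c(default_bands(amplitude_cv = 0.1),
                  list(exc(2960, 15, 0.25), exc(1690, 14, 0.20),
                       exc(1210, 12, 0.22), exc(990, 18, 0.25),
                       exc(860, 10, 0.15)))
    ext <- generate_spectra(synthetic_config(
      ext_n, bands = rx_bands, scatter_slope_sd = 0.05,
      scatter_offset_sd = 0.01, noise_sd = 0.003, seed = seed + 1))
  }
  list(training = train, external = ext)
}
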