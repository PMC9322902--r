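# Shared fixture builders and a cross-test memo cache for the expensive
# study-scale objects (computed once per test run).

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, .fixture_cache))
    assign(name, force(expr), .fixture_cache)
  get(name, .fixture_cache)
}

# a small labeled transmittance set with visible band structure
tiny_spectra <- function(n_per_class = 6, seed = 42, noise_sd = 0.005) {
  generate_spectra(synthetic_config(n_per_class, noise_sd = noise_sd,
                                    seed = seed))
}

# deterministic unlabeled absorbance set on a short grid
toy_absorbance <- function(values, grid = NULL) {
  if (is.null(grid)) grid <- seq(1000 + 4 * (ncol(as.matrix(values)) - 1),
                                 1000, by = -4)
  spectrum_set(grid, values, "absorbance")
}

# noise-free, scatter-free, jitter-free two-class set (perfectly separable)
noise_free_spectra <- function(n_per_class = 20, seed = 11) {
  generate_spectra(synthetic_config(
    n_per_class, bands = default_bands(amplitude_cv = 0), baseline = NULL,
    scatter_slope_sd = 0, scatter_offset_sd = 0, noise_sd = 0, seed = seed))
}

# preprocessed calibration/validation matrices for a fixture + recipe
prep_fixture <- function(name = "easy", recipe_name = "vector_first",
                         seed = 20220720, n_per_class = 100) {
  s <- make_fixture(name, seed = seed, n_per_class = n_per_class)$training
  ftirdisc:::prepare_split_data(s, recipe_name, 0.8, NULL, seed)
}

expect_same_predictions <- function(a, b) {
  expect_identical(a$labels, b$labels)
  expect_identical(a$scores, b$scores)
}
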