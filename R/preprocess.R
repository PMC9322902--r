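#' Standard normal variate (SNV)
#'
#' Per-spectrum centering and scaling: each row becomes
#' (x - mean(x)) / sd(x), with the sample (n-1) standard deviation.
#'
#' @param s a `spectrum_set`
#' @return the transformed `spectrum_set`
#' @export
snv <- function(s) {
  mu <- rowMeans(s$values)
  sd_ <- apply(s$values, 1, stats::sd)
  if (any(sd_ == 0))
    stop("constant row(s), SNV undefined: ",
         paste(s$sample_ids[sd_ == 0], collapse = ", "))
  set_values(s, (s$values - mu) / sd_)
}

#' Multiplicative scatter correction (MSC)
#'
#' Each spectrum is regressed on a reference spectrum by ordinary least
#' squares, x ~ a*ref + b, and corrected to (x - b)/a. The reference
#' defaults to the mean spectrum of `s`; supply the calibration-set mean to
#' correct validation or external spectra without leakage.
#'
#' @param s a `spectrum_set`
#' @param reference numeric reference spectrum (default `colMeans(s$values)`)
#' @return the corrected `spectrum_set`
#' @export
msc <- function(s, reference = NULL) {
  if (is.null(reference)) reference <- colMeans(s$values)
  if (length(reference) != n_points(s))
    stop("reference length must match the grid")
  if (stats::sd(reference) == 0) stop("constant MSC reference")
  rc <- reference - mean(reference)
  denom <- sum(rc^2)
  out <- s$values
  for (i in seq_len(nrow(out))) {
    x <- out[i, ]
    a <- sum((x - mean(x)) * rc) / denom
    if (a == 0) stop("zero MSC slope for sample ", s$sample_ids[i])
    b <- mean(x) - a * mean(reference)
    out[i, ] <- (x - b) / a
  }
  set_values(s, out)
}

#' Savitzky-Golay smoothing / derivative filter
#'
#' Per-row Savitzky-Golay filtering with a local polynomial of order
#' `polyorder` over an odd window (9 points by default, the usual
#' chemometrics setting). `deriv` selects smoothing (0) or the first/second
#' derivative taken with respect to point index (unit step); boundary
#' windows are handled by the one-sided polynomial fits of the filter
#' matrix.
#'
#' @param s a `spectrum_set`
#' @param window odd window length (default 9)
#' @param polyorder polynomial order, < window (default 2)
#' @param deriv 0, 1 or 2
#' @return the filtered `spectrum_set`
#' @export
savitzky_golay <- function(s, window = 9, polyorder = 2, deriv = 0) {
  if (window %% 2 != 1) stop("window must be odd")
  if (polyorder >= window) stop("polyorder must be < window")
  if (!deriv %in% 0:2) stop("deriv must be 0, 1 or 2")
  if (window > n_points(s)) stop("window exceeds number of grid points")
  out <- t(apply(s$values, 1, function(x)
    signal::sgolayfilt(x, p = polyorder, n = window, m = deriv)))
  set_values(s, out)
}

#' Euclidean (vector) normalization
#'
#' Each row is divided by its Euclidean norm, so output rows have unit L2
#' norm.
#'
#' @param s a `spectrum_set`
#' @return the normalized `spectrum_set`
#' @export
vector_normalize <- function(s) {
  nrm <- sqrt(rowSums(s$values^2))
  if (any(nrm == 0))
    stop("zero row(s): ", paste(s$sample_ids[nrm == 0], collapse = ", "))
  set_values(s, s$values / nrm)
}

#' Area normalization
#'
#' Each row is divided by its integrated absorbance area, computed by the
#' trapezoidal rule with respect to increasing wavenumber. Output rows
#' integrate to 1; rows with non-positive area are rejected.
#'
#' @param s a `spectrum_set`
#' @return the normalized `spectrum_set`
#' @export
area_normalize <- function(s) {
  # signed integral w.r.t. increasing wavenumber (grid is stored descending)
  areas <- -row_trapz(s$values, s$wavenumbers)
  if (any(areas <= 0))
    stop("non-positive spectral area: ",
         paste(s$sample_ids[areas <= 0], collapse = ", "))
  set_values(s, s$values / areas)
}

# trapezoidal integral of each row over grid wn (signed)
row_trapz <- function(values, wn) {
  dw <- diff(wn)
  m <- length(wn)
  drop((values[, -m, drop = FALSE] + values[, -1, drop = FALSE]) %*% (dw / 2))
}

#' Min-max normalization
#'
#' The default variant (`"range"`) divides each row by its range
#' (max - min), leaving the offset untouched — the scaling convention of
#' this workflow's acquisition software. The `"conventional"` variant maps
#' each row onto [0, 1] via (x - min)/(max - min).
#'
#' @param s a `spectrum_set`
#' @param variant `"range"` or `"conventional"`
#' @return the normalized `spectrum_set`
#' @export
minmax_normalize <- function(s, variant = c("range", "conventional")) {
  variant <- match.arg(variant)
  lo <- apply(s$values, 1, min)
  hi <- apply(s$values, 1, max)
  rng <- hi - lo
  if (any(rng == 0))
    stop("constant row(s): ", paste(s$sample_ids[rng == 0], collapse = ", "))
  out <- if (variant == "range") s$values / rng else (s$values - lo) / rng
  set_values(s, out)
}

#' Row centering
#'
#' Subtracts the row mean from each spectrum; output row means are 0.
#'
#' @param s a `spectrum_set`
#' @return the centered `spectrum_set`
#' @export
row_center <- function(s) set_values(s, s$values - rowMeans(s$values))

#' Exponentially weighted moving-average smoothing
#'
#' One forward pass along the grid per row: z1 = x1,
#' z_t = lam*x_t + (1-lam)*z_(t-1).
#'
#' @param s a `spectrum_set`
#' @param lam smoothing weight in (0, 1]; default 0.2
#' @return the smoothed `spectrum_set`
#' @export
ewma_smooth <- function(s, lam = 0.2) {
  if (!(lam > 0 && lam <= 1)) stop("lam must be in (0, 1]")
  v <- s$values
  out <- v
  for (j in seq_len(ncol(v))[-1])
    out[, j] <- lam * v[, j] + (1 - lam) * out[, j - 1]
  set_values(s, out)
}

#' airPLS baseline correction
#'
#' Adaptive iteratively reweighted penalized least squares: per row, a
#' Whittaker smoother with roughness penalty lambda * ||D^d z||^2 is fit
#' under weights that are adaptively driven to zero wherever the signal
#' exceeds the running baseline estimate (peaks) and grown exponentially
#' with the iteration count below it, so the fit settles onto the baseline.
#' Iteration stops when the summed negative residual falls below
#' `tol * sum(|x|)` or at `max_iter` (with a warning).
#'
#' @param s a `spectrum_set` (absorbance recommended)
#' @param lambda smoothness penalty, > 0 (default 1e5)
#' @param diff_order penalty difference order, 1 or 2 (default 2)
#' @param max_iter iteration cap (default 15)
#' @param tol termination ratio in (0, 1) (default 0.001)
#' @return list(baseline =, corrected =) of `spectrum_set` objects;
#'   corrected + baseline reproduces the input exactly
#' @export
airpls <- function(s, lambda = 1e5, diff_order = 2, max_iter = 15,
                   tol = 0.001) {
  stopifnot(lambda > 0, diff_order %in% 1:2, max_iter >= 1,
            tol > 0, tol < 1)
  m <- n_points(s)
  if (m <= diff_order + 1) stop("too few grid points for the penalty order")
  D <- difference_matrix(m, diff_order)
  P <- lambda * Matrix::crossprod(D)
  base <- s$values
  for (i in seq_len(nrow(base)))
    base[i, ] <- airpls_row(s$values[i, ], P, max_iter, tol,
                            s$sample_ids[i])
  list(baseline = set_values(s, base),
       corrected = set_values(s, s$values - base))
}

# sparse d-th order forward-difference operator, (m - d) x m
difference_matrix <- function(m, d) {
  coefs <- (-1)^(0:d) * choose(d, 0:d)
  Matrix::sparseMatrix(
    i = rep(seq_len(m - d), each = d + 1),
    j = as.integer(outer(0:d, seq_len(m - d), `+`)),
    x = rep(rev(coefs), m - d), dims = c(m - d, m))
}

airpls_row <- function(x, P, max_iter, tol, id) {
  m <- length(x)
  w <- rep(1, m)
  z <- numeric(m)
  abs_x <- sum(abs(x))
  for (it in seq_len(max_iter)) {
    z <- as.numeric(Matrix::solve(Matrix::Diagonal(m, w) + P, w * x))
    d <- x - z
    neg <- d < 0
    dssn <- sum(abs(d[neg]))
    if (dssn < tol * abs_x) return(z)
    if (it == max_iter) break
    w[!neg] <- 0
    w[neg] <- exp(it * abs(d[neg]) / dssn)
  }
  warning("airPLS did not converge in ", max_iter, " iterations for sample ",
          id)
  z
}

#' Approximate ATR penetration-depth correction
#'
#' In ATR the effective path length scales inversely with wavenumber, so
#' low-wavenumber bands are over-weighted. This applies the simple
#' proportional compensation A'(v) = A(v) * v / ref_wavenumber — an
#' approximation of the instrument vendor's proprietary correction, linear
#' in A and the identity at the reference wavenumber.
#'
#' @param s a `spectrum_set` in absorbance mode
#' @param ref_wavenumber reference in cm-1 (default 1000)
#' @return the corrected `spectrum_set`
#' @export
atr_correct <- function(s, ref_wavenumber = 1000) {
  if (s$mode != "absorbance") stop("atr_correct expects absorbance")
  set_values(s, sweep(s$values, 2, s$wavenumbers / ref_wavenumber, `*`))
}

# ---------------------------------------------------------------------------
# Recipes: ordered, parameterized transform chains

transform_registry <- function() {
  list(
    to_absorbance   = function(s, p, st) to_absorbance(s),
    snv             = function(s, p, st) snv(s),
    msc             = function(s, p, st) msc(s, reference = st$reference),
    savitzky_golay  = function(s, p, st)
      do.call(savitzky_golay, c(list(s), p)),
    vector_normalize = function(s, p, st) vector_normalize(s),
    area_normalize  = function(s, p, st) area_normalize(s),
    minmax_normalize = function(s, p, st)
      do.call(minmax_normalize, c(list(s), p)),
    row_center      = function(s, p, st) row_center(s),
    ewma_smooth     = function(s, p, st) do.call(ewma_smooth, c(list(s), p)),
    airpls          = function(s, p, st)
      do.call(airpls, c(list(s), p))$corrected,
    atr_correct     = function(s, p, st)
      do.call(atr_correct, c(list(s), p)))
}

#' Build a preprocessing recipe
#'
#' A recipe is an ordered chain of named transforms with parameters, applied
#' left to right by [apply_recipe()]. Use [fit_recipe()] to freeze
#' data-dependent state (the MSC reference) on a calibration set.
#'
#' @param steps list of `list(name = <transform>, params = list(...))`
#'   entries; a bare character vector of transform names is also accepted
#' @param name optional preset id
#' @return a `preprocess_recipe`
#' @export
recipe <- function(steps, name = NULL) {
  reg <- names(transform_registry())
  if (is.character(steps))
    steps <- lapply(steps, function(nm) list(name = nm, params = list()))
  for (st in steps) {
    if (!st$name %in% reg)
      stop("unknown transform: ", st$name)
  }
  structure(list(steps = steps, name = name), class = "preprocess_recipe")
}

#' Names of the eleven preset pretreatment recipes
#' @return character vector of preset ids
#' @export
preset_names <- function() {
  c("none", "vector_first", "vector_second", "minmax", "area", "ewma",
    "msc", "rc", "sg", "snv", "airpls")
}

#' Preset pretreatment recipes
#'
#' The eleven pretreatments compared in this workflow's model grid. Every
#' preset starts by converting percent transmittance to absorbance
#' ("none" stops there). "vector_first"/"vector_second" take the first or
#' second Savitzky-Golay derivative (window 9, order 2) and then Euclidean
#' normalization; "area" and "minmax" apply the approximate ATR correction
#' before normalizing; the rest are single filters.
#'
#' @param name a preset id from [preset_names()]
#' @return a [recipe()]
#' @export
preset_recipe <- function(name) {
  step <- function(nm, ...) list(name = nm, params = list(...))
  chains <- list(
    none          = list(step("to_absorbance")),
    vector_first  = list(step("to_absorbance"),
                         step("savitzky_golay", window = 9, polyorder = 2,
                              deriv = 1),
                         step("vector_normalize")),
    vector_second = list(step("to_absorbance"),
                         step("savitzky_golay", window = 9, polyorder = 2,
                              deriv = 2),
                         step("vector_normalize")),
    minmax        = list(step("to_absorbance"), step("atr_correct"),
                         step("minmax_normalize")),
    area          = list(step("to_absorbance"), step("atr_correct"),
                         step("area_normalize")),
    ewma          = list(step("to_absorbance"), step("ewma_smooth")),
    msc           = list(step("to_absorbance"), step("msc")),
    rc            = list(step("to_absorbance"), step("row_center")),
    sg            = list(step("to_absorbance"),
                         step("savitzky_golay", window = 9, polyorder = 2,
                              deriv = 0)),
    snv           = list(step("to_absorbance"), step("snv")),
    airpls        = list(step("to_absorbance"), step("airpls")))
  if (!name %in% names(chains)) stop("unknown preset recipe: ", name)
  recipe(chains[[name]], name = name)
}

#' Fit a recipe's data-dependent state on a calibration set
#'
#' Walks the chain over the calibration spectra, recording learned
#' statistics (currently: the MSC reference = mean calibration spectrum at
#' that point in the chain). The returned fitted recipe applies identically
#' to calibration, validation and external sets, so no validation
#' information leaks into the state.
#'
#' @param rec a [recipe()]
#' @param s calibration `spectrum_set`
#' @return a `fitted_recipe`
#' @export
fit_recipe <- function(rec, s) {
  stopifnot(inherits(rec, "preprocess_recipe"))
  reg <- transform_registry()
  states <- vector("list", length(rec$steps))
  cur <- s
  for (i in seq_along(rec$steps)) {
    stp <- rec$steps[[i]]
    st <- NULL
    if (stp$name == "msc" && is.null(stp$params$reference))
      st <- list(reference = colMeans(cur$values))
    states[[i]] <- st
    cur <- reg[[stp$name]](cur, stp$params, st)
  }
  structure(list(recipe = rec, states = states), class = "fitted_recipe")
}

#' Apply a recipe (or fitted recipe) to a spectrum set
#'
#' A plain recipe is fitted on `s` itself and applied (self-contained mode,
#' used before any calibration/validation split exists); a
#' [fit_recipe()]-fitted recipe reuses its frozen calibration state.
#'
#' @param rec a `preprocess_recipe` or `fitted_recipe`
#' @param s a `spectrum_set`
#' @return the preprocessed `spectrum_set`
#' @export
apply_recipe <- function(rec, s) {
  if (inherits(rec, "preprocess_recipe")) rec <- fit_recipe(rec, s)
  stopifnot(inherits(rec, "fitted_recipe"))
  reg <- transform_registry()
  cur <- s
  for (i in seq_along(rec$recipe$steps)) {
    stp <- rec$recipe$steps[[i]]
    cur <- tryCatch(
      reg[[stp$name]](cur, stp$params, rec$states[[i]]),
      error = function(e)
        stop(sprintf("recipe %s, step %d (%s): %s",
                     rec$recipe$name %||% "<anonymous>", i, stp$name,
                     conditionMessage(e)), call. = FALSE))
  }
  cur
}

`%||%` <- function(a, b) if (is.null(a)) b else a
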