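# Row-wise transform oracles: every transform is checked against its
# closed-form identity and an independent arithmetic computation.

test_that("SNV centers and scales each row with the sample sd", {
  s <- toy_absorbance(matrix(c(1, 2, 3), 1))
  expect_equal(unname(snv(s)$values[1, ]), c(-1, 0, 1))

  set.seed(1)
  r <- toy_absorbance(matrix(rnorm(40, 2, 3), 2))
  out <- snv(r)
  # two-pass mean/sd oracle
  for (i in 1:2) {
    x <- r$values[i, ]
    expect_equal(unname(out$values[i, ]),
                 unname((x - mean(x)) / sqrt(sum((x - mean(x))^2) / 19)))
  }
  expect_equal(snv(out)$values, out$values)   # idempotent
  expect_error(snv(toy_absorbance(matrix(5, 1, 4))), "constant")
})

test_that("MSC de-slopes and de-offsets against the reference", {
  set.seed(2)
  ref <- abs(rnorm(30)) + 1
  s <- toy_absorbance(rbind(ref, 2 * ref + 3))
  out <- msc(s, reference = ref)
  expect_equal(unname(out$values[1, ]), unname(ref))
  expect_equal(unname(out$values[2, ]), unname(ref), tolerance = 1e-12)

  # random spectrum: slope/offset match the closed-form simple regression
  x <- rnorm(30, 1, 2)
  a <- sum((x - mean(x)) * (ref - mean(ref))) / sum((ref - mean(ref))^2)
  b <- mean(x) - a * mean(ref)
  got <- msc(toy_absorbance(matrix(x, 1)), reference = ref)
  expect_equal(unname(got$values[1, ]), (x - b) / a)

  # default reference is the column-mean spectrum
  expect_equal(msc(s)$values,
               msc(s, reference = colMeans(s$values))$values)
  expect_error(msc(s, reference = rep(1, 30)), "constant")
})

test_that("Savitzky-Golay is exact on polynomials and their derivatives", {
  t <- 0:30
  const <- toy_absorbance(matrix(5, 1, 31))
  expect_equal(unname(savitzky_golay(const, deriv = 1)$values[1, ]),
               rep(0, 31), tolerance = 1e-12)

  # deriv of t^2 fitted with order-2 polynomial is 2t at interior points
  sq <- toy_absorbance(matrix(t^2, 1))
  d1 <- savitzky_golay(sq, window = 9, polyorder = 2, deriv = 1)
  expect_equal(unname(d1$values[1, 5:27]), 2 * t[5:27], tolerance = 1e-9)

  # smoothing reproduces any polynomial of degree <= polyorder exactly
  poly <- 1 + 0.5 * t - 0.02 * t^2
  sm <- savitzky_golay(toy_absorbance(matrix(poly, 1)), deriv = 0)
  expect_equal(unname(sm$values[1, 5:27]), poly[5:27], tolerance = 1e-9)

  expect_error(savitzky_golay(sq, window = 8), "odd")
  expect_error(savitzky_golay(sq, window = 9, polyorder = 9), "polyorder")
  expect_error(savitzky_golay(toy_absorbance(matrix(1:5, 1)), window = 9),
               "exceeds")
})

test_that("vector normalization yields unit Euclidean rows", {
  s <- toy_absorbance(matrix(c(3, 4), 1))
  expect_equal(unname(vector_normalize(s)$values[1, ]), c(0.6, 0.8))
  set.seed(3)
  r <- toy_absorbance(matrix(rnorm(60), 3))
  out <- vector_normalize(r)
  expect_equal(unname(sqrt(rowSums(out$values^2))), rep(1, 3),
               tolerance = 1e-12)
  scaled <- vector_normalize(ftirdisc:::set_values(r, r$values * 7))
  expect_equal(scaled$values, out$values)
  expect_error(vector_normalize(toy_absorbance(matrix(0, 1, 4))), "zero")
})

test_that("area normalization divides by the trapezoidal integral", {
  g <- seq(4000, 600, by = -4)
  s <- spectrum_set(g, matrix(1, 1, length(g)), "absorbance")
  expect_equal(unname(area_normalize(s)$values[1, 1]), 1 / 3400)

  set.seed(4)
  r <- spectrum_set(g, matrix(runif(2 * length(g), 0.1, 2), 2), "absorbance")
  out <- area_normalize(r)
  # brute-force trapezoid oracle
  for (i in 1:2) {
    area <- sum((r$values[i, -1] + r$values[i, -length(g)]) / 2 * 4)
    expect_equal(unname(out$values[i, ]), unname(r$values[i, ] / area))
    out_area <- sum((out$values[i, -1] + out$values[i, -length(g)]) / 2 * 4)
    expect_equal(out_area, 1, tolerance = 1e-9)
  }
  neg <- spectrum_set(g, matrix(-1, 1, length(g)), "absorbance")
  expect_error(area_normalize(neg), "area")
})

test_that("min-max normalization has a range-only and a conventional form", {
  s <- toy_absorbance(matrix(c(0, 1, 2), 1))
  expect_equal(unname(minmax_normalize(s)$values[1, ]), c(0, 0.5, 1))
  shifted <- toy_absorbance(matrix(c(5, 6, 7), 1))
  # range-only scaling is not shift invariant
  expect_equal(unname(minmax_normalize(shifted)$values[1, ]),
               c(2.5, 3, 3.5))
  expect_equal(unname(minmax_normalize(shifted,
                                       "conventional")$values[1, ]),
               c(0, 0.5, 1))
  expect_error(minmax_normalize(toy_absorbance(matrix(2, 1, 3))), "constant")
})

test_that("row centering removes the row mean and is idempotent", {
  s <- toy_absorbance(matrix(c(1, 2, 3), 1))
  expect_equal(unname(row_center(s)$values[1, ]), c(-1, 0, 1))
  set.seed(5)
  r <- toy_absorbance(matrix(rnorm(50, 3), 2))
  out <- row_center(r)
  expect_equal(unname(rowMeans(out$values)), c(0, 0), tolerance = 1e-12)
  expect_equal(row_center(out)$values, out$values)
})

test_that("EWMA runs the stated forward recursion", {
  s <- toy_absorbance(matrix(c(0, 1, 1), 1))
  expect_equal(unname(ewma_smooth(s, 0.5)$values[1, ]), c(0, 0.5, 0.75))
  expect_equal(ewma_smooth(s, 1)$values, s$values)
  const <- toy_absorbance(matrix(2, 2, 5))
  expect_equal(ewma_smooth(const, 0.3)$values, const$values)
  expect_error(ewma_smooth(s, 0), "lam")
  expect_error(ewma_smooth(s, 1.5), "lam")
})

test_that("ATR correction scales absorbance in proportion to wavenumber", {
  s <- spectrum_set(c(2000, 1000, 500), matrix(c(1, 1, 1), 1), "absorbance")
  out <- atr_correct(s, ref_wavenumber = 1000)
  expect_equal(unname(out$values[1, ]), c(2, 1, 0.5))
  # linear in A
  out2 <- atr_correct(ftirdisc:::set_values(s, 3 * s$values), ref_wavenumber = 1000)
  expect_equal(out2$values, 3 * out$values)
  expect_error(atr_correct(tiny_spectra(1)), "absorbance")
})

test_that("every transform commutes with sample reordering", {
  s <- tiny_spectra(4, seed = 9)
  sa <- to_absorbance(s)
  ref <- colMeans(sa$values)
  perm <- c(3, 1, 4, 2)
  ops <- list(
    function(x) snv(x), function(x) msc(x, reference = ref),
    function(x) savitzky_golay(x, deriv = 1),
    function(x) vector_normalize(x), function(x) area_normalize(x),
    function(x) minmax_normalize(x), function(x) row_center(x),
    function(x) ewma_smooth(x), function(x) airpls(x)$corrected)
  for (op in ops) {
    a <- op(subset_samples(sa, perm))
    b <- subset_samples(op(sa), perm)
    expect_equal(a$values, b$values)
  }
})

test_that("preset recipes compose the documented chains", {
  expect_setequal(preset_names(),
                  c("none", "vector_first", "vector_second", "minmax",
                    "area", "ewma", "msc", "rc", "sg", "snv", "airpls"))
  s <- tiny_spectra(3, seed = 10)
  expect_equal(apply_recipe(preset_recipe("none"), s)$values,
               to_absorbance(s)$values)
  manual <- vector_normalize(savitzky_golay(to_absorbance(s), window = 9,
                                            polyorder = 2, deriv = 1))
  expect_equal(apply_recipe(preset_recipe("vector_first"), s)$values,
               manual$values)
  manual_area <- area_normalize(atr_correct(to_absorbance(s)))
  expect_equal(apply_recipe(preset_recipe("area"), s)$values,
               manual_area$values)
  expect_error(preset_recipe("nope"), "unknown")
  expect_error(recipe(list(list(name = "bogus", params = list()))),
               "unknown transform")
})

test_that("fitted recipes freeze calibration statistics for reuse", {
  s <- tiny_spectra(6, seed = 12)
  cal <- subset_samples(s, 1:8)
  val <- subset_samples(s, 9:12)
  fr <- fit_recipe(preset_recipe("msc"), cal)
  # frozen reference = calibration-set mean at that point in the chain
  expect_equal(fr$states[[2]]$reference,
               colMeans(to_absorbance(cal)$values))
  v1 <- apply_recipe(fr, val)
  v2 <- msc(to_absorbance(val),
            reference = colMeans(to_absorbance(cal)$values))
  expect_equal(v1$values, v2$values)
  # self-mode on the validation set differs (different reference)
  v3 <- apply_recipe(preset_recipe("msc"), val)
  expect_false(isTRUE(all.equal(v1$values, v3$values)))
})
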