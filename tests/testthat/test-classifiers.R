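# compact two-cloud geometry for the kernel-machine checks
two_clouds <- function(n = 20, sep = 6, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(2 * n), ncol = 2),
             matrix(rnorm(2 * n, mean = sep), ncol = 2))
  list(X = X, y = rep(c("A", "B"), each = n))
}

test_that("RF fits are deterministic and expose OOB state", {
  d <- two_clouds()
  m1 <- fit_rf(d$X, d$y, n_tree = 100, seed = 3)
  m2 <- fit_rf(d$X, d$y, n_tree = 100, seed = 3)
  expect_same_predictions(predict(m1, d$X), predict(m2, d$X))
  expect_true(is.numeric(m1$oob_error))
  expect_length(rf_importance(m1), 2)
  expect_error(fit_rf(d$X, rep("A", 40)), "2 classes")
})

test_that("n_tree tuning returns the OOB-error argmin with its table", {
  d <- two_clouds(n = 15, sep = 2.2, seed = 5)
  single <- tune_ntree(d$X, d$y, rf_config(n_tree_grid = 300, seed = 5))
  expect_equal(single$best_n_tree, 300)
  res <- tune_ntree(d$X, d$y,
                    rf_config(n_tree_grid = c(50, 100, 200), seed = 5))
  expect_equal(nrow(res$table), 3)
  best_err <- res$table$oob_error[res$table$n_tree == res$best_n_tree]
  expect_true(all(best_err <= res$table$oob_error))
})

test_that("m_try tuning centers its default grid on floor(sqrt(p))", {
  expect_equal(default_mtry_grid(100), c(4, 6, 8, 10, 12, 14, 16, 18))
  expect_length(default_mtry_grid(851), 8)
  expect_true(29 %in% default_mtry_grid(851))   # floor(sqrt(851)) = 29

  d <- two_clouds(n = 15, sep = 2.2, seed = 6)
  one <- tune_mtry(d$X, d$y, n_tree = 100, grid = 2, seed = 6)
  expect_equal(one$best_m_try, 2)
  expect_error(tune_mtry(d$X, d$y, grid = 5), "exceeds")
  res <- tune_mtry(d$X, d$y, n_tree = 100, grid = 1:2, seed = 6)
  best <- res$table[res$table$m_try == res$best_m_try, ]
  expect_true(all(best$oob_error <= res$table$oob_error))
})

test_that("permutation importance singles out the informative variable", {
  set.seed(9)
  n <- 60; p <- 25; j <- 7
  X <- matrix(rnorm(n * p), n)
  y <- rep(c("A", "B"), each = n / 2)
  X[, j] <- X[, j] + ifelse(y == "A", 2.5, -2.5)
  m <- fit_rf(X, y, n_tree = 300, seed = 9)
  sc <- rf_importance(m)
  expect_equal(unname(which.max(sc)), j)
  expect_equal(max(sc), 1)
  expect_lt(median(abs(sc[-j])), 0.05)
  expect_length(sc, p)
  expect_length(attr(sc, "raw"), p)
})

test_that("VIP selection thresholds the rescaled scores", {
  sc <- c(a = 0.002, b = 0.5, c = 1, d = 0.019, e = 0.3)
  expect_equal(select_by_vip(sc, 1e-9), 1:5, ignore_attr = TRUE)
  expect_warning(top <- select_by_vip(sc, 1), "top 2")
  expect_setequal(top, c(2, 3))
  n_kept <- sapply(c(0.01, 0.1, 0.4, 0.9),
                   function(ct) length(suppressWarnings(select_by_vip(sc, ct))))
  expect_true(all(diff(n_kept) <= 0))
})

test_that("RBF SVM separates distant clouds and degrades on XOR at tiny gamma", {
  d <- two_clouds(n = 20, sep = 8, seed = 11)
  m <- fit_svm_rbf(d$X, d$y)
  expect_equal(mean(predict(m, d$X)$labels == d$y), 1)
  newpt <- matrix(c(0, 0, 8, 8), 2, byrow = TRUE)
  pr <- predict(m, newpt)
  expect_equal(pr$labels, c("A", "B"))
  expect_true(all(pr$scores >= 0 & pr$scores <= 1))

  # XOR is not linearly separable; gamma -> 0 flattens the RBF to ~linear
  set.seed(12)
  Xx <- matrix(runif(400, -1, 1), ncol = 2)
  yx <- ifelse(Xx[, 1] * Xx[, 2] > 0, "A", "B")
  mx <- fit_svm_rbf(Xx, yx, svm_config(gamma = 2^-10, cost = 1))
  expect_lte(mean(predict(mx, Xx)$labels == yx), 0.75)
  # while a tuned-width machine solves it
  mg <- fit_svm_rbf(Xx, yx, svm_config(gamma = 1, cost = 10))
  expect_gt(mean(predict(mg, Xx)$labels == yx), 0.9)
})

test_that("SVM grid search picks by CV accuracy with deterministic ties", {
  d <- two_clouds(n = 10, sep = 5, seed = 13)
  m <- fit_svm_rbf(d$X, d$y, svm_config(gamma = "grid", cost = "grid",
                                        seed = 13))
  expect_true(m$tuned_params$gamma %in% 2^(-10:2))
  expect_true(m$tuned_params$cost %in% 2^(-3:7))
  tab <- m$tuning_table
  expect_equal(nrow(tab), 11 * 13)
  # the chosen cell attains the maximal CV accuracy
  expect_equal(max(tab$cv_acc),
               tab$cv_acc[tab$gamma == m$tuned_params$gamma &
                            tab$cost == m$tuned_params$cost])
})

test_that("PCA-Mahalanobis screen flags at the chi-square rate", {
  set.seed(14)
  X <- matrix(rnorm(200 * 5), 200) %*% diag(c(5, 4, 3, 2, 1))
  keep <- plsda_outlier_removal(X, plsda_config())
  flagged <- 200 - length(keep)
  # Binomial(200, 0.025): central 99% interval is [0, 11]
  expect_lte(flagged, 11)

  # a gross displacement along PC1 is flagged
  X2 <- X
  X2[1, ] <- X2[1, ] + c(50, 0, 0, 0, 0)
  expect_false(1 %in% plsda_outlier_removal(X2, plsda_config()))
  # quantile 1 disables flagging
  expect_length(plsda_outlier_removal(X2,
                                      plsda_config(outlier_chi2_quantile = 1)),
                200)
})

test_that("PLS-DA matches linear-discriminant behavior on one component", {
  set.seed(15)
  n <- 60
  z <- rep(c(-1.5, 1.5), each = n / 2) + rnorm(n, 0, 0.6)
  dirn <- c(2, -1, 0.5, 0, 0)
  X <- outer(z, dirn) + matrix(rnorm(n * 5, 0, 0.05), n)
  y <- rep(c("A", "B"), each = n / 2)
  m <- fit_plsda(X, y, plsda_config(n_components = 1), positive_class = "B")
  pr <- predict(m, X)
  ld <- MASS::lda(X, grouping = y)
  ld_lab <- as.character(predict(ld, X)$class)
  expect_gte(mean(pr$labels == ld_lab), 0.95)
  expect_true(all(is.finite(pr$scores)))
  expect_true(all(pr$scores >= 0 & pr$scores <= 1))
})

test_that("PLS-DA component count comes from CV and caps at the rank", {
  d <- two_clouds(n = 15, sep = 3, seed = 16)
  m <- fit_plsda(d$X, d$y, plsda_config(seed = 16))
  expect_true(m$tuned_params$n_components >= 1)
  expect_lte(m$tuned_params$n_components, 2)
  expect_equal(nrow(m$cv_table), 2)
  expect_warning(fit_plsda(d$X, d$y, plsda_config(n_components = 10)),
                 "truncated")
})

test_that("prediction validates shape, is deterministic, and round-trips", {
  s <- noise_free_spectra(10)
  prep <- ftirdisc:::prepare_split_data(s, "snv", 0.8, NULL, 1)
  for (kind in c("rf", "svm", "plsda")) {
    m <- fit_model(kind, prep$Xcal, prep$ycal)
    expect_error(predict(m, prep$Xval[, 1:10]), "expected")
    pr <- predict(m, prep$Xval)
    expect_equal(pr$labels, prep$yval)      # separable fixture
    dup <- predict(m, prep$Xval[c(1, 1), ])
    expect_equal(dup$scores[1], dup$scores[2])
    dir <- withr::local_tempfile()
    save_model(m, dir)
    expect_true(file.exists(file.path(dir, "metadata.json")))
    m2 <- load_model(dir)
    expect_same_predictions(predict(m2, prep$Xval), pr)
  }
})
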