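# brute-force implementations used as oracles
metrics_brute <- function(TP, TN, FP, FN) {
  total <- TP + TN + FP + FN
  sens <- if (TP + FN == 0) 0 else TP / (TP + FN)
  spec <- if (TN + FP == 0) 0 else TN / (TN + FP)
  den <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  mcc <- if (den == 0) 0 else (TP * TN - FP * FN) / sqrt(den)
  c(sens = sens, spec = spec, acc = (TP + TN) / total, mcc = mcc)
}

auc_brute <- function(scores, y, pos) {
  sp <- scores[y == pos]; sn <- scores[y != pos]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

test_that("confusion tabulates the 2x2 counts", {
  y <- rep(c("A", "B"), each = 10)
  cc <- confusion(y, y, "A")
  expect_equal(c(cc$TP, cc$TN, cc$FP, cc$FN), c(10, 10, 0, 0))

  all_pos <- confusion(y, rep("A", 20), "A")
  expect_equal(c(all_pos$FN, all_pos$TN), c(0, 0))

  set.seed(6)
  yt <- sample(c("A", "B"), 30, replace = TRUE)
  yp <- sample(c("A", "B"), 30, replace = TRUE)
  cc <- confusion(yt, yp, "B")
  expect_equal(cc$TP, sum(yt == "B" & yp == "B"))
  expect_equal(cc$FP, sum(yt == "A" & yp == "B"))

  expect_error(confusion(yt, rep("C", 30), "A"), "unseen")
  expect_error(confusion(c("A", "B", "C"), c("A", "B", "C"), "A"),
               "more than 2")
})

test_that("metrics match the four closed-form definitions", {
  perfect <- metrics(confusion(rep(c("P", "N"), each = 50),
                               rep(c("P", "N"), each = 50), "P"))
  expect_equal(unlist(perfect[c("sens", "spec", "acc", "mcc")]),
               c(sens = 1, spec = 1, acc = 1, mcc = 1))

  cc <- structure(list(TP = 45, TN = 40, FP = 10, FN = 5,
                       positive_class = "P"), class = "confusion_counts")
  m <- metrics(cc)
  expect_equal(m$sens, 0.9)
  expect_equal(m$spec, 0.8)
  expect_equal(m$acc, 0.85)
  expect_equal(m$mcc, unname(metrics_brute(45, 40, 10, 5)["mcc"]))
})

test_that("metrics agree with enumeration over all tables of total <= 20", {
  for (total in 1:20) {
    parts <- expand.grid(TP = 0:total, TN = 0:total, FP = 0:total)
    parts$FN <- total - parts$TP - parts$TN - parts$FP
    parts <- parts[parts$FN >= 0, ]
    for (r in seq_len(nrow(parts))) {
      cc <- structure(list(TP = parts$TP[r], TN = parts$TN[r],
                           FP = parts$FP[r], FN = parts$FN[r],
                           positive_class = "P"),
                      class = "confusion_counts")
      got <- unlist(metrics(cc)[c("sens", "spec", "acc", "mcc")])
      want <- metrics_brute(parts$TP[r], parts$TN[r], parts$FP[r],
                            parts$FN[r])
      if (!isTRUE(all.equal(unname(got), unname(want))))
        fail(sprintf("mismatch at TP=%d TN=%d FP=%d FN=%d", parts$TP[r],
                     parts$TN[r], parts$FP[r], parts$FN[r]))
    }
  }
  succeed()
})

test_that("degenerate denominators yield 0 with a flag, not an error", {
  cc <- confusion(rep("A", 4), rep("A", 4), "A")   # no negatives at all
  m <- metrics(cc)
  expect_equal(m$spec, 0)
  expect_equal(m$mcc, 0)
  expect_true(all(c("spec", "mcc") %in% attr(m, "degenerate")))
})

test_that("rank AUC matches the pairwise oracle and its invariances", {
  y <- rep(c("P", "N"), each = 5)
  expect_equal(roc_auc(c(rep(1, 5), rep(0, 5)), y, "P"), 1)
  expect_equal(roc_auc(rep(0.3, 10), y, "P"), 0.5)
  expect_true(is.na(roc_auc(1:5, rep("P", 5), "P")))

  set.seed(7)
  for (rep in 1:100) {
    n <- sample(5:30, 1)
    yt <- c("P", "N", sample(c("P", "N"), n - 2, replace = TRUE))
    sc <- round(rnorm(n), sample(0:2, 1))   # rounding forces ties
    expect_equal(roc_auc(sc, yt, "P"), auc_brute(sc, yt, "P"))
  }

  # invariant under strictly monotone transforms of the scores
  sc <- rnorm(30)
  yt <- sample(c("P", "N"), 30, replace = TRUE, prob = c(.4, .6))
  expect_equal(roc_auc(exp(2 * sc) + 1, yt, "P"), roc_auc(sc, yt, "P"))
})

test_that("rank AUC agrees with an independent ROC package", {
  skip_if_not_installed("pROC")
  set.seed(8)
  sc <- rnorm(40)
  yt <- sample(c("P", "N"), 40, replace = TRUE)
  want <- as.numeric(pROC::auc(pROC::roc(
    response = yt, predictor = sc, levels = c("N", "P"),
    direction = "<", quiet = TRUE)))
  expect_equal(roc_auc(sc, yt, "P"), want)
})

test_that("comparison grid emits one row per recipe x model x set", {
  s <- cached("grid_small", {
    make_fixture("easy", seed = 5, n_per_class = 15)$training
  })
  tab <- cached("grid_small_tab", {
    comparison_grid(s, recipes = c("none", "snv", "rc"),
                    model_kinds = c("rf", "plsda"), seed = 5)
  })
  expect_equal(nrow(tab), 3 * 2 * 2)
  expect_setequal(unique(tab$set), c("calibration", "validation"))
  expect_true(all(is.na(tab$error)))
  expect_true(all(tab$acc >= 0 & tab$acc <= 1))
  # reproducible bit-identically under the same seed
  tab2 <- comparison_grid(s, recipes = c("none", "snv", "rc"),
                          model_kinds = c("rf", "plsda"), seed = 5)
  expect_identical(tab, tab2)
})

test_that("region experiment reports one row per region", {
  s <- cached("grid_small",
              make_fixture("easy", seed = 5, n_per_class = 15)$training)
  tab <- region_experiment(s, n_tree = 100, seed = 5)
  expect_equal(nrow(tab), 4)
  expect_equal(tab$n_variables[tab$region == "full"], 851)
  expect_true(all(is.na(tab$error)))
})

test_that("VIP experiment keeps fewer variables at higher cutoffs", {
  s <- cached("grid_small",
              make_fixture("easy", seed = 5, n_per_class = 15)$training)
  tab <- vip_experiment(s, cutoffs = c(0.05, 0.01, 0.015, 0.020),
                        n_tree = 100, seed = 5)
  expect_equal(nrow(tab), 4)
  ord <- order(tab$cutoff)
  expect_true(all(diff(tab$n_selected[ord]) <= 0))
})
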