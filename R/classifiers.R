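#' Random forest tuning configuration
#'
#' @param n_tree_grid ensemble sizes screened by OOB error
#' @param m_try "sqrt" (floor of sqrt(p)) or a positive integer
#' @param m_try_grid optional explicit m_try grid; `NULL` uses 8 values
#'   spaced by 2 and centered on floor(sqrt(p))
#' @param vip_cutoff_grid importance cutoffs screened in the variable
#'   selection experiment
#' @param seed RNG seed for bootstrap draws
#' @return an `rf_config` list
#' @export
rf_config <- function(n_tree_grid = c(100, 200, 300, 500, 800, 1000),
                      m_try = "sqrt", m_try_grid = NULL,
                      vip_cutoff_grid = c(0.05, 0.01, 0.015, 0.020),
                      seed = 20220720) {
  stopifnot(length(n_tree_grid) >= 1, length(vip_cutoff_grid) >= 1)
  structure(list(n_tree_grid = n_tree_grid, m_try = m_try,
                 m_try_grid = m_try_grid, vip_cutoff_grid = vip_cutoff_grid,
                 seed = seed), class = "rf_config")
}

#' SVM (RBF kernel) configuration
#'
#' `gamma = "auto"` uses 1/p; `gamma = "grid"` / `cost = "grid"` trigger a
#' 5-fold cross-validated search over gamma in 2^(-10..2) and cost in
#' 2^(-3..7), ties resolved toward smaller cost then smaller gamma.
#' Binary problems use libsvm's one-versus-one machinery (which for two
#' classes is the single +/-1-coded soft-margin machine).
#'
#' @param gamma RBF width: positive number, "auto" or "grid"
#' @param cost soft-margin penalty: positive number or "grid"
#' @param seed RNG seed for the CV folds
#' @return an `svm_config` list
#' @export
svm_config <- function(gamma = "auto", cost = 1, seed = 20220720) {
  structure(list(gamma = gamma, cost = cost,
                 multiclass_strategy = "OVO", seed = seed),
            class = "svm_config")
}

#' PLS-DA configuration
#'
#' @param n_components "cv" (choose by 5-fold CV misclassification, ties
#'   toward fewer components) or a positive integer
#' @param max_components upper bound for the CV search
#' @param decision_threshold class-1 threshold on the 0/1 response scale
#' @param outlier_pca_variance cumulative PCA variance retained for the
#'   Mahalanobis outlier screen
#' @param outlier_chi2_quantile chi-square flagging quantile (1 disables)
#' @param seed RNG seed for the CV folds
#' @return a `plsda_config` list
#' @export
plsda_config <- function(n_components = "cv", max_components = 10,
                         decision_threshold = 0.5,
                         outlier_pca_variance = 0.95,
                         outlier_chi2_quantile = 0.975, seed = 20220720) {
  stopifnot(decision_threshold > 0, decision_threshold < 1)
  structure(list(n_components = n_components, max_components = max_components,
                 decision_threshold = decision_threshold,
                 outlier_pca_variance = outlier_pca_variance,
                 outlier_chi2_quantile = outlier_chi2_quantile, seed = seed),
            class = "plsda_config")
}

check_two_class <- function(y) {
  y <- as.character(y)
  lv <- sort(unique(y))
  if (length(lv) != 2) stop("need exactly 2 classes, got: ",
                            paste(lv, collapse = ", "))
  lv
}

resolve_mtry <- function(m_try, p) {
  if (identical(m_try, "sqrt") || is.null(m_try)) return(max(1L, floor(sqrt(p))))
  m_try <- as.integer(m_try)
  if (m_try < 1 || m_try > p) stop("m_try must be in [1, p]")
  m_try
}

new_ftir_model <- function(kind, fit, tuned_params, var_names,
                           selected_idx, classes, positive_class,
                           importance = NULL, extra = list(),
                           metadata = list()) {
  structure(c(list(kind = kind, fit = fit, tuned_params = tuned_params,
                   var_names = var_names, selected_idx = selected_idx,
                   classes = classes, positive_class = positive_class,
                   importance = importance, metadata = metadata), extra),
            class = "ftir_model")
}

#' @export
print.ftir_model <- function(x, ...) {
  cat(sprintf("<ftir_model:%s> %d/%d variables, classes %s (positive: %s)\n",
              x$kind, length(x$selected_idx), length(x$var_names),
              paste(x$classes, collapse = "/"), x$positive_class))
  invisible(x)
}

#' Fit a random forest classifier
#'
#' Bagged CART ensemble over a random `m_try`-variable subset per node,
#' majority-vote prediction with per-class vote fractions as scores, OOB
#' predictions retained, permutation accuracy importance computed at fit
#' time.
#'
#' @param X calibration matrix (samples x variables)
#' @param y class labels (2 classes)
#' @param n_tree number of trees (default 300)
#' @param m_try variables tried per node ("sqrt" or integer)
#' @param seed RNG seed (fit is deterministic given it)
#' @param positive_class label treated as class 1 (default: first sorted
#'   level)
#' @return an `ftir_model`
#' @export
fit_rf <- function(X, y, n_tree = 300, m_try = "sqrt", seed = 20220720,
                   positive_class = NULL) {
  X <- as.matrix(X)
  lv <- check_two_class(y)
  positive_class <- positive_class %||% lv[1]
  mtry <- resolve_mtry(m_try, ncol(X))
  set.seed(seed)
  fit <- randomForest::randomForest(
    x = X, y = factor(y, levels = lv), ntree = n_tree, mtry = mtry,
    importance = TRUE, keep.forest = TRUE)
  raw_imp <- fit$importance[, "MeanDecreaseAccuracy"]
  new_ftir_model(
    "rf", fit, list(n_tree = n_tree, m_try = mtry),
    colnames(X) %||% as.character(seq_len(ncol(X))),
    seq_len(ncol(X)), lv, positive_class,
    importance = raw_imp,
    extra = list(oob_error = unname(fit$err.rate[n_tree, "OOB"]),
                 oob_votes = fit$votes, oob_predicted = fit$predicted,
                 seed = seed))
}

oob_metric_row <- function(fit, y, positive_class) {
  oob_pred <- as.character(fit$predicted)
  oob_score <- fit$votes[, positive_class]
  ev <- evaluate_predictions(y, oob_pred, oob_score, positive_class)
  cbind(data.frame(oob_error = mean(oob_pred != as.character(y))), ev)
}

#' Choose the number of trees by OOB error
#'
#' Fits one forest per grid value at `m_try = sqrt(p)` and returns the value
#' with the lowest OOB misclassification error (ties toward fewer trees),
#' together with the per-value OOB metric table.
#'
#' @param X,y calibration data
#' @param cfg an [rf_config()]
#' @param positive_class label treated as class 1
#' @return list(best_n_tree =, table =)
#' @export
tune_ntree <- function(X, y, cfg = rf_config(), positive_class = NULL) {
  lv <- check_two_class(y)
  positive_class <- positive_class %||% lv[1]
  rows <- lapply(cfg$n_tree_grid, function(nt) {
    m <- fit_rf(X, y, n_tree = nt, m_try = cfg$m_try, seed = cfg$seed,
                positive_class = positive_class)
    cbind(data.frame(n_tree = nt), oob_metric_row(m$fit, y, positive_class))
  })
  tab <- do.call(rbind, rows)
  best <- tab$n_tree[order(tab$oob_error, tab$n_tree)][1]
  list(best_n_tree = best, table = tab)
}

#' Default m_try screening grid: 8 values, step 2, centered on floor(sqrt(p))
#' @param p number of variables
#' @return integer grid clipped to [1, p]
#' @export
default_mtry_grid <- function(p) {
  ctr <- max(1L, floor(sqrt(p)))
  g <- ctr + 2L * (-3:4)
  sort(unique(pmin(pmax(g, 1L), p)))
}

#' Choose m_try by OOB error at a fixed number of trees
#'
#' Ties are resolved toward higher calibration (resubstitution) accuracy,
#' then the smaller m_try.
#'
#' @param X,y calibration data
#' @param n_tree fixed ensemble size
#' @param grid m_try values (default [default_mtry_grid()])
#' @param seed RNG seed
#' @param positive_class label treated as class 1
#' @return list(best_m_try =, table =)
#' @export
tune_mtry <- function(X, y, n_tree = 300, grid = NULL, seed = 20220720,
                      positive_class = NULL) {
  X <- as.matrix(X)
  lv <- check_two_class(y)
  positive_class <- positive_class %||% lv[1]
  if (is.null(grid)) grid <- default_mtry_grid(ncol(X))
  if (any(grid > ncol(X))) stop("m_try grid value exceeds variable count")
  rows <- lapply(grid, function(mt) {
    m <- fit_rf(X, y, n_tree = n_tree, m_try = mt, seed = seed,
                positive_class = positive_class)
    cal_acc <- mean(as.character(stats::predict(m$fit, X)) == as.character(y))
    cbind(data.frame(m_try = mt),
          oob_metric_row(m$fit, y, positive_class),
          data.frame(cal_acc = cal_acc))
  })
  tab <- do.call(rbind, rows)
  best <- tab$m_try[order(tab$oob_error, -tab$cal_acc, tab$m_try)][1]
  list(best_m_try = best, table = tab)
}

#' Permutation accuracy importance, rescaled to max 1
#'
#' Mean OOB accuracy drop when each variable is permuted (as retained by the
#' forest at fit time), divided by the maximum drop so the top variable
#' scores 1. The raw (unscaled) drops are attached as attribute `"raw"`.
#'
#' @param model a fitted RF `ftir_model`
#' @return named numeric vector of rescaled scores
#' @export
rf_importance <- function(model) {
  stopifnot(inherits(model, "ftir_model"), model$kind == "rf")
  raw <- model$importance
  mx <- max(raw)
  if (mx <= 0) {
    warning("no variable has positive importance; returning zeros")
    sc <- raw * 0
  } else sc <- raw / mx
  attr(sc, "raw") <- raw
  sc
}

#' Select variables whose rescaled importance reaches a cutoff
#'
#' Keeps variables with score >= cutoff; if fewer than two survive, the top
#' two by score are kept with a warning.
#'
#' @param importance rescaled importance scores ([rf_importance()])
#' @param cutoff threshold on the max-1 scale
#' @return integer indices of the retained variables
#' @export
select_by_vip <- function(importance, cutoff) {
  keep <- which(importance >= cutoff)
  if (length(keep) < 2) {
    warning("fewer than 2 variables at cutoff ", cutoff,
            "; keeping the top 2 by score")
    keep <- order(importance, decreasing = TRUE)[1:2]
  }
  sort(keep)
}

#' Fit an RBF-kernel support vector machine
#'
#' Soft-margin SVM with kernel K(x, y) = exp(-gamma * ||x - y||^2) on
#' +/-1-coded classes (libsvm). When `gamma` or `cost` is `"grid"`, both are
#' chosen by 5-fold cross-validated accuracy over the log grids in
#' [svm_config()]. Features are used as given: put them on a common scale
#' via the pretreatment recipe.
#'
#' @param X,y calibration data (2 classes)
#' @param cfg an [svm_config()]
#' @param positive_class label treated as class 1
#' @return an `ftir_model`
#' @export
fit_svm_rbf <- function(X, y, cfg = svm_config(), positive_class = NULL) {
  X <- as.matrix(X)
  lv <- check_two_class(y)
  positive_class <- positive_class %||% lv[1]
  yf <- factor(y, levels = lv)
  p <- ncol(X)
  gamma <- cfg$gamma
  cost <- cfg$cost
  if (identical(gamma, "auto")) gamma <- 1 / p
  tuning <- NULL
  if (identical(gamma, "grid") || identical(cost, "grid")) {
    g_grid <- if (identical(gamma, "grid")) 2^(-10:2) else gamma
    c_grid <- if (identical(cost, "grid")) 2^(-3:7) else cost
    folds <- stratified_kfold(as.character(y), k = 5, seed = cfg$seed)
    combos <- expand.grid(cost = c_grid, gamma = g_grid,
                          KEEP.OUT.ATTRS = FALSE)
    accs <- vapply(seq_len(nrow(combos)), function(i) {
      hits <- 0L
      for (f in folds) {
        m <- e1071::svm(X[-f, , drop = FALSE], yf[-f], kernel = "radial",
                        gamma = combos$gamma[i], cost = combos$cost[i],
                        scale = FALSE)
        hits <- hits + sum(stats::predict(m, X[f, , drop = FALSE]) == yf[f])
      }
      hits / nrow(X)
    }, numeric(1))
    best <- order(-accs, combos$cost, combos$gamma)[1]
    gamma <- combos$gamma[best]
    cost <- combos$cost[best]
    tuning <- cbind(combos, cv_acc = accs)
  }
  stopifnot(gamma > 0, cost > 0)
  fit <- e1071::svm(X, yf, kernel = "radial", gamma = gamma, cost = cost,
                    scale = FALSE)
  new_ftir_model(
    "svm", fit, list(gamma = gamma, cost = cost),
    colnames(X) %||% as.character(seq_len(p)),
    seq_len(p), lv, positive_class,
    extra = list(tuning_table = tuning))
}

#' PCA + Mahalanobis calibration outlier screen
#'
#' Principal components are retained up to `outlier_pca_variance` cumulative
#' variance (zero-variance directions dropped, with a warning if that
#' reduces the requested dimension); the squared Mahalanobis distance of
#' each sample's scores is compared against the chi-square
#' `outlier_chi2_quantile` with as many degrees of freedom as retained
#' components.
#'
#' @param X calibration matrix
#' @param cfg a [plsda_config()]
#' @return integer indices of the retained (non-outlying) samples
#' @export
plsda_outlier_removal <- function(X, cfg = plsda_config()) {
  X <- as.matrix(X)
  pca <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pca$sdev^2
  ev <- ev[ev > max(ev) * 1e-12]   # numerical null space of rank-deficient X
  k <- which(cumsum(ev) / sum(ev) >= cfg$outlier_pca_variance)[1]
  if (k > nrow(X) - 1L) {
    warning("scores covariance singular; reducing components to ",
            nrow(X) - 1L)
    k <- nrow(X) - 1L
  }
  scores <- pca$x[, seq_len(k), drop = FALSE]
  md2 <- stats::mahalanobis(scores, colMeans(scores),
                            diag(ev[seq_len(k)], k))
  thr <- stats::qchisq(cfg$outlier_chi2_quantile, df = k)
  which(md2 <= thr)
}

# NIPALS PLS1: X (centered), y (centered) -> weights/loadings/coefficients
nipals_pls1 <- function(Xc, yc, ncomp) {
  p <- ncol(Xc)
  W <- matrix(0, p, ncomp)
  P <- matrix(0, p, ncomp)
  q <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(Xc, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { ncomp <- a - 1L; break }
    w <- w / nw
    tt <- drop(Xc %*% w)
    tt2 <- sum(tt^2)
    pl <- drop(crossprod(Xc, tt)) / tt2
    qa <- sum(yc * tt) / tt2
    Xc <- Xc - tcrossprod(tt, pl)
    yc <- yc - qa * tt
    W[, a] <- w; P[, a] <- pl; q[a] <- qa
  }
  if (ncomp == 0) stop("X carries no covariance with y")
  W <- W[, seq_len(ncomp), drop = FALSE]
  P <- P[, seq_len(ncomp), drop = FALSE]
  q <- q[seq_len(ncomp)]
  # B for each truncation 1..ncomp (cheap; reused by the CV search)
  R <- W %*% solve(crossprod(P, W))
  list(W = W, P = P, q = q, R = R, ncomp = ncomp)
}

plsda_coef <- function(dec, a) dec$R[, seq_len(a), drop = FALSE] %*% dec$q[seq_len(a)]

#' Fit a PLS-DA classifier
#'
#' PLS1 regression (NIPALS) on the class membership coded 0/1 (the positive
#' class is 1), predicting class 1 when the fitted response is at or above
#' the decision threshold (default 0.5). The number of latent components is
#' chosen by 5-fold cross-validated misclassification (ties toward fewer
#' components) unless given. Screen calibration outliers first with
#' [plsda_outlier_removal()].
#'
#' @param X,y calibration data (2 classes)
#' @param cfg a [plsda_config()]
#' @param positive_class label coded 1 (default: first sorted level)
#' @return an `ftir_model`
#' @export
fit_plsda <- function(X, y, cfg = plsda_config(), positive_class = NULL) {
  X <- as.matrix(X)
  lv <- check_two_class(y)
  positive_class <- positive_class %||% lv[1]
  y01 <- as.numeric(as.character(y) == positive_class)
  max_nc <- max(1L, min(cfg$max_components, nrow(X) - 2L, ncol(X)))
  ncomp <- cfg$n_components
  cv_table <- NULL
  if (identical(ncomp, "cv")) {
    folds <- stratified_kfold(as.character(y), k = 5, seed = cfg$seed)
    err <- matrix(NA_real_, length(folds), max_nc)
    for (fi in seq_along(folds)) {
      f <- folds[[fi]]
      Xtr <- X[-f, , drop = FALSE]; ytr <- y01[-f]
      xm <- colMeans(Xtr); ym <- mean(ytr)
      dec <- nipals_pls1(sweep(Xtr, 2, xm), ytr - ym,
                         min(max_nc, nrow(Xtr) - 1L))
      Xte <- sweep(X[f, , drop = FALSE], 2, xm)
      for (a in seq_len(max_nc)) {
        aa <- min(a, dec$ncomp)
        yhat <- ym + drop(Xte %*% plsda_coef(dec, aa))
        err[fi, a] <- mean((yhat >= cfg$decision_threshold) != (y01[f] == 1))
      }
    }
    mean_err <- colMeans(err)
    ncomp <- which(mean_err == min(mean_err))[1]   # ties -> fewer components
    cv_table <- data.frame(n_components = seq_len(max_nc),
                           cv_error = mean_err)
  } else {
    ncomp <- as.integer(ncomp)
    if (ncomp > max_nc) {
      warning("n_components truncated to ", max_nc)
      ncomp <- max_nc
    }
  }
  xm <- colMeans(X); ym <- mean(y01)
  dec <- nipals_pls1(sweep(X, 2, xm), y01 - ym, ncomp)
  if (dec$ncomp < ncomp)
    warning("components truncated to rank ", dec$ncomp)
  fit <- list(x_mean = xm, y_mean = ym, coef = plsda_coef(dec, dec$ncomp),
              decomposition = dec, threshold = cfg$decision_threshold)
  new_ftir_model(
    "plsda", fit, list(n_components = dec$ncomp,
                       decision_threshold = cfg$decision_threshold),
    colnames(X) %||% as.character(seq_len(ncol(X))),
    seq_len(ncol(X)), lv, positive_class,
    extra = list(cv_table = cv_table))
}

#' Predict classes and class-1 scores from a fitted model
#'
#' Scores are on [0, 1]: vote fractions (RF), logistic-rescaled decision
#' values (SVM) or the clipped fitted response (PLS-DA), always oriented
#' toward the model's positive class.
#'
#' @param object an `ftir_model`
#' @param X new data with the training variable count (selection is applied
#'   internally)
#' @param ... unused
#' @return list(labels = character, scores = numeric)
#' @export
predict.ftir_model <- function(object, X, ...) {
  X <- as.matrix(X)
  if (ncol(X) != length(object$var_names))
    stop("expected ", length(object$var_names), " variables, got ", ncol(X))
  Xs <- X[, object$selected_idx, drop = FALSE]
  pos <- object$positive_class
  if (object$kind == "rf") {
    labels <- as.character(stats::predict(object$fit, Xs))
    votes <- stats::predict(object$fit, Xs, type = "vote")
    scores <- votes[, pos]
  } else if (object$kind == "svm") {
    pr <- stats::predict(object$fit, Xs, decision.values = TRUE)
    labels <- as.character(pr)
    dec <- drop(attr(pr, "decision.values"))
    towards <- strsplit(colnames(attr(pr, "decision.values"))[1], "/")[[1]][1]
    if (towards != pos) dec <- -dec
    scores <- stats::plogis(dec)
  } else {
    f <- object$fit
    yhat <- f$y_mean + drop(sweep(Xs, 2, f$x_mean) %*% f$coef)
    neg <- setdiff(object$classes, pos)
    labels <- ifelse(yhat >= f$threshold, pos, neg)
    scores <- pmin(pmax(yhat, 0), 1)
  }
  list(labels = unname(labels), scores = unname(scores))
}

#' Fit any of the three classifiers through one interface
#'
#' For `"plsda"` the calibration outlier screen runs first and the model is
#' fit on the retained samples (their indices are recorded in the model
#' metadata).
#'
#' @param kind "rf", "svm" or "plsda"
#' @param X,y calibration data
#' @param positive_class label treated as class 1
#' @param rf,svm,plsda per-kind configurations
#' @return an `ftir_model`
#' @export
fit_model <- function(kind = c("rf", "svm", "plsda"), X, y,
                      positive_class = NULL, rf = rf_config(),
                      svm = svm_config(), plsda = plsda_config()) {
  kind <- match.arg(kind)
  if (kind == "rf")
    fit_rf(X, y, n_tree = 300, m_try = rf$m_try, seed = rf$seed,
           positive_class = positive_class)
  else if (kind == "svm")
    fit_svm_rbf(X, y, cfg = svm, positive_class = positive_class)
  else {
    keep <- plsda_outlier_removal(X, plsda)
    m <- fit_plsda(as.matrix(X)[keep, , drop = FALSE], y[keep], cfg = plsda,
                   positive_class = positive_class)
    m$metadata$retained_idx <- keep
    m
  }
}

#' Serialize a trained model to a directory
#'
#' Writes `metadata.json` (kind, tuned parameters, variable selection,
#' classes) alongside the opaque fitted state (`model.rds`), so
#' [load_model()] reproduces predictions bit-identically.
#'
#' @param model an `ftir_model`
#' @param dir output directory (created)
#' @return `dir`, invisibly
#' @export
save_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(kind = model$kind, tuned_params = model$tuned_params,
               n_variables = length(model$var_names),
               selected_variable_idx = model$selected_idx,
               selected_variables = model$var_names[model$selected_idx],
               classes = model$classes,
               positive_class = model$positive_class,
               metadata = model$metadata,
               package_version = as.character(utils::packageVersion("ftirdisc")))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  saveRDS(model, file.path(dir, "model.rds"))
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  readRDS(file.path(dir, "model.rds"))
}
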