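#' Two-class confusion counts
#'
#' @param y_true,y_pred equal-length label vectors drawn from the same
#'   two-class alphabet
#' @param positive_class the label counted as positive
#' @return a `confusion_counts` list with TP, TN, FP, FN
#' @export
confusion <- function(y_true, y_pred, positive_class) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  alphabet <- unique(y_true)
  if (length(alphabet) > 2) stop("more than 2 classes in y_true")
  bad <- setdiff(unique(c(y_pred, positive_class)), alphabet)
  if (length(bad) && !positive_class %in% alphabet)
    stop("positive_class not in label alphabet")
  if (length(setdiff(unique(y_pred), alphabet)))
    stop("unseen label(s) in y_pred: ",
         paste(setdiff(unique(y_pred), alphabet), collapse = ", "))
  pos <- y_true == positive_class
  structure(list(TP = sum(pos & y_pred == positive_class),
                 TN = sum(!pos & y_pred != positive_class),
                 FP = sum(!pos & y_pred == positive_class),
                 FN = sum(pos & y_pred != positive_class),
                 positive_class = positive_class),
            class = "confusion_counts")
}

#' Sensitivity, specificity, accuracy and Matthews correlation
#'
#' SENS = TP/(TP+FN), SPEC = TN/(TN+FP), ACC = (TP+TN)/total and
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)). A metric
#' whose denominator vanishes is reported as 0 and named in the
#' `degenerate` attribute instead of raising, so grid runs never abort.
#'
#' @param cc a [confusion()] result
#' @return data.frame(sens, spec, acc, mcc) with attribute `degenerate`
#' @export
metrics <- function(cc) {
  stopifnot(inherits(cc, "confusion_counts"))
  TP <- cc$TP; TN <- cc$TN; FP <- cc$FP; FN <- cc$FN
  total <- TP + TN + FP + FN
  if (total == 0) stop("empty confusion table")
  flags <- character(0)
  div <- function(num, den, name) {
    if (den == 0) { flags <<- c(flags, name); 0 } else num / den
  }
  sens <- div(TP, TP + FN, "sens")
  spec <- div(TN, TN + FP, "spec")
  acc <- (TP + TN) / total
  mccden <- as.numeric(TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  mcc <- if (mccden == 0) { flags <- c(flags, "mcc"); 0 } else
    (as.numeric(TP) * TN - as.numeric(FP) * FN) / sqrt(mccden)
  out <- data.frame(sens = sens, spec = spec, acc = acc, mcc = mcc)
  attr(out, "degenerate") <- flags
  out
}

#' Rank-based AUC (Mann-Whitney, midrank tie correction)
#'
#' Equivalent to the trapezoidal area under the ROC curve; invariant under
#' strictly monotone transforms of the scores. Returns `NA` when `y_true`
#' holds a single class.
#'
#' @param scores finite numeric scores, larger = more positive
#' @param y_true labels
#' @param positive_class label treated as positive
#' @return AUC in [0, 1], or `NA`
#' @export
roc_auc <- function(scores, y_true, positive_class) {
  stopifnot(all(is.finite(scores)), length(scores) == length(y_true))
  pos <- as.character(y_true) == positive_class
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' One evaluation row from labels + scores
#' @param y_true true labels
#' @param labels predicted labels
#' @param scores class-1 scores (for AUC); `NULL` omits AUC
#' @param positive_class label treated as positive
#' @return data.frame(sens, spec, acc, mcc, auc)
#' @export
evaluate_predictions <- function(y_true, labels, scores, positive_class) {
  out <- metrics(confusion(y_true, labels, positive_class))
  out$auc <- if (is.null(scores)) NA_real_ else
    roc_auc(scores, y_true, positive_class)
  out
}

# 5-fold CV predictions on the calibration set; returns labels + scores
# aligned with rows of X. For plsda, the outlier screen runs inside each
# training fold only.
cv_predict <- function(kind, X, y, positive_class, k = 5, seed = 20220720,
                       rf = rf_config(), svm = svm_config(),
                       plsda = plsda_config(), rf_params = NULL) {
  X <- as.matrix(X)
  folds <- stratified_kfold(as.character(y), k = k, seed = seed)
  labels <- character(nrow(X)); scores <- numeric(nrow(X))
  for (f in folds) {
    m <- if (kind == "rf" && !is.null(rf_params))
      fit_rf(X[-f, , drop = FALSE], y[-f], n_tree = rf_params$n_tree,
             m_try = rf_params$m_try, seed = rf$seed,
             positive_class = positive_class)
    else
      fit_model(kind, X[-f, , drop = FALSE], y[-f],
                positive_class = positive_class, rf = rf, svm = svm,
                plsda = plsda)
    pr <- stats::predict(m, X[f, , drop = FALSE])
    labels[f] <- pr$labels; scores[f] <- pr$scores
  }
  list(labels = labels, scores = scores)
}

#' Pretreatment x classifier comparison grid
#'
#' For every (recipe, model) pair: preprocess, Kennard-Stone split (computed
#' on the same pretreatment, unless a split is supplied), refit the recipe
#' state on the calibration rows, then report calibration metrics from
#' 5-fold cross-validated predictions and validation metrics from the model
#' fit on the full calibration set. Any cell failure is recorded in the
#' `error` column and the grid continues.
#'
#' @param s labeled `spectrum_set` in transmittance mode
#' @param recipes preset recipe names (default all eleven)
#' @param model_kinds subset of c("rf", "svm", "plsda")
#' @param fraction calibration fraction for the split
#' @param split optional fixed [kennard_stone()] result reused for every
#'   recipe
#' @param seed RNG seed for model fits and CV folds
#' @param positive_class label treated as class 1 (default first sorted)
#' @param rf,svm,plsda model configurations
#' @return long data.frame (recipe, model, set, sens, spec, acc, mcc, auc,
#'   error)
#' @export
comparison_grid <- function(s, recipes = preset_names(),
                            model_kinds = c("rf", "svm", "plsda"),
                            fraction = 0.8, split = NULL, seed = 20220720,
                            positive_class = NULL, rf = rf_config(),
                            svm = svm_config(), plsda = plsda_config()) {
  stopifnot(length(recipes) >= 1, length(model_kinds) >= 1,
            !is.null(s$labels))
  positive_class <- positive_class %||% sort(unique(s$labels))[1]
  rf$seed <- svm$seed <- plsda$seed <- seed
  rows <- list()
  empty <- data.frame(sens = NA_real_, spec = NA_real_, acc = NA_real_,
                      mcc = NA_real_, auc = NA_real_)
  for (rname in recipes) {
    prep <- tryCatch(prepare_split_data(s, rname, fraction, split, seed),
                     error = function(e) e)
    for (kind in model_kinds) {
      if (inherits(prep, "error")) {
        for (setn in c("calibration", "validation"))
          rows[[length(rows) + 1]] <- cbind(
            data.frame(recipe = rname, model = kind, set = setn), empty,
            data.frame(error = conditionMessage(prep)))
        next
      }
      res <- tryCatch({
        cv <- cv_predict(kind, prep$Xcal, prep$ycal, positive_class,
                         seed = seed, rf = rf, svm = svm, plsda = plsda)
        cal_row <- evaluate_predictions(prep$ycal, cv$labels, cv$scores,
                                        positive_class)
        m <- fit_model(kind, prep$Xcal, prep$ycal,
                       positive_class = positive_class, rf = rf, svm = svm,
                       plsda = plsda)
        pv <- stats::predict(m, prep$Xval)
        val_row <- evaluate_predictions(prep$yval, pv$labels, pv$scores,
                                        positive_class)
        rbind(cbind(data.frame(recipe = rname, model = kind,
                               set = "calibration"), cal_row,
                    data.frame(error = NA_character_)),
              cbind(data.frame(recipe = rname, model = kind,
                               set = "validation"), val_row,
                    data.frame(error = NA_character_)))
      }, error = function(e) {
        rbind(cbind(data.frame(recipe = rname, model = kind,
                               set = "calibration"), empty,
                    data.frame(error = conditionMessage(e))),
              cbind(data.frame(recipe = rname, model = kind,
                               set = "validation"), empty,
                    data.frame(error = conditionMessage(e))))
      })
      rows[[length(rows) + 1]] <- res
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# preprocess + split + leakage-safe refit on the calibration rows
prepare_split_data <- function(s, recipe_name, fraction, split, seed) {
  rec <- preset_recipe(recipe_name)
  if (is.null(split)) {
    pre_all <- apply_recipe(rec, s)          # self mode: distances only
    split <- kennard_stone(pre_all, fraction = fraction)
  }
  cal_raw <- subset_samples(s, split$calibration_idx)
  val_raw <- subset_samples(s, split$validation_idx)
  frec <- fit_recipe(rec, cal_raw)
  cal <- suppressWarnings(apply_recipe(frec, cal_raw))
  val <- suppressWarnings(apply_recipe(frec, val_raw))
  list(split = split, fitted_recipe = frec,
       Xcal = cal$values, ycal = cal$labels,
       Xval = val$values, yval = val$labels)
}

#' The four standard wavenumber regions of the region experiment
#'
#' Full range; full range minus the water-vapor (4000-3500 cm-1) and CO2
#' (2442-2208 cm-1) bands; fingerprint half (2000-600); high half
#' (4000-2000).
#'
#' @param lo,hi grid limits in cm-1
#' @return named list of [region_set()] objects
#' @export
default_regions <- function(lo = 600, hi = 4000) {
  list(
    no_water_co2 = region_set(rbind(c(3500, hi), c(2208, 2442)), "exclude"),
    `2000-600`   = region_set(c(lo, 2000), "keep"),
    `4000-2000`  = region_set(c(2000, hi), "keep"),
    full         = region_set(c(lo, hi), "keep"))
}

#' Wavenumber-region experiment for the RF model
#'
#' Per region: restrict the raw spectra, preprocess, split, fit the RF at
#' the tuned parameters and report validation metrics plus the variable
#' count. Regions that leave no grid points are recorded as skipped.
#'
#' @param s labeled `spectrum_set` (transmittance)
#' @param regions named list of [region_set()]s (default
#'   [default_regions()])
#' @param recipe_name pretreatment preset used throughout
#' @param n_tree,m_try tuned RF parameters (`m_try = NULL` uses sqrt(p) of
#'   each region)
#' @param fraction calibration fraction
#' @param seed RNG seed
#' @param positive_class label treated as class 1
#' @return data.frame (region, n_variables, sens, spec, acc, mcc, auc,
#'   error)
#' @export
region_experiment <- function(s, regions = default_regions(),
                              recipe_name = "vector_first", n_tree = 300,
                              m_try = NULL, fraction = 0.8,
                              seed = 20220720, positive_class = NULL) {
  stopifnot(length(regions) >= 1, !is.null(s$labels))
  positive_class <- positive_class %||% sort(unique(s$labels))[1]
  rows <- lapply(names(regions), function(rn) {
    res <- tryCatch({
      sr <- suppressWarnings(subset_region(s, regions[[rn]]))
      prep <- prepare_split_data(sr, recipe_name, fraction, NULL, seed)
      mt <- if (is.null(m_try)) "sqrt" else m_try
      m <- fit_rf(prep$Xcal, prep$ycal, n_tree = n_tree, m_try = mt,
                  seed = seed, positive_class = positive_class)
      pv <- stats::predict(m, prep$Xval)
      cbind(data.frame(region = rn, n_variables = ncol(prep$Xcal)),
            evaluate_predictions(prep$yval, pv$labels, pv$scores,
                                 positive_class),
            data.frame(error = NA_character_))
    }, error = function(e)
      data.frame(region = rn, n_variables = NA_integer_, sens = NA_real_,
                 spec = NA_real_, acc = NA_real_, mcc = NA_real_,
                 auc = NA_real_, error = conditionMessage(e)))
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Variable-importance cutoff experiment for the RF model
#'
#' Fits the RF at the tuned parameters, computes rescaled permutation
#' importance, and for each cutoff retains the surviving variables, refits
#' at the same (n_tree, m_try capped to the surviving count) and reports
#' validation metrics plus the surviving-variable count.
#'
#' @inheritParams region_experiment
#' @param cutoffs importance cutoffs on the max-1 scale
#' @return data.frame (cutoff, n_selected, sens, spec, acc, mcc, auc)
#' @export
vip_experiment <- function(s, cutoffs = c(0.05, 0.01, 0.015, 0.020),
                           recipe_name = "vector_first", n_tree = 300,
                           m_try = NULL, fraction = 0.8, seed = 20220720,
                           positive_class = NULL) {
  stopifnot(length(cutoffs) >= 1, !is.null(s$labels))
  positive_class <- positive_class %||% sort(unique(s$labels))[1]
  prep <- prepare_split_data(s, recipe_name, fraction, NULL, seed)
  mt <- if (is.null(m_try)) "sqrt" else m_try
  full <- fit_rf(prep$Xcal, prep$ycal, n_tree = n_tree, m_try = mt,
                 seed = seed, positive_class = positive_class)
  imp <- rf_importance(full)
  rows <- lapply(cutoffs, function(ct) {
    sel <- suppressWarnings(select_by_vip(imp, ct))
    m <- fit_rf(prep$Xcal[, sel, drop = FALSE], prep$ycal, n_tree = n_tree,
                m_try = min(resolve_mtry(mt, ncol(prep$Xcal)), length(sel)),
                seed = seed, positive_class = positive_class)
    pv <- stats::predict(m, prep$Xval[, sel, drop = FALSE])
    cbind(data.frame(cutoff = ct, n_selected = length(sel)),
          evaluate_predictions(prep$yval, pv$labels, pv$scores,
                               positive_class))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Render a metrics table as aligned text
#' @param df a metrics data.frame
#' @param digits significant digits for numeric columns
#' @return character vector of lines, invisibly printed
#' @export
render_table <- function(df, digits = 4) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, digits))
  txt <- utils::capture.output(print(df, row.names = FALSE))
  cat(txt, sep = "\n")
  invisible(txt)
}
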