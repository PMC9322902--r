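#' Kennard-Stone calibration/validation split
#'
#' Deterministic max-min-distance sample selection: within each stratum
#' (class, when `stratified = TRUE`), the pair at maximal Euclidean distance
#' seeds the calibration set, then samples are added greedily by maximal
#' minimum distance to the already-selected set until the stratum quota
#' `round(fraction * n_stratum)` is reached. Remaining samples form the
#' validation set. Ties are broken by lowest index, so the split is fully
#' reproducible. Distances are computed on the rows of `s` as given, i.e.
#' on whatever pretreatment the caller has applied.
#'
#' @param s a `spectrum_set` (labels required when `stratified = TRUE`)
#' @param fraction target calibration fraction (default 0.8, the 4/5 split)
#' @param stratified run the selection independently per class
#'   (default TRUE)
#' @return a `split_result`: list(calibration_idx, validation_idx, fraction)
#' @export
kennard_stone <- function(s, fraction = 0.8, stratified = TRUE) {
  stopifnot(fraction > 0, fraction <= 1)
  strata <- if (stratified) {
    if (is.null(s$labels)) stop("stratified split requires labels")
    split(seq_len(n_samples(s)), s$labels)
  } else list(all = seq_len(n_samples(s)))
  cal <- integer(0)
  for (idx in strata) {
    if (length(idx) < 2) stop("need >= 2 samples per stratum")
    quota <- round(fraction * length(idx))
    quota <- max(min(quota, length(idx)), if (fraction == 1) length(idx) else 1L)
    cal <- c(cal, idx[ks_select(s$values[idx, , drop = FALSE], quota)])
  }
  cal <- sort(cal)
  structure(list(calibration_idx = cal,
                 validation_idx = setdiff(seq_len(n_samples(s)), cal),
                 fraction = fraction),
            class = "split_result")
}

# greedy max-min KS selection on a plain matrix; returns local row indices
ks_select <- function(X, quota) {
  n <- nrow(X)
  if (quota >= n) return(seq_len(n))
  d <- as.matrix(stats::dist(X))
  # seed: maximal-distance pair, ties by lowest (row, col) index
  dw <- d
  diag(dw) <- -Inf
  pos <- which(dw == max(dw), arr.ind = TRUE)
  pos <- pos[order(pmin(pos[, 1], pos[, 2]), pmax(pos[, 1], pos[, 2])), ,
             drop = FALSE]
  sel <- sort(pos[1, ])
  if (quota == 1) return(sel[1])
  mind <- pmin(d[, sel[1]], d[, sel[2]])
  while (length(sel) < quota) {
    mind[sel] <- -Inf
    nxt <- which.max(mind)          # which.max takes the lowest index on ties
    sel <- c(sel, nxt)
    mind <- pmin(mind, d[, nxt])
  }
  sort(sel)
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("<split_result> %d calibration / %d validation (fraction %.2f)\n",
              length(x$calibration_idx), length(x$validation_idx), x$fraction))
  invisible(x)
}

#' Write a split to a two-column CSV (sample_id, set)
#' @param split a `split_result`
#' @param s the `spectrum_set` it partitions
#' @param path output path
#' @return `path`, invisibly
#' @export
write_split_csv <- function(split, s, path) {
  set <- rep("validation", n_samples(s))
  set[split$calibration_idx] <- "calibration"
  utils::write.csv(data.frame(sample_id = s$sample_ids, set = set),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Stratified k-fold assignment
#'
#' Shuffles each class independently under `seed` and deals its members
#' round-robin across folds, so per-class counts differ by at most one
#' between folds.
#'
#' @param labels per-sample class labels
#' @param k number of folds (>= 2)
#' @param seed RNG seed
#' @return list of `k` disjoint index vectors covering all samples
#' @export
stratified_kfold <- function(labels, k = 5, seed = 20220720) {
  stopifnot(k >= 2)
  tab <- table(labels)
  if (any(tab < k))
    stop("class smaller than k: ", paste(names(tab)[tab < k], collapse = ", "))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  folds <- vector("list", k)
  for (cls in names(tab)) {
    idx <- sample(which(labels == cls))
    grp <- rep(seq_len(k), length.out = length(idx))
    for (f in seq_len(k)) folds[[f]] <- c(folds[[f]], idx[grp == f])
  }
  lapply(folds, sort)
}
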