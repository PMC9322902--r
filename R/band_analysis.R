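#' Band catalogue for peak matching
#'
#' @param centers band centers in cm-1 (> 0)
#' @param assignments vibrational assignment text per band
#' @param expected_classes per band: "A", "B" or "both"
#' @param tolerance matching half-window in cm-1 (default 10)
#' @return a `band_table` data.frame with the tolerance attached
#' @export
band_table <- function(centers, assignments = "",
                       expected_classes = "both", tolerance = 10) {
  stopifnot(all(centers > 0), tolerance >= 0)
  out <- data.frame(center = centers,
                    assignment = rep_len(assignments, length(centers)),
                    expected_classes = rep_len(expected_classes,
                                               length(centers)),
                    stringsAsFactors = FALSE)
  attr(out, "tolerance") <- tolerance
  class(out) <- c("band_table", "data.frame")
  out
}

#' The default band catalogue (matches [default_bands()])
#' @param tolerance matching half-window in cm-1
#' @return a [band_table()]
#' @export
default_band_table <- function(tolerance = 10) {
  bands <- default_bands()
  band_table(
    centers = vapply(bands, `[[`, numeric(1), "center"),
    assignments = vapply(bands, `[[`, character(1), "assignment"),
    expected_classes = vapply(bands, function(b)
      if (length(b$classes) == 2) "both" else b$classes, character(1)),
    tolerance = tolerance)
}

#' Detect peaks in one spectrum by local maxima and prominence
#'
#' A peak is a strict local maximum whose topographic prominence (height
#' above the higher of the two base minima, each taken between the peak and
#' the nearest higher point or the signal edge) reaches `min_prominence`.
#' The default prominence threshold is 2\% of the row maximum.
#'
#' @param x intensity vector (absorbance recommended)
#' @param grid wavenumber grid aligned with `x`
#' @param min_prominence prominence threshold (>= 0); `NULL` uses
#'   `0.02 * max(x)`
#' @return numeric peak positions (grid values), with `heights` and
#'   `prominences` attributes
#' @export
detect_peaks <- function(x, grid, min_prominence = NULL) {
  stopifnot(length(x) == length(grid))
  if (is.null(min_prominence)) min_prominence <- 0.02 * max(x, 0)
  stopifnot(min_prominence >= 0)
  n <- length(x)
  if (n < 3) return(numeric(0))
  # plateau-aware local maxima: collapse equal-value runs, keep interior
  # runs higher than both flanking runs, report the run midpoint (a band
  # centered between two grid points produces an exact 2-point tie)
  runs <- rle(x)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  nr <- length(runs$values)
  cand <- integer(0)
  if (nr >= 3) {
    k <- 2:(nr - 1)
    is_peak <- runs$values[k] > runs$values[k - 1] &
      runs$values[k] > runs$values[k + 1]
    cand <- floor((starts[k][is_peak] + ends[k][is_peak]) / 2)
  }
  if (!length(cand)) return(numeric(0))
  prom <- vapply(cand, function(i) {
    h <- x[i]
    left <- if (i > 1) x[seq_len(i - 1)] else numeric(0)
    hi_l <- which(left > h)
    base_l <- min(left[seq(from = if (length(hi_l)) max(hi_l) else 1,
                           to = i - 1)])
    right <- if (i < n) x[(i + 1):n] else numeric(0)
    hi_r <- which(right > h)
    base_r <- min(right[seq_len(if (length(hi_r)) min(hi_r) else
      length(right))])
    h - max(base_l, base_r)
  }, numeric(1))
  keep <- prom >= min_prominence
  pos <- grid[cand[keep]]
  attr(pos, "heights") <- x[cand[keep]]
  attr(pos, "prominences") <- prom[keep]
  pos
}

#' Report presence/absence of catalogue bands in each class-mean spectrum
#'
#' Computes the mean absorbance spectrum of each class (transmittance input
#' is converted first), detects its peaks and matches them to the catalogue
#' within the table's tolerance. The discriminating pattern of the two
#' classes — e.g. presence at 1545/1400/930 cm-1 versus 1528/781 cm-1 —
#' reads directly off the `detected` column.
#'
#' @param s a labeled `spectrum_set` with exactly two classes
#' @param bands a [band_table()] (default [default_band_table()])
#' @param min_prominence peak-detection threshold passed to
#'   [detect_peaks()]
#' @return data.frame (class, band_center, assignment, expected, detected,
#'   detected_position); one row per band per class
#' @export
discriminating_report <- function(s, bands = default_band_table(),
                                  min_prominence = NULL) {
  if (is.null(s$labels)) stop("labels required")
  classes <- sort(unique(s$labels))
  if (length(classes) != 2) stop("need exactly 2 classes, got ",
                                 length(classes))
  tol <- attr(bands, "tolerance")
  sa <- if (s$mode == "transmittance_percent") to_absorbance(s) else s
  rows <- list()
  for (cls in classes) {
    mu <- colMeans(sa$values[sa$labels == cls, , drop = FALSE])
    peaks <- detect_peaks(mu, sa$wavenumbers, min_prominence)
    for (i in seq_len(nrow(bands))) {
      ctr <- bands$center[i]
      hit <- if (length(peaks)) which.min(abs(peaks - ctr)) else integer(0)
      detected <- length(hit) > 0 && abs(peaks[hit] - ctr) <= tol
      rows[[length(rows) + 1]] <- data.frame(
        class = cls, band_center = ctr, assignment = bands$assignment[i],
        expected = bands$expected_classes[i] %in% c("both", cls),
        detected = detected,
        detected_position = if (detected) peaks[hit] else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
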