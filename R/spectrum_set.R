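#' Spectral data container
#'
#' A `spectrum_set` holds a set of mid-infrared spectra on a shared
#' wavenumber grid: one row per sample, one column per grid point. The grid
#' is canonicalized to strictly descending order (4000 -> 600 cm-1 by
#' convention) with uniform spacing. Values are either percent transmittance
#' (`"transmittance_percent"`, all > 0) or absorbance (`"absorbance"`, AU).
#'
#' @param wavenumbers numeric grid in cm-1; any strictly monotonic uniform
#'   grid is accepted and stored descending (columns are reordered to match).
#' @param values numeric matrix, `length(sample_ids)` rows by
#'   `length(wavenumbers)` columns, all finite.
#' @param mode `"transmittance_percent"` or `"absorbance"`.
#' @param sample_ids unique character ids, one per row. Defaults to
#'   `"s1".."sn"`.
#' @param labels optional per-sample class tags (e.g. `"A"`/`"B"`), or `NULL`
#'   for unknowns.
#' @return an object of class `spectrum_set`.
#' @export
spectrum_set <- function(wavenumbers, values, mode, sample_ids = NULL,
                         labels = NULL) {
  wavenumbers <- as.numeric(wavenumbers)
  if (is.null(dim(values))) values <- matrix(values, nrow = 1L)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(n))
  sample_ids <- as.character(sample_ids)
  mode <- match.arg(mode, c("transmittance_percent", "absorbance"))

  if (length(wavenumbers) != ncol(values))
    stop("values must have one column per wavenumber")
  if (length(sample_ids) != n)
    stop("sample_ids must have one entry per row of values")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (!all(is.finite(wavenumbers)) || !all(is.finite(values)))
    stop("wavenumbers and values must all be finite")
  # strictly monotonic; spacing may be non-uniform after region exclusion
  dw <- diff(wavenumbers)
  if (length(dw) && (any(dw == 0) || (any(dw > 0) && any(dw < 0))))
    stop("wavenumber grid must be strictly monotonic")
  # canonicalize to descending order
  if (length(dw) && dw[1] > 0) {
    ord <- rev(seq_along(wavenumbers))
    wavenumbers <- wavenumbers[ord]
    values <- values[, ord, drop = FALSE]
  }
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != n)
      stop("labels must have one entry per sample")
  }
  if (mode == "transmittance_percent" && any(values <= 0))
    stop("transmittance_percent values must all be > 0")

  dimnames(values) <- list(sample_ids, format(wavenumbers, trim = TRUE))
  structure(
    list(wavenumbers = wavenumbers, values = values, mode = mode,
         sample_ids = sample_ids, labels = labels),
    class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set> %d samples x %d points, %.0f..%.0f cm-1, mode=%s\n",
              nrow(x$values), ncol(x$values), x$wavenumbers[1],
              x$wavenumbers[length(x$wavenumbers)], x$mode))
  if (!is.null(x$labels))
    print(table(labels = x$labels))
  invisible(x)
}

#' @export
dim.spectrum_set <- function(x) dim(x$values)

#' Number of samples / grid points
#' @param s a `spectrum_set`
#' @return integer count
#' @export
n_samples <- function(s) nrow(s$values)

#' @rdname n_samples
#' @export
n_points <- function(s) ncol(s$values)

#' Subset samples of a spectrum_set by row index
#' @param s a `spectrum_set`
#' @param idx integer or logical row index
#' @return a `spectrum_set` with the selected samples
#' @export
subset_samples <- function(s, idx) {
  spectrum_set(s$wavenumbers, s$values[idx, , drop = FALSE], s$mode,
               s$sample_ids[idx],
               if (!is.null(s$labels)) s$labels[idx] else NULL)
}

#' Replace the intensity matrix, keeping grid and metadata
#'
#' Internal helper used by the preprocessing transforms; the replacement must
#' have the same shape as the original.
#' @param s a `spectrum_set`
#' @param values replacement matrix
#' @param mode optional new mode
#' @return a `spectrum_set`
#' @keywords internal
set_values <- function(s, values, mode = s$mode) {
  spectrum_set(s$wavenumbers, values, mode, s$sample_ids, s$labels)
}

#' Read spectra from wide CSV
#'
#' Expected layout (the dialect written by [write_spectra_csv()]): a header
#' row `sample_id,label,mode,<wavenumber values...>` and one row per sample.
#' The `label` and `mode` columns are optional; `orientation = "long"` is not
#' supported (spectra are wide by convention in this workflow). Any grid
#' order in the file is accepted; the returned grid is descending.
#'
#' @param path CSV file path.
#' @param mode fallback acquisition mode when the file carries no `mode`
#'   column.
#' @return a [spectrum_set()].
#' @export
read_spectra_csv <- function(path, mode = "transmittance_percent") {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = NA)
  if (!nrow(df)) stop("empty spectra file: ", path)
  if (names(df)[1] != "sample_id")
    stop("first column must be 'sample_id'")
  ids <- as.character(df[["sample_id"]])
  labels <- NULL
  if ("label" %in% names(df)) {
    labels <- as.character(df[["label"]])
    if (all(is.na(labels) | labels == "")) labels <- NULL
  }
  if ("mode" %in% names(df)) {
    modes <- unique(as.character(df[["mode"]]))
    if (length(modes) != 1)
      stop("inconsistent mode column")
    mode <- modes
  }
  wn_cols <- setdiff(names(df), c("sample_id", "label", "mode"))
  wn <- suppressWarnings(as.numeric(wn_cols))
  if (anyNA(wn))
    stop("non-numeric wavenumber header: ",
         paste(utils::head(wn_cols[is.na(wn)], 3), collapse = ", "))
  vals <- as.matrix(df[, wn_cols, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(!vapply(df[wn_cols], is.numeric, logical(1)))
    stop("non-numeric cell(s) in column(s): ",
         paste(utils::head(wn_cols[bad], 3), collapse = ", "))
  }
  spectrum_set(wn, vals, mode, ids, labels)
}

#' Write spectra to wide CSV
#'
#' Inverse of [read_spectra_csv()]; values are written at 10 significant
#' digits so a read/write round trip preserves them to at least that
#' precision.
#'
#' @param s a `spectrum_set`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_spectra_csv <- function(s, path) {
  vals <- apply(s$values, 2, function(col) format(col, digits = 10, trim = TRUE))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1L)
  df <- data.frame(sample_id = s$sample_ids, stringsAsFactors = FALSE)
  if (!is.null(s$labels)) df$label <- s$labels
  df$mode <- s$mode
  df <- cbind(df, as.data.frame(vals, stringsAsFactors = FALSE))
  names(df) <- c("sample_id", if (!is.null(s$labels)) "label", "mode",
                 format(s$wavenumbers, digits = 10, trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a single-spectrum JCAMP-DX file (XYDATA, (X++(Y..Y)) form)
#'
#' Minimal read-only support for the common fixed-abscissa JCAMP-DX layout:
#' `##XYDATA=(X++(Y..Y))` blocks with space-separated numeric lines, using
#' `##XFACTOR`/`##YFACTOR` scaling. AFFN only (no compressed SQZ/DIF forms).
#'
#' @param path JCAMP-DX file
#' @param mode acquisition mode of the stored ordinates
#' @param sample_id id for the single spectrum (default: file base name)
#' @return a [spectrum_set()] with one sample
#' @export
read_jcamp <- function(path, mode = "transmittance_percent",
                       sample_id = NULL) {
  lines <- readLines(path, warn = FALSE)
  get_field <- function(key, default = NA_real_) {
    m <- grep(paste0("^##", key, "="), lines, value = TRUE)
    if (!length(m)) return(default)
    as.numeric(sub(paste0("^##", key, "="), "", m[1]))
  }
  xfac <- get_field("XFACTOR", 1)
  yfac <- get_field("YFACTOR", 1)
  start <- grep("^##XYDATA=", lines)
  if (!length(start)) stop("no ##XYDATA block in ", path)
  end <- grep("^##END", lines)
  end <- end[end > start[1]]
  body <- lines[(start[1] + 1):(if (length(end)) end[1] - 1 else length(lines))]
  xs <- c(); ys <- c()
  for (ln in body) {
    nums <- suppressWarnings(as.numeric(strsplit(trimws(ln), "[ \t]+")[[1]]))
    if (anyNA(nums) || length(nums) < 2) next
    xs <- c(xs, nums[1])
    ys <- c(ys, nums[-1])
  }
  npts <- get_field("NPOINTS", length(ys))
  if (length(ys) != npts)
    warning("NPOINTS mismatch: header ", npts, ", parsed ", length(ys))
  first_x <- get_field("FIRSTX", xs[1] * xfac)
  last_x <- get_field("LASTX", NA_real_)
  if (is.na(last_x))
    stop("##LASTX required to reconstruct the abscissa grid")
  wn <- seq(first_x, last_x, length.out = length(ys))
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  spectrum_set(wn, matrix(ys * yfac, nrow = 1L), mode, sample_id)
}

#' Combine several single-spectrum sets on a common grid
#' @param ... `spectrum_set` objects sharing one grid and mode
#' @return a combined `spectrum_set`
#' @export
bind_spectra <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) &&
      !inherits(sets[[1]], "spectrum_set")) sets <- sets[[1]]
  ref <- sets[[1]]
  for (s in sets[-1]) {
    if (!isTRUE(all.equal(s$wavenumbers, ref$wavenumbers)))
      stop("grids differ")
    if (s$mode != ref$mode) stop("modes differ")
  }
  labels <- lapply(sets, function(s)
    if (is.null(s$labels)) rep(NA_character_, n_samples(s)) else s$labels)
  labels <- unlist(labels)
  if (all(is.na(labels))) labels <- NULL
  spectrum_set(ref$wavenumbers, do.call(rbind, lapply(sets, `[[`, "values")),
               ref$mode, unlist(lapply(sets, `[[`, "sample_ids")), labels)
}

#' Convert percent transmittance to absorbance
#'
#' Applies A = 2 - log10(\%T). A set already in absorbance mode is returned
#' unchanged with a warning. \%T values at or below zero are rejected unless
#' `floor_t` is given, in which case values are clipped up to `floor_t`
#' before the log (opt-in, off by default).
#'
#' @param s a `spectrum_set` in transmittance mode
#' @param floor_t optional positive clip floor for \%T (e.g. `1e-4`)
#' @return the set in absorbance mode
#' @export
to_absorbance <- function(s, floor_t = NULL) {
  if (s$mode == "absorbance") {
    warning("already in absorbance mode; returning unchanged")
    return(s)
  }
  v <- s$values
  if (!is.null(floor_t)) {
    stopifnot(floor_t > 0)
    v[v < floor_t] <- floor_t
  }
  if (any(v <= 0)) {
    bad <- s$sample_ids[apply(v <= 0, 1, any)]
    stop("non-positive %T (enable floor_t to clip): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  set_values(s, 2 - log10(v), mode = "absorbance")
}

#' Wavenumber region set
#'
#' A list of closed intervals in cm-1 with a `keep` or `exclude` mode, used
#' to restrict spectra to sub-regions (e.g. dropping the water-vapor
#' 4000-3500 and CO2 2442-2208 bands). A grid point lying exactly on a
#' boundary belongs to the interval.
#'
#' @param intervals numeric matrix or list of `c(lo, hi)` pairs, lo < hi
#' @param mode `"keep"` or `"exclude"`
#' @return a `region_set`
#' @export
region_set <- function(intervals, mode = c("keep", "exclude")) {
  mode <- match.arg(mode)
  if (is.numeric(intervals) && is.null(dim(intervals)))
    intervals <- matrix(intervals, ncol = 2, byrow = TRUE)
  if (is.list(intervals)) intervals <- do.call(rbind, intervals)
  intervals <- as.matrix(intervals)
  if (ncol(intervals) != 2 || any(intervals[, 1] >= intervals[, 2]))
    stop("each interval must be c(lo, hi) with lo < hi")
  # normalize: sort and merge overlaps so intervals are pairwise disjoint
  intervals <- intervals[order(intervals[, 1]), , drop = FALSE]
  merged <- intervals[1, , drop = FALSE]
  for (i in seq_len(nrow(intervals))[-1]) {
    k <- nrow(merged)
    if (intervals[i, 1] <= merged[k, 2])
      merged[k, 2] <- max(merged[k, 2], intervals[i, 2])
    else merged <- rbind(merged, intervals[i, ])
  }
  structure(list(intervals = unname(merged), mode = mode),
            class = "region_set")
}

#' Restrict a spectrum set to a wavenumber region
#'
#' Keeps exactly the grid points inside the keep-intervals (or outside all
#' exclude-intervals). Closed-interval convention; column order preserved.
#'
#' @param s a `spectrum_set`
#' @param r a [region_set()]
#' @return the restricted `spectrum_set`
#' @export
subset_region <- function(s, r) {
  stopifnot(inherits(r, "region_set"))
  inside <- rep(FALSE, n_points(s))
  for (i in seq_len(nrow(r$intervals))) {
    lo <- r$intervals[i, 1]; hi <- r$intervals[i, 2]
    hit <- s$wavenumbers >= lo & s$wavenumbers <= hi
    if (!any(hit))
      warning(sprintf("interval [%g, %g] contains no grid points", lo, hi))
    inside <- inside | hit
  }
  sel <- if (r$mode == "keep") inside else !inside
  if (!any(sel)) stop("region selection leaves no grid points")
  spectrum_set(s$wavenumbers[sel], s$values[, sel, drop = FALSE], s$mode,
               s$sample_ids, s$labels)
}

#' The default acquisition grid: 4000 down to 600 cm-1, step 4
#' @param from,to,by grid limits and spacing in cm-1
#' @return descending numeric grid
#' @export
default_grid <- function(from = 4000, to = 600, by = 4) seq(from, to, by = -abs(by))
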