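# Spectral data model and I/O.
#
# A `spectra_set` holds a collection of spectra that share one wavelength
# grid: a numeric wavelength vector (nm), an n x p value matrix (one row per
# spectrum) and a metadata data.frame keyed by
# (sample_id, replicate, instrument, scan_mode) with a `group` (farm/bunker)
# label. `domain` records whether values are reflectance, absorbance or a
# derivative, and `provenance` accumulates a free-text log of transforms.

SPECTRA_META_COLS <- c("sample_id", "replicate", "instrument", "scan_mode", "group")
SCAN_MODES <- c("static", "moving", "turntable")

# Grid-equality comparisons use this tolerance (nm).
GRID_TOL_NM <- 1e-6

#' Construct a spectra set
#'
#' Bundles a shared wavelength grid, a value matrix and per-spectrum metadata
#' into a validated `spectra_set` object, the container used by every stage of
#' the pipeline.
#'
#' @param wavelengths Strictly increasing numeric vector of wavelengths (nm),
#'   length at least 2.
#' @param values Numeric matrix, one row per spectrum, `length(wavelengths)`
#'   columns. Reflectance values must lie in (0, 1]; absorbance and
#'   derivative values need only be finite.
#' @param meta Data frame with columns `sample_id`, `replicate`, `instrument`,
#'   `scan_mode` and `group`; one row per row of `values`. The combination
#'   (sample_id, replicate, instrument, scan_mode) must be unique.
#' @param domain One of `"reflectance"`, `"absorbance"`, `"derivative"`.
#' @param provenance Character vector describing transforms already applied.
#'
#' @return An object of class `spectra_set`.
#' @export
spectra_set <- function(wavelengths, values, meta,
                        domain = c("reflectance", "absorbance", "derivative"),
                        provenance = character()) {
  domain <- match.arg(domain)
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) < 2L || any(!is.finite(wavelengths))) {
    stopf("wavelengths must be finite and of length >= 2")
  }
  if (any(diff(wavelengths) <= 0)) {
    stopf("wavelengths must be strictly increasing")
  }
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (ncol(values) != length(wavelengths)) {
    stopf("values has %d columns but there are %d wavelengths",
          ncol(values), length(wavelengths))
  }
  if (any(!is.finite(values))) stopf("spectral values must all be finite")
  if (domain == "reflectance" && (any(values <= 0) || any(values > 1))) {
    stopf("reflectance values must lie in (0, 1]")
  }
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  missing_cols <- setdiff(SPECTRA_META_COLS, names(meta))
  if (length(missing_cols)) {
    stopf("metadata is missing column(s): %s", paste(missing_cols, collapse = ", "))
  }
  meta <- meta[SPECTRA_META_COLS]
  if (nrow(meta) != nrow(values)) {
    stopf("metadata has %d rows but values has %d", nrow(meta), nrow(values))
  }
  meta$sample_id <- as.character(meta$sample_id)
  meta$replicate <- as.integer(meta$replicate)
  meta$instrument <- as.character(meta$instrument)
  meta$scan_mode <- as.character(meta$scan_mode)
  meta$group <- as.character(meta$group)
  if (any(is.na(meta$replicate)) || any(meta$replicate < 1L)) {
    stopf("replicate must be an integer >= 1")
  }
  bad_mode <- setdiff(unique(meta$scan_mode), SCAN_MODES)
  if (length(bad_mode)) {
    stopf("unknown scan_mode value(s): %s", paste(bad_mode, collapse = ", "))
  }
  key <- spectra_key(meta)
  if (anyDuplicated(key)) {
    stopf("duplicate (sample_id, replicate, instrument, scan_mode): %s",
          paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  rownames(values) <- NULL
  rownames(meta) <- NULL
  structure(
    list(wavelengths = wavelengths, values = values, meta = meta,
         domain = domain, provenance = as.character(provenance)),
    class = "spectra_set"
  )
}

spectra_key <- function(meta) {
  paste(meta$sample_id, meta$replicate, meta$instrument, meta$scan_mode, sep = "\r")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("<spectra_set> %d spectra x %d wavelengths [%s]\n",
              nrow(x$values), length(x$wavelengths), x$domain))
  cat(sprintf("  grid: %.6g-%.6g nm; instruments: %s; modes: %s\n",
              min(x$wavelengths), max(x$wavelengths),
              paste(unique(x$meta$instrument), collapse = ","),
              paste(unique(x$meta$scan_mode), collapse = ",")))
  if (length(x$provenance)) {
    cat("  provenance:", paste(x$provenance, collapse = " | "), "\n")
  }
  invisible(x)
}

#' Number of spectra in a spectra set
#' @param x A `spectra_set`.
#' @return Integer count of spectra (rows).
#' @export
n_spectra <- function(x) nrow(x$values)

add_provenance <- function(x, msg) {
  x$provenance <- c(x$provenance, msg)
  x
}

#' Subset a spectra set by row
#' @param x A `spectra_set`.
#' @param i Row indices or logical mask.
#' @return A `spectra_set` with the selected spectra.
#' @export
subset_spectra <- function(x, i) {
  spectra_set(x$wavelengths, x$values[i, , drop = FALSE],
              x$meta[i, , drop = FALSE], x$domain, x$provenance)
}

#' Read spectra from a wide CSV file
#'
#' Expects the metadata columns `sample_id`, `replicate`, `instrument`,
#' `scan_mode`, `group` followed by wavelength columns whose headers parse as
#' numbers (nm). Values are read as reflectance. Rows containing unparseable
#' numeric cells are dropped with a warning naming the row indices.
#'
#' @param path Path to a UTF-8 comma-separated file with '.' decimals.
#' @return A `spectra_set` in the reflectance domain.
#' @export
read_spectra <- function(path) {
  raw <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing_cols <- setdiff(SPECTRA_META_COLS, names(raw))
  if (length(missing_cols)) {
    stopf("spectra file %s is missing metadata column(s): %s",
          path, paste(missing_cols, collapse = ", "))
  }
  wl_names <- setdiff(names(raw), SPECTRA_META_COLS)
  wl <- suppressWarnings(as.numeric(wl_names))
  if (any(is.na(wl))) {
    stopf("non-numeric wavelength header(s): %s",
          paste(wl_names[is.na(wl)], collapse = ", "))
  }
  if (any(diff(wl) <= 0)) stopf("wavelength headers are not strictly increasing")
  vals <- suppressWarnings(
    vapply(raw[wl_names], function(col) as.numeric(col), numeric(nrow(raw)))
  )
  vals <- matrix(vals, nrow = nrow(raw))
  bad_rows <- which(apply(vals, 1L, function(r) any(!is.finite(r))))
  if (length(bad_rows)) {
    warning(sprintf("dropping %d row(s) with unparseable numeric cells: %s",
                    length(bad_rows), paste(bad_rows, collapse = ", ")),
            call. = FALSE)
    vals <- vals[-bad_rows, , drop = FALSE]
    raw <- raw[-bad_rows, , drop = FALSE]
  }
  spectra_set(wl, vals, raw[SPECTRA_META_COLS], "reflectance",
              provenance = sprintf("read_spectra(%s)", basename(path)))
}

#' Write spectra to a wide CSV file
#'
#' Inverse of [read_spectra()]; metadata columns first, then one column per
#' wavelength. The provenance log is written to a sidecar text file
#' `<path>.log`.
#'
#' @param x A `spectra_set`.
#' @param path Output CSV path.
#' @param digits Significant digits for the numeric values (default keeps
#'   round-trips exact to at least 12 significant digits).
#' @return `path`, invisibly.
#' @export
write_spectra <- function(x, path, digits = 15L) {
  stopifnot(inherits(x, "spectra_set"))
  df <- cbind(
    x$meta,
    as.data.frame(signif(x$values, digits), check.names = FALSE)
  )
  names(df) <- c(SPECTRA_META_COLS, format(x$wavelengths, trim = TRUE, digits = 15))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  writeLines(c(sprintf("domain: %s", x$domain), x$provenance),
             paste0(path, ".log"))
  invisible(path)
}

#' Convert reflectance spectra to absorbance
#'
#' Applies the standard log(1/R) transform, the absorbance representation
#' used for diffuse-reflectance NIR data.
#'
#' @param x A `spectra_set` in the reflectance domain with all values > 0.
#' @return A `spectra_set` in the absorbance domain.
#' @export
to_absorbance <- function(x) {
  stopifnot(inherits(x, "spectra_set"))
  if (x$domain != "reflectance") {
    stopf("to_absorbance() requires reflectance input, got %s", x$domain)
  }
  bad <- which(apply(x$values, 1L, function(r) any(r <= 0)))
  if (length(bad)) {
    stopf("non-positive reflectance for sample(s): %s",
          paste(unique(x$meta$sample_id[bad]), collapse = ", "))
  }
  x$values <- -log10(x$values)
  x$domain <- "absorbance"
  add_provenance(x, "to_absorbance: log10(1/R)")
}

#' Resample spectra onto an arithmetic wavelength grid
#'
#' Piecewise-linear interpolation onto the grid `start_nm, start_nm + step_nm,
#' ...` up to `stop_nm`. No extrapolation: the requested range must lie within
#' the span of the source grid.
#'
#' @param x A `spectra_set`.
#' @param start_nm,stop_nm Target range (nm), inclusive.
#' @param step_nm Target step (nm), > 0.
#' @return A `spectra_set` on the new grid.
#' @export
resample_to_grid <- function(x, start_nm, stop_nm, step_nm) {
  stopifnot(inherits(x, "spectra_set"))
  if (step_nm <= 0) stopf("step_nm must be > 0")
  src <- x$wavelengths
  if (start_nm < src[1L] - GRID_TOL_NM || stop_nm > src[length(src)] + GRID_TOL_NM) {
    stopf("requested range [%g, %g] exceeds source span [%g, %g]; refusing to extrapolate",
          start_nm, stop_nm, src[1L], src[length(src)])
  }
  grid <- seq(start_nm, stop_nm, by = step_nm)
  if (max(abs(range(grid - round(grid)))) < GRID_TOL_NM) grid <- round(grid)
  if (length(grid) < 2L) stopf("target grid has fewer than 2 points")
  same <- length(grid) == length(src) && all(abs(grid - src) < GRID_TOL_NM)
  if (same) return(add_provenance(x, "resample_to_grid: identity"))
  vals <- t(apply(x$values, 1L, function(r) approx(src, r, xout = grid)$y))
  out <- spectra_set(grid, vals, x$meta, x$domain, x$provenance)
  add_provenance(out, sprintf("resample_to_grid: %g-%g nm step %g (linear)",
                              start_nm, stop_nm, step_nm))
}

#' Aggregate replicate scans
#'
#' With `policy = "mean"`, replaces the replicates of each
#' (sample_id, instrument, scan_mode) by their arithmetic mean spectrum
#' (replicate number set to 1); `"keep_all"` returns the input unchanged.
#' Averaging before calibration avoids pseudo-replication inflating the
#' apparent sample size.
#'
#' @param x A `spectra_set` with a uniform domain.
#' @param policy `"mean"` or `"keep_all"`.
#' @return A `spectra_set`.
#' @export
aggregate_replicates <- function(x, policy = c("mean", "keep_all")) {
  stopifnot(inherits(x, "spectra_set"))
  policy <- match.arg(policy)
  if (policy == "keep_all") return(x)
  key <- paste(x$meta$sample_id, x$meta$instrument, x$meta$scan_mode, sep = "\r")
  idx <- split(seq_len(nrow(x$values)), key)
  # keep first-appearance order
  idx <- idx[unique(key)]
  vals <- t(vapply(idx, function(i) colMeans(x$values[i, , drop = FALSE]),
                   numeric(ncol(x$values))))
  first <- vapply(idx, `[`, integer(1), 1L)
  meta <- x$meta[first, , drop = FALSE]
  meta$replicate <- 1L
  out <- spectra_set(x$wavelengths, vals, meta, x$domain, x$provenance)
  add_provenance(out, "aggregate_replicates: mean")
}
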