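# Reference chemistry table: per-sample constituent values in %DM.

#' Forage constituents handled by the pipeline
#'
#' In vitro total digestibility (IVTD), neutral detergent fiber (aNDF), NDF
#' digestibility (NDFD, % of NDF), acid detergent fiber (ADF), acid detergent
#' lignin (ADL) and crude protein (CP), all on a dry-matter basis.
#' @export
FORAGE_CONSTITUENTS <- c("IVTD", "aNDF", "NDFD", "ADF", "ADL", "CP")

#' Default reference-chemistry distribution for mixed haylage
#'
#' Summary statistics (mean, SD, min, max, all %DM) typical of laboratory wet
#' chemistry on mixed alfalfa-grass haylage sampled from farm silage bunkers.
#' These are the default targets of the synthetic generator and the default
#' plausibility bounds of [reference_table()].
#'
#' @return Data frame with columns `constituent`, `mean`, `sd`, `min`, `max`.
#' @export
default_reference_stats <- function() {
  data.frame(
    constituent = FORAGE_CONSTITUENTS,
    mean = c(79.22, 50.13, 58.84, 37.18, 7.35, 17.62),
    sd   = c(7.31, 10.42, 9.39, 5.80, 2.18, 4.43),
    min  = c(38.13, 28.81, 11.40, 24.22, 3.12, 6.12),
    max  = c(92.92, 81.60, 80.87, 59.06, 20.60, 27.72),
    stringsAsFactors = FALSE
  )
}

#' Construct a reference-chemistry table
#'
#' @param df Data frame with columns `sample_id`, `group` and one column per
#'   constituent in [FORAGE_CONSTITUENTS].
#' @param bounds Optional data frame with `constituent`, `min`, `max` columns
#'   giving plausibility bounds; defaults to [default_reference_stats()].
#'   Values outside the bounds raise an error (they indicate unit mix-ups or
#'   corrupted laboratory exports).
#' @return A data frame of class `reference_table`.
#' @export
reference_table <- function(df, bounds = default_reference_stats()) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", FORAGE_CONSTITUENTS)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stopf("reference table missing column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  df <- df[need]
  df$sample_id <- as.character(df$sample_id)
  df$group <- as.character(df$group)
  if (anyDuplicated(df$sample_id)) stopf("duplicate sample_id in reference table")
  for (cc in FORAGE_CONSTITUENTS) {
    v <- as.numeric(df[[cc]])
    if (any(!is.finite(v))) stopf("non-finite %s value(s)", cc)
    b <- bounds[bounds$constituent == cc, ]
    if (nrow(b) == 1L && (any(v < b$min - 1e-9) || any(v > b$max + 1e-9))) {
      stopf("%s value(s) outside plausibility bounds [%g, %g]", cc, b$min, b$max)
    }
    df[[cc]] <- v
  }
  rownames(df) <- NULL
  class(df) <- c("reference_table", "data.frame")
  df
}

#' Read a reference-chemistry CSV
#'
#' Expects header `sample_id,group,IVTD,aNDF,NDFD,ADF,ADL,CP` with values in
#' %DM.
#' @param path CSV path.
#' @param ... Passed to [reference_table()] (e.g. `bounds`).
#' @return A `reference_table`.
#' @export
read_reference <- function(path, ...) {
  reference_table(read.csv(path, stringsAsFactors = FALSE), ...)
}

#' Write a reference-chemistry CSV
#' @param x A `reference_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
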