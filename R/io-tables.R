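#' Read a per-window tumour/normal count table
#'
#' Tab-separated table with columns `chrom`, `start`, `end`, `t_count`,
#' `n_count` (BED-style 0-based half-open intervals) and optionally a
#' precomputed `log2r` column. The normal-count mean and SD used by the
#' coverage mask are recomputed from the windows on access.
#'
#' @param path path to a TSV file.
#' @return A [WindowCounts-class] object. An empty table yields an empty
#'   object whose statistics are `NA`.
#' @export
readWindowCounts <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!nrow(df)) return(WindowCounts())
  .checkCols(df, .WINDOW_COLS[1:5], "readWindowCounts")
  for (k in c("start", "end", "t_count", "n_count")) {
    v <- suppressWarnings(as.numeric(df[[k]]))
    if (anyNA(v) && !all(is.na(df[[k]])))
      stop("non-numeric value in column '", k, "' of ", path, call. = FALSE)
    df[[k]] <- v
  }
  WindowCounts(df)
}

#' Write a WindowCounts object as TSV
#'
#' Windows are written in genomic order; reading the file back with
#' [readWindowCounts()] reproduces the object (including any computed
#' `log2r` values).
#'
#' @param x a [WindowCounts-class] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeWindowCounts <- function(x, path) {
  df <- windowTable(x)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write copy-number segment tables
#'
#' Segments are exchanged as TSV with columns `chrom`, `first_window`,
#' `last_window`, `n_windows`, `seg_mean`, `ploidy_call`.
#'
#' @param path file path.
#' @return `readSegments`: a [CNSegments-class] object.
#' @export
readSegments <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!nrow(df)) return(CNSegments())
  CNSegments(df)
}

#' @rdname readSegments
#' @param x a [CNSegments-class] object.
#' @export
writeSegments <- function(x, path) {
  write.table(segTable(x), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
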