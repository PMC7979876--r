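#' @useDynLib tnsomatic, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats mad sd rbinom rnorm rnbinom rpois runif dbinom pbinom
#'   weighted.mean setNames
#' @importFrom utils read.delim write.table packageVersion
NULL

SV_TYPES <- c("DEL", "DUP", "INV", "TRA", "INS")
INTRA_SV_TYPES <- c("DEL", "DUP", "INV", "INS")

SNV_INFO_FIELDS <- c("NUMALT", "AO", "RO", "SAF", "SAR", "SRF", "SRR",
                     "QA", "QR", "MQM", "SAP", "AB")

.SMALLVAR_COLS <- c(chrom = "character", pos = "integer", ref = "character",
                    alt = "character", qual = "numeric", numalt = "integer",
                    ao = "integer", ro = "integer", saf = "integer",
                    sar = "integer", srf = "integer", srr = "integer",
                    qa = "numeric", qr = "numeric", mqm = "numeric",
                    sap = "numeric", ab = "numeric")

.SV_COLS <- c(svtype = "character", chrom = "character", start = "integer",
              chr2 = "character", end = "integer", svlen = "numeric",
              precise = "logical", af = "numeric",
              filter_status = "character", source_method = "character",
              truth_label = "character")

.WINDOW_COLS <- c(chrom = "character", start = "integer", end = "integer",
                  t_count = "numeric", n_count = "numeric", log2r = "numeric")

.SEGMENT_COLS <- c(chrom = "character", first_window = "integer",
                   last_window = "integer", n_windows = "integer",
                   seg_mean = "numeric", ploidy_call = "integer")

.coerceCols <- function(df, spec) {
  for (nm in names(spec)) {
    df[[nm]] <- switch(spec[[nm]],
      character = as.character(df[[nm]]),
      integer = as.integer(df[[nm]]),
      numeric = as.numeric(df[[nm]]),
      logical = as.logical(df[[nm]]))
  }
  df[names(spec)]
}

.checkCols <- function(df, spec, what) {
  missing <- setdiff(names(spec), names(df))
  if (length(missing))
    stop(what, ": missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
}

#' Annotated small-variant call set
#'
#' Container for small-variant records carrying the per-call annotation
#' fields used by the somatic subtraction pipeline: call quality, the number
#' of alternate alleles at the site, alternate/reference observation counts
#' (total and per strand), summed base qualities, mean mapping quality of
#' alternate observations, phred-scaled strand-balance probability, and the
#' reference-read ratio. One row per (site, alternate allele); multi-allelic
#' sites are expanded but retain the site-level allele count in `numalt`.
#'
#' @slot calls `data.frame` with columns `chrom`, `pos`, `ref`, `alt`,
#'   `qual`, `numalt`, `ao`, `ro`, `saf`, `sar`, `srf`, `srr`, `qa`, `qr`,
#'   `mqm`, `sap`, `ab`.
#' @export
setClass("SmallVariantCalls", representation(calls = "data.frame"))

setValidity("SmallVariantCalls", function(object) {
  df <- object@calls
  msg <- character(0)
  missing <- setdiff(names(.SMALLVAR_COLS), names(df))
  if (length(missing))
    return(paste("missing column(s):", paste(missing, collapse = ", ")))
  if (nrow(df)) {
    if (any(df$pos < 1)) msg <- c(msg, "pos must be >= 1")
    counts <- c("ao", "ro", "saf", "sar", "srf", "srr", "numalt")
    if (any(vapply(counts, function(k) any(df[[k]] < 0), logical(1))))
      msg <- c(msg, "observation counts must be non-negative")
    if (any(df$saf + df$sar != df$ao)) msg <- c(msg, "saf + sar must equal ao")
    if (any(df$srf + df$srr != df$ro)) msg <- c(msg, "srf + srr must equal ro")
    if (any(df$qual < 0, na.rm = TRUE)) msg <- c(msg, "qual must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SmallVariantCalls object
#'
#' @param calls `data.frame` with the columns documented in
#'   [SmallVariantCalls-class]; extra columns are dropped, types are coerced.
#' @return A [SmallVariantCalls-class] object.
#' @export
SmallVariantCalls <- function(calls = .emptySmallVarDf()) {
  .checkCols(calls, .SMALLVAR_COLS, "SmallVariantCalls")
  df <- .coerceCols(as.data.frame(calls), .SMALLVAR_COLS)
  rownames(df) <- NULL
  new("SmallVariantCalls", calls = df)
}

.emptySmallVarDf <- function() {
  df <- lapply(.SMALLVAR_COLS, function(tp) vector(tp, 0L))
  as.data.frame(df, stringsAsFactors = FALSE)
}

#' Structural-variant call set
#'
#' One row per SV call: type (`DEL`, `DUP`, `INV`, `TRA`, `INS`), the two
#' breakpoints (`chrom`/`start` and `chr2`/`end`), length in bases (`NA`
#' permitted for translocations), breakpoint precision flag, caller-reported
#' allele fraction, filter status, producing method and an optional truth
#' label (`true_somatic`, `false_call` or `unlabelled`).
#'
#' @slot calls `data.frame` of SV records.
#' @slot skipped number of input records dropped on read (unknown SVTYPE).
#' @export
setClass("SvCallSet",
         representation(calls = "data.frame", skipped = "integer"),
         prototype(skipped = 0L))

setValidity("SvCallSet", function(object) {
  df <- object@calls
  msg <- character(0)
  missing <- setdiff(names(.SV_COLS), names(df))
  if (length(missing))
    return(paste("missing column(s):", paste(missing, collapse = ", ")))
  if (nrow(df)) {
    if (!all(df$svtype %in% SV_TYPES))
      msg <- c(msg, paste("svtype must be one of", paste(SV_TYPES, collapse = "/")))
    intra <- df$svtype %in% INTRA_SV_TYPES
    if (any(intra & df$chrom != df$chr2))
      msg <- c(msg, "intra-chromosomal SV must have chrom == chr2")
    if (any(intra & df$end < df$start))
      msg <- c(msg, "intra-chromosomal SV must have end >= start")
    bad_af <- !is.na(df$af) & (df$af < 0 | df$af > 1)
    if (any(bad_af)) msg <- c(msg, "af must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an SvCallSet
#'
#' @param calls `data.frame`; missing optional columns (`svlen`, `precise`,
#'   `af`, `filter_status`, `source_method`, `truth_label`) are filled with
#'   defaults (`NA`, `TRUE`, `NA`, `"PASS"`, `NA`, `"unlabelled"`).
#' @param skipped integer count of records skipped during parsing.
#' @return An [SvCallSet-class] object.
#' @export
SvCallSet <- function(calls = .emptySvDf(), skipped = 0L) {
  calls <- as.data.frame(calls)
  if (nrow(calls)) {
    if (is.null(calls$chr2)) calls$chr2 <- calls$chrom
    if (is.null(calls$svlen)) calls$svlen <- NA_real_
    if (is.null(calls$precise)) calls$precise <- TRUE
    if (is.null(calls$af)) calls$af <- NA_real_
    if (is.null(calls$filter_status)) calls$filter_status <- "PASS"
    if (is.null(calls$source_method)) calls$source_method <- NA_character_
    if (is.null(calls$truth_label)) calls$truth_label <- "unlabelled"
  }
  .checkCols(calls, .SV_COLS, "SvCallSet")
  df <- .coerceCols(calls, .SV_COLS)
  rownames(df) <- NULL
  new("SvCallSet", calls = df, skipped = as.integer(skipped))
}

.emptySvDf <- function() {
  df <- lapply(.SV_COLS, function(tp) vector(tp, 0L))
  as.data.frame(df, stringsAsFactors = FALSE)
}

#' Tumour/normal window counts
#'
#' Per-window read counts for the tumour (`t_count`) and normal (`n_count`)
#' samples over fixed-size genomic windows (0-based half-open intervals), in
#' genomic order, plus the count totals used for the automatic log-ratio
#' offset. The `log2r` column holds the normalised log2 tumour/normal ratio
#' once computed; masked windows carry `NA`.
#'
#' @slot windows `data.frame` with columns `chrom`, `start`, `end`,
#'   `t_count`, `n_count`, `log2r`.
#' @slot tTotal,nTotal total tumour/normal counts over all windows.
#' @export
setClass("WindowCounts",
         representation(windows = "data.frame", tTotal = "numeric",
                        nTotal = "numeric"))

setValidity("WindowCounts", function(object) {
  df <- object@windows
  msg <- character(0)
  missing <- setdiff(names(.WINDOW_COLS), names(df))
  if (length(missing))
    return(paste("missing column(s):", paste(missing, collapse = ", ")))
  if (nrow(df)) {
    if (any(df$t_count < 0) || any(df$n_count < 0))
      msg <- c(msg, "window counts must be non-negative")
    if (any(df$end <= df$start)) msg <- c(msg, "windows must have end > start")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a WindowCounts object
#'
#' @param windows `data.frame` with columns `chrom`, `start`, `end`,
#'   `t_count`, `n_count` and optionally `log2r`.
#' @return A [WindowCounts-class] object; totals are computed from the
#'   counts.
#' @export
WindowCounts <- function(windows = .emptyWindowDf()) {
  windows <- as.data.frame(windows)
  if (is.null(windows$log2r)) windows$log2r <- NA_real_
  .checkCols(windows, .WINDOW_COLS, "WindowCounts")
  df <- .coerceCols(windows, .WINDOW_COLS)
  rownames(df) <- NULL
  new("WindowCounts", windows = df,
      tTotal = sum(df$t_count), nTotal = sum(df$n_count))
}

.emptyWindowDf <- function() {
  df <- lapply(.WINDOW_COLS, function(tp) vector(tp, 0L))
  as.data.frame(df, stringsAsFactors = FALSE)
}

#' Copy-number segments
#'
#' Contiguous runs of (non-masked) windows with their mean log2 ratio, the
#' number of contributing windows, and, after classification, the assigned
#' integer tumour ploidy (0-6, `NA` when unclassified). Window indices refer
#' to rows of the originating [WindowCounts-class] object.
#'
#' @slot segments `data.frame` with columns `chrom`, `first_window`,
#'   `last_window`, `n_windows`, `seg_mean`, `ploidy_call`.
#' @export
setClass("CNSegments", representation(segments = "data.frame"))

setValidity("CNSegments", function(object) {
  df <- object@segments
  missing <- setdiff(names(.SEGMENT_COLS), names(df))
  if (length(missing))
    return(paste("missing column(s):", paste(missing, collapse = ", ")))
  if (nrow(df) && any(df$n_windows < 1)) return("n_windows must be >= 1")
  TRUE
})

#' Construct a CNSegments object
#'
#' @param segments `data.frame` with the columns documented in
#'   [CNSegments-class]; `ploidy_call` defaults to `NA`.
#' @return A [CNSegments-class] object.
#' @export
CNSegments <- function(segments = .emptySegmentDf()) {
  segments <- as.data.frame(segments)
  if (is.null(segments$ploidy_call)) segments$ploidy_call <- NA_integer_
  .checkCols(segments, .SEGMENT_COLS, "CNSegments")
  df <- .coerceCols(segments, .SEGMENT_COLS)
  rownames(df) <- NULL
  new("CNSegments", segments = df)
}

.emptySegmentDf <- function() {
  df <- lapply(.SEGMENT_COLS, function(tp) vector(tp, 0L))
  as.data.frame(df, stringsAsFactors = FALSE)
}

#' Tumour purity model
#'
#' Holds the tumour-cell fraction estimated from clusters of non-neutral
#' segment means, the per-cluster estimates it was averaged from, and the
#' ploidy-2 recentring offset that was subtracted from all segment means
#' beforehand.
#'
#' @slot purity tumour DNA fraction alpha in `[0, 1]`.
#' @slot clusterEstimates named numeric vector of per-cluster purity
#'   estimates (names are the provisional tumour ploidies, e.g. "1", "3",
#'   "4").
#' @slot baselineOffset the recentring value subtracted from segment means.
#' @export
setClass("PurityModel",
         representation(purity = "numeric", clusterEstimates = "numeric",
                        baselineOffset = "numeric"),
         prototype(baselineOffset = NA_real_))

setValidity("PurityModel", function(object) {
  if (length(object@purity) != 1 || is.na(object@purity) ||
      object@purity < 0 || object@purity > 1)
    return("purity must be a single value in [0, 1]")
  TRUE
})

#' Circular binary segmentation parameters
#'
#' @slot alpha permutation significance level for accepting a split.
#' @slot minWidth minimum number of windows per segment.
#' @slot undoSD threshold (in units of the point-level noise SD) below which
#'   an accepted change point is undone.
#' @slot nPermutations number of permutations per significance test.
#' @slot seed RNG seed making segmentation deterministic.
#' @export
setClass("CbsParams",
         representation(alpha = "numeric", minWidth = "integer",
                        undoSD = "numeric", nPermutations = "integer",
                        seed = "integer"))

setValidity("CbsParams", function(object) {
  msg <- character(0)
  if (object@alpha <= 0 || object@alpha >= 1) msg <- c(msg, "alpha must be in (0, 1)")
  if (object@minWidth < 2L) msg <- c(msg, "minWidth must be >= 2")
  if (object@nPermutations < 1L) msg <- c(msg, "nPermutations must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct CBS parameters
#'
#' Defaults follow the segmentation settings used throughout the package's
#' copy-number pipeline: `alpha = 0.01`, `minWidth = 5`, sd-undo with
#' `undoSD = 3`.
#'
#' @param alpha,minWidth,undoSD,nPermutations,seed see [CbsParams-class].
#' @return A [CbsParams-class] object.
#' @export
CbsParams <- function(alpha = 0.01, minWidth = 5L, undoSD = 3,
                      nPermutations = 1000L, seed = 1L) {
  new("CbsParams", alpha = alpha, minWidth = as.integer(minWidth),
      undoSD = undoSD, nPermutations = as.integer(nPermutations),
      seed = as.integer(seed))
}

#' Cis/trans phasing scenario
#'
#' Describes a somatic SNV co-located with a heterogeneous somatic deletion:
#' the tumour purity (percent of cells that are tumour), the percentage of
#' all cells carrying the deletion, and optionally the observed SNV VAF and
#' deletion allele fraction (both percentages).
#'
#' @slot purityPct tumour-cell percentage of the sample.
#' @slot deletionCellPct percentage of all cells carrying the deletion.
#' @slot observedVafPct observed somatic-SNV VAF (percent), `NA` if unknown.
#' @slot deletionAfPct observed deletion allele fraction (percent), `NA` if
#'   unknown.
#' @export
setClass("PhasingScenario",
         representation(purityPct = "numeric", deletionCellPct = "numeric",
                        observedVafPct = "numeric", deletionAfPct = "numeric"),
         prototype(observedVafPct = NA_real_, deletionAfPct = NA_real_))

setValidity("PhasingScenario", function(object) {
  p <- object@purityPct; x <- object@deletionCellPct
  if (p < 0 || p > 100) return("purityPct must lie in [0, 100]")
  if (x < 0 || x > p)
    return("deletionCellPct must lie in [0, purityPct]")
  TRUE
})

#' Construct a PhasingScenario
#'
#' @param purityPct,deletionCellPct,observedVafPct,deletionAfPct see
#'   [PhasingScenario-class].
#' @return A [PhasingScenario-class] object.
#' @export
PhasingScenario <- function(purityPct, deletionCellPct,
                            observedVafPct = NA_real_,
                            deletionAfPct = NA_real_) {
  new("PhasingScenario", purityPct = purityPct,
      deletionCellPct = deletionCellPct,
      observedVafPct = observedVafPct, deletionAfPct = deletionAfPct)
}
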