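#' @describeIn SmallVariantCalls-class number of records
#' @param x object
#' @export
setMethod("length", "SmallVariantCalls", function(x) nrow(x@calls))

#' @describeIn SvCallSet-class number of records
#' @export
setMethod("length", "SvCallSet", function(x) nrow(x@calls))

#' @describeIn WindowCounts-class number of windows
#' @export
setMethod("length", "WindowCounts", function(x) nrow(x@windows))

#' @describeIn CNSegments-class number of segments
#' @export
setMethod("length", "CNSegments", function(x) nrow(x@segments))

#' Extract the record table from a container
#'
#' `callTable` returns the underlying `data.frame` of a
#' [SmallVariantCalls-class] or [SvCallSet-class]; `windowTable` and
#' `segTable` do the same for [WindowCounts-class] and [CNSegments-class].
#'
#' @param x the container object.
#' @return A `data.frame`.
#' @export
setGeneric("callTable", function(x) standardGeneric("callTable"))

#' @rdname callTable
#' @export
setMethod("callTable", "SmallVariantCalls", function(x) x@calls)

#' @rdname callTable
#' @export
setMethod("callTable", "SvCallSet", function(x) x@calls)

#' @rdname callTable
#' @export
setGeneric("windowTable", function(x) standardGeneric("windowTable"))

#' @rdname callTable
#' @export
setMethod("windowTable", "WindowCounts", function(x) x@windows)

#' @rdname callTable
#' @export
setGeneric("segTable", function(x) standardGeneric("segTable"))

#' @rdname callTable
#' @export
setMethod("segTable", "CNSegments", function(x) x@segments)

#' Normal-sample count statistics of a WindowCounts object
#'
#' `nMean` and `nSd` are the mean and standard deviation of the normal
#' counts over all windows (the quantities the coverage mask is based on);
#' `tumourTotal`/`normalTotal` are the count totals used for the automatic
#' log-ratio offset.
#'
#' @param x a [WindowCounts-class] object.
#' @return A single numeric value (`NA` for an empty object).
#' @export
setGeneric("nMean", function(x) standardGeneric("nMean"))

#' @rdname nMean
#' @export
setMethod("nMean", "WindowCounts", function(x)
  if (nrow(x@windows)) mean(x@windows$n_count) else NA_real_)

#' @rdname nMean
#' @export
setGeneric("nSd", function(x) standardGeneric("nSd"))

#' @rdname nMean
#' @export
setMethod("nSd", "WindowCounts", function(x) {
  if (nrow(x@windows) < 2L) return(if (nrow(x@windows)) 0 else NA_real_)
  sd(x@windows$n_count)
})

#' @rdname nMean
#' @export
setGeneric("tumourTotal", function(x) standardGeneric("tumourTotal"))

#' @rdname nMean
#' @export
setMethod("tumourTotal", "WindowCounts", function(x) x@tTotal)

#' @rdname nMean
#' @export
setGeneric("normalTotal", function(x) standardGeneric("normalTotal"))

#' @rdname nMean
#' @export
setMethod("normalTotal", "WindowCounts", function(x) x@nTotal)

#' Accessors for PurityModel
#'
#' @param x a [PurityModel-class] object.
#' @return `purity`: the averaged tumour-cell fraction; `clusterEstimates`:
#'   the per-cluster estimates it was averaged from; `baselineOffset`: the
#'   ploidy-2 recentring offset.
#' @export
setGeneric("purity", function(x) standardGeneric("purity"))

#' @rdname purity
#' @export
setMethod("purity", "PurityModel", function(x) x@purity)

#' @rdname purity
#' @export
setGeneric("clusterEstimates", function(x) standardGeneric("clusterEstimates"))

#' @rdname purity
#' @export
setMethod("clusterEstimates", "PurityModel", function(x) x@clusterEstimates)

#' @rdname purity
#' @export
setGeneric("baselineOffset", function(x) standardGeneric("baselineOffset"))

#' @rdname purity
#' @export
setMethod("baselineOffset", "PurityModel", function(x) x@baselineOffset)

setMethod("show", "SmallVariantCalls", function(object) {
  cat("SmallVariantCalls with", nrow(object@calls), "record(s) on",
      length(unique(object@calls$chrom)), "chromosome(s)\n")
  if (nrow(object@calls)) print(utils::head(object@calls, 5L))
})

setMethod("show", "SvCallSet", function(object) {
  df <- object@calls
  cat("SvCallSet with", nrow(df), "call(s)")
  if (object@skipped) cat(" (", object@skipped, " skipped on read)", sep = "")
  cat("\n")
  if (nrow(df)) print(table(df$svtype))
})

setMethod("show", "WindowCounts", function(object) {
  df <- object@windows
  cat("WindowCounts:", nrow(df), "window(s) on",
      length(unique(df$chrom)), "chromosome(s);",
      sum(!is.na(df$log2r)), "with log2r\n")
})

setMethod("show", "CNSegments", function(object) {
  cat("CNSegments with", nrow(object@segments), "segment(s)\n")
  if (nrow(object@segments)) print(object@segments)
})

setMethod("show", "PurityModel", function(object) {
  cat("PurityModel: purity =", format(object@purity, digits = 3),
      "(cluster estimates:",
      paste(sprintf("p=%s: %.3f", names(object@clusterEstimates),
                    object@clusterEstimates), collapse = ", "),
      ")\n  baseline offset:", format(object@baselineOffset, digits = 3), "\n")
})

setMethod("show", "CbsParams", function(object) {
  cat(sprintf(
    "CbsParams: alpha=%g, minWidth=%d, undoSD=%g, nPermutations=%d, seed=%d\n",
    object@alpha, object@minWidth, object@undoSD, object@nPermutations,
    object@seed))
})

setMethod("show", "PhasingScenario", function(object) {
  cat(sprintf("PhasingScenario: purity %g%%, deletion cell fraction %g%%",
              object@purityPct, object@deletionCellPct))
  if (!is.na(object@observedVafPct))
    cat(sprintf(", observed VAF %g%%", object@observedVafPct))
  cat("\n")
})
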