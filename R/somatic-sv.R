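#' Subtract germline SVs from a tumour SV call set
#'
#' A tumour call is removed when some germline call of the same SV type has
#' both breakpoints within a length-scaled tolerance: start and end must
#' each lie within `L/100` bases of the germline call's, where `L` is the
#' germline SV length. Chromosome identity is required at both breakpoints.
#' The tolerance is floored at `minTol` so that short germline SVs still
#' subtract their re-called twins, and translocations (whose length is
#' undefined) use the fixed `traTol` window instead.
#'
#' @param tumour,germline [SvCallSet-class] objects.
#' @param traTol fixed breakpoint tolerance (bases) for translocations.
#' @param minTol floor on the length-scaled tolerance.
#' @return The somatic [SvCallSet-class] (subset of `tumour`).
#' @export
subtractGermlineSvs <- function(tumour, germline, traTol = 1000,
                                minTol = 10) {
  tdf <- callTable(tumour)
  gdf <- callTable(germline)
  if (!nrow(tdf) || !nrow(gdf)) return(SvCallSet(tdf))
  tol <- ifelse(gdf$svtype == "TRA" | is.na(gdf$svlen), traTol,
                pmax(gdf$svlen / 100, minTol))
  removed <- vapply(seq_len(nrow(tdf)), function(i) {
    hit <- gdf$svtype == tdf$svtype[i] &
      gdf$chrom == tdf$chrom[i] & gdf$chr2 == tdf$chr2[i] &
      abs(gdf$start - tdf$start[i]) <= tol &
      abs(gdf$end - tdf$end[i]) <= tol
    any(hit)
  }, logical(1))
  SvCallSet(tdf[!removed, , drop = FALSE])
}

#' Size/precision/decoy filter for somatic SV calls
#'
#' The pass set keeps precise calls with `SVLEN > minLen` whose second
#' breakpoint is not on the decoy contig; translocations, whose length is
#' undefined, satisfy the length criterion by construction (they join two
#' chromosomes). Imprecise calls with allele fraction above `afCutoff` are
#' returned separately for manual review; everything else is dropped.
#'
#' @param calls an [SvCallSet-class] object.
#' @param minLen minimum SV length in bases (strict inequality).
#' @param decoy decoy contig name.
#' @param afCutoff allele-fraction cutoff for the imprecise side set.
#' @return A list with `pass` and `imprecise` [SvCallSet-class] objects.
#' @export
filterSomaticSvs <- function(calls, minLen = 10000, decoy = "hs37d5",
                             afCutoff = 0.2) {
  df <- callTable(calls)
  longEnough <- ifelse(is.na(df$svlen), df$svtype == "TRA",
                       df$svlen > minLen)
  pass <- df$precise & longEnough & df$chr2 != decoy
  side <- !df$precise & !is.na(df$af) & df$af > afCutoff
  list(pass = SvCallSet(df[pass, , drop = FALSE]),
       imprecise = SvCallSet(df[side, , drop = FALSE]))
}

#' Match SV calls across methods
#'
#' Clusters the calls from several methods into unique variants: two calls
#' represent the same variant when their SV types match and both breakpoints
#' lie within `tol` bases of each other. Clusters are the connected
#' components of this pairwise relation, so the result does not depend on
#' the order in which the call sets are supplied. Each cluster is reported
#' with the coordinates of its first call in genomic order, plus a presence
#' flag per method.
#'
#' @param callsets named list of [SvCallSet-class] objects (name = method).
#' @param tol breakpoint tolerance in bases.
#' @return A `data.frame` with one row per unique variant: `variant_id`,
#'   `svtype`, `chrom`, `start`, `chr2`, `end`, `truth_label`, one logical
#'   column per method, and `n_methods`.
#' @export
matchAcrossMethods <- function(callsets, tol = 1000) {
  stopifnot(length(callsets) >= 1, !is.null(names(callsets)))
  methods <- names(callsets)
  df <- do.call(rbind, lapply(methods, function(m) {
    d <- callTable(callsets[[m]])
    if (nrow(d)) d$source_method <- m
    d
  }))
  if (is.null(df) || !nrow(df)) {
    out <- data.frame(variant_id = character(0), svtype = character(0),
                      chrom = character(0), start = integer(0),
                      chr2 = character(0), end = integer(0),
                      truth_label = character(0))
    for (m in methods) out[[m]] <- logical(0)
    out$n_methods <- integer(0)
    return(out)
  }
  df <- df[order(df$chrom, df$start, df$end, df$svtype, df$source_method), ,
           drop = FALSE]
  n <- nrow(df)
  parent <- seq_len(n)
  findRoot <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)[-1]) {
    prev <- seq_len(i - 1L)
    hits <- prev[df$svtype[prev] == df$svtype[i] &
                   df$chrom[prev] == df$chrom[i] &
                   df$chr2[prev] == df$chr2[i] &
                   abs(df$start[prev] - df$start[i]) <= tol &
                   abs(df$end[prev] - df$end[i]) <= tol]
    for (j in hits) {
      ri <- findRoot(i); rj <- findRoot(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  root <- vapply(seq_len(n), findRoot, integer(1))
  groups <- split(seq_len(n), root)
  rows <- lapply(groups, function(idx) {
    first <- idx[1]
    labels <- setdiff(unique(df$truth_label[idx]), "unlabelled")
    out <- data.frame(
      svtype = df$svtype[first], chrom = df$chrom[first],
      start = df$start[first], chr2 = df$chr2[first], end = df$end[first],
      truth_label = if (length(labels) == 1) labels else "unlabelled",
      stringsAsFactors = FALSE)
    for (m in methods) out[[m]] <- m %in% df$source_method[idx]
    out
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  out <- cbind(variant_id = sprintf("sv%04d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  out$n_methods <- rowSums(as.matrix(out[, methods, drop = FALSE]))
  rownames(out) <- NULL
  out
}

#' Assign truth labels to matched variants
#'
#' Labels each unique variant `true_somatic` when it matches an entry of the
#' truth table (same type, both breakpoints within `tol`), else
#' `false_call`. True variants that no method detected are appended with
#' all presence flags `FALSE` (the benchmark's false-negative rate counts
#' them), unless `addMissing = FALSE`.
#'
#' @param variants output of [matchAcrossMethods()].
#' @param truth `data.frame` with columns `svtype`, `chrom`, `start`,
#'   `chr2`, `end`.
#' @param tol breakpoint tolerance in bases.
#' @param addMissing append truth entries detected by no method.
#' @return `variants` with `truth_label` filled in.
#' @export
labelVariants <- function(variants, truth, tol = 1000, addMissing = TRUE) {
  if (is.null(truth$chr2)) truth$chr2 <- truth$chrom
  hitsFor <- function(i) {
    which(truth$svtype == variants$svtype[i] &
            truth$chrom == variants$chrom[i] &
            truth$chr2 == variants$chr2[i] &
            abs(truth$start - variants$start[i]) <= tol &
            abs(truth$end - variants$end[i]) <= tol)
  }
  hits <- lapply(seq_len(nrow(variants)), hitsFor)
  variants$truth_label <- ifelse(lengths(hits) > 0, "true_somatic",
                                 "false_call")
  if (addMissing) {
    methods <- names(variants)[vapply(variants, is.logical, logical(1))]
    missed <- setdiff(seq_len(nrow(truth)), unlist(hits))
    if (length(missed)) {
      extra <- data.frame(
        variant_id = sprintf("missed%04d", seq_along(missed)),
        svtype = truth$svtype[missed], chrom = truth$chrom[missed],
        start = truth$start[missed], chr2 = truth$chr2[missed],
        end = truth$end[missed], truth_label = "true_somatic",
        stringsAsFactors = FALSE)
      for (m in methods) extra[[m]] <- FALSE
      extra$n_methods <- 0L
      variants <- rbind(variants, extra[, names(variants)])
    }
  }
  variants
}

#' FNR/FDR benchmark of SV calling methods
#'
#' Evaluates each method against the labelled unique variants, per SV type
#' and aggregated over all types, using
#' `FNR = (true variants not detected by the method) / (total true
#' variants)` and `FDR = (false calls detected by the method) / (total calls
#' from the method)`. A zero denominator yields `NA`, not zero.
#'
#' @param variants output of [matchAcrossMethods()] (optionally via
#'   [labelVariants()]); every row must be labelled `true_somatic` or
#'   `false_call`.
#' @param methods method columns to evaluate; defaults to the logical
#'   columns of `variants`.
#' @return A `data.frame` with one row per (svtype, method), svtype "All"
#'   aggregating across types, and columns `n_true`, `detected`, `missed`,
#'   `false_calls`, `total_calls`, `fnr`, `fdr`.
#' @export
evaluateMethods <- function(variants, methods = NULL) {
  if (is.null(methods))
    methods <- names(variants)[vapply(variants, is.logical, logical(1))]
  bad <- !variants$truth_label %in% c("true_somatic", "false_call")
  if (any(bad))
    stop(sum(bad), " variant(s) lack a truth label; every unique variant ",
         "must be labelled true_somatic or false_call", call. = FALSE)
  types <- c(intersect(SV_TYPES, unique(variants$svtype)), "All")
  rows <- list()
  for (tp in types) {
    sub <- if (tp == "All") variants else
      variants[variants$svtype == tp, , drop = FALSE]
    istrue <- sub$truth_label == "true_somatic"
    for (m in methods) {
      det <- sub[[m]]
      nTrue <- sum(istrue)
      detected <- sum(istrue & det)
      falseCalls <- sum(!istrue & det)
      totalCalls <- sum(det)
      rows[[length(rows) + 1L]] <- data.frame(
        svtype = tp, method = m, n_true = nTrue, detected = detected,
        missed = nTrue - detected, false_calls = falseCalls,
        total_calls = totalCalls,
        fnr = if (nTrue > 0) (nTrue - detected) / nTrue else NA_real_,
        fdr = if (totalCalls > 0) falseCalls / totalCalls else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Round half-up to a number of decimal places
#'
#' Presentation rounding for benchmark rates (two decimals, halves up),
#' matching how such tables are conventionally printed.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Rounded numeric vector.
#' @export
roundHalfUp <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Format a benchmark table for reporting
#'
#' Rounds the `fnr` and `fdr` columns of an [evaluateMethods()] result to
#' two decimal places (half-up).
#'
#' @param bench output of [evaluateMethods()].
#' @param digits decimal places.
#' @return The table with rounded rate columns.
#' @export
formatBenchmarkTable <- function(bench, digits = 2) {
  bench$fnr <- roundHalfUp(bench$fnr, digits)
  bench$fdr <- roundHalfUp(bench$fdr, digits)
  bench
}
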