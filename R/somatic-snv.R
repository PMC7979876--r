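#' Initial quality filter for small-variant calls
#'
#' Retains calls with `QUAL > 1 & NUMALT < 2 & SAF > 1 & SAR > 1` (all
#' comparisons strict). This removes very low quality calls, multi-allelic
#' sites and calls whose alternate allele is seen on essentially one strand
#' only, before germline subtraction.
#'
#' @param calls a [SmallVariantCalls-class] object.
#' @param minQual,maxNumalt,minSaf,minSar thresholds; defaults are the
#'   pipeline's standard settings.
#' @return The filtered [SmallVariantCalls-class] object.
#' @export
initialFilter <- function(calls, minQual = 1, maxNumalt = 2, minSaf = 1,
                          minSar = 1) {
  df <- callTable(calls)
  keep <- df$qual > minQual & df$numalt < maxNumalt &
    df$saf > minSaf & df$sar > minSar
  SmallVariantCalls(df[keep, , drop = FALSE])
}

.snvKey <- function(df) paste(df$chrom, df$pos, df$alt, sep = ":")

#' Subtract germline calls from a tumour call set
#'
#' A tumour call is removed when some germline call shares its CHROM, POS
#' and ALT fields. The REF field is deliberately not part of the matching
#' key.
#'
#' @param tumour,germline [SmallVariantCalls-class] objects.
#' @return The putative somatic calls (a [SmallVariantCalls-class]).
#' @export
subtractGermline <- function(tumour, germline) {
  tdf <- callTable(tumour)
  keep <- !(.snvKey(tdf) %in% .snvKey(callTable(germline)))
  SmallVariantCalls(tdf[keep, , drop = FALSE])
}

#' Strand-bias exclusion filter
#'
#' Removes calls whose alternate-allele fraction is more than four times
#' higher (or lower) on the forward strand than on the reverse strand.
#' Fractions are per strand: `saf / (saf + srf)` on the forward strand and
#' `sar / (sar + srr)` on the reverse. The comparison is strict, so a
#' fraction ratio of exactly four is retained. A strand with zero total
#' depth contributes a fraction of zero, so such a call is removable only
#' when the other strand's fraction is positive.
#'
#' @param calls a [SmallVariantCalls-class] object.
#' @param maxRatio maximum tolerated fraction ratio between strands.
#' @return The filtered [SmallVariantCalls-class] object.
#' @export
strandBiasFilter <- function(calls, maxRatio = 4) {
  df <- callTable(calls)
  fwdDepth <- df$saf + df$srf
  revDepth <- df$sar + df$srr
  fFwd <- ifelse(fwdDepth > 0, df$saf / fwdDepth, 0)
  fRev <- ifelse(revDepth > 0, df$sar / revDepth, 0)
  biased <- fFwd > maxRatio * fRev | fRev > maxRatio * fFwd
  SmallVariantCalls(df[!biased, , drop = FALSE])
}

#' Final count/quality filter for somatic calls
#'
#' Retains calls satisfying `AO > 10 & RO > 10 & QA > 100 & QR > 100 &
#' AO < 100 & RO < 100 & SAP < 30 & MQM > 55`, all strict. The depth upper
#' bounds remove repeat-driven pile-ups; the lower bounds, quality sums and
#' mapping-quality threshold remove weakly supported calls; the SAP cap
#' removes residual strand imbalance.
#'
#' @param calls a [SmallVariantCalls-class] object.
#' @param minAo,minRo,minQa,minQr,maxAo,maxRo,maxSap,minMqm thresholds;
#'   defaults are the pipeline's standard settings.
#' @return The filtered [SmallVariantCalls-class] object.
#' @export
finalFilter <- function(calls, minAo = 10, minRo = 10, minQa = 100,
                        minQr = 100, maxAo = 100, maxRo = 100, maxSap = 30,
                        minMqm = 55) {
  df <- callTable(calls)
  keep <- df$ao > minAo & df$ro > minRo & df$qa > minQa & df$qr > minQr &
    df$ao < maxAo & df$ro < maxRo & df$sap < maxSap & df$mqm > minMqm
  SmallVariantCalls(df[keep, , drop = FALSE])
}

#' Overlap between two SNV call sets
#'
#' Counts calls shared between, and private to, two call sets, matching on
#' (CHROM, POS, ALT). Counts are over unique keys, so
#' `shared + only_a == |a|` and `shared + only_b == |b|`.
#'
#' @param a,b [SmallVariantCalls-class] objects.
#' @return A list with elements `shared`, `only_a`, `only_b`.
#' @export
compareCallsets <- function(a, b) {
  ka <- unique(.snvKey(callTable(a)))
  kb <- unique(.snvKey(callTable(b)))
  shared <- sum(ka %in% kb)
  list(shared = shared, only_a = length(ka) - shared,
       only_b = length(kb) - shared)
}

.keepSnvs <- function(calls) {
  df <- callTable(calls)
  nuc <- c("A", "C", "G", "T")
  keep <- df$ref %in% nuc & df$alt %in% nuc
  list(calls = SmallVariantCalls(df[keep, , drop = FALSE]),
       dropped = sum(!keep))
}

#' Run the subtraction-based somatic SNV pipeline
#'
#' Applies, in order: restriction to SNV records (indels/MNPs are dropped
#' with a logged count), the initial quality filter to both tumour and
#' germline call sets, germline subtraction on (CHROM, POS, ALT), the
#' strand-bias exclusion, the final count/quality filter, and optionally a
#' second germline subtraction against a cross-platform germline call set.
#'
#' @param tumour,germline [SmallVariantCalls-class] objects or paths to VCF
#'   files readable by [readSmallVariantVcf()].
#' @param secondGermline optional second germline call set (object or path)
#'   subtracted from the filtered somatic calls.
#' @param ... threshold overrides passed to [initialFilter()] and
#'   [finalFilter()] (matched by argument name).
#' @return A list with `somatic` (a [SmallVariantCalls-class]) and `report`,
#'   a `data.frame` of per-stage call counts (non-increasing through the
#'   pipeline).
#' @export
runSnvPipeline <- function(tumour, germline, secondGermline = NULL, ...) {
  asCalls <- function(x) {
    if (is.character(x)) readSmallVariantVcf(x) else x
  }
  tumour <- asCalls(tumour)
  germline <- asCalls(germline)
  dots <- list(...)
  argsFor <- function(fun) dots[intersect(names(dots), names(formals(fun)))]

  stages <- character(0); counts <- integer(0)
  note <- function(stage, x) {
    stages <<- c(stages, stage); counts <<- c(counts, length(x))
    x
  }
  note("input_tumour", tumour)
  snv <- .keepSnvs(tumour)
  if (snv$dropped)
    message(snv$dropped, " non-SNV record(s) dropped from the tumour set")
  x <- note("snv_only", snv$calls)
  x <- note("initial_filter",
            do.call(initialFilter, c(list(x), argsFor(initialFilter))))
  g <- do.call(initialFilter,
               c(list(.keepSnvs(germline)$calls), argsFor(initialFilter)))
  x <- note("germline_subtracted", subtractGermline(x, g))
  x <- note("strand_bias_filter", strandBiasFilter(x))
  x <- note("final_filter",
            do.call(finalFilter, c(list(x), argsFor(finalFilter))))
  if (!is.null(secondGermline)) {
    g2 <- asCalls(secondGermline)
    x <- note("second_subtraction", subtractGermline(x, g2))
  }
  list(somatic = x,
       report = data.frame(stage = stages, n = counts,
                           stringsAsFactors = FALSE))
}
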