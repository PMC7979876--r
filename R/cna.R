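#' Normalised log2 tumour/normal ratio with coverage masking
#'
#' Fills the `log2r` column of a [WindowCounts-class] object:
#' `R(w) = log2(T(w) / N(w)) - offset` for windows whose normal count
#' exceeds `mean(N) - 2 * sd(N)` (strictly); other windows are masked to
#' `NA`. The offset absorbs the difference in total sequencing yield
#' between the two samples; `"auto"` sets it to
#' `log2(sum(T) / sum(N))`. A window with a zero tumour count that passes
#' the mask is also set to `NA` (log of zero), with a logged count.
#'
#' @param counts a [WindowCounts-class] object.
#' @param offset a numeric offset in log2 units, or `"auto"`.
#' @param maskSd number of SDs below the mean normal count at which windows
#'   are masked.
#' @return The [WindowCounts-class] object with `log2r` filled.
#' @export
computeLog2R <- function(counts, offset = "auto", maskSd = 2) {
  df <- windowTable(counts)
  if (!nrow(df)) return(counts)
  if (identical(offset, "auto")) {
    if (normalTotal(counts) <= 0)
      stop("cannot compute automatic offset: zero total normal count",
           call. = FALSE)
    offset <- log2(tumourTotal(counts) / normalTotal(counts))
  }
  nsd <- nSd(counts)
  # degenerate case: with no count variability there are no low-coverage
  # windows to mask (a strict > threshold would otherwise mask everything)
  usable <- if (is.na(nsd) || nsd == 0) rep(TRUE, nrow(df)) else
    df$n_count > nMean(counts) - maskSd * nsd
  r <- rep(NA_real_, nrow(df))
  zeroT <- usable & df$t_count == 0
  if (any(zeroT))
    message(sum(zeroT), " unmasked window(s) with zero tumour count set to NA")
  ok <- usable & df$t_count > 0
  r[ok] <- log2(df$t_count[ok] / df$n_count[ok]) - offset
  df$log2r <- r
  out <- WindowCounts(df)
  out@tTotal <- tumourTotal(counts)
  out@nTotal <- normalTotal(counts)
  out
}

#' Theoretical segment mean for an integer tumour ploidy
#'
#' Expected log2 tumour/normal ratio of a segment with tumour copy number
#' `p` in a mixture of tumour cells (fraction `purity`) and normal cells:
#' `log2((purity * p + 2 * (1 - purity)) / 2)` for autosomes (germline
#' ploidy 2) and `log2(purity * p + (1 - purity))` for sex chromosomes
#' (germline ploidy 1). Equal tumour and germline ploidy gives 0 for any
#' purity; the mean is strictly increasing in `p` when `purity > 0`.
#'
#' @param p integer tumour ploidy (vectorised).
#' @param purity tumour-cell fraction in `[0, 1]`.
#' @param germlinePloidy 1 or 2.
#' @return Expected segment mean(s); `-Inf` when the mixture has zero copies
#'   (pure tumour at ploidy 0).
#' @export
theoreticalMean <- function(p, purity, germlinePloidy = 2) {
  stopifnot(purity >= 0, purity <= 1, germlinePloidy %in% c(1, 2))
  g <- germlinePloidy
  log2((purity * p + g * (1 - purity)) / g)
}

#' Recentre segment means on the ploidy-2 baseline
#'
#' When the tumour genome's average ploidy exceeds 2, the yield-normalised
#' log ratios of copy-neutral segments sit below/above zero. The baseline is
#' estimated as the window-weighted mean of the means of long neutral
#' segments (more than `minWindows` windows and `|seg_mean| < zeroBand`)
#' and subtracted from every segment mean.
#'
#' The ploidy-2 band is located robustly: since most of the genome is
#' copy-neutral, the window-weighted median of the long segments' means
#' sits on the neutral level even when the yield offset has shifted it away
#' from zero, and segments within `zeroBand` of that level are taken as
#' ploidy 2. Sex chromosomes are excluded: in a germline-haploid setting
#' they cannot represent ploidy 2.
#'
#' @param segments a [CNSegments-class] object.
#' @param minWindows minimum windows for a segment to qualify (strict).
#' @param zeroBand half-width of the band around zero regarded as ploidy 2.
#' @param excludeChroms chromosomes never used for the baseline.
#' @return A list with `segments` (shifted) and `baseline` (the subtracted
#'   offset).
#' @export
recentreSegments <- function(segments, minWindows = 500, zeroBand = 0.25,
                             excludeChroms = c("X", "Y", "chrX", "chrY")) {
  df <- segTable(segments)
  long <- df$n_windows > minWindows & !df$chrom %in% excludeChroms
  if (!any(long))
    stop("no segment qualifies for recentring (need > ", minWindows,
         " windows); supply a manual baseline offset", call. = FALSE)
  centre <- .weightedMedian(df$seg_mean[long], df$n_windows[long])
  qual <- long & abs(df$seg_mean - centre) < zeroBand
  if (!any(qual))
    stop("no segment qualifies for recentring (need > ", minWindows,
         " windows and a mean within ", zeroBand, " of the dominant level",
         "); supply a manual baseline offset", call. = FALSE)
  baseline <- weighted.mean(df$seg_mean[qual], df$n_windows[qual])
  df$seg_mean <- df$seg_mean - baseline
  list(segments = CNSegments(df), baseline = baseline)
}

.weightedMedian <- function(x, w) {
  ord <- order(x)
  cw <- cumsum(w[ord])
  x[ord][which(cw >= sum(w) / 2)[1]]
}

# gap-based 1-D clustering of segment means; returns a list of index vectors
.clusterMeans <- function(means, gap) {
  ord <- order(means)
  breaks <- which(diff(means[ord]) > gap)
  bounds <- c(0L, breaks, length(means))
  lapply(seq_len(length(bounds) - 1L), function(k)
    ord[(bounds[k] + 1L):bounds[k + 1L]])
}

#' Estimate tumour purity from non-neutral segment clusters
#'
#' Clusters the recentred means of non-neutral autosomal segments
#' (`|seg_mean| >= zeroBand`) along the real line (adjacent means more than
#' `gapThreshold` apart start a new cluster), assigns provisional tumour
#' ploidies to the clusters — the most negative cluster is single-copy loss
#' (p = 1), positive clusters in ascending order are p = 3 then p = 4 —
#' and inverts the autosomal mixture formula per cluster:
#' `alpha = (2^(m + 1) - 2) / (p - 2)` where `m` is the window-weighted
#' cluster mean. The reported purity is the plain average of the
#' per-cluster estimates.
#'
#' @param segments a [CNSegments-class] object (after recentring).
#' @param zeroBand neutral band half-width; segments inside it are ignored.
#' @param gapThreshold minimum gap between clusters of segment means.
#' @param excludeChroms chromosomes excluded from purity estimation (sex
#'   chromosomes, whose germline ploidy differs).
#' @param baseline recentring offset to record in the model.
#' @return A [PurityModel-class] object.
#' @export
estimatePurity <- function(segments, zeroBand = 0.25, gapThreshold = 0.1,
                           excludeChroms = c("X", "Y", "chrX", "chrY"),
                           baseline = NA_real_) {
  df <- segTable(segments)
  df <- df[!df$chrom %in% excludeChroms, , drop = FALSE]
  df <- df[abs(df$seg_mean) >= zeroBand, , drop = FALSE]
  if (!nrow(df))
    stop("only neutral segments present: purity is unidentifiable from ",
         "ploidy-2 segments alone", call. = FALSE)
  clusters <- .clusterMeans(df$seg_mean, gapThreshold)
  cmeans <- vapply(clusters, function(idx)
    weighted.mean(df$seg_mean[idx], df$n_windows[idx]), numeric(1))
  neg <- which(cmeans < 0)
  pos <- which(cmeans > 0)
  if (length(neg) > 1L || length(pos) > 2L)
    warning("found ", length(neg), " negative and ", length(pos),
            " positive segment-mean clusters where at most 1 and 2 were ",
            "expected; using the most negative and the two lowest positive ",
            "clusters", call. = FALSE)
  assign <- integer(0)
  est <- numeric(0)
  if (length(neg)) {
    m <- cmeans[neg[which.min(cmeans[neg])]]
    est <- c(est, (2^(m + 1) - 2) / (1 - 2))
    assign <- c(assign, 1L)
  }
  if (length(pos)) {
    posOrd <- pos[order(cmeans[pos])]
    ps <- c(3L, 4L)
    for (k in seq_len(min(2L, length(posOrd)))) {
      m <- cmeans[posOrd[k]]
      est <- c(est, (2^(m + 1) - 2) / (ps[k] - 2))
      assign <- c(assign, ps[k])
    }
  }
  est <- pmin(pmax(est, 0), 1)
  new("PurityModel", purity = mean(est),
      clusterEstimates = setNames(est, as.character(assign)),
      baselineOffset = baseline)
}

#' Classify segments to integer tumour ploidies
#'
#' Assigns each segment the tumour ploidy `p` in `0..6` whose theoretical
#' segment mean (at the model's purity, with germline ploidy 1 on sex
#' chromosomes and 2 elsewhere) is nearest the observed segment mean.
#' Distance ties break toward the lower ploidy; a segment farther than
#' `maxDistance` from every theoretical mean is left unclassified (`NA`).
#'
#' @param segments a [CNSegments-class] object (after recentring).
#' @param model a [PurityModel-class] object (or a bare purity value).
#' @param maxDistance maximum |seg_mean - theoretical mean| for a call.
#' @param sexChroms chromosome names treated as germline ploidy 1.
#' @param ploidies candidate integer ploidies.
#' @return The [CNSegments-class] object with `ploidy_call` filled.
#' @export
classifySegments <- function(segments, model, maxDistance = 0.5,
                             sexChroms = c("X", "Y", "chrX", "chrY"),
                             ploidies = 0:6) {
  alpha <- if (is(model, "PurityModel")) purity(model) else model
  df <- segTable(segments)
  df$ploidy_call <- vapply(seq_len(nrow(df)), function(i) {
    g <- if (df$chrom[i] %in% sexChroms) 1 else 2
    means <- theoreticalMean(ploidies, alpha, g)
    d <- abs(df$seg_mean[i] - means)
    d[is.nan(d)] <- 0  # seg_mean and theoretical mean both -Inf
    k <- which.min(d)
    if (d[k] > maxDistance) NA_integer_ else as.integer(ploidies[k])
  }, integer(1))
  CNSegments(df)
}

#' Run the full windowed copy-number pipeline
#'
#' Chains [computeLog2R()], [segmentCBS()], [recentreSegments()],
#' [estimatePurity()] and [classifySegments()].
#'
#' @param counts a [WindowCounts-class] object.
#' @param params a [CbsParams-class] object.
#' @param offset log-ratio offset or `"auto"`.
#' @param minWindows,zeroBand recentring parameters (see
#'   [recentreSegments()]).
#' @param gapThreshold cluster gap for [estimatePurity()].
#' @param maxDistance classification cap (see [classifySegments()]).
#' @param sexChroms chromosomes with germline ploidy 1.
#' @return A list with `counts` (log2r filled), `segments` (recentred and
#'   classified) and `model` (a [PurityModel-class]).
#' @export
runCnaPipeline <- function(counts, params = CbsParams(), offset = "auto",
                           minWindows = 500, zeroBand = 0.25,
                           gapThreshold = 0.1, maxDistance = 0.5,
                           sexChroms = c("X", "Y", "chrX", "chrY")) {
  counts <- computeLog2R(counts, offset = offset)
  segs <- segmentCBS(counts, params)
  rec <- recentreSegments(segs, minWindows = minWindows, zeroBand = zeroBand)
  model <- estimatePurity(rec$segments, zeroBand = zeroBand,
                          gapThreshold = gapThreshold,
                          excludeChroms = sexChroms,
                          baseline = rec$baseline)
  segs <- classifySegments(rec$segments, model, maxDistance = maxDistance,
                           sexChroms = sexChroms)
  list(counts = counts, segments = segs, model = model)
}
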