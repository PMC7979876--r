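# run `code` with a private RNG stream seeded by `seed`, restoring the
# caller's RNG state afterwards
.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Best circular two-segment split of a sequence
#'
#' Scans all circular splits of `x` into an arc `x[(i+1):j]` and its
#' complement, subject to both parts containing at least `minWidth` points,
#' and returns the split maximising the standardised mean-difference
#' statistic `|mean(arc) - mean(rest)| / sqrt(1/k + 1/(n-k))`.
#'
#' @param x numeric vector (no missing values).
#' @param minWidth minimum points per part.
#' @return A list with `stat`, and the arc boundaries `i`, `j` (the arc is
#'   `x[(i+1):j]`, `0 <= i < j <= length(x)`), or `NA` entries when no valid
#'   split exists.
#' @export
cbsBestSplit <- function(x, minWidth = 2L) {
  stopifnot(is.numeric(x), !anyNA(x))
  .cbs_max_stat(as.numeric(x), as.integer(minWidth))
}

.segmentVector <- function(x, params) {
  n <- length(x)
  alpha <- params@alpha
  w <- params@minWidth
  nperm <- params@nPermutations

  recurse <- function(lo, hi) {
    n0 <- hi - lo + 1L
    if (n0 < 2L * w) return(integer(0))
    seg <- x[lo:hi]
    if (max(seg) - min(seg) < .Machine$double.eps * 100) return(integer(0))
    perms <- matrix(0L, nrow = nperm, ncol = n0)
    for (p in seq_len(nperm)) perms[p, ] <- sample.int(n0)
    res <- .cbs_scan(seg, w, perms, alpha)
    if (!isTRUE(res$significant)) return(integer(0))
    i <- res$i; j <- res$j
    cps <- c(if (i > 0L) lo + i - 1L, if (j < n0) lo + j - 1L)
    bounds <- sort(unique(c(lo - 1L, cps, hi)))
    out <- cps
    for (s in seq_len(length(bounds) - 1L))
      out <- c(out, recurse(bounds[s] + 1L, bounds[s + 1L]))
    sort(unique(out))
  }

  cps <- .withSeed(params@seed, recurse(1L, n))

  # sd-undo: remove change points whose adjacent segment means differ by
  # less than undoSD point-level standard deviations
  sdest <- mad(diff(x)) / sqrt(2)
  if (sdest == 0) sdest <- sd(diff(x)) / sqrt(2)
  if (is.na(sdest)) sdest <- 0
  if (sdest > 0) {
    while (length(cps)) {
      bounds <- c(0L, cps, n)
      means <- vapply(seq_len(length(bounds) - 1L), function(s)
        mean(x[(bounds[s] + 1L):bounds[s + 1L]]), numeric(1))
      gaps <- abs(diff(means)) / sdest
      k <- which.min(gaps)
      if (gaps[k] < params@undoSD) cps <- cps[-k] else break
    }
  }
  cps
}

#' Circular binary segmentation
#'
#' Recursive change-point detection: each chromosome's sequence of log2
#' ratios is treated as a circle and repeatedly split at the arc maximising
#' the standardised mean-difference statistic, a split being accepted when
#' its permutation p-value is at most `alpha`. Accepted change points whose
#' adjacent segment means differ by less than `undoSD` point-level standard
#' deviations (estimated robustly from lag-1 differences) are subsequently
#' undone. Missing (`NA`) values are excluded; segmentation is deterministic
#' given the seed in `params`.
#'
#' @param x a [WindowCounts-class] object with `log2r` computed, or a plain
#'   numeric vector (one chromosome, `NA`s allowed).
#' @param params a [CbsParams-class] object.
#' @param ... unused.
#' @return A [CNSegments-class] object. Window indices refer to rows of the
#'   input object (or positions in the vector); `n_windows` counts the
#'   non-missing windows in the segment. A chromosome with no usable
#'   windows yields no segments (with a message).
#' @export
setGeneric("segmentCBS", function(x, params = CbsParams(), ...)
  standardGeneric("segmentCBS"))

#' @rdname segmentCBS
#' @export
setMethod("segmentCBS", "numeric", function(x, params = CbsParams(), ...) {
  .segmentChrom(x, seq_along(x), "1", params)
})

#' @rdname segmentCBS
#' @export
setMethod("segmentCBS", "WindowCounts", function(x, params = CbsParams(), ...) {
  df <- windowTable(x)
  segs <- list()
  for (chr in unique(df$chrom)) {
    idx <- which(df$chrom == chr)
    res <- .segmentChrom(df$log2r[idx], idx, chr, params)
    if (length(res)) segs[[chr]] <- segTable(res)
  }
  if (!length(segs)) return(CNSegments())
  CNSegments(do.call(rbind, segs))
})

.segmentChrom <- function(values, globalIdx, chrom, params) {
  ok <- which(!is.na(values))
  if (!length(ok)) {
    message("chromosome ", chrom, ": no usable windows, skipped")
    return(CNSegments())
  }
  v <- values[ok]
  gi <- globalIdx[ok]
  cps <- if (length(v) >= 2L * params@minWidth)
    .segmentVector(v, params) else integer(0)
  bounds <- c(0L, cps, length(v))
  rows <- lapply(seq_len(length(bounds) - 1L), function(s) {
    member <- (bounds[s] + 1L):bounds[s + 1L]
    data.frame(chrom = chrom, first_window = gi[member[1]],
               last_window = gi[member[length(member)]],
               n_windows = length(member), seg_mean = mean(v[member]),
               ploidy_call = NA_integer_, stringsAsFactors = FALSE)
  })
  CNSegments(do.call(rbind, rows))
}
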