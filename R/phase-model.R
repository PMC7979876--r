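.scenarioArgs <- function(scenario, x) {
  if (is(scenario, "PhasingScenario")) {
    p <- scenario@purityPct
    if (is.null(x)) x <- scenario@deletionCellPct
  } else {
    p <- scenario
    if (is.null(x)) stop("supply the deletion cell fraction x", call. = FALSE)
  }
  if (any(x < 0) || any(x > p))
    stop("deletion cell fraction must lie in [0, purity]", call. = FALSE)
  list(p = p, x = x)
}

#' Expected somatic-SNV VAF when the SNV is in cis with the deletion
#'
#' Consider a sample of purity `p` percent tumour cells in which `x` percent
#' of all cells carry a heterozygous somatic deletion overlapping the SNV
#' locus. If the SNV lies on the deleted haplotype it is present only in
#' the tumour cells that have not (yet) acquired the deletion, so the read
#' fraction is at most `(p - x) / (200 - x) * 100` percent: the denominator
#' counts two allele copies in each undeleted cell and one in each deleted
#' cell. The bound is strictly decreasing in `x` and maximal at `x = 0`
#' (`p / 2` percent).
#'
#' @param scenario a [PhasingScenario-class] object, or the purity in
#'   percent.
#' @param x deletion cell fraction(s) in percent (vectorised); taken from
#'   the scenario when omitted.
#' @return Expected maximum VAF in percent.
#' @export
expectedVafCis <- function(scenario, x = NULL) {
  a <- .scenarioArgs(scenario, x)
  (a$p - a$x) / (200 - a$x) * 100
}

#' Expected somatic-SNV VAF when the SNV is in trans with the deletion
#'
#' As [expectedVafCis()], but with the SNV on the non-deleted haplotype, so
#' all tumour cells carry it: the read fraction is at most
#' `p / (200 - x) * 100` percent, strictly increasing in `x` from `p / 2`
#' (at `x = 0`) to `p * 100 / (200 - p)` (at `x = p`).
#'
#' @inheritParams expectedVafCis
#' @return Expected maximum VAF in percent.
#' @export
expectedVafTrans <- function(scenario, x = NULL) {
  a <- .scenarioArgs(scenario, x)
  a$p / (200 - a$x) * 100
}

#' Convert a deletion allele fraction to a cell fraction
#'
#' Under the same mixture model, a deletion carried by `x` percent of cells
#' appears at allele fraction `x / (200 - x) * 100` percent. Inverting:
#' `x = 200 * af / (100 + af)`.
#'
#' @param afPct deletion allele fraction in percent.
#' @return Deletion cell fraction in percent.
#' @export
deletionAfToCellFraction <- function(afPct) 200 * afPct / (100 + afPct)

#' Classify the cis/trans configuration from an observed VAF
#'
#' An observed somatic-SNV VAF strictly above the cis-configuration maximum
#' (`purity / 2` percent, attained at deletion cell fraction 0) can only
#' arise in trans. An observed VAF below both the cis bound at the
#' scenario's deletion cell fraction and the trans minimum supports cis.
#' Anything else — including the boundary itself — is inconclusive.
#'
#' @param scenario a [PhasingScenario-class] object with `observedVafPct`
#'   set.
#' @return A list with `configuration` (`"supports_trans"`,
#'   `"supports_cis"` or `"inconclusive"`) and `margin`, the distance (in
#'   VAF percentage points) of the observation from the cis maximum.
#' @export
classifyConfiguration <- function(scenario) {
  stopifnot(is(scenario, "PhasingScenario"))
  obs <- scenario@observedVafPct
  if (is.na(obs)) stop("scenario has no observed VAF", call. = FALSE)
  p <- scenario@purityPct
  cisMax <- p / 2
  cisAtX <- expectedVafCis(scenario)
  transMin <- p / 2
  configuration <- if (obs > cisMax) "supports_trans"
    else if (obs < cisAtX && obs < transMin) "supports_cis"
    else "inconclusive"
  list(configuration = configuration, margin = obs - cisMax)
}

#' Haplotag reads by majority vote over phased heterozygous sites
#'
#' Each read votes once per phased heterozygous site it covers, for the
#' haplotype whose allele it shows there (an allele matching neither REF
#' nor ALT is non-informative at that site). The read is assigned to the
#' haplotype with the strict majority of votes; ties and reads with no
#' informative site stay unassigned. Per-site REF/ALT allele counts are
#' reported within each haplotype group and over all reads.
#'
#' @param reads `data.frame` in long format with columns `read_id`, `pos`,
#'   `allele` (one row per covered site per read).
#' @param sites `data.frame` of phased heterozygous sites with columns
#'   `pos`, `ref`, `alt`, `haplotype_of_alt` (1 or 2).
#' @return A list with `reads` (`read_id`, `votes_hap1`, `votes_hap2`,
#'   `haplotype` with `NA` when unassigned) and `siteCounts` (per site:
#'   REF/ALT counts within haplotype 1, haplotype 2, and all reads).
#' @export
haplotagReads <- function(reads, sites) {
  stopifnot(all(c("read_id", "pos", "allele") %in% names(reads)),
            all(c("pos", "ref", "alt", "haplotype_of_alt") %in% names(sites)),
            all(sites$haplotype_of_alt %in% c(1L, 2L)))
  m <- match(reads$pos, sites$pos)
  covered <- !is.na(m)
  rd <- reads[covered, , drop = FALSE]
  st <- sites[m[covered], , drop = FALSE]
  hap1Allele <- ifelse(st$haplotype_of_alt == 1L, st$alt, st$ref)
  hap2Allele <- ifelse(st$haplotype_of_alt == 2L, st$alt, st$ref)
  vote <- ifelse(rd$allele == hap1Allele, 1L,
                 ifelse(rd$allele == hap2Allele, 2L, NA_integer_))
  ids <- unique(reads$read_id)
  v1 <- tapply(vote == 1L, factor(rd$read_id, levels = ids),
               function(z) sum(z, na.rm = TRUE))
  v2 <- tapply(vote == 2L, factor(rd$read_id, levels = ids),
               function(z) sum(z, na.rm = TRUE))
  v1[is.na(v1)] <- 0; v2[is.na(v2)] <- 0
  hap <- ifelse(v1 > v2, 1L, ifelse(v2 > v1, 2L, NA_integer_))
  readTab <- data.frame(read_id = ids, votes_hap1 = as.integer(v1),
                        votes_hap2 = as.integer(v2), haplotype = hap,
                        row.names = NULL, stringsAsFactors = FALSE)
  readHap <- readTab$haplotype[match(rd$read_id, readTab$read_id)]
  countFor <- function(sel) {
    vapply(seq_len(nrow(sites)), function(i) {
      here <- sel & st$pos == sites$pos[i]
      c(ref = sum(here & rd$allele == sites$ref[i]),
        alt = sum(here & rd$allele == sites$alt[i]))
    }, integer(2))
  }
  all_ <- countFor(rep(TRUE, nrow(rd)))
  h1 <- countFor(!is.na(readHap) & readHap == 1L)
  h2 <- countFor(!is.na(readHap) & readHap == 2L)
  siteCounts <- data.frame(
    pos = sites$pos, ref = sites$ref, alt = sites$alt,
    haplotype_of_alt = sites$haplotype_of_alt,
    hap1_ref = h1["ref", ], hap1_alt = h1["alt", ],
    hap2_ref = h2["ref", ], hap2_alt = h2["alt", ],
    all_ref = all_["ref", ], all_alt = all_["alt", ],
    stringsAsFactors = FALSE)
  list(reads = readTab, siteCounts = siteCounts)
}
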