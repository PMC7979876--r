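#' Simulation configuration
#'
#' Builds the configuration consumed by the `simulate*` generators. The
#' defaults describe a diploid tumour/normal pair at purity 0.63 whose
#' tumour genome carries whole-chromosome copy-number changes to 4, 3, 3
#' and 1 on autosomes plus loss of a germline-haploid sex chromosome,
#' chromosome-17-style small-variant call sets, and an SV inventory whose
#' per-type counts match a large-SV survey of a single lymphoma genome
#' (49 deletions, 6 duplications, 10 inversions, 4 translocations).
#'
#' @param seed default RNG seed for the generators.
#' @param purity simulated tumour purity (cell fraction).
#' @param snv,sv,cna,phase named lists overriding individual defaults of
#'   the corresponding generator (see Details in the package vignette).
#' @return A list of class `SimConfig`.
#' @export
simConfig <- function(seed = 1L, purity = 0.63, snv = list(), sv = list(),
                      cna = list(), phase = list()) {
  stopifnot(purity >= 0, purity <= 1)
  base <- list(
    seed = as.integer(seed),
    purity = purity,
    snv = list(
      chrom = "17", chromLength = 78e6,
      nGermline = 1000L, nSomatic = 20L, nArtifacts = 5L,
      nMultiallelic = 3L,
      somaticCellFraction = purity,   # clonal somatic SNVs by default
      depth = 60, depthDispersion = 0.05,
      meanBaseQual = 13, mqmMean = 60, mqmSd = 1.5,
      clean = TRUE),
    sv = list(
      chroms = paste0("c", 1:5), chromLength = 2e8,
      nGermline = 60L,
      germlineLenRange = c(2e4, 5e5),
      somaticCounts = c(DEL = 49L, DUP = 6L, INV = 10L, TRA = 4L),
      somaticLenRange = c(2e4, 2e6),
      methodJitter = 200,
      nDecoy = 3L, nImpreciseHighAf = 3L, nImpreciseLowAf = 3L,
      nShort = 5L,
      methods = list(
        illumina = list(miss = c(DEL = 0.14, DUP = 0.17, INV = 0, TRA = 0),
                        nFalse = 5L),
        ont_minimap2 = list(miss = c(DEL = 0.06, DUP = 0, INV = 0.1,
                                     TRA = 0.25), nFalse = 8L),
        ont_ngmlr = list(miss = c(DEL = 0.22, DUP = 0, INV = 0.2,
                                  TRA = 0.25), nFalse = 4L))),
    cna = list(
      # whole-genome layout, window counts mirroring real chromosome
      # lengths at 100 kb; the tumour gains chromosome 3 to ploidy 4 and
      # 7/18 to ploidy 3, loses one copy of 17 and all of the
      # germline-haploid Y
      layout = data.frame(
        chrom = c("c1", "c2", "c3", "c4", "c5", "c6", "c7", "c8", "c9",
                  "c10", "c11", "c12", "c13", "c14", "c15", "c16", "c17",
                  "c18", "c19", "c20", "c21", "c22", "X", "Y"),
        nWindows = c(2490L, 2430L, 1980L, 1910L, 1810L, 1710L, 1590L,
                     1460L, 1410L, 1360L, 1350L, 1340L, 1150L, 1070L,
                     1030L, 900L, 810L, 780L, 590L, 630L, 480L, 510L,
                     1550L, 590L),
        ploidy = c(2L, 2L, 4L, 2L, 2L, 2L, 3L, 2L, 2L, 2L, 2L, 2L, 2L,
                   2L, 2L, 2L, 1L, 3L, 2L, 2L, 2L, 2L, 1L, 0L),
        germlinePloidy = c(rep(2L, 22), 1L, 1L),
        stringsAsFactors = FALSE),
      windowSize = 1e5L, meanCount = 60, dispersion = 0.02,
      maskFraction = 0.01, noise = "nb"),
    phase = list(
      nSites = 14L, nReads = 200L, sitesPerRead = 5L, errorRate = 0.1,
      siteSpacing = 1000L, startPos = 7570000L))
  # overrides replace entries wholesale (a supplied layout or method list
  # must not be merged element-wise with the default one)
  override <- function(section, vals) {
    unknown <- setdiff(names(vals), names(section))
    if (length(unknown))
      stop("unknown simulation parameter(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    for (nm in names(vals)) section[[nm]] <- vals[[nm]]
    section
  }
  base$snv <- override(base$snv, snv)
  base$sv <- override(base$sv, sv)
  base$cna <- override(base$cna, cna)
  base$phase <- override(base$phase, phase)
  structure(base, class = "SimConfig")
}

.NUC <- c("A", "C", "G", "T")

.rdepth <- function(n, mean, dispersion) {
  if (dispersion > 0) rnbinom(n, mu = mean, size = 1 / dispersion)
  else rpois(n, mean)
}

# truncated draws: resample until the value lands in [lo, hi]
.rtrunc <- function(draw, lo, hi, maxIter = 100L) {
  v <- draw()
  it <- 0L
  while ((v < lo || v > hi) && it < maxIter) {
    v <- draw(); it <- it + 1L
  }
  min(max(v, lo), hi)
}

# phred-scaled two-tail binomial probability of the observed strand split
.strandBalancePhred <- function(saf, ao) {
  if (ao == 0) return(0)
  p <- 2 * min(pbinom(saf, ao, 0.5), 1 - pbinom(saf - 1L, ao, 0.5))
  p <- min(p, 1)
  -10 * log10(max(p, 1e-300))
}

# one annotated record at a given VAF; clean = TRUE truncates the draws into
# the pipeline's filter-passing ranges
.drawRecord <- function(vaf, cfg, clean, strandArtifact = FALSE) {
  if (clean) {
    depth <- .rtrunc(function() .rdepth(1, cfg$depth, cfg$depthDispersion),
                     40, 120)
    ao <- .rtrunc(function() rbinom(1, depth, vaf),
                  max(12, depth - 99), min(99, depth - 12))
  } else {
    depth <- max(.rdepth(1, cfg$depth, cfg$depthDispersion), 1)
    ao <- rbinom(1, depth, vaf)
  }
  ro <- depth - ao
  if (strandArtifact) {
    saf <- ao; sar <- 0L
  } else if (clean) {
    saf <- .rtrunc(function() rbinom(1, ao, 0.5), 2, ao - 2)
    it <- 0L
    while (.strandBalancePhred(saf, ao) >= 30 && it < 50L) {
      saf <- .rtrunc(function() rbinom(1, ao, 0.5), 2, ao - 2)
      it <- it + 1L
    }
    sar <- ao - saf
  } else {
    saf <- rbinom(1, ao, 0.5); sar <- ao - saf
  }
  srf <- rbinom(1, ro, 0.5)
  qa <- round(ao * (cfg$meanBaseQual + rnorm(1, 0, 0.5)), 1)
  qr <- round(ro * (cfg$meanBaseQual + rnorm(1, 0, 0.5)), 1)
  mqm <- if (clean)
    round(.rtrunc(function() rnorm(1, cfg$mqmMean, cfg$mqmSd), 56, 70), 1)
  else round(rnorm(1, cfg$mqmMean, cfg$mqmSd), 1)
  data.frame(
    qual = round(10 + qa / 10, 1), ao = ao, ro = ro,
    saf = saf, sar = ao - saf, srf = srf, srr = ro - srf,
    qa = max(qa, 0), qr = max(qr, 0), mqm = mqm,
    sap = round(.strandBalancePhred(saf, ao), 1),
    ab = round(if (depth > 0) ro / depth else 0, 4))
}

#' Simulate annotated tumour/germline small-variant call sets
#'
#' Plants germline heterozygous SNVs (present in both samples, VAF drawn
#' as Binomial(depth, 1/2)), clonal/subclonal somatic SNVs (tumour only,
#' expected VAF = cell fraction / 2 under the diploid mixture model),
#' strand-artifact calls with all alternate observations on one strand, and
#' multi-allelic tumour-only sites. Observation counts, quality sums, mean
#' mapping quality and the phred-scaled strand-balance score follow the
#' configured noise model; with `clean = TRUE` (the default) the somatic and
#' germline annotations are truncated into the pipeline's filter-passing
#' ranges so that truth labels are exactly recoverable.
#'
#' @param config a [simConfig()] object.
#' @param seed RNG seed (defaults to the config's seed).
#' @return A list with `tumour` and `germline`
#'   ([SmallVariantCalls-class]) and `truth`, a `data.frame` with columns
#'   `chrom`, `pos`, `alt`, `label` (`germline`, `somatic` or `artifact`).
#' @export
simulateSmallVariants <- function(config = simConfig(), seed = config$seed) {
  cfg <- config$snv
  .withSeed(seed, {
    nTotal <- cfg$nGermline + cfg$nSomatic + cfg$nArtifacts +
      cfg$nMultiallelic
    pos <- sort(sample.int(cfg$chromLength, nTotal))
    cat_ <- sample(rep(c("germline", "somatic", "artifact", "multi"),
                       c(cfg$nGermline, cfg$nSomatic, cfg$nArtifacts,
                         cfg$nMultiallelic)))
    refs <- sample(.NUC, nTotal, replace = TRUE)
    alts <- vapply(refs, function(r) sample(setdiff(.NUC, r), 1),
                   character(1))
    somaticVaf <- cfg$somaticCellFraction / 2
    tumourRows <- list(); germlineRows <- list(); truthRows <- list()
    for (i in seq_len(nTotal)) {
      base <- data.frame(chrom = cfg$chrom, pos = pos[i], ref = refs[i],
                         alt = alts[i], numalt = 1L,
                         stringsAsFactors = FALSE)
      if (cat_[i] == "germline") {
        tumourRows[[length(tumourRows) + 1L]] <-
          cbind(base, .drawRecord(0.5, cfg, cfg$clean))
        germlineRows[[length(germlineRows) + 1L]] <-
          cbind(base, .drawRecord(0.5, cfg, cfg$clean))
        lab <- "germline"
      } else if (cat_[i] == "somatic") {
        tumourRows[[length(tumourRows) + 1L]] <-
          cbind(base, .drawRecord(somaticVaf, cfg, cfg$clean))
        lab <- "somatic"
      } else if (cat_[i] == "artifact") {
        tumourRows[[length(tumourRows) + 1L]] <-
          cbind(base, .drawRecord(somaticVaf, cfg, cfg$clean,
                                  strandArtifact = TRUE))
        lab <- "artifact"
      } else {
        # multi-allelic site: two alternate alleles, numalt = 2
        alt2 <- sample(setdiff(.NUC, c(refs[i], alts[i])), 1)
        for (a in c(alts[i], alt2)) {
          b <- base; b$alt <- a; b$numalt <- 2L
          tumourRows[[length(tumourRows) + 1L]] <-
            cbind(b, .drawRecord(somaticVaf / 2, cfg, FALSE))
        }
        lab <- "artifact"
      }
      truthRows[[length(truthRows) + 1L]] <-
        data.frame(chrom = cfg$chrom, pos = pos[i], alt = alts[i],
                   label = lab, stringsAsFactors = FALSE)
    }
    list(tumour = SmallVariantCalls(do.call(rbind, tumourRows)),
         germline = SmallVariantCalls(do.call(rbind, germlineRows)),
         truth = do.call(rbind, truthRows))
  })
}

.randomLen <- function(n, range) {
  round(10^runif(n, log10(range[1]), log10(range[2])))
}

.jitterBy <- function(pos, j) {
  pos + vapply(j, function(m) if (m >= 1) sample(-floor(m):floor(m), 1)
               else 0L, numeric(1))
}

#' Simulate germline and somatic structural-variant call sets
#'
#' Builds a germline SV inventory present in both samples (the tumour-side
#' re-calls carry breakpoint jitter of at most length/200, i.e. half the
#' subtraction tolerance), a tumour-only somatic inventory, tumour-set
#' noise calls exercising the downstream filters (decoy-contig
#' translocations, imprecise calls above and below the allele-fraction
#' cutoff, sub-threshold-length calls), and per-method somatic call sets in
#' which each true SV is missed with a configured per-type probability and
#' false calls are added in a coordinate range disjoint from the truth.
#'
#' @inheritParams simulateSmallVariants
#' @return A list with `tumour`, `germline` ([SvCallSet-class]), `methods`
#'   (named list of per-method [SvCallSet-class]) and `truth` (`data.frame`
#'   of the somatic inventory).
#' @export
simulateSvSets <- function(config = simConfig(), seed = config$seed) {
  cfg <- config$sv
  .withSeed(seed, {
    # germline inventory
    gl <- data.frame(
      svtype = sample(c("DEL", "DUP", "INV"), cfg$nGermline, replace = TRUE),
      chrom = sample(cfg$chroms, cfg$nGermline, replace = TRUE),
      svlen = .randomLen(cfg$nGermline, cfg$germlineLenRange),
      stringsAsFactors = FALSE)
    gl$start <- sample.int(cfg$chromLength %/% 2, cfg$nGermline)
    gl$end <- gl$start + gl$svlen
    gl$chr2 <- gl$chrom
    gl$af <- round(runif(cfg$nGermline, 0.3, 1), 3)
    gl$precise <- TRUE

    # tumour-side re-calls of the germline SVs, jittered within tolerance
    glT <- gl
    j <- gl$svlen / 200
    glT$start <- .jitterBy(gl$start, j)
    glT$end <- .jitterBy(gl$end, j)

    # somatic inventory (tumour only)
    counts <- cfg$somaticCounts
    som <- data.frame(
      svtype = rep(names(counts), counts), stringsAsFactors = FALSE)
    nSom <- nrow(som)
    som$chrom <- sample(cfg$chroms, nSom, replace = TRUE)
    som$svlen <- .randomLen(nSom, cfg$somaticLenRange)
    som$start <- sample.int(cfg$chromLength %/% 2, nSom)
    som$end <- som$start + som$svlen
    som$chr2 <- som$chrom
    isTra <- som$svtype == "TRA"
    som$chr2[isTra] <- vapply(som$chrom[isTra], function(c1)
      sample(setdiff(cfg$chroms, c1), 1), character(1))
    som$end[isTra] <- sample.int(cfg$chromLength %/% 2, sum(isTra))
    som$svlen[isTra] <- NA_real_
    som$af <- round(runif(nSom, 0.2, 0.6), 3)
    som$precise <- TRUE

    noise <- function(n, svtype, chr2 = NULL, precise = TRUE, af = NULL,
                      lenRange = cfg$somaticLenRange) {
      if (!n) return(NULL)
      d <- data.frame(svtype = rep(svtype, length.out = n),
                      chrom = sample(cfg$chroms, n, replace = TRUE),
                      svlen = .randomLen(n, lenRange),
                      stringsAsFactors = FALSE)
      d$start <- sample.int(cfg$chromLength %/% 2, n)
      d$end <- d$start + d$svlen
      d$chr2 <- if (is.null(chr2)) d$chrom else rep(chr2, n)
      if (!is.null(chr2)) { d$svlen <- NA_real_; d$end <- d$start + 1L }
      d$af <- if (is.null(af)) round(runif(n, 0.2, 0.6), 3) else
        rep(af, length.out = n)
      d$precise <- precise
      d
    }
    decoy <- noise(cfg$nDecoy, "TRA", chr2 = "hs37d5")
    impHi <- noise(cfg$nImpreciseHighAf, "DEL", precise = FALSE, af = 0.35)
    impLo <- noise(cfg$nImpreciseLowAf, "DUP", precise = FALSE, af = 0.05)
    short <- noise(cfg$nShort, "DEL", lenRange = c(500, 9000))

    tumour <- rbind(glT, som, decoy, impHi, impLo, short)

    # per-method call sets over the somatic truth
    methodSets <- lapply(names(cfg$methods), function(mname) {
      mc <- cfg$methods[[mname]]
      missP <- mc$miss[som$svtype]
      kept <- runif(nSom) >= missP
      d <- som[kept, , drop = FALSE]
      mj <- rep(cfg$methodJitter, nrow(d))
      d$start <- .jitterBy(d$start, mj)
      d$end <- .jitterBy(d$end, mj)
      fp <- if (mc$nFalse) {
        f <- data.frame(
          svtype = sample(c("DEL", "INV"), mc$nFalse, replace = TRUE),
          chrom = sample(cfg$chroms, mc$nFalse, replace = TRUE),
          svlen = .randomLen(mc$nFalse, cfg$somaticLenRange),
          stringsAsFactors = FALSE)
        # false calls live beyond the truth coordinate range
        f$start <- sample.int(cfg$chromLength %/% 2, mc$nFalse) +
          cfg$chromLength %/% 2
        f$end <- f$start + f$svlen
        f$chr2 <- f$chrom
        f$af <- round(runif(mc$nFalse, 0.2, 0.6), 3)
        f$precise <- TRUE
        f
      } else NULL
      d <- rbind(d, fp)
      d$source_method <- mname
      SvCallSet(d)
    })
    names(methodSets) <- names(cfg$methods)

    list(tumour = SvCallSet(tumour), germline = SvCallSet(gl),
         methods = methodSets,
         truth = som[, c("svtype", "chrom", "start", "chr2", "end",
                         "svlen")])
  })
}

#' Simulate tumour/normal window counts for a piecewise-constant genome
#'
#' Draws per-window read counts for a genome laid out as consecutive
#' constant-ploidy blocks. With diploid-equivalent mean count `m`, the
#' normal sample draws counts with mean `m * g / 2` (`g` = germline
#' ploidy) and the tumour sample with mean
#' `m * (alpha * p + g * (1 - alpha)) / 2` (`p` = tumour ploidy,
#' `alpha` = purity), so the expected log2 ratio equals the theoretical
#' segment mean. Counts are negative-binomial with the configured
#' overdispersion (`dispersion = 0` gives Poisson; `noise = "none"` gives
#' deterministic expected counts). A configured fraction of windows is
#' given near-zero normal counts to exercise the coverage mask.
#'
#' @inheritParams simulateSmallVariants
#' @return A list with `counts` (a [WindowCounts-class]) and `truth` (the
#'   layout table with per-block window index ranges).
#' @export
simulateWindowCounts <- function(config = simConfig(), seed = config$seed) {
  cfg <- config$cna
  alpha <- config$purity
  .withSeed(seed, {
    rows <- list(); truth <- cfg$layout
    truth$first_window <- NA_integer_; truth$last_window <- NA_integer_
    offsetByChrom <- list()
    idx <- 0L
    for (b in seq_len(nrow(cfg$layout))) {
      chr <- cfg$layout$chrom[b]
      nw <- cfg$layout$nWindows[b]
      g <- cfg$layout$germlinePloidy[b]
      p <- cfg$layout$ploidy[b]
      muN <- cfg$meanCount * g / 2
      muT <- cfg$meanCount * (alpha * p + g * (1 - alpha)) / 2
      nC <- switch(cfg$noise,
                   nb = .rdepth(nw, muN, cfg$dispersion),
                   poisson = rpois(nw, muN),
                   none = rep(round(muN), nw))
      tC <- switch(cfg$noise,
                   nb = .rdepth(nw, muT, cfg$dispersion),
                   poisson = rpois(nw, muT),
                   none = rep(round(muT), nw))
      if (cfg$maskFraction > 0 && cfg$noise != "none") {
        nMask <- rbinom(1, nw, cfg$maskFraction)
        if (nMask) {
          at <- sample.int(nw, nMask)
          nC[at] <- rpois(nMask, 0.2)
        }
      }
      prev <- offsetByChrom[[chr]]
      startW <- if (is.null(prev)) 0L else prev
      offsetByChrom[[chr]] <- startW + nw
      rows[[b]] <- data.frame(
        chrom = chr,
        start = (startW + seq_len(nw) - 1L) * cfg$windowSize,
        end = (startW + seq_len(nw)) * cfg$windowSize,
        t_count = tC, n_count = nC, stringsAsFactors = FALSE)
      truth$first_window[b] <- idx + 1L
      truth$last_window[b] <- idx + nw
      idx <- idx + nw
    }
    list(counts = WindowCounts(do.call(rbind, rows)), truth = truth)
  })
}

#' Simulate phased reads over heterozygous sites
#'
#' Lays out two haplotypes over a run of phased heterozygous sites and
#' draws reads covering contiguous site runs from one haplotype each, with
#' a per-site allele error that substitutes the opposite haplotype's
#' allele.
#'
#' @inheritParams simulateSmallVariants
#' @return A list with `sites` (phased het sites: `pos`, `ref`, `alt`,
#'   `haplotype_of_alt`), `reads` (long-format read alleles: `read_id`,
#'   `pos`, `allele`) and `truth` (`read_id`, `haplotype`).
#' @export
simulatePhasedReads <- function(config = simConfig(), seed = config$seed) {
  cfg <- config$phase
  .withSeed(seed, {
    refs <- sample(.NUC, cfg$nSites, replace = TRUE)
    alts <- vapply(refs, function(r) sample(setdiff(.NUC, r), 1),
                   character(1))
    sites <- data.frame(
      pos = cfg$startPos + (seq_len(cfg$nSites) - 1L) * cfg$siteSpacing,
      ref = refs, alt = alts,
      haplotype_of_alt = sample(1:2, cfg$nSites, replace = TRUE),
      stringsAsFactors = FALSE)
    hapAllele <- function(i, h)
      if (sites$haplotype_of_alt[i] == h) sites$alt[i] else sites$ref[i]
    reads <- list(); truth <- list()
    maxStart <- cfg$nSites - cfg$sitesPerRead + 1L
    for (r in seq_len(cfg$nReads)) {
      hap <- sample(1:2, 1)
      s0 <- sample.int(maxStart, 1)
      covered <- s0:(s0 + cfg$sitesPerRead - 1L)
      allele <- vapply(covered, function(i) {
        if (runif(1) < cfg$errorRate) hapAllele(i, 3L - hap)
        else hapAllele(i, hap)
      }, character(1))
      id <- sprintf("read%04d", r)
      reads[[r]] <- data.frame(read_id = id, pos = sites$pos[covered],
                               allele = allele, stringsAsFactors = FALSE)
      truth[[r]] <- data.frame(read_id = id, haplotype = hap,
                               stringsAsFactors = FALSE)
    }
    list(sites = sites, reads = do.call(rbind, reads),
         truth = do.call(rbind, truth))
  })
}
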