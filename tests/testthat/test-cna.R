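test_that("log2 ratio uses the configured offset and masks low coverage", {
  # single-window arithmetic with the yield offset log2(252/187)
  wc <- WindowCounts(data.frame(chrom = "1", start = 0L, end = 100000L,
                                t_count = 200, n_count = 100))
  out <- computeLog2R(wc, offset = log2(252 / 187))
  expect_equal(windowTable(out)$log2r, 1 - log2(252 / 187),
               tolerance = 1e-12)
  expect_equal(windowTable(out)$log2r, 0.56956, tolerance = 1e-4)

  # equal counts and equal totals give zero everywhere under "auto"
  df <- data.frame(chrom = "1", start = (0:9) * 1e5, end = (1:10) * 1e5,
                   t_count = c(40, 50, 60, 70, 80, 40, 50, 60, 70, 80),
                   n_count = c(40, 50, 60, 70, 80, 40, 50, 60, 70, 80))
  expect_equal(windowTable(computeLog2R(WindowCounts(df)))$log2r,
               rep(0, 10))
})

test_that("the coverage mask is strict at the threshold", {
  # with maskSd = 0 the threshold is mean(N); a window exactly at the mean
  # fails the strict > comparison
  df <- data.frame(chrom = "1", start = (0:2) * 1e5, end = (1:3) * 1e5,
                   t_count = 50, n_count = c(10, 20, 30))
  r <- windowTable(computeLog2R(WindowCounts(df), offset = 0, maskSd = 0))$log2r
  expect_true(is.na(r[1]))
  expect_true(is.na(r[2]))     # exactly mean(N) = 20: masked
  expect_false(is.na(r[3]))

  # a zero tumour count in an unmasked window becomes NA with a message
  df$t_count <- c(50, 50, 0)
  expect_message(
    r2 <- windowTable(computeLog2R(WindowCounts(df), offset = 0))$log2r,
    "zero tumour count")
  expect_true(is.na(r2[3]))
})

test_that("theoretical segment means follow the mixture model", {
  expect_equal(theoreticalMean(2, 0.3), 0)
  expect_equal(theoreticalMean(2, 0.9), 0)
  expect_equal(theoreticalMean(4, 1), 1)
  expect_equal(theoreticalMean(4, 0.63), log2(1.63))
  expect_equal(theoreticalMean(4, 0.63), 0.7049, tolerance = 1e-4)
  expect_equal(theoreticalMean(1, 1, germlinePloidy = 1), 0)
  expect_equal(theoreticalMean(0, 1), -Inf)
  # strictly increasing in p for positive purity, zero at the germline ploidy
  for (a in c(0.2, 0.5, 0.95)) {
    m <- theoreticalMean(0:6, a)
    expect_true(all(diff(m) > 0))
    expect_equal(m[3], 0)
    m1 <- theoreticalMean(0:6, a, germlinePloidy = 1)
    expect_true(all(diff(m1) > 0))
    expect_equal(m1[2], 0)
  }
})

test_that("recentring shifts to the weighted neutral baseline", {
  segs <- CNSegments(data.frame(
    chrom = c("1", "2", "3"), first_window = c(1L, 1000L, 2000L),
    last_window = c(999L, 1999L, 2600L),
    n_windows = c(600L, 600L, 550L),
    seg_mean = c(0.09, 0.10, 0.80)))
  rec <- recentreSegments(segs)
  expect_equal(rec$baseline, 0.095)
  expect_equal(segTable(rec$segments)$seg_mean, c(-0.005, 0.005, 0.705))
  # defining property: qualifying means average to zero afterwards
  st <- segTable(rec$segments)
  qual <- st$n_windows > 500 & abs(st$seg_mean) < 0.25
  expect_equal(weighted.mean(st$seg_mean[qual], st$n_windows[qual]), 0)

  # already-centred data is unchanged
  segs0 <- CNSegments(data.frame(chrom = "1", first_window = 1L,
                                 last_window = 600L, n_windows = 600L,
                                 seg_mean = 0))
  expect_equal(recentreSegments(segs0)$baseline, 0)

  # nothing long enough to anchor the baseline
  short <- CNSegments(data.frame(chrom = "1", first_window = 1L,
                                 last_window = 100L, n_windows = 100L,
                                 seg_mean = 0.01))
  expect_error(recentreSegments(short), "manual baseline")
})

test_that("purity estimation inverts noiseless cluster means exactly", {
  mkSegs <- function(alpha, ps, nw = 600L) {
    CNSegments(data.frame(
      chrom = as.character(seq_along(ps)),
      first_window = 1L, last_window = nw, n_windows = nw,
      seg_mean = theoreticalMean(ps, alpha)))
  }
  # single cluster at the triploid mean recovers the generating purity
  m <- estimatePurity(mkSegs(0.63, c(2, 3)))
  expect_equal(unname(clusterEstimates(m)["3"]), 0.63, tolerance = 1e-12)
  # a pure single-copy loss halves coverage: m = -1 gives purity 1
  m1 <- estimatePurity(CNSegments(data.frame(
    chrom = "1", first_window = 1L, last_window = 600L, n_windows = 600L,
    seg_mean = -1)))
  expect_equal(purity(m1), 1)
  # three clusters generated at one purity average back to it exactly
  m05 <- estimatePurity(mkSegs(0.5, c(1, 2, 3, 4)))
  expect_equal(purity(m05), 0.5, tolerance = 1e-12)
  expect_equal(sort(names(clusterEstimates(m05))), c("1", "3", "4"))

  # purity round trip across the working range; below ~0.35 purity the
  # aberrant means approach zero, so the noiseless check narrows the
  # neutral band accordingly
  for (a in seq(0.2, 0.95, by = 0.05))
    expect_equal(purity(estimatePurity(mkSegs(a, c(1, 2, 3, 4)),
                                       zeroBand = 0.05)), a,
                 tolerance = 1e-10)

  # a fully neutral genome is unidentifiable
  expect_error(estimatePurity(mkSegs(0.63, c(2, 2))), "unidentifiable")
})

test_that("segments classify to the nearest theoretical ploidy", {
  alpha <- 0.63
  segs <- CNSegments(data.frame(
    chrom = c("1", "1", "Y"), first_window = c(1L, 300L, 1L),
    last_window = c(299L, 600L, 200L), n_windows = c(299L, 301L, 200L),
    seg_mean = c(theoreticalMean(3, alpha), 0,
                 theoreticalMean(0, alpha, 1))))
  got <- segTable(classifySegments(segs, alpha))
  expect_equal(got$ploidy_call, c(3L, 2L, 0L))

  # ties break toward the lower ploidy
  mid <- (theoreticalMean(2, alpha) + theoreticalMean(3, alpha)) / 2
  tie <- CNSegments(data.frame(chrom = "1", first_window = 1L,
                               last_window = 10L, n_windows = 10L,
                               seg_mean = mid))
  expect_equal(segTable(classifySegments(tie, alpha))$ploidy_call, 2L)

  # beyond the distance cap the segment stays unclassified
  far <- CNSegments(data.frame(chrom = "1", first_window = 1L,
                               last_window = 10L, n_windows = 10L,
                               seg_mean = 5))
  expect_true(is.na(segTable(classifySegments(far, alpha))$ploidy_call))

  # noiseless round trip for every ploidy on both germline backgrounds
  for (a in c(0.3, 0.63, 0.9)) {
    for (g in c(1, 2)) {
      ps <- if (g == 1 && a == 1) 1:6 else 0:6
      segs <- CNSegments(data.frame(
        chrom = if (g == 1) "X" else "7", first_window = 1L,
        last_window = 10L, n_windows = 10L,
        seg_mean = theoreticalMean(ps, a, g)))
      got <- segTable(classifySegments(segs, a))$ploidy_call
      expect_equal(got, as.integer(ps), info = paste("alpha", a, "g", g))
    }
  }
})

test_that("the noiseless pipeline recovers the generating genome", {
  cfg <- simConfig(seed = 17, cna = list(noise = "none"))
  sim <- simulateWindowCounts(cfg)
  res <- suppressMessages(runCnaPipeline(sim$counts, CbsParams(seed = 17)))
  expect_equal(purity(res$model), 0.63, tolerance = 0.01)
  st <- segTable(res$segments)
  # the germline-haploid X and Y sit at half the diploid count, which in
  # the noiseless setting is below the mean(N) - 2 sd(N) mask, so only the
  # 22 autosomes yield segments
  truth <- cfg$cna$layout[cfg$cna$layout$germlinePloidy == 2L, ]
  expect_equal(nrow(st), nrow(truth))
  got <- st$ploidy_call[match(truth$chrom, st$chrom)]
  expect_equal(got, truth$ploidy)
})
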