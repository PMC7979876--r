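test_that("germline SV subtraction uses a length-scaled tolerance", {
  germ <- makeSvSet(makeSv(svtype = "DEL", start = 100000L, end = 110000L,
                           svlen = 10000))
  inside <- makeSvSet(makeSv(svtype = "DEL", start = 100050L,
                             end = 110080L, svlen = 10030))
  expect_equal(length(subtractGermlineSvs(inside, germ)), 0L)
  outside <- makeSvSet(makeSv(svtype = "DEL", start = 100150L,
                              end = 110080L, svlen = 9930))
  expect_equal(length(subtractGermlineSvs(outside, germ)), 1L)
  # type must match even at identical coordinates
  dup <- makeSvSet(makeSv(svtype = "DUP", start = 100000L, end = 110000L))
  expect_equal(length(subtractGermlineSvs(dup, germ)), 1L)
})

test_that("breakpoint jitter of exactly L/100 separates subtracted from retained", {
  for (L in c(10000L, 50000L, 200000L)) {
    tol <- L / 100
    germ <- makeSvSet(makeSv(svtype = "DEL", start = 1000000L,
                             end = 1000000L + L, svlen = L))
    atTol <- makeSvSet(makeSv(svtype = "DEL", start = 1000000L + tol,
                              end = 1000000L + L + tol, svlen = L))
    expect_equal(length(subtractGermlineSvs(atTol, germ)), 0L,
                 info = paste("L =", L))
    past <- makeSvSet(makeSv(svtype = "DEL", start = 1000000L + tol + 1L,
                             end = 1000000L + L + tol, svlen = L))
    expect_equal(length(subtractGermlineSvs(past, germ)), 1L,
                 info = paste("L =", L))
  }
})

test_that("SV subtraction identities and TRA tolerance", {
  sv <- simulateSvSets(simConfig(seed = 9))
  tum <- sv$tumour
  expect_equal(callTable(subtractGermlineSvs(tum, SvCallSet())),
               callTable(tum))
  expect_equal(length(subtractGermlineSvs(tum, tum)), 0L)

  # translocations subtract within the fixed window, not L/100
  germTra <- makeSvSet(makeSv(svtype = "TRA", chrom = "1", start = 500000L,
                              chr2 = "5", end = 900000L,
                              svlen = NA_real_))
  near <- makeSvSet(makeSv(svtype = "TRA", chrom = "1", start = 500900L,
                           chr2 = "5", end = 900900L, svlen = NA_real_))
  far <- makeSvSet(makeSv(svtype = "TRA", chrom = "1", start = 501100L,
                          chr2 = "5", end = 900000L, svlen = NA_real_))
  expect_equal(length(subtractGermlineSvs(near, germTra)), 0L)
  expect_equal(length(subtractGermlineSvs(far, germTra)), 1L)
})

test_that("somatic SV filter separates pass, imprecise-review and dropped", {
  calls <- makeSvSet(
    makeSv(svtype = "DEL", start = 1L, end = 10001L, svlen = 10000),
    makeSv(svtype = "DEL", chrom = "2", start = 1L, end = 10002L,
           svlen = 10001),
    makeSv(svtype = "TRA", chrom = "3", start = 1000L, chr2 = "hs37d5",
           end = 99L, svlen = NA_real_),
    makeSv(svtype = "TRA", chrom = "3", start = 1000L, chr2 = "4",
           end = 99L, svlen = NA_real_),
    makeSv(svtype = "DUP", chrom = "5", start = 1L, end = 50001L,
           svlen = 50000, precise = FALSE, af = 0.3),
    makeSv(svtype = "DUP", chrom = "5", start = 1L, end = 50001L,
           svlen = 50000, precise = FALSE, af = 0.1))
  flt <- filterSomaticSvs(calls)
  pass <- callTable(flt$pass)
  expect_equal(nrow(pass), 2L)   # svlen 10000 dropped (strict), decoy dropped
  expect_setequal(pass$chrom, c("2", "3"))
  expect_true(all(pass$chr2 != "hs37d5"))
  side <- callTable(flt$imprecise)
  expect_equal(nrow(side), 1L)
  expect_equal(side$af, 0.3)
})

test_that("cross-method matching clusters jittered calls and gates on type", {
  sets <- list(
    m1 = makeSvSet(makeSv(start = 1000000L, end = 1200000L,
                          source_method = "m1")),
    m2 = makeSvSet(makeSv(start = 1000150L, end = 1200100L,
                          source_method = "m2")),
    m3 = makeSvSet(makeSv(start = 999900L, end = 1199850L,
                          source_method = "m3")))
  mv <- matchAcrossMethods(sets)
  expect_equal(nrow(mv), 1L)
  expect_true(all(unlist(mv[, c("m1", "m2", "m3")])))

  sets$m2 <- makeSvSet(makeSv(svtype = "INV", start = 1000000L,
                              end = 1200000L, source_method = "m2"))
  mv2 <- matchAcrossMethods(sets)
  expect_equal(nrow(mv2), 2L)
  expect_setequal(mv2$svtype, c("DEL", "INV"))
})

test_that("matching equals the transitive-closure oracle and is order-invariant", {
  skip_if_not_installed("igraph")
  for (seed in 1:4) {
    sv <- simulateSvSets(simConfig(seed = seed, sv = list(
      somaticCounts = c(DEL = 20L, DUP = 5L, INV = 5L, TRA = 3L))))
    mv <- matchAcrossMethods(sv$methods, tol = 1000)

    pooled <- do.call(rbind, lapply(names(sv$methods), function(m) {
      d <- callTable(sv$methods[[m]]); d$source_method <- m; d
    }))
    keys <- paste(pooled$source_method, pooled$svtype, pooled$chrom,
                  pooled$start, pooled$end)
    membership <- oracleClusters(pooled, tol = 1000)
    expect_equal(length(unique(membership)), nrow(mv))

    # permuting the method order leaves cluster composition unchanged
    mvRev <- matchAcrossMethods(rev(sv$methods), tol = 1000)
    expect_equal(nrow(mvRev), nrow(mv))
    expect_equal(mvRev[order(mvRev$chrom, mvRev$start),
                       c("svtype", "chrom", "start", "end")],
                 mv[order(mv$chrom, mv$start),
                    c("svtype", "chrom", "start", "end")],
                 ignore_attr = TRUE)
  }
})

test_that("FNR/FDR evaluation follows the benchmark formulas", {
  variants <- data.frame(
    svtype = rep("DEL", 5),
    truth_label = c("true_somatic", "true_somatic", "true_somatic",
                    "false_call", "false_call"),
    mA = c(TRUE, TRUE, FALSE, TRUE, FALSE),
    mB = c(TRUE, TRUE, TRUE, FALSE, FALSE))
  bench <- evaluateMethods(variants)
  a <- bench[bench$method == "mA" & bench$svtype == "DEL", ]
  expect_equal(a$fnr, 1 / 3)            # one of three true DELs missed
  expect_equal(a$fdr, 1 / 3)            # one false among three calls
  b <- bench[bench$method == "mB" & bench$svtype == "DEL", ]
  expect_equal(b$fnr, 0)
  expect_equal(b$fdr, 0)
  # fnr + detected/total_true = 1
  expect_equal(bench$fnr + bench$detected / bench$n_true,
               rep(1, nrow(bench)))
})

test_that("evaluation handles empty denominators and unlabelled input", {
  variants <- data.frame(svtype = "DUP", truth_label = "true_somatic",
                         mA = FALSE)
  bench <- evaluateMethods(variants)
  expect_true(is.na(bench$fdr[1]))      # method made no call: FDR undefined
  expect_equal(bench$fnr[1], 1)

  bad <- data.frame(svtype = "DEL", truth_label = "unlabelled", mA = TRUE)
  expect_error(evaluateMethods(bad), "truth label")
})

test_that("half-up rounding matches printed-table conventions", {
  expect_equal(roundHalfUp(c(0.125, 0.135, 0.1449), 2),
               c(0.13, 0.14, 0.14))
  expect_equal(roundHalfUp(1 / 6, 2), 0.17)
  expect_equal(roundHalfUp(7 / 49, 2), 0.14)
})
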