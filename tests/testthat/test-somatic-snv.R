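test_that("initial filter applies strict QUAL/NUMALT/SAF/SAR thresholds", {
  cases <- list(
    list(call = makeCall(qual = 1.0, numalt = 1L, saf = 5L, sar = 5L,
                         ao = 10L), kept = FALSE),   # QUAL boundary, strict
    list(call = makeCall(qual = 30, numalt = 1L, saf = 2L, sar = 2L,
                         ao = 4L), kept = TRUE),
    list(call = makeCall(qual = 30, numalt = 2L, saf = 9L, sar = 9L,
                         ao = 18L), kept = FALSE),   # multi-allelic site
    list(call = makeCall(saf = 1L, sar = 10L, ao = 11L), kept = FALSE))
  for (cs in cases) {
    out <- initialFilter(SmallVariantCalls(cs$call))
    expect_equal(length(out), as.integer(cs$kept), info = paste(cs$call,
                                                collapse = "/"))
  }
  expect_equal(length(initialFilter(SmallVariantCalls())), 0L)
})

test_that("germline subtraction matches on chrom/pos/alt, not ref", {
  tum <- makeCalls(makeCall(pos = 100L, alt = "T"))
  expect_equal(length(subtractGermline(tum,
                                       makeCalls(makeCall(pos = 100L,
                                                          alt = "T")))), 0L)
  expect_equal(length(subtractGermline(tum,
                                       makeCalls(makeCall(pos = 100L,
                                                          alt = "G")))), 1L)
  # ref deliberately not in the key
  germDiffRef <- makeCalls(makeCall(pos = 100L, ref = "C", alt = "T"))
  expect_equal(length(subtractGermline(tum, germDiffRef)), 0L)
})

test_that("subtraction identities hold for arbitrary call sets", {
  x <- randomCalls(80, seed = 4)
  expect_equal(callTable(subtractGermline(x, SmallVariantCalls())),
               callTable(x))
  expect_equal(length(subtractGermline(x, x)), 0L)
})

test_that("strand-bias filter compares per-strand alt fractions at 4x", {
  frac <- function(saf, srf, sar, srr)
    SmallVariantCalls(makeCall(saf = saf, srf = srf, sar = sar, srr = srr,
                               ao = saf + sar, ro = srf + srr))
  # f_fwd = 0.5 vs f_rev = 0.1: ratio 5, removed
  expect_equal(length(strandBiasFilter(frac(10L, 10L, 2L, 18L))), 0L)
  # f_fwd = 0.4 vs f_rev = 0.1: ratio exactly 4, "more than" is strict
  expect_equal(length(strandBiasFilter(frac(8L, 12L, 2L, 18L))), 1L)
  # symmetric fractions retained
  expect_equal(length(strandBiasFilter(frac(10L, 10L, 10L, 10L))), 1L)
  # zero-depth strand: removable only because the other fraction is positive
  expect_equal(length(strandBiasFilter(frac(0L, 0L, 5L, 15L))), 0L)
  expect_equal(length(strandBiasFilter(frac(0L, 0L, 0L, 20L))), 1L)
})

test_that("final filter applies all eight strict inequalities", {
  expect_equal(length(finalFilter(makeCalls(
    makeCall(ao = 50L, ro = 50L, saf = 25L, sar = 25L, srf = 25L,
             srr = 25L, qa = 1500, qr = 1500, sap = 5, mqm = 60)))), 1L)
  boundary <- list(
    makeCall(ao = 100L, saf = 50L, sar = 50L),          # AO < 100 strict
    makeCall(mqm = 55),                                  # MQM > 55 strict
    makeCall(ao = 10L, saf = 5L, sar = 5L),              # AO > 10 strict
    makeCall(qa = 100), makeCall(qr = 100),
    makeCall(sap = 30),
    makeCall(ro = 100L, srf = 50L, srr = 50L),
    makeCall(ro = 10L, srf = 5L, srr = 5L))
  for (b in boundary)
    expect_equal(length(finalFilter(SmallVariantCalls(b))), 0L)
})

test_that("filters are idempotent and commute on arbitrary input", {
  filters <- list(initial = initialFilter, strand = strandBiasFilter,
                  final = finalFilter)
  for (seed in 1:3) {
    x <- randomCalls(120, seed = seed)
    for (f in filters)
      expect_equal(callTable(f(f(x))), callTable(f(x)))
    for (a in seq_along(filters)) {
      for (b in seq_along(filters)) {
        if (a >= b) next
        ab <- filters[[b]](filters[[a]](x))
        ba <- filters[[a]](filters[[b]](x))
        expect_equal(callTable(ab), callTable(ba))
      }
    }
  }
})

test_that("call-set overlap counts agree with a brute-force key oracle", {
  a <- makeCalls(makeCall(pos = 1L), makeCall(pos = 2L), makeCall(pos = 3L))
  expect_equal(compareCallsets(a, a),
               list(shared = 3L, only_a = 0L, only_b = 0L))
  b <- makeCalls(makeCall(pos = 10L), makeCall(pos = 11L),
                 makeCall(pos = 12L), makeCall(pos = 13L),
                 makeCall(pos = 14L))
  expect_equal(compareCallsets(a, b),
               list(shared = 0L, only_a = 3L, only_b = 5L))
  for (seed in 1:5) {
    set.seed(seed)
    x <- randomCalls(60, seed = seed)
    y <- randomCalls(60, seed = seed + 100)
    got <- compareCallsets(x, y)
    kx <- unique(snvKeys(x)); ky <- unique(snvKeys(y))
    expect_equal(got$shared, length(intersect(kx, ky)))
    expect_equal(got$only_a, length(setdiff(kx, ky)))
    expect_equal(got$only_b, length(setdiff(ky, kx)))
    expect_equal(got$shared + got$only_a, length(kx))
    expect_equal(got$shared + got$only_b, length(ky))
  }
})

test_that("pipeline recovers planted somatic calls and reports stages", {
  sim <- simulateSmallVariants(simConfig(seed = 31, snv = list(
    nGermline = 100L, nSomatic = 10L)))
  res <- runSnvPipeline(sim$tumour, sim$germline)
  somTruth <- sim$truth[sim$truth$label == "somatic", ]
  expect_equal(length(res$somatic), nrow(somTruth))
  expect_setequal(snvKeys(res$somatic),
                  paste(somTruth$chrom, somTruth$pos, somTruth$alt,
                        sep = ":"))
  # stage counts non-increasing and output a subset of the input
  expect_true(all(diff(res$report$n) <= 0))
  expect_true(all(snvKeys(res$somatic) %in% snvKeys(sim$tumour)))
})

test_that("degenerate pipeline inputs behave as documented", {
  empty <- SmallVariantCalls()
  res <- runSnvPipeline(empty, empty)
  expect_equal(length(res$somatic), 0L)
  expect_true(all(res$report$n == 0L))

  sim <- simulateSmallVariants(simConfig(seed = 32, snv = list(
    nGermline = 50L, nSomatic = 5L)))
  once <- runSnvPipeline(sim$tumour, sim$germline)
  twice <- runSnvPipeline(sim$tumour, sim$germline,
                          secondGermline = once$somatic)
  expect_equal(length(twice$somatic), 0L)
  expect_equal(tail(twice$report$n, 1L), 0L)
})
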