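test_that("unmethylated uniform truth gives uniform cleavage counts", {
  L <- 120L
  tr <- SimulationTruth(L, nFragments = 1e5, seed = 101)
  prof <- simulateEndCounts(tr)
  # each event is a matched 3'/5' pair; the 3' counts over internal bonds
  # are the multinomial draw itself
  x <- threePrimeCounts(prof)[seq_len(L - 1)]
  gof <- chisq.test(x, p = rep(1 / (L - 1), L - 1))
  expect_gt(gof$p.value, 0.001)
  expect_equal(sum(x), 1e5L)
})

test_that("full methylation at one site zeroes its bond and scores MI 1", {
  tr <- SimulationTruth(100, methylation = c(`50` = 1), nFragments = 5e4,
                        seed = 5)
  prof <- combineEndCounts(simulateEndCounts(tr))
  expect_equal(combinedCounts(prof)[50], 0)
  expect_equal(scoreC(prof, 50), 1)
})

test_that("score C recovers the true methylated fraction", {
  tr <- SimulationTruth(400, methylation = c(`200` = 0.8),
                        nFragments = 2e5, seed = 42)
  prof <- combineEndCounts(simulateEndCounts(tr))
  expect_lt(abs(scoreC(prof, 200) - 0.8), 0.03)
})

test_that("end-count depletion is monotone in the methylated fraction", {
  ms <- seq(0, 1, by = 0.2)
  counts <- vapply(ms, function(m) {
    tr <- SimulationTruth(200, methylation = c(`100` = m),
                          nFragments = 1e5, seed = 8)
    combinedCounts(combineEndCounts(simulateEndCounts(tr)))[100]
  }, numeric(1))
  expect_true(all(diff(counts) < 0))
})

test_that("fragment-pair mode respects the size-selection window", {
  tr <- SimulationTruth(300, nFragments = 2000, seed = 12)
  prof <- simulateEndCounts(tr, mode = "fragments",
                            fragmentLength = c(30L, 50L))
  expect_equal(sum(fivePrimeCounts(prof)), sum(threePrimeCounts(prof)))
  expect_gt(sum(fivePrimeCounts(prof)), 0)
})

test_that("simulator seeds are explicit and leak no RNG state", {
  tr <- SimulationTruth(100, nFragments = 1e4, seed = 3)
  a <- simulateEndCounts(tr)
  b <- simulateEndCounts(tr)
  expect_identical(threePrimeCounts(a), threePrimeCounts(b))
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(simulateEndCounts(tr)); after <- runif(3)
  expect_identical(before, after)
})

test_that("the MI-matrix simulator honours sigma = 0 and stores truth", {
  means <- matrix(c(0.2, 0.8, 0.5, 0.5), 2, 2,
                  dimnames = list(c("m_1", "m_2"), c("A", "B")))
  spec <- GroupEffectSpec(means, sigma = 0, nPerGroup = c(A = 3L, B = 3L),
                          seed = 2L)
  mt <- simulateMIMatrix(spec)
  mi <- methylationIndex(mt)
  expect_equal(unname(mi[, "A_r1"]), unname(means[, "A"]))
  expect_equal(unname(mi[, "B_r3"]), unname(means[, "B"]))
  expect_identical(S4Vectors::metadata(mt)$truth, means)
})

test_that("a shifted group is reliably detected as hyper", {
  hits <- 0L
  for (s in 1:200) {
    spec <- GroupEffectSpec(
      matrix(c(0.5, 0.8), 1, 2, dimnames = list("x_1", c("A", "B"))),
      sigma = 0.05, nPerGroup = c(A = 4L, B = 4L), seed = s)
    mt <- simulateMIMatrix(spec)
    mi <- methylationIndex(mt)
    r <- ttestSite(mi[1, 1:4], mi[1, 5:8])
    if (classifyShift(r$p_value, r$delta) == "hyper") hits <- hits + 1L
  }
  expect_gte(hits, 190L)  # >= 95% power
})

test_that("noiseless qPCR simulations invert their models exactly", {
  ct <- simulateRTLPCt(c(a = 0.5, b = 0.2), sigmaCt = 0, seed = 1)
  got <- rtlpIndex(ct$ct_up_low, ct$ct_down_low, ct$ct_up_high,
                   ct$ct_down_high)
  expect_equal(got, c(0.5, 0.2))
  expect_error(simulateRTLPCt(1), "must be < 1")

  dil <- simulateDilutionSeries(sigmaCt = 0, seed = 1)
  curve <- fitStandardCurve(dil$log10_dilution, dil$ct)
  expect_equal(curveSlope(curve), attr(dil, "slope"), tolerance = 1e-9)
})

test_that("RTL-P recovery stays accurate under cycle noise", {
  errs <- vapply(1:50, function(s) {
    ct <- simulateRTLPCt(c(x = 0.6), sigmaCt = 0.2, seed = s)
    abs(rtlpIndex(ct$ct_up_low, ct$ct_down_low, ct$ct_up_high,
                  ct$ct_down_high) - 0.6)
  }, numeric(1))
  expect_lt(median(errs), 0.1)
})

test_that("fixture sets are deterministic and internally consistent", {
  d1 <- file.path(tempdir(), "fixA"); d2 <- file.path(tempdir(), "fixB")
  unlink(c(d1, d2), recursive = TRUE)
  writeFixtures(d1, seed = 4, nFragments = 3000L)
  writeFixtures(d2, seed = 4, nFragments = 3000L)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  # SAM and count-table views of the same sample agree
  refs <- readRRNAReference(file.path(d1, "references.fa"))
  pSam <- countReadEnds(file.path(d1, "sam", "ESC_WT_r1_18S.sam"),
                        refs, "18S", "ESC_WT_r1")
  pTsv <- readEndCountTable(file.path(d1, "counts", "ESC_WT_r1_18S.tsv"),
                            "18S", "ESC_WT_r1")
  expect_equal(fivePrimeCounts(pSam), fivePrimeCounts(pTsv))
  expect_equal(threePrimeCounts(pSam), threePrimeCounts(pTsv))
  # truth manifest round-trips
  manifest <- yaml::read_yaml(file.path(d1, "truth.yaml"))
  expect_equal(manifest$seed, 4L)
  expect_true(file.exists(file.path(d1, "site_catalogue.tsv")))
})
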