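refsFor <- function(L, name = "18S")
  readRRNAReference(writeTestFasta(stats::setNames(
    list(strrep("ACGT", ceiling(L / 4)) |> substr(1, L)), name)))

test_that("read ends are tallied at the aligned reference span", {
  refs <- refsFor(60)
  sam <- writeTestSam(samRow("r1", 0L, "18S", 10L, "20M", 20L), "18S", 60L)
  prof <- countReadEnds(sam, refs, "18S", "s1")
  expect_equal(fivePrimeCounts(prof)[10], 1L)
  expect_equal(threePrimeCounts(prof)[29], 1L)
  expect_equal(sum(fivePrimeCounts(prof)), 1L)
  expect_equal(sum(threePrimeCounts(prof)), 1L)
  expect_equal(totalReads(prof), 1L)

  # an unmapped record changes nothing
  sam2 <- writeTestSam(c(samRow("r1", 0L, "18S", 10L, "20M", 20L),
                         sprintf("u1\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t*",
                                 strrep("A", 20))),
                       "18S", 60L)
  prof2 <- countReadEnds(sam2, refs, "18S", "s1")
  expect_equal(fivePrimeCounts(prof2), fivePrimeCounts(prof))
  expect_equal(threePrimeCounts(prof2), threePrimeCounts(prof))

  # soft clips do not move the counted end; minus strand is skipped
  sam3 <- writeTestSam(c(samRow("r1", 0L, "18S", 10L, "5S20M", 25L),
                         samRow("r2", 16L, "18S", 30L, "10M", 10L)),
                       "18S", 60L)
  prof3 <- countReadEnds(sam3, refs, "18S", "s1")
  expect_equal(fivePrimeCounts(prof3)[10], 1L)
  expect_equal(threePrimeCounts(prof3)[29], 1L)
  expect_equal(totalReads(prof3), 1L)
  expect_equal(prof3@qc$skipped_minus_strand, 1L)
})

test_that("counting matches a brute-force per-read tally and ignores order", {
  L <- 200L
  refs <- refsFor(L)
  set.seed(11)
  n <- 50L
  pos <- sample.int(150L, n, replace = TRUE)
  len <- sample(20:50, n, replace = TRUE)
  len <- pmin(len, L - pos + 1L)
  rows <- vapply(seq_len(n), function(i)
    samRow(paste0("r", i), 0L, "18S", pos[i],
           paste0(len[i], "M"), len[i]), character(1))
  sam <- writeTestSam(rows, "18S", L)
  prof <- countReadEnds(sam, refs, "18S", "s1")
  oracle <- bruteForceEndTally(sam, "18S", L)
  expect_equal(fivePrimeCounts(prof), oracle$five)
  expect_equal(threePrimeCounts(prof), oracle$three)

  shuffled <- writeTestSam(sample(rows), "18S", L)
  prof2 <- countReadEnds(shuffled, refs, "18S", "s1")
  expect_equal(fivePrimeCounts(prof2), fivePrimeCounts(prof))
  expect_equal(threePrimeCounts(prof2), threePrimeCounts(prof))
})

test_that("header mismatches and empty streams are handled", {
  refs <- refsFor(60)
  sam <- writeTestSam(character(0), "28S", 60L)
  expect_error(countReadEnds(sam, refs, "18S", "s1"), "absent from")
  samLen <- writeTestSam(character(0), "18S", 61L)
  expect_error(countReadEnds(samLen, refs, "18S", "s1"), "disagrees")
  samEmpty <- writeTestSam(character(0), "18S", 60L)
  expect_warning(prof <- countReadEnds(samEmpty, refs, "18S", "s1"),
                 "no counted reads")
  expect_equal(sum(fivePrimeCounts(prof)), 0L)
})

test_that("shift-and-combine follows the bond-coordinate definition", {
  p <- combineEndCounts(makeProfile(c(1, 2, 3, 4), c(5, 6, 7, 8)))
  expect_equal(combinedCounts(p), c(7, 9, 11, 8))
  expect_equal(p@fivePrimeStart, 1L)

  z <- combineEndCounts(makeProfile(integer(5), integer(5)))
  expect_equal(combinedCounts(z), rep(0, 5))
})

test_that("combining conserves counts apart from the 5'-start exclusion", {
  set.seed(7)
  for (i in 1:5) {
    L <- sample(20:200, 1)
    p <- makeProfile(rpois(L, 30), rpois(L, 30))
    cp <- combineEndCounts(p)
    expect_equal(sum(combinedCounts(cp)),
                 sum(threePrimeCounts(p)) + sum(fivePrimeCounts(p)[-1]))
  }
  # mirrored convention conserves symmetrically (3' terminal excluded)
  p <- makeProfile(c(1, 2, 3, 4), c(5, 6, 7, 8))
  cm <- combineEndCounts(p, shiftDirection = "toward_end")
  expect_equal(sum(combinedCounts(cm)),
               sum(fivePrimeCounts(p)) + sum(threePrimeCounts(p)[-4]))
})

test_that("count tables round-trip and sparse input is gated", {
  p <- makeProfile(rpois(10, 5), rpois(10, 5))
  path <- tempfile(fileext = ".tsv")
  writeEndCountTable(p, path)
  back <- readEndCountTable(path, "18S", "s1")
  expect_equal(fivePrimeCounts(back), fivePrimeCounts(p))
  expect_equal(threePrimeCounts(back), threePrimeCounts(p))

  sparse <- tempfile(fileext = ".tsv")
  writeLines(c("position\tfive_prime\tthree_prime",
               "2\t3\t1", "5\t0\t2", "9\t1\t1", "10\t2\t0", "4\t1\t1"),
             sparse)
  expect_error(readEndCountTable(sparse, "18S", "s1", length = 10),
               "sparse")
  dense <- readEndCountTable(sparse, "18S", "s1", length = 10,
                             allowSparse = TRUE)
  expect_equal(fivePrimeCounts(dense), c(0L, 3L, 0L, 1L, 0L, 0L, 0L, 0L, 1L, 2L))
  expect_equal(threePrimeCounts(dense), c(0L, 1L, 0L, 1L, 2L, 0L, 0L, 0L, 1L, 0L))
})

test_that("coverage QC warns below the median threshold", {
  p <- combineEndCounts(makeProfile(rep(1L, 20), rep(1L, 20)))
  expect_warning(profileQC(p, minMedianCoverage = 100), "median")
  p2 <- combineEndCounts(makeProfile(rep(100L, 20), rep(100L, 20)))
  expect_silent(qc <- profileQC(p2, minMedianCoverage = 100))
  expect_true(qc$median_coverage_ok)
})
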