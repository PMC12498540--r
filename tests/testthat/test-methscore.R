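test_that("the neighbourhood average matches hand-computed cases", {
  flat <- combinedProfile(rep(10, 50))
  for (k in c(1L, 3L, 6L))
    expect_equal(neighborAverage(flat, 25, ScoreParams(k = k)), 10)

  spike <- combinedProfile(c(0, 4, 0))
  expect_equal(neighborAverage(spike, 2, ScoreParams(k = 1L)), 0)

  # k = 2, linear decay: w = (1, 0.5); A = (4 + 4 + 0.5*2 + 0.5*2) / 3
  p <- combinedProfile(c(2, 4, 8, 4, 2))
  expect_equal(neighborAverage(p, 3, ScoreParams(k = 2L)), 10 / 3)
  # uniform weights on the same window
  expect_equal(
    neighborAverage(p, 3, ScoreParams(k = 2L, weightScheme = "uniform")),
    3)
  # edge window: positions outside 1..L drop from both sums
  # site 1, k = 2: only right neighbours (1*4 + 0.5*8) / (1 + 0.5)
  expect_equal(neighborAverage(p, 1, ScoreParams(k = 2L)), 8 / 1.5)
})

test_that("score C encodes protection as depletion relative to neighbours", {
  prot <- combinedProfile(c(rep(100, 6), 0, rep(100, 6)))
  expect_equal(scoreC(prot, 7), 1)         # complete protection
  flat <- combinedProfile(rep(100, 13))
  expect_equal(scoreC(flat, 7), 0)         # no depletion
  p <- combinedProfile(c(rep(100, 6), 25, rep(100, 6)))
  expect_equal(scoreC(p, 7), 0.75)
  expect_error(scoreC(p, 14), "outside")
})

test_that("low coverage and empty neighbourhoods yield missing, not zero", {
  low <- combinedProfile(c(rep(2, 6), 0, rep(2, 6)))
  expect_true(is.na(scoreC(low, 7, ScoreParams(minSiteCoverage = 100))))
  expect_equal(scoreC(low, 7, ScoreParams(minSiteCoverage = 0)), 1)
  zero <- combinedProfile(rep(0, 13))
  expect_true(is.na(scoreC(zero, 7, ScoreParams(minSiteCoverage = 0))))
})

test_that("score C is scale invariant and monotone in the site count", {
  set.seed(3)
  base <- rpois(41, 200) + 1
  p <- combinedProfile(base)
  for (const in c(0.5, 2, 17)) {
    ps <- combinedProfile(base * const)
    for (pos in c(7, 20, 35))
      expect_equal(scoreC(ps, pos), scoreC(p, pos), tolerance = 1e-12)
  }
  # raising the site's own count never increases the score
  scores <- vapply(seq(0, 400, by = 50), function(n) {
    v <- base; v[20] <- n
    scoreC(combinedProfile(v), 20)
  }, numeric(1))
  expect_true(all(diff(scores) <= 1e-12))
  # without clamping, a site exceeding its neighbourhood goes negative
  v <- base; v[20] <- 10 * max(base)
  expect_lt(scoreC(combinedProfile(v), 20, ScoreParams(clamp = FALSE)), 0)
  expect_equal(scoreC(combinedProfile(v), 20), 0)
})

test_that("scoreSample scores exactly the catalogue, once per site", {
  sites <- defaultSiteCatalogue("18S")
  p <- combinedProfile(rep(150, 1869), molecule = "18S")
  mi <- scoreSample(p, sites)
  expect_length(mi, 42L)
  expect_named(mi, sites$site_id)
  expect_true(all(mi == 0))

  empty <- combinedProfile(rep(0, 1869), molecule = "18S")
  expect_true(all(is.na(scoreSample(empty, sites))))

  p28 <- combinedProfile(rep(150, 5070), molecule = "28S")
  expect_error(scoreSample(p28, sites), "molecule")
})

test_that("replicate aggregation reports mean, SEM and missingness", {
  sites <- GenomicRanges::GRanges("18S", IRanges::IRanges(c(10, 20), width = 1))
  sites$site_id <- c("18S_10", "18S_20")
  sites$guide_snorna <- NA_character_
  mat <- matrix(c(0.2, 0.4, NA,
                  NA,  NA,  0.5),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("18S_10", "18S_20"),
                                c("a1", "a2", "b1")))
  design <- data.frame(sample_id = c("a1", "a2", "b1"),
                       group = c("A", "A", "B"))
  mt <- buildMethylationTable(mat, sites, design)
  agg <- aggregateReplicates(mt)
  a10 <- agg[agg$site_id == "18S_10" & agg$group == "A", ]
  expect_equal(a10$mean, 0.3)
  expect_equal(a10$sem, 0.1)                      # sd/sqrt(2)
  b10 <- agg[agg$site_id == "18S_10" & agg$group == "B", ]
  expect_true(is.na(b10$mean) && b10$all_missing) # missing everywhere
  b20 <- agg[agg$site_id == "18S_20" & agg$group == "B", ]
  expect_equal(b20$mean, 0.5)                     # single replicate
  expect_true(is.na(b20$sem))
})

test_that("the methylation table enforces its contract", {
  sites <- GenomicRanges::GRanges("18S", IRanges::IRanges(10, width = 1))
  sites$site_id <- "18S_10"; sites$guide_snorna <- NA_character_
  design <- data.frame(sample_id = "s1", group = "A")
  bad <- matrix(1.2, 1, 1, dimnames = list("18S_10", "s1"))
  expect_error(buildMethylationTable(bad, sites, design), "0, 1")
  expect_error(buildMethylationTable(
    matrix(0.5, 1, 1, dimnames = list("other", "s1")), sites, design),
    "absent from the site catalogue")
})
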