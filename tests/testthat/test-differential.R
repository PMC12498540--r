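test_that("the pooled-variance t-test matches the closed form", {
  same <- ttestSite(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3))
  expect_equal(same$p_value, 1)
  expect_equal(same$t, 0)
  expect_equal(same$delta, 0)

  r <- ttestSite(c(0.1, 0.2, 0.3), c(0.4, 0.5, 0.6))
  oracle <- pooledTP(c(0.1, 0.2, 0.3), c(0.4, 0.5, 0.6))
  expect_equal(r$t, oracle$t, tolerance = 1e-10)
  expect_equal(r$p_value, oracle$p, tolerance = 1e-10)
  expect_equal(round(r$t, 3), 3.674)
  expect_equal(round(r$p_value, 4), 0.0213)
  expect_equal(r$df, 4)
  expect_equal(r$delta, 0.3)
})

test_that("degenerate t-test inputs carry reason codes", {
  short <- ttestSite(0.5, c(0.1, 0.2))
  expect_true(is.na(short$p_value))
  expect_match(short$reason, "fewer than 2")

  degen <- ttestSite(c(0.2, 0.2), c(0.8, 0.8))
  expect_equal(degen$p_value, 0)
  expect_match(degen$reason, "zero variance")
  expect_equal(degen$delta, 0.6)
})

test_that("ANOVA + Tukey agree with a Monte-Carlo null oracle", {
  g <- list(a = c(0.1, 0.2), b = c(0.5, 0.6), c = c(0.9, 1.0))
  vals <- unlist(g)
  labs <- rep(names(g), lengths(g))
  r <- anovaTukeySite(vals, labs)

  # Monte-Carlo oracle: simulate the null distribution of the F statistic
  # and of the studentized range (max over pairs), 1e5 draws
  set.seed(20240901)
  B <- 1e5L
  n <- 2L; k <- 3L
  draws <- matrix(rnorm(B * n * k), ncol = n * k)
  gm <- vapply(1:k, function(j)
    rowMeans(draws[, ((j - 1) * n + 1):(j * n), drop = FALSE]),
    numeric(B))
  gv <- vapply(1:k, function(j)
    apply(draws[, ((j - 1) * n + 1):(j * n), drop = FALSE], 1, var),
    numeric(B))
  msw <- rowMeans(gv)
  msb <- n * apply(gm, 1, var)
  fNull <- msb / msw
  qNull <- (apply(gm, 1, max) - apply(gm, 1, min)) / sqrt(msw / n)

  fObs <- r$f
  expect_lt(abs(r$anova_p - mean(fNull >= fObs)), 0.02)

  groupMeans <- vapply(g, mean, numeric(1))
  mswObs <- mean(vapply(g, var, numeric(1)))
  for (pair in list(c("b", "a"), c("c", "a"), c("c", "b"))) {
    qObs <- abs(groupMeans[pair[1]] - groupMeans[pair[2]]) /
      sqrt(mswObs / n)
    mc <- mean(qNull >= qObs)
    expect_lt(abs(unname(r$tukey_p[paste(pair, collapse = "-")]) - mc),
              0.02)
  }

  # ordering property: the pair spanning the shifted group is smallest
  shifted <- anovaTukeySite(c(0.5, 0.52, 0.48, 0.9, 0.92, 0.88,
                              0.5, 0.51, 0.49),
                            rep(c("a", "b", "c"), each = 3))
  expect_true(names(which.min(shifted$tukey_p)) %in% c("b-a", "c-b"))
})

test_that("identical groups give F = 0 and all-ones Tukey", {
  r <- anovaTukeySite(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3))
  expect_equal(r$anova_p, 1, tolerance = 1e-12)
  expect_equal(unname(r$f), 0, tolerance = 1e-12)
  expect_true(all(r$tukey_p > 0.999))
  skip <- anovaTukeySite(c(0.1, 0.2, 0.3, 0.4, 0.5),
                         c("a", "a", "b", "b", "c"))
  expect_true(is.na(skip$anova_p))
  expect_match(skip$reason, "fewer than 2")
})

test_that("Tukey p is never below the unadjusted pairwise p", {
  set.seed(5)
  for (i in 1:10) {
    vals <- rnorm(9, 0.5, 0.1)
    labs <- rep(c("a", "b", "c"), each = 3)
    r <- anovaTukeySite(vals, labs)
    for (pair in list(c("b", "a"), c("c", "a"), c("c", "b"))) {
      tt <- t.test(vals[labs == pair[1]], vals[labs == pair[2]],
                   var.equal = TRUE)$p.value
      expect_gte(r$tukey_p[[paste(pair, collapse = "-")]] + 1e-12, tt)
    }
  }
})

test_that("shift classification follows printed means and p-values", {
  esc <- fmr1KoComparisonTable("esc")
  cls <- classifyShift(esc$p_value, esc$mi_ko - esc$mi_wt)
  s428 <- which(esc$molecule_id == "18S" & esc$position == 428)
  s1536 <- which(esc$molecule_id == "18S" & esc$position == 1536)
  expect_equal(cls[s428], "hyper")    # 0.3384 -> 0.5689, p 0.0079
  expect_equal(cls[s1536], "hypo")    # 0.9388 -> 0.1264, p 0.00029
  expect_equal(classifyShift(0.5, 0.3), "unchanged")
  expect_equal(classifyShift(NA_real_, 0.3), "unchanged")
  expect_warning(tied <- classifyShift(0.01, 0), "delta exactly 0")
  expect_equal(tied, "unchanged")
})

test_that("classification is antisymmetric under group swap", {
  set.seed(9)
  spec <- GroupEffectSpec(
    means = matrix(runif(40, 0.3, 1), 20, 2,
                   dimnames = list(paste0("s_", 1:20), c("A", "B"))),
    sigma = 0.04, nPerGroup = c(A = 4L, B = 4L), seed = 31L)
  mt <- simulateMIMatrix(spec)
  ab <- compareGroups(mt, "A", "B")
  ba <- compareGroups(mt, "B", "A")
  expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)
  expect_equal(ab$delta, -ba$delta, tolerance = 1e-12)
  flip <- c(hyper = "hypo", hypo = "hyper", unchanged = "unchanged")
  expect_equal(unname(flip[ab$classification]), ba$classification)
})

test_that("hypomethylated site selection is inclusive at the threshold", {
  wt <- wtDifferentiationTable("18S")
  agg <- data.frame(site_id = paste0("18S_", wt$position),
                    group = "ESC_WT", mean = wt$mi_esc)
  hypo <- selectHypomethylated(agg, "ESC_WT", 0.9)
  expect_true("18S_428" %in% hypo)      # ESC mean 0.3384
  expect_false("18S_27" %in% hypo)      # ESC mean 0.9931
  boundary <- data.frame(site_id = c("x", "y"), group = "g",
                         mean = c(0.9, 0.9000001))
  expect_equal(selectHypomethylated(boundary, "g"), "x")
})

test_that("significant-site counting splits by molecule and class", {
  cmp <- data.frame(molecule_id = c("18S", "18S", "28S"),
                    p_value = c(0.01, 0.2, 0.001),
                    classification = c("hyper", "unchanged", "hypo"))
  cnt <- countSignificant(cmp)
  expect_equal(cnt$n_significant[cnt$molecule_id == "18S"], 1L)
  expect_equal(cnt$n_hypo[cnt$molecule_id == "28S"], 1L)
  empty <- countSignificant(cmp[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("heatmap rows split into variable and saturated classes", {
  wt <- wtDifferentiationTable("18S")
  sites <- GenomicRanges::GRanges("18S",
    IRanges::IRanges(wt$position, width = 1))
  sites$site_id <- paste0("18S_", wt$position)
  sites$guide_snorna <- NA_character_
  mat <- cbind(ESC = wt$mi_esc, NSC = wt$mi_nsc, Neuron = wt$mi_neuron)
  rownames(mat) <- sites$site_id
  design <- data.frame(sample_id = colnames(mat),
                       group = colnames(mat))
  mt <- buildMethylationTable(pmin(mat, 1), sites, design)
  hm <- heatmapMatrix(mt, variabilityDelta = 0.05)
  cls <- stats::setNames(as.character(hm$grouping), rownames(hm$matrix))
  expect_equal(unname(cls["18S_428"]), "variable")  # 0.34/0.76/0.96
  expect_equal(unname(cls["18S_27"]), "saturated")  # ~0.993 throughout
  all_sat <- heatmapMatrix(mt, variabilityDelta = 1.0)
  expect_true(all(all_sat$grouping == "saturated"))
})
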