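test_that("KS statistic is the sup distance between reverse cumulatives", {
  fx <- ovarianFixture()
  p <- empiricalDistribution(fx$counts, M = 62L)

  # identity: feeding the empirical frequencies back as the null
  selfNull <- nullFromFrequencies(p@normalized, M = 62L)
  ks <- ksCompare(p, selfNull)
  expect_equal(ks$statistic, 0, tolerance = 1e-12)
  expect_equal(ks$p1, 1)

  # maximal separation on M = 1
  pMax <- empiricalDistribution(c(a = 1L, b = 1L), M = 1L)
  ndMax <- nullFromFrequencies(c(1, 0), M = 1L, n0 = 2L)
  expect_equal(ksCompare(pMax, ndMax)$statistic, 1)

  expect_error(ksCompare(p, nullFromFrequencies(c(1), M = 3L)),
               "disagree on M")
})

test_that("KS statistic equals a brute-force sup over the support (property)", {
  set.seed(19)
  for (rep in 1:10) {
    M <- sample(3:12, 1)
    n0 <- sample(10:50, 1)
    counts <- stats::setNames(
      pmin(M, stats::rpois(n0, 1)), paste0("g", seq_len(n0)))
    p <- empiricalDistribution(counts, M)
    ef <- as.numeric(stats::rmultinom(1, 500, runif(M + 1))) / 500
    nd <- nullFromFrequencies(ef, M, n0 = n0)
    brute <- max(abs(bruteReverseCumulative(p@normalized) -
                     bruteReverseCumulative(nd@EF)))
    expect_equal(ksCompare(p, nd)$statistic, brute, tolerance = 1e-12)
  }
})

test_that("threshold p-values are expected-to-actual tail ratios", {
  fx <- ovarianFixture()
  p <- empiricalDistribution(fx$counts, M = 62L)
  nd <- nullFromFrequencies(fx$expectedPct / 100, M = 62L)
  p2 <- thresholdPvalues(p, nd)
  # hand computation from the published columns:
  # R_EF(2) = (1.89 + 0.08)/100, R_F(2) = 12/36
  expect_equal(unname(p2["2"]), 0.0197 / (12 / 36), tolerance = 1e-3)
  # beyond the empirical support the ratio is undefined
  expect_true(all(is.na(p2[as.character(7:62)])))
  # expected tail empty but actual occupied: p-value 0
  expect_equal(unname(p2["4"]), 0)

  # a profile identical to its null has p2 = 1 on all non-empty tails
  selfP2 <- thresholdPvalues(p, nullFromFrequencies(p@normalized, 62L))
  expect_true(all(selfP2[!is.na(selfP2)] == 1))
})

test_that("threshold choice takes the smallest qualifying r", {
  expect_identical(chooseThreshold(c(`1` = 0.8, `2` = 0.06, `3` = 0.004)),
                   3L)
  expect_identical(chooseThreshold(c(`1` = 0.01, `2` = 0.2)), 1L)
  expect_identical(chooseThreshold(c(`1` = NA, `2` = 0.03)), 2L)
  expect_warning(r <- chooseThreshold(c(`1` = 0.8, `2` = 0.6)), "SN")
  expect_true(is.na(r))
  expect_error(chooseThreshold(c(`1` = 0.5), alpha = 1.2))
})

test_that("genes at or above the threshold are statistically common", {
  fx <- mapkClassificationFixture()
  counts <- stats::setNames(as.integer(fx$count), fx$gene)
  labels <- classifyGenes(counts, rStar = 4L)
  expect_identical(unname(labels["FGFR4"]), "SN")   # count 3
  expect_identical(unname(labels["DUSP5"]), "SC")   # count 4
  expect_identical(unname(labels["DUSP4"]), "SC")   # count 12
  expect_identical(unname(labels["ATF2"]), "SN")    # count 0
  # labels are exhaustive and exclusive
  expect_length(labels, nrow(fx))
  expect_true(all(labels %in% c("SN", "SC")))
  expect_error(classifyGenes(counts, rStar = 0L))
})

test_that("enrichment ratios are NA where the null has no mass", {
  fx <- ovarianFixture()
  p <- empiricalDistribution(fx$counts, M = 62L)
  nd <- nullFromFrequencies(fx$expectedPct / 100, M = 62L)
  enr <- enrichmentRatios(p, nd)
  expect_equal(unname(enr["0"]), 52.78 / 80.89, tolerance = 1e-3)
  expect_equal(unname(enr["2"]), 19.44 / 1.89, tolerance = 1e-3)
  expect_true(all(is.na(enr[as.character(4:6)])))
  expect_true(all(enr[!is.na(enr)] >= 0))
})

test_that("full classification wrapper ties the pieces together", {
  fx <- ovarianFixture()
  p <- empiricalDistribution(fx$counts, M = 62L)
  nd <- nullFromFrequencies(fx$expectedPct / 100, M = 62L)
  out <- classifySignature(p, nd, alpha = 0.05)
  expect_s4_class(out, "ClassificationOutcome")
  # p2(2) ~ 0.059 misses alpha; p2(3) = 0.0008/(5/36) ~ 0.006 qualifies
  expect_identical(out@rStar, 3L)
  expect_true(out@p2[out@rStar] <= 0.05)
  # SC iff count >= r*
  expect_identical(sort(names(out@labels[out@labels == "SC"])),
                   sort(names(fx$counts[fx$counts >= out@rStar])))

  forced <- classifySignature(p, nd, forcedR = 4L)
  expect_true(forced@forced)
  expect_identical(forced@rStar, 4L)
  expect_identical(unname(forced@labels[c("CCL2", "TUBB")]),
                   c("SN", "SC"))
})
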