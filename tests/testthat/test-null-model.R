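test_that("analytic null reduces to the binomial in the equal-p case", {
  nd <- analyticNull(c(2, 2), bg = 4, n0 = 10)
  expect_equal(nd@EF, c(0.25, 0.5, 0.25), tolerance = 1e-12)
  expect_identical(nd@source, "analytic")

  nd3 <- analyticNull(c(10, 20, 30), bg = 100, n0 = 5)
  expect_equal(nd3@EF[1], 0.9 * 0.8 * 0.7, tolerance = 1e-12)
  # hand enumeration over the 2^3 inclusion patterns
  expect_equal(nd3@EF, c(0.504, 0.398, 0.092, 0.006), tolerance = 1e-12)

  expect_error(analyticNull(200, bg = 100, n0 = 5), "exceeds")
})

test_that("single-reference null approaches the Bernoulli limit", {
  k <- 50; d <- 500
  nd <- simulateNull(n0 = 40, refSizes = k, bg = d, N = 3000, seed = 5)
  se <- sqrt((k / d) * (1 - k / d) / (3000 * 40))
  expect_lt(abs(nd@EF[2] - k / d), 3 * se)
  expect_lt(abs(nd@EF[1] - (1 - k / d)), 3 * se)
})

test_that("Monte-Carlo null matches the analytic oracle (property)", {
  set.seed(301)
  for (rep in 1:5) {
    M <- sample(2:8, 1)
    d <- sample(300:2000, 1)
    sizes <- sample(10:floor(d / 4), M, replace = TRUE)
    n0 <- sample(20:80, 1)
    mc <- simulateNull(n0, sizes, d, N = 400, seed = 1000 + rep)
    an <- analyticNull(sizes, d, n0)
    se <- sqrt(an@EF * (1 - an@EF) / (400 * n0))
    dev <- abs(mc@EF - an@EF)
    expect_true(all(dev <= 4 * se + 2 / (400 * n0)))
    expect_equal(sum(mc@EF), 1, tolerance = 1e-12)
    expect_equal(sum(an@EF), 1, tolerance = 1e-12)
  }
})

test_that("simulations are reproducible and extendable under one seed", {
  a <- simulateNull(30, c(5, 10, 20), 400, N = 50, seed = 99)
  b <- simulateNull(30, c(5, 10, 20), 400, N = 50, seed = 99)
  expect_identical(a@perSim, b@perSim)
  expect_identical(a@EF, b@EF)
  # growing N preserves the earlier simulations (per-sim substreams)
  big <- simulateNull(30, c(5, 10, 20), 400, N = 80, seed = 99)
  expect_identical(big@perSim[1:50, ], a@perSim)
  # a different seed gives a different draw
  expect_false(identical(simulateNull(30, c(5, 10, 20), 400, N = 50,
                                      seed = 100)@perSim, a@perSim))
})

test_that("EF equals the per-simulation histogram average exactly", {
  nd <- simulateNull(25, c(10, 30), 200, N = 40, seed = 3)
  expect_equal(nd@EF, colSums(nd@perSim) / (40 * 25), tolerance = 1e-15)
  noSims <- simulateNull(25, c(10, 30), 200, N = 40, seed = 3,
                         keepSims = FALSE)
  expect_null(noSims@perSim)
  expect_identical(noSims@EF, nd@EF)
})

test_that("saturated references match every tested gene", {
  nd <- simulateNull(10, c(50, 50, 50), 50, N = 20, seed = 2)
  expect_equal(nd@EF[4], 1, tolerance = 1e-15)
  expect_equal(analyticNull(c(50, 50, 50), 50, 10)@EF[4], 1,
               tolerance = 1e-12)
})

test_that("invalid null configurations are rejected", {
  expect_error(simulateNull(0, 10, 100, N = 5), "positive")
  expect_error(simulateNull(10, 200, 100, N = 5), "exceeds")
  expect_error(simulateNull(10, 10, 100, N = 0), "at least 1")
})

test_that("background family holds sizes fixed and spans the mean counts", {
  sizes <- seq(20, 200, by = 20)
  fam <- backgroundFamily(100, sizes, c(20000, 10000, 5000, 1000, 500),
                          N = 50, seed = 17)
  expect_named(fam, c("20000", "10000", "5000", "1000", "500"))
  means <- vapply(fam, function(nd) sum((0:nd@M) * nd@EF), numeric(1))
  expected <- 1100 / c(20000, 10000, 5000, 1000, 500)
  # Monte-Carlo means concentrate tightly around sum(p_i) = 1100/|D|
  for (i in seq_along(means))
    expect_equal(unname(means[i]), expected[i], tolerance = 0.15)
  # analytic means are exact
  famA <- backgroundFamily(100, sizes, c(20000, 500), method = "analytic")
  expect_equal(sum((0:10) * famA[["20000"]]@EF), 1100 / 20000,
               tolerance = 1e-10)
  expect_equal(sum((0:10) * famA[["500"]]@EF), 1100 / 500,
               tolerance = 1e-10)

  single <- backgroundFamily(30, c(10, 20), 300, N = 25, seed = 4)
  expect_identical(single[["300"]]@EF,
                   simulateNull(30, c(10, 20), 300, N = 25, seed = 4)@EF)
  expect_length(backgroundFamily(30, c(10, 20), integer(), N = 5), 0L)
})

test_that("shrinking the background shifts the analytic null rightward", {
  sizes <- seq(20, 200, by = 20)
  fam <- backgroundFamily(100, sizes, c(20000, 10000, 5000, 1000, 500),
                          method = "analytic")
  tails <- vapply(fam, function(nd) as.numeric(reverseCumulative(nd)),
                  numeric(11))
  for (r in 2:11)   # every r >= 1: tail mass grows as |D| shrinks
    expect_true(all(diff(tails[r, ]) >= -1e-15))
})

test_that("null TSV export carries provenance", {
  nd <- simulateNull(20, c(5, 10), 100, N = 30, seed = 8)
  f <- tempfile(fileext = ".tsv")
  df <- writeNullDistribution(nd, f)
  expect_true(file.exists(f) && file.exists(paste0(f, ".json")))
  prov <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(prov$seed, 8)
  expect_equal(prov$N, 30)
  expect_identical(prov$source, "monte_carlo")
  expect_equal(sum(df$EF), 1, tolerance = 1e-12)
})
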