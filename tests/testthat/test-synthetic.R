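test_that("synthetic backgrounds are deterministic pseudo-symbol universes", {
  bg <- makeBackground(20000)
  expect_identical(setSize(bg), 20000L)
  expect_identical(geneIds(makeBackground(20000)), geneIds(bg))
  expect_identical(geneIds(makeBackground(1)), "G000001")
  expect_error(makeBackground(0), "at least 1")
})

test_that("reference collections are reproducible without-replacement draws", {
  bg <- makeBackground(1000)
  sizes <- seq(20L, 200L, by = 20L)
  refs <- makeReferenceCollection(sizes, bg, seed = 11)
  expect_length(refs, 10L)
  expect_identical(vapply(refs, setSize, integer(1)),
                   stats::setNames(sizes, names(refs)))
  for (r in refs) expect_true(all(geneIds(r) %in% geneIds(bg)))
  refs2 <- makeReferenceCollection(sizes, bg, seed = 11)
  expect_identical(lapply(refs, geneIds), lapply(refs2, geneIds))

  expect_length(makeReferenceCollection(integer(), bg), 0L)
  full <- makeReferenceCollection(1000L, bg, seed = 2)
  expect_setequal(geneIds(full[[1]]), geneIds(bg))
})

test_that("planted structure is verifiable by co-occurrence counting", {
  sc <- syntheticScenario(bgSize = 2000, n0 = 100,
                          refSizes = seq(20, 200, 20),
                          nCommon = 10, plantDepth = 5, nNovel = 10,
                          seed = 21)
  bg <- makeBackground(sc@bgSize)
  refs <- makeReferenceCollection(sc@refSizes, bg, sc@seed)
  planted <- makePlantedTgss(sc, bg, refs)
  expect_identical(setSize(planted$tgss), 100L)

  counts <- countCooccurrences(planted$tgss, planted$refs)
  common <- names(planted$truth[planted$truth == "SC"])
  novel <- names(planted$truth[planted$truth == "SN"])
  expect_length(common, 10L)
  expect_length(novel, 10L)
  expect_true(all(counts[common] >= 5L))
  expect_identical(unname(counts[novel]), rep(0L, 10))

  # references grew by at most nCommon and kept their other members
  for (i in seq_along(refs)) {
    expect_true(all(geneIds(refs[[i]]) %in% geneIds(planted$refs[[i]])))
    expect_lte(setSize(planted$refs[[i]]), setSize(refs[[i]]) + 10L)
  }
})

test_that("plant depth zero guarantees nothing and labels all truth SN", {
  sc <- syntheticScenario(bgSize = 500, n0 = 30, refSizes = c(10, 20),
                          nCommon = 5, plantDepth = 0, nNovel = 3,
                          seed = 2)
  bg <- makeBackground(sc@bgSize)
  refs <- makeReferenceCollection(sc@refSizes, bg, sc@seed)
  planted <- makePlantedTgss(sc, bg, refs)
  expect_true(all(planted$truth == "SN"))
  # references untouched
  expect_identical(lapply(planted$refs, geneIds), lapply(refs, geneIds))
})

test_that("infeasible planting requests fail loudly", {
  bg <- makeBackground(100)
  # a depth beyond the declared references is rejected at construction
  expect_error(syntheticScenario(bgSize = 100, n0 = 20, refSizes = c(10, 10),
                                 nCommon = 2, plantDepth = 5, nNovel = 0,
                                 seed = 1),
               "plantDepth")
  # a valid scenario handed too few actual references is rejected too
  sc <- syntheticScenario(bgSize = 100, n0 = 20,
                          refSizes = rep(10L, 5), nCommon = 2,
                          plantDepth = 5, nNovel = 0, seed = 1)
  refs <- makeReferenceCollection(c(10, 10), bg, 1)
  expect_error(makePlantedTgss(sc, bg, refs), "not enough references")

  expect_error(syntheticScenario(bgSize = 100, n0 = 10, refSizes = 20,
                                 nCommon = 8, plantDepth = 1, nNovel = 8),
               "exceed")
})

test_that("scenario files round-trip through the standard formats", {
  sc <- syntheticScenario(bgSize = 400, n0 = 40, refSizes = c(15, 30, 45),
                          nCommon = 4, plantDepth = 2, nNovel = 4,
                          seed = 33)
  dir <- file.path(tempfile(), "scenario")
  files <- writeSyntheticScenario(sc, dir)
  bg <- loadBackground(files$background)
  expect_identical(setSize(bg), 400L)
  refs <- readGmt(files$refs)
  expect_length(refs, 3L)
  tg <- readSymbolList(files$tgss, "tgss")
  expect_identical(setSize(tg), 40L)
  expect_setequal(geneIds(tg), geneIds(files$objects$tgss))
  truth <- read.delim(files$truth)
  expect_identical(nrow(truth), 8L)
  # counts from the files match the in-memory construction
  expect_identical(
    countCooccurrences(tg, refs)[truth$gene],
    countCooccurrences(files$objects$tgss, files$objects$refs)[truth$gene])
})
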