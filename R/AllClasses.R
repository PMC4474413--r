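#' @import methods
NULL

setClassUnion("integerOrNA", c("integer", "logical"))
setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' GeneSet: a named, deduplicated collection of gene symbols
#'
#' Holds one gene signature: a short unique identifier, a free-text label,
#' and an ordered vector of normalized (trimmed, upper-cased) gene symbols
#' with no duplicates.
#'
#' @slot id Short unique identifier.
#' @slot label Free-text description.
#' @slot symbols Character vector of normalized gene symbols.
#' @slot metadata List of provenance items (e.g. a [FilterReport] recorded
#'   by [restrictToBackground()], or an `empty` flag).
#'
#' @seealso [GeneSet()], [readGmt()], [readSymbolList()]
#' @export
setClass("GeneSet",
  representation(
    id = "character",
    label = "character",
    symbols = "character",
    metadata = "list"
  ),
  prototype(label = "", metadata = list())
)

setValidity("GeneSet", function(object) {
  msg <- character()
  if (length(object@id) != 1L || !nzchar(object@id))
    msg <- c(msg, "'id' must be a single non-empty string")
  if (anyDuplicated(object@symbols))
    msg <- c(msg, "symbols must be unique after normalization")
  if (length(object@symbols) &&
      (any(!nzchar(object@symbols)) || any(grepl("\\s", object@symbols))))
    msg <- c(msg, "symbols must be non-empty and contain no whitespace")
  if (length(msg)) msg else TRUE
})

#' BackgroundSpace: the biomarker universe
#'
#' The set of admissible gene symbols (e.g. all RefGene symbols, or the
#' genes represented on a platform) from which random reference sets are
#' sampled. Every signature admitted into an analysis is first restricted
#' to this universe.
#'
#' @slot symbols Character vector of normalized, unique gene symbols.
#'
#' @seealso [loadBackground()], [makeBackground()]
#' @export
setClass("BackgroundSpace", representation(symbols = "character"))

setValidity("BackgroundSpace", function(object) {
  msg <- character()
  if (!length(object@symbols))
    msg <- c(msg, "background space must be non-empty")
  if (anyDuplicated(object@symbols))
    msg <- c(msg, "background symbols must be unique")
  if (length(object@symbols) &&
      (any(!nzchar(object@symbols)) || any(grepl("\\s", object@symbols))))
    msg <- c(msg, "background symbols must be non-empty, whitespace-free")
  if (length(msg)) msg else TRUE
})

#' FilterReport: accounting of a symbol-filtering step
#'
#' Records, for one filtering operation, how many raw symbols were kept and
#' which were dropped because they were absent from the background space or
#' were duplicates. `kept + length(droppedUnmapped) + length(droppedDuplicate)`
#' always equals the raw input length.
#'
#' @slot kept Number of symbols retained.
#' @slot droppedUnmapped Symbols absent from the background.
#' @slot droppedDuplicate Symbols removed as duplicate occurrences.
#' @slot rawLength Number of raw input symbols.
#'
#' @export
setClass("FilterReport",
  representation(
    kept = "integer",
    droppedUnmapped = "character",
    droppedDuplicate = "character",
    rawLength = "integer"
  )
)

setValidity("FilterReport", function(object) {
  tot <- object@kept + length(object@droppedUnmapped) +
    length(object@droppedDuplicate)
  if (tot != object@rawLength)
    return("kept + dropped symbols must account for every raw symbol")
  TRUE
})

#' CooccurrenceProfile: empirical co-occurrence frequency distribution
#'
#' For a tested signature of size `n0` compared against `M` reference
#' signatures: per-gene co-occurrence counts, the histogram `O_m`
#' (number of tested genes found in exactly `m` references, m = 0..M) and
#' its normalization `F_m = O_m / n0`.
#'
#' @slot counts Named integer vector, one count in `[0, M]` per tested gene.
#' @slot M Number of reference signatures compared against.
#' @slot n0 Size of the tested signature.
#' @slot histogram Integer vector `O_m`, m = 0..M.
#' @slot normalized Numeric vector `F_m`, sums to 1.
#'
#' @seealso [countCooccurrences()], [empiricalDistribution()]
#' @export
setClass("CooccurrenceProfile",
  representation(
    counts = "integer",
    M = "integer",
    n0 = "integer",
    histogram = "integer",
    normalized = "numeric"
  )
)

setValidity("CooccurrenceProfile", function(object) {
  msg <- character()
  if (length(object@histogram) != object@M + 1L)
    msg <- c(msg, "histogram must cover m = 0..M")
  if (sum(object@histogram) != object@n0)
    msg <- c(msg, "histogram must sum to the tested-set size n0")
  if (object@n0 > 0L && abs(sum(object@normalized) - 1) > 1e-12)
    msg <- c(msg, "normalized frequencies must sum to 1")
  if (length(object@counts) &&
      (min(object@counts) < 0L || max(object@counts) > object@M))
    msg <- c(msg, "per-gene counts must lie in [0, M]")
  if (any(tabulate(object@counts + 1L, nbins = object@M + 1L) !=
          object@histogram))
    msg <- c(msg, "histogram must tabulate the per-gene counts")
  if (length(msg)) msg else TRUE
})

#' NullDistribution: expected background co-occurrence distribution
#'
#' The expected normalized frequencies `EF_m` (m = 0..M) of tested-gene
#' co-occurrence counts under size-matched random sampling of the reference
#' signatures from the background space, obtained either by Monte-Carlo
#' simulation (`source = "monte_carlo"`) or from the exact Poisson-binomial
#' distribution (`source = "analytic"`).
#'
#' @slot N Number of Monte-Carlo simulations (0 for the analytic source).
#' @slot seed Master RNG seed (NA for the analytic source).
#' @slot M Number of reference signatures.
#' @slot n0 Tested-signature size used.
#' @slot refSizes Sizes of the reference signatures.
#' @slot bgSize Size of the background space.
#' @slot EF Numeric vector `EF_m`, m = 0..M, sums to 1.
#' @slot perSim Optional `N x (M+1)` integer matrix of per-simulation
#'   histograms `RO_{j,m}`, or NULL when not retained.
#' @slot source `"monte_carlo"` or `"analytic"`.
#'
#' @seealso [simulateNull()], [analyticNull()], [backgroundFamily()]
#' @export
setClass("NullDistribution",
  representation(
    N = "integer",
    seed = "integerOrNA",
    M = "integer",
    n0 = "integer",
    refSizes = "integer",
    bgSize = "integer",
    EF = "numeric",
    perSim = "matrixOrNULL",
    source = "character"
  ),
  prototype(perSim = NULL)
)

setValidity("NullDistribution", function(object) {
  msg <- character()
  if (!object@source %in% c("monte_carlo", "analytic"))
    msg <- c(msg, "source must be 'monte_carlo' or 'analytic'")
  if (length(object@EF) != object@M + 1L)
    msg <- c(msg, "EF must cover m = 0..M")
  if (any(object@EF < 0))
    msg <- c(msg, "EF must be non-negative")
  if (abs(sum(object@EF) - 1) > 1e-12)
    msg <- c(msg, "EF must sum to 1")
  if (length(object@refSizes) != object@M)
    msg <- c(msg, "refSizes must have length M")
  if (!is.null(object@perSim)) {
    if (!identical(dim(object@perSim),
                   c(object@N, object@M + 1L)) &&
        !identical(dim(object@perSim),
                   as.integer(c(object@N, object@M + 1L))))
      msg <- c(msg, "perSim must be an N x (M+1) matrix")
    else {
      ef <- colSums(object@perSim) / (object@N * object@n0)
      if (max(abs(ef - object@EF)) > 1e-12)
        msg <- c(msg, "EF must equal colSums(perSim)/(N*n0)")
    }
  }
  if (length(msg)) msg else TRUE
})

#' ClassificationOutcome: SN/SC dichotomization result
#'
#' Captures the comparison of the empirical and null distributions: the
#' Kolmogorov-Smirnov statistic on the reverse cumulative curves and its
#' (approximate, discrete-data) p-value `p1`; the per-threshold tail-ratio
#' p-values `p2(r)`; the chosen threshold `r*`; per-gene SN/SC labels; and
#' per-level enrichment ratios `F_m / EF_m`.
#'
#' @slot ksStatistic Sup distance between the reverse cumulative curves.
#' @slot p1 Two-sided KS p-value (approximate on discrete support).
#' @slot p2 Named numeric vector of threshold p-values for r = 1..M (NA
#'   where the empirical tail is empty).
#' @slot alpha Significance level used by the threshold search.
#' @slot rStar Chosen threshold, or NA when no threshold qualifies.
#' @slot labels Named character vector, `"SN"` or `"SC"` per tested gene.
#' @slot enrichment Named numeric vector `F_m/EF_m` (NA where `EF_m` = 0).
#' @slot forced TRUE when `rStar` was supplied by the user rather than
#'   selected from `p2`.
#'
#' @seealso [classifySignature()], [ksCompare()], [thresholdPvalues()]
#' @export
setClass("ClassificationOutcome",
  representation(
    ksStatistic = "numeric",
    p1 = "numeric",
    p2 = "numeric",
    alpha = "numeric",
    rStar = "integerOrNA",
    labels = "character",
    enrichment = "numeric",
    forced = "logical"
  ),
  prototype(forced = FALSE)
)

setValidity("ClassificationOutcome", function(object) {
  msg <- character()
  if (object@ksStatistic < -1e-12 || object@ksStatistic > 1 + 1e-12)
    msg <- c(msg, "ksStatistic must lie in [0, 1]")
  p2 <- object@p2[!is.na(object@p2)]
  if (length(p2) && (any(p2 < 0) || any(p2 > 1)))
    msg <- c(msg, "p2 values must lie in [0, 1] or be NA")
  if (length(object@labels) && !all(object@labels %in% c("SN", "SC")))
    msg <- c(msg, "labels must be 'SN' or 'SC'")
  if (length(msg)) msg else TRUE
})

#' CurveFit: Weibull or sigmoid fit to a null reverse cumulative curve
#'
#' @slot family `"weibull"` or `"sigmoid"`.
#' @slot params Named parameter vector (weibull: `a`, `lambda`, `k`;
#'   sigmoid: `a`, `x0`, `s`).
#' @slot sse Sum of squared residuals at the optimum.
#' @slot fitted Fitted values on the support m = 0..M.
#' @slot data The reverse cumulative values that were fitted.
#' @slot converged Optimizer convergence flag.
#' @slot wellConstrained FALSE when the curve has too few interior points
#'   to constrain three parameters (e.g. all null mass at m = 0).
#'
#' @seealso [fitCurve()], [compareFits()]
#' @export
setClass("CurveFit",
  representation(
    family = "character",
    params = "numeric",
    sse = "numeric",
    fitted = "numeric",
    data = "numeric",
    converged = "logical",
    wellConstrained = "logical"
  )
)

setValidity("CurveFit", function(object) {
  msg <- character()
  if (!object@family %in% c("weibull", "sigmoid"))
    msg <- c(msg, "family must be 'weibull' or 'sigmoid'")
  if (object@sse < 0)
    msg <- c(msg, "sse must be non-negative")
  if (length(object@fitted) != length(object@data))
    msg <- c(msg, "fitted values must match the data length")
  if (length(msg)) msg else TRUE
})

#' SyntheticScenario: parameters of a planted-signal benchmark
#'
#' Describes one synthetic study: a background of `bgSize` pseudo-symbols,
#' `M = length(refSizes)` random reference signatures, and a tested
#' signature of size `n0` in which `nCommon` genes are planted into
#' `plantDepth` distinct references (guaranteed statistically common) and
#' `nNovel` genes are guaranteed absent from every reference.
#'
#' @slot bgSize Background-space size.
#' @slot n0 Tested-signature size.
#' @slot refSizes Reference-signature sizes.
#' @slot nCommon Number of planted common genes.
#' @slot plantDepth Number of references each planted common gene joins.
#' @slot nNovel Number of planted never-occurring genes.
#' @slot seed Integer RNG seed.
#'
#' @seealso [syntheticScenario()], [makePlantedTgss()]
#' @export
setClass("SyntheticScenario",
  representation(
    bgSize = "integer",
    n0 = "integer",
    refSizes = "integer",
    nCommon = "integer",
    plantDepth = "integer",
    nNovel = "integer",
    seed = "integer"
  )
)

setValidity("SyntheticScenario", function(object) {
  msg <- character()
  if (object@nCommon + object@nNovel > object@n0)
    msg <- c(msg, "nCommon + nNovel must not exceed n0")
  if (object@plantDepth > length(object@refSizes))
    msg <- c(msg, "plantDepth must not exceed the number of references")
  if (any(object@refSizes > object@bgSize))
    msg <- c(msg, "reference sizes must not exceed the background size")
  if (object@n0 > object@bgSize)
    msg <- c(msg, "n0 must not exceed the background size")
  if (length(msg)) msg else TRUE
})

#' AnalysisConfig: configuration of an end-to-end run
#'
#' @slot tgss Path to the tested signature (plain symbol list, or GMT with
#'   a single record).
#' @slot refs Path to the reference collection: a GMT file or a directory
#'   of plain symbol lists.
#' @slot background Path to the background symbol list.
#' @slot outdir Output directory.
#' @slot N Number of null simulations.
#' @slot seed Master RNG seed.
#' @slot alpha Significance level for the threshold search.
#' @slot forcedR Optional user-forced threshold (NA to search).
#' @slot fitFamilies Subset of `c("weibull", "sigmoid")` to fit (may be
#'   empty).
#' @slot precision Decimal places for rendered percentages.
#' @slot keepSims Retain the per-simulation histogram matrix.
#'
#' @seealso [analysisConfig()], [runAnalysis()]
#' @export
setClass("AnalysisConfig",
  representation(
    tgss = "character",
    refs = "character",
    background = "character",
    outdir = "character",
    N = "integer",
    seed = "integer",
    alpha = "numeric",
    forcedR = "integerOrNA",
    fitFamilies = "character",
    precision = "integer",
    keepSims = "logical"
  )
)

setValidity("AnalysisConfig", function(object) {
  msg <- character()
  if (object@N < 1L)
    msg <- c(msg, "N must be at least 1")
  if (object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "alpha must lie in (0, 1)")
  if (!all(object@fitFamilies %in% c("weibull", "sigmoid")))
    msg <- c(msg, "fitFamilies must be a subset of {weibull, sigmoid}")
  if (length(msg)) msg else TRUE
})
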