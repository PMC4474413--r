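#' @include AllClasses.R
NULL

#' Gene symbols of an object
#'
#' @param x A [GeneSet] or [BackgroundSpace].
#' @return Character vector of normalized gene symbols.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' Identifier of a gene set
#'
#' @param x A [GeneSet].
#' @return The set identifier.
#' @export
setGeneric("setId", function(x) standardGeneric("setId"))

#' Size of a set-like object
#'
#' @param x A [GeneSet], [BackgroundSpace] or [CooccurrenceProfile].
#' @return Integer: number of member symbols (for a profile, the tested-set
#'   size n0).
#' @export
setGeneric("setSize", function(x) standardGeneric("setSize"))

#' Per-gene co-occurrence counts
#'
#' @param x A [CooccurrenceProfile].
#' @return Named integer vector of counts.
#' @export
setGeneric("geneCounts", function(x) standardGeneric("geneCounts"))

#' Normalized frequencies of a distribution over m = 0..M
#'
#' @param x A [CooccurrenceProfile] (empirical `F_m`) or
#'   [NullDistribution] (expected `EF_m`).
#' @return Numeric vector summing to 1, named by m.
#' @export
setGeneric("frequencies", function(x) standardGeneric("frequencies"))

#' Reverse cumulative frequency curve
#'
#' Tail sums `R(r) = sum_{m >= r} f_m` of a normalized frequency vector.
#' `R(0) = 1`, `R` is non-increasing, and the tail beyond the support is 0.
#'
#' @param x A [CooccurrenceProfile], [NullDistribution], or a bare numeric
#'   frequency vector over m = 0..M.
#' @return Numeric vector of tail sums for r = 0..M, named by r.
#' @export
setGeneric("reverseCumulative",
           function(x) standardGeneric("reverseCumulative"))

setMethod("geneIds", "GeneSet", function(x) x@symbols)
setMethod("geneIds", "BackgroundSpace", function(x) x@symbols)
setMethod("setId", "GeneSet", function(x) x@id)
setMethod("setSize", "GeneSet", function(x) length(x@symbols))
setMethod("setSize", "BackgroundSpace", function(x) length(x@symbols))
setMethod("setSize", "CooccurrenceProfile", function(x) x@n0)
setMethod("geneCounts", "CooccurrenceProfile", function(x) x@counts)

setMethod("frequencies", "CooccurrenceProfile", function(x) {
  stats::setNames(x@normalized, 0:x@M)
})
setMethod("frequencies", "NullDistribution", function(x) {
  stats::setNames(x@EF, 0:x@M)
})

setMethod("reverseCumulative", "numeric", function(x) {
  stats::setNames(rev(cumsum(rev(x))), seq_along(x) - 1L)
})
setMethod("reverseCumulative", "CooccurrenceProfile", function(x) {
  reverseCumulative(x@normalized)
})
setMethod("reverseCumulative", "NullDistribution", function(x) {
  reverseCumulative(x@EF)
})

setMethod("show", "GeneSet", function(object) {
  cat(sprintf("GeneSet '%s' (%d symbols)\n", object@id,
              length(object@symbols)))
  if (nzchar(object@label)) cat("  label:", object@label, "\n")
  syms <- object@symbols
  if (length(syms) > 6L) syms <- c(syms[1:6], "...")
  cat("  symbols:", paste(syms, collapse = ", "), "\n")
})

setMethod("show", "BackgroundSpace", function(object) {
  cat(sprintf("BackgroundSpace of %d symbols\n", length(object@symbols)))
})

setMethod("show", "FilterReport", function(object) {
  cat(sprintf(
    "FilterReport: %d/%d kept (%d unmapped, %d duplicate dropped)\n",
    object@kept, object@rawLength, length(object@droppedUnmapped),
    length(object@droppedDuplicate)))
})

setMethod("show", "CooccurrenceProfile", function(object) {
  cat(sprintf(
    "CooccurrenceProfile: %d tested genes vs %d reference signatures\n",
    object@n0, object@M))
  occ <- which(object@histogram > 0L) - 1L
  cat("  occupied levels m:", paste(occ, collapse = ", "), "\n")
})

setMethod("show", "NullDistribution", function(object) {
  if (object@source == "monte_carlo")
    cat(sprintf(
      "NullDistribution (Monte-Carlo, N = %d, seed = %s)\n",
      object@N, object@seed))
  else
    cat("NullDistribution (analytic Poisson-binomial)\n")
  cat(sprintf("  M = %d references, |D| = %d, n0 = %d\n",
              object@M, object@bgSize, object@n0))
  cat(sprintf("  EF_0 = %.4f, mean match count = %.4f\n", object@EF[1],
              sum((0:object@M) * object@EF)))
})

setMethod("show", "ClassificationOutcome", function(object) {
  cat("ClassificationOutcome\n")
  cat(sprintf("  KS statistic = %.4f, p1 = %.3g (approximate, discrete)\n",
              object@ksStatistic, object@p1))
  if (is.na(object@rStar))
    cat("  r* = NA (no threshold qualified); all genes SN\n")
  else
    cat(sprintf("  r* = %d%s, alpha = %g\n", object@rStar,
                if (object@forced) " (forced)" else "", object@alpha))
  tab <- table(factor(object@labels, levels = c("SN", "SC")))
  cat(sprintf("  labels: %d SN, %d SC of %d genes\n", tab[["SN"]],
              tab[["SC"]], length(object@labels)))
})

setMethod("show", "CurveFit", function(object) {
  cat(sprintf("CurveFit (%s): sse = %.4g, converged = %s%s\n",
              object@family, object@sse, object@converged,
              if (object@wellConstrained) "" else ", poorly constrained"))
  cat("  params:", paste(sprintf("%s = %.4g", names(object@params),
                                 object@params), collapse = ", "), "\n")
})

setMethod("show", "SyntheticScenario", function(object) {
  cat(sprintf(
    "SyntheticScenario: |D| = %d, n0 = %d, M = %d, seed = %d\n",
    object@bgSize, object@n0, length(object@refSizes), object@seed))
  cat(sprintf("  planted: %d common (depth %d), %d novel\n",
              object@nCommon, object@plantDepth, object@nNovel))
})
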