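#' @include AllClasses.R
NULL

# Asymptotic two-sided Kolmogorov p-value: 2 * sum (-1)^{k-1} exp(-2k^2 x^2)
kolmogorovPvalue <- function(d, nEff) {
  if (d <= 0) return(1)
  lambda <- sqrt(nEff) * d
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(1, max(0, p))
}

checkSharedM <- function(profile, null) {
  stopifnot(is(profile, "CooccurrenceProfile"), is(null, "NullDistribution"))
  if (profile@M != null@M)
    stop("profile and null distribution disagree on M (",
         profile@M, " vs ", null@M, ")", call. = FALSE)
}

#' Kolmogorov-Smirnov comparison of empirical and null distributions
#'
#' The statistic is the sup distance `max_r |R_F(r) - R_EF(r)|` between the
#' reverse cumulative curves of the empirical and expected frequencies over
#' r = 0..M. The p-value `p1` is the asymptotic two-sided two-sample KS
#' p-value with effective sample sizes `n0` (tested genes) and `N * n0`
#' (pooled simulated genes; the analytic source is treated as an infinite
#' second sample). On a discrete support with heavy ties the classical
#' p-value is conservative, so `p1` is flagged approximate.
#'
#' @param profile A [CooccurrenceProfile].
#' @param null A [NullDistribution] over the same M.
#' @return A list: `statistic`, `p1`, and `note` ("approximate (discrete
#'   data)").
#' @export
ksCompare <- function(profile, null) {
  checkSharedM(profile, null)
  d <- max(abs(reverseCumulative(profile) - reverseCumulative(null)))
  n <- profile@n0
  m <- if (null@source == "monte_carlo") null@N * null@n0 else Inf
  nEff <- if (is.finite(m)) n * m / (n + m) else n
  list(statistic = d, p1 = kolmogorovPvalue(d, nEff),
       note = "approximate (discrete data)")
}

#' Per-threshold dichotomization p-values
#'
#' For each candidate threshold r >= 1, the significance of dichotomizing
#' at r is the ratio of the expected to the actual tail mass at r:
#' `p2(r) = min(1, R_EF(r) / R_F(r))`, where `R` is the reverse cumulative
#' (tail from r inclusive). When no tested gene reaches level r
#' (`R_F(r) = 0`) the ratio is undefined and reported NA; an empty
#' expected tail over a populated actual tail gives p2 = 0. Computed on
#' unrounded frequencies; rounding happens only at report time.
#'
#' @inheritParams ksCompare
#' @return Named numeric vector `p2(r)` for r = 1..M.
#' @export
thresholdPvalues <- function(profile, null) {
  checkSharedM(profile, null)
  rf <- reverseCumulative(profile)[-1]   # r = 1..M
  re <- reverseCumulative(null)[-1]
  p2 <- ifelse(rf > 0, pmin(1, re / rf), NA_real_)
  stats::setNames(p2, seq_len(profile@M))
}

#' Choose the co-occurrence threshold r*
#'
#' The chosen threshold is the smallest r whose dichotomization p-value is
#' defined and at most `alpha`. When no threshold qualifies, NA is
#' returned (all genes will be labelled statistically novel) with a
#' warning.
#'
#' @param p2 Named vector from [thresholdPvalues()].
#' @param alpha Significance level in (0, 1); default 0.05.
#' @return Integer threshold, or NA.
#' @examples
#' chooseThreshold(c(`1` = 0.8, `2` = 0.06, `3` = 0.004))  # 3
#' @export
chooseThreshold <- function(p2, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  ok <- which(!is.na(p2) & p2 <= alpha)
  if (!length(ok)) {
    warning("no threshold reaches alpha = ", alpha,
            "; all genes will be labelled SN", call. = FALSE)
    return(NA_integer_)
  }
  r <- if (is.null(names(p2))) min(ok) else as.integer(names(p2)[min(ok)])
  as.integer(r)
}

#' Label tested genes as statistically novel or common
#'
#' A gene is statistically common (SC) when its co-occurrence count is at
#' least the threshold `rStar`, statistically novel (SN) otherwise. The
#' inclusive convention (count >= r*) means a "minimum threshold of r*"
#' reference signatures: genes recorded r* or more times are treated as
#' sufficiently well recorded common biomarkers.
#'
#' @param counts Named integer vector of per-gene co-occurrence counts.
#' @param rStar Integer threshold >= 1.
#' @return Named character vector of `"SN"` / `"SC"` labels.
#' @examples
#' classifyGenes(c(FGFR4 = 3L, DUSP5 = 4L, DUSP4 = 12L), rStar = 4L)
#' @export
classifyGenes <- function(counts, rStar) {
  rStar <- as.integer(rStar)
  stopifnot(length(rStar) == 1L, !is.na(rStar), rStar >= 1L)
  stats::setNames(ifelse(counts >= rStar, "SC", "SN"), names(counts))
}

#' Per-level enrichment of actual over expected frequency
#'
#' The ratio `F_m / EF_m` for each co-occurrence level m = 0..M. Where the
#' null assigns zero mass (`EF_m = 0`) the ratio is undefined and reported
#' NA ("Not applicable" in rendered tables), never silently zero or
#' infinite.
#'
#' @inheritParams ksCompare
#' @return Named numeric vector over m = 0..M.
#' @export
enrichmentRatios <- function(profile, null) {
  checkSharedM(profile, null)
  f <- profile@normalized
  ef <- null@EF
  stats::setNames(ifelse(ef > 0, f / ef, NA_real_), 0:profile@M)
}

#' Full SN/SC classification of a tested signature
#'
#' Convenience wrapper running [ksCompare()], [thresholdPvalues()],
#' [chooseThreshold()] (unless a threshold is forced), [classifyGenes()]
#' and [enrichmentRatios()], returning a single [ClassificationOutcome].
#' When no threshold qualifies every gene is labelled SN.
#'
#' @inheritParams ksCompare
#' @param alpha Significance level for the threshold search.
#' @param forcedR Optional user-imposed threshold bypassing the search.
#' @return A [ClassificationOutcome].
#' @export
classifySignature <- function(profile, null, alpha = 0.05,
                              forcedR = NA_integer_) {
  ks <- ksCompare(profile, null)
  p2 <- thresholdPvalues(profile, null)
  forced <- !is.na(forcedR)
  rStar <- if (forced) as.integer(forcedR)
           else chooseThreshold(p2, alpha)
  labels <- if (is.na(rStar))
    stats::setNames(rep("SN", length(profile@counts)),
                    names(profile@counts))
  else classifyGenes(profile@counts, rStar)
  new("ClassificationOutcome", ksStatistic = ks$statistic, p1 = ks$p1,
      p2 = p2, alpha = alpha, rStar = rStar, labels = labels,
      enrichment = enrichmentRatios(profile, null), forced = forced)
}
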