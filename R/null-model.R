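#' @include AllClasses.R
NULL

# Deterministic per-simulation substreams: the master seed fixes a vector
# of sub-seeds, so growing N extends the sequence without changing earlier
# simulations.
simSeeds <- function(seed, N) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, N)
}

#' Monte-Carlo null distribution of co-occurrence counts
#'
#' Simulates the background frequency distribution (BFD): in each of `N`
#' simulations, `M` random reference sets are drawn, each a uniform
#' without-replacement sample of its actual size from the background space;
#' the sets are mutually independent, so a gene may fall into several of
#' them. Per-gene match counts against a fixed tested set of size `n0` are
#' histogrammed and averaged over simulations into the expected normalized
#' frequencies `EF_m = sum_j RO_{j,m} / (N * n0)`.
#'
#' By exchangeability only the tested-set size matters, so gene indices
#' `1..n0` stand in for the tested symbols.
#'
#' @param n0 Tested-signature size.
#' @param refSizes Integer vector of the M reference-signature sizes.
#' @param bg A [BackgroundSpace], or a single integer giving its size.
#' @param N Number of simulations (default 100; usually enough to resolve
#'   the structure and shape of the null, with N = 1000 or 10000 available
#'   for extra tail sensitivity).
#' @param seed Master RNG seed.
#' @param keepSims Retain the `N x (M+1)` per-simulation histogram matrix
#'   (default: only for N <= 1000).
#' @return A [NullDistribution] with `source = "monte_carlo"`.
#' @seealso [analyticNull()] for the exact Poisson-binomial counterpart.
#' @export
simulateNull <- function(n0, refSizes, bg, N = 100L, seed = 1L,
                         keepSims = N <= 1000L) {
  bgSize <- if (is(bg, "BackgroundSpace")) setSize(bg) else as.integer(bg)
  n0 <- as.integer(n0)
  refSizes <- as.integer(refSizes)
  N <- as.integer(N)
  if (n0 < 1L) stop("tested-set size n0 must be positive", call. = FALSE)
  if (n0 > bgSize) stop("n0 exceeds the background size", call. = FALSE)
  if (any(refSizes < 1L))
    stop("reference sizes must be positive", call. = FALSE)
  if (any(refSizes > bgSize))
    stop("reference size exceeds the background size (",
         max(refSizes), " > ", bgSize, ")", call. = FALSE)
  if (N < 1L) stop("N must be at least 1", call. = FALSE)

  M <- length(refSizes)
  seeds <- simSeeds(seed, N)
  perSim <- matrix(0L, nrow = N, ncol = M + 1L)
  for (j in seq_len(N)) {
    set.seed(seeds[j])
    counts <- integer(n0)
    for (sz in refSizes) {
      idx <- sample.int(bgSize, sz)
      hit <- idx[idx <= n0]
      counts[hit] <- counts[hit] + 1L
    }
    perSim[j, ] <- tabulate(counts + 1L, nbins = M + 1L)
  }
  EF <- colSums(perSim) / (N * n0)
  new("NullDistribution", N = N, seed = as.integer(seed), M = M, n0 = n0,
      refSizes = refSizes, bgSize = bgSize, EF = EF,
      perSim = if (keepSims) perSim else NULL, source = "monte_carlo")
}

#' Exact (Poisson-binomial) null distribution
#'
#' Under independent without-replacement sampling of the reference sets,
#' a fixed tested gene lands in reference set i with probability
#' `p_i = |AS_i| / |D|`, independently across sets; its match count is
#' therefore Poisson-binomial. The expected normalized frequencies equal
#' that probability mass function exactly (by linearity over the tested
#' genes), computed by the standard O(M^2) convolution recursion.
#'
#' @inheritParams simulateNull
#' @return A [NullDistribution] with `source = "analytic"`, `N = 0` and
#'   no seed.
#' @examples
#' analyticNull(c(2, 2), bg = 4, n0 = 10)  # binomial p = 0.5: 1/4,1/2,1/4
#' @export
analyticNull <- function(refSizes, bg, n0) {
  bgSize <- if (is(bg, "BackgroundSpace")) setSize(bg) else as.integer(bg)
  refSizes <- as.integer(refSizes)
  n0 <- as.integer(n0)
  if (n0 < 1L) stop("tested-set size n0 must be positive", call. = FALSE)
  p <- refSizes / bgSize
  if (any(p > 1))
    stop("reference size exceeds the background size", call. = FALSE)
  if (any(p < 0)) stop("negative reference size", call. = FALSE)
  pmf <- 1
  for (pi in p) pmf <- c(pmf * (1 - pi), 0) + c(0, pmf * pi)
  pmf <- pmf / sum(pmf)  # guard rounding drift
  new("NullDistribution", N = 0L, seed = NA, M = length(p), n0 = n0,
      refSizes = refSizes, bgSize = bgSize, EF = pmf, perSim = NULL,
      source = "analytic")
}

#' Family of null distributions across background sizes
#'
#' Recomputes the null for each background size in `bgSizes`, holding the
#' tested-set size and reference sizes fixed. Shrinking the background
#' shifts the null rightward: with fewer genes to sample from, random
#' reference sets overlap the tested set more often.
#'
#' @inheritParams simulateNull
#' @param bgSizes Integer vector of background sizes.
#' @param method `"monte_carlo"` (default) or `"analytic"`.
#' @return A list of [NullDistribution]s, named by background size.
#' @export
backgroundFamily <- function(n0, refSizes, bgSizes, N = 100L, seed = 1L,
                             method = c("monte_carlo", "analytic")) {
  method <- match.arg(method)
  out <- lapply(bgSizes, function(d) {
    if (method == "monte_carlo")
      simulateNull(n0, refSizes, d, N = N, seed = seed)
    else
      analyticNull(refSizes, d, n0)
  })
  names(out) <- as.character(bgSizes)
  out
}

#' Write a null distribution as TSV plus a provenance JSON block
#'
#' The TSV has columns m, EF_m, expected percentage and (for the
#' Monte-Carlo source) the per-bin Monte-Carlo standard error of EF_m
#' estimated from the per-simulation histograms when retained, else from
#' the binomial approximation. The JSON sidecar records seed, N, reference
#' sizes, background size and source.
#'
#' @param null A [NullDistribution].
#' @param path Output TSV path; the provenance JSON is written next to it
#'   as `<path>.json`.
#' @return Invisibly, the data.frame that was written.
#' @export
writeNullDistribution <- function(null, path) {
  m <- 0:null@M
  se <- rep(NA_real_, length(m))
  if (null@source == "monte_carlo") {
    if (!is.null(null@perSim)) {
      frac <- null@perSim / null@n0
      se <- apply(frac, 2, stats::sd) / sqrt(null@N)
    } else {
      se <- sqrt(null@EF * (1 - null@EF) / (null@N * null@n0))
    }
  }
  df <- data.frame(m = m, EF = null@EF, expected_pct = 100 * null@EF,
                   mc_se = se)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  prov <- list(source = null@source, N = null@N,
               seed = if (is.na(null@seed)) NULL else null@seed,
               n0 = null@n0, ref_sizes = null@refSizes,
               bg_size = null@bgSize)
  jsonlite::write_json(prov, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(df)
}
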