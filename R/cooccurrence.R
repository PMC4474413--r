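#' @include AllClasses.R
NULL

#' Count reference co-occurrences for each tested gene
#'
#' For every gene of the tested signature, counts the number of distinct
#' reference signatures containing it (set membership, not multiplicity).
#' A reference whose id equals the tested set's id is excluded, so a
#' signature stored inside its own reference collection does not count
#' itself.
#'
#' @param tgss The tested [GeneSet] (already restricted to the common
#'   background).
#' @param refs List of reference [GeneSet]s (same background).
#' @return Named integer vector: one co-occurrence count per tested gene.
#' @examples
#' tg <- GeneSet("t", c("A", "B"))
#' refs <- list(GeneSet("r1", c("A", "C")), GeneSet("r2", c("A", "D")),
#'              GeneSet("r3", "E"))
#' countCooccurrences(tg, refs)   # A: 2, B: 0
#' @export
countCooccurrences <- function(tgss, refs) {
  stopifnot(is(tgss, "GeneSet"))
  refs <- Filter(function(r) !identical(setId(r), setId(tgss)), refs)
  if (!length(refs))
    stop("no reference signatures (after excluding the tested set itself)",
         call. = FALSE)
  counts <- integer(length(tgss@symbols))
  names(counts) <- tgss@symbols
  for (r in refs) {
    hit <- tgss@symbols %in% r@symbols
    counts[hit] <- counts[hit] + 1L
  }
  counts
}

#' Empirical co-occurrence frequency distribution
#'
#' Builds the histogram `O_m` (number of tested genes found in exactly
#' `m` reference signatures, m = 0..M) and its normalization
#' `F_m = O_m / n0`, where `n0` is the tested-signature size. The m = 0
#' level (genes found in no reference) is part of the distribution, so the
#' histogram sums exactly to `n0` and the frequencies to 1.
#'
#' @param counts Named integer vector of per-gene co-occurrence counts.
#' @param M Number of reference signatures compared against.
#' @return A [CooccurrenceProfile].
#' @examples
#' empiricalDistribution(c(g1 = 1L, g2 = 1L, g3 = 2L), M = 2L)
#' @export
empiricalDistribution <- function(counts, M) {
  if (!length(counts))
    stop("no per-gene counts supplied", call. = FALSE)
  M <- as.integer(M)
  counts <- stats::setNames(as.integer(round(counts)), names(counts))
  if (any(counts < 0L))
    stop("negative co-occurrence count", call. = FALSE)
  if (max(counts) > M)
    stop("co-occurrence count exceeds the number of reference sets (",
         max(counts), " > ", M, "); corrupt input", call. = FALSE)
  O <- tabulate(counts + 1L, nbins = M + 1L)
  new("CooccurrenceProfile", counts = counts, M = M,
      n0 = length(counts), histogram = O, normalized = O / length(counts))
}

#' Write a per-gene co-occurrence table
#'
#' One row per tested gene: symbol, co-occurrence count, and the
#' semicolon-joined ids of the reference signatures containing it.
#'
#' @param tgss Tested [GeneSet].
#' @param refs Reference [GeneSet]s (the tested set's own record, if
#'   present, is excluded as in [countCooccurrences()]).
#' @param path Output TSV path.
#' @return Invisibly, the data.frame that was written.
#' @export
writeGeneCounts <- function(tgss, refs, path) {
  refs <- Filter(function(r) !identical(setId(r), setId(tgss)), refs)
  counts <- countCooccurrences(tgss, refs)
  members <- vapply(tgss@symbols, function(g) {
    inRefs <- vapply(refs, function(r) g %in% r@symbols, logical(1))
    paste(vapply(refs[inRefs], setId, character(1)), collapse = ";")
  }, character(1))
  df <- data.frame(gene = tgss@symbols, count = as.integer(counts),
                   reference_sets = members, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(df)
}
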