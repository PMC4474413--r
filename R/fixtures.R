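#' @include AllClasses.R
NULL

#' Worked-example data: ovarian 36-gene signature occurrence table
#'
#' The published occurrence analysis of a 36-gene ovarian cancer
#' prognostic signature against 62 comparator reference signatures,
#' shipped as a plain-text fixture: for each co-occurrence level m the
#' expected percentage under the 100-simulation null and the tested genes
#' observed at that level. Useful as a desk-scale worked example and for
#' validating [empiricalDistribution()] and [enrichmentRatios()].
#'
#' @return A list: `counts` (named integer vector of per-gene
#'   co-occurrence counts reconstructed from the per-level gene lists),
#'   `expectedPct` (numeric vector of expected percentages at m = 0..6),
#'   and `table` (the raw data.frame).
#' @examples
#' fx <- ovarianOccurrenceFixture()
#' empiricalDistribution(fx$counts, M = 62L)
#' @export
ovarianOccurrenceFixture <- function() {
  path <- system.file("extdata", "table1_ovarian_occurrences.tsv",
                      package = "SigConsensus", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  counts <- integer()
  for (i in seq_len(nrow(tab))) {
    genes <- strsplit(tab$genes[i], ";", fixed = TRUE)[[1]]
    counts <- c(counts, stats::setNames(rep(tab$occurrence[i],
                                            length(genes)), genes))
  }
  list(counts = counts, expectedPct = tab$expected_pct, table = tab)
}

#' Worked-example data: MAPK-pathway genes in breast cancer signatures
#'
#' The published occurrence counts (out of 70 breast cancer reference
#' signatures) and SN/SC labels, at a minimum threshold of four, for the
#' 31 MAPK signalling pathway genes present in the tested obesity and
#' IGF1 signatures. Useful for validating [classifyGenes()] with a forced
#' threshold.
#'
#' @return A data.frame with columns `gene`, `in_obesity`, `in_igf1`,
#'   `count`, `label`.
#' @examples
#' fx <- mapkClassificationFixture()
#' all(classifyGenes(stats::setNames(fx$count, fx$gene), 4L) == fx$label)
#' @export
mapkClassificationFixture <- function() {
  path <- system.file("extdata", "table2_mapk_genes.tsv",
                      package = "SigConsensus", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
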