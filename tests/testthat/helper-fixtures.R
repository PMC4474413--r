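# Small builders shared across test files. All fixtures are generated in
# code; file-based inputs are written to tempdir() at test time.

writeTempLines <- function(lines) {
  f <- tempfile(fileext = ".txt")
  writeLines(lines, f)
  f
}

# A CooccurrenceProfile directly from a count vector.
profileFromCounts <- function(counts, M) {
  empiricalDistribution(counts, M = as.integer(M))
}

# A NullDistribution carrying externally supplied expected frequencies
# (e.g. a published expected-percentage column), padded with zeros to M.
nullFromFrequencies <- function(ef, M, n0 = 36L, bgSize = 20000L) {
  ef <- c(ef, rep(0, M + 1L - length(ef)))
  ef <- ef / sum(ef)
  new("NullDistribution", N = 0L, seed = NA, M = as.integer(M),
      n0 = as.integer(n0), refSizes = rep(1L, M),
      bgSize = as.integer(bgSize), EF = ef, perSim = NULL,
      source = "analytic")
}

# The published ovarian worked example: per-gene counts plus the
# 100-simulation expected percentages, as shipped in extdata.
ovarianFixture <- function() ovarianOccurrenceFixture()

# Brute-force reverse cumulative: independent tail-sum oracle.
bruteReverseCumulative <- function(f) {
  vapply(seq_along(f), function(r) sum(f[r:length(f)]), numeric(1))
}
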