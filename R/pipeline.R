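#' @include AllClasses.R
NULL

#' Construct an analysis configuration
#'
#' @param tgss Path to the tested signature: a plain symbol list, or a GMT
#'   file whose first record is used.
#' @param refs Path to the reference collection: a GMT file, or a
#'   directory of plain symbol lists (one set per file).
#' @param background Path to the background symbol list.
#' @param outdir Output directory (created if needed).
#' @param N Number of null simulations (default 100).
#' @param seed Master RNG seed.
#' @param alpha Significance level for the threshold search (default 0.05).
#' @param forcedR Optional forced threshold; NA (default) searches via
#'   [chooseThreshold()].
#' @param fitFamilies Curve families to fit to the null reverse cumulative
#'   (default both; use `character()` to skip fitting).
#' @param precision Decimal places for rendered percentages (default 2).
#' @param keepSims Retain per-simulation histograms (default: N <= 1000).
#' @return An [AnalysisConfig].
#' @export
analysisConfig <- function(tgss, refs, background, outdir,
                           N = 100L, seed = 1L, alpha = 0.05,
                           forcedR = NA_integer_,
                           fitFamilies = c("weibull", "sigmoid"),
                           precision = 2L, keepSims = N <= 1000L) {
  new("AnalysisConfig", tgss = tgss, refs = refs, background = background,
      outdir = outdir, N = as.integer(N), seed = as.integer(seed),
      alpha = alpha,
      forcedR = if (is.na(forcedR)) NA_integer_ else as.integer(forcedR),
      fitFamilies = fitFamilies, precision = as.integer(precision),
      keepSims = keepSims)
}

readReferenceCollection <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, full.names = TRUE))
    if (!length(files))
      stop("reference directory '", path, "' is empty", call. = FALSE)
    sets <- lapply(files, function(f)
      readSymbolList(f, id = tools::file_path_sans_ext(basename(f))))
    names(sets) <- vapply(sets, setId, character(1))
    if (anyDuplicated(names(sets)))
      stop("duplicate reference set ids in '", path, "'", call. = FALSE)
    sets
  } else {
    readGmt(path)
  }
}

readTestedSignature <- function(path) {
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    sets <- readGmt(path)
    if (length(sets) > 1L)
      message("tested-signature GMT has ", length(sets),
              " records; using the first ('", setId(sets[[1]]), "')")
    sets[[1]]
  } else {
    readSymbolList(path, id = tools::file_path_sans_ext(basename(path)))
  }
}

#' Render a Table-1-style occurrence report
#'
#' One row per co-occurrence level m = 0..M (rows beyond the last occupied
#' empirical level with zero expected mass are trimmed): expected
#' percentage under the null, actual percentage, enrichment ratio (or
#' "Not applicable" where the null assigns zero mass), number of tested
#' genes at that level, and their semicolon-joined symbols. Percentages
#' are rounded to `precision` decimals at render time only; internal
#' state is never rounded.
#'
#' @param profile A [CooccurrenceProfile].
#' @param null A [NullDistribution] over the same M.
#' @param precision Decimal places (default 2).
#' @return The TSV text as a single character string.
#' @export
renderTable1 <- function(profile, null, precision = 2L) {
  header <- paste("occurrence", "expected_pct", "actual_pct",
                  "enrichment", "n_genes", "genes", sep = "\t")
  if (!length(profile@counts)) return(paste0(header, "\n"))
  checkSharedM(profile, null)
  enr <- enrichmentRatios(profile, null)
  mMax <- max(max(profile@counts),
              max(c(0L, which(null@EF > 0) - 1L)))
  rows <- vapply(0:mMax, function(m) {
    genes <- names(profile@counts)[profile@counts == m]
    paste(m,
          format(round(100 * null@EF[m + 1], precision), nsmall = precision),
          format(round(100 * profile@normalized[m + 1], precision),
                 nsmall = precision),
          if (is.na(enr[m + 1])) "Not applicable"
          else format(round(enr[m + 1], precision), nsmall = precision),
          length(genes),
          paste(genes, collapse = ";"),
          sep = "\t")
  }, character(1))
  paste0(paste(c(header, rows), collapse = "\n"), "\n")
}

#' Run the full signature-consensus analysis
#'
#' Orchestrates the pipeline end to end: load the background and
#' signatures, restrict every set to the background (dropping unmapped
#' symbols and skipping references left empty, with every exclusion
#' logged), count co-occurrences, build the Monte-Carlo null, classify
#' genes as SN/SC, optionally fit null tail curves, and write the report
#' files into `outdir`:
#' \itemize{
#'   \item `occurrence_report.tsv` — Table-1-style per-level report;
#'   \item `gene_labels.tsv` — per-gene count and SN/SC label;
#'   \item `null_distribution.tsv` (+ `.json` provenance);
#'   \item `summary.json` — KS statistic, p1, p2 table, r*, alpha, seed;
#'   \item `fit_summary.tsv` / `fitted_curves.tsv` — when fits requested;
#'   \item `run.log` — seed, N, filter reports, warnings.
#' }
#' On any error the partially written outputs are removed before the
#' error propagates.
#'
#' @param config An [AnalysisConfig].
#' @return Invisibly, a list with the in-memory results (`profile`,
#'   `null`, `outcome`, `fits`, `files`).
#' @export
runAnalysis <- function(config) {
  stopifnot(is(config, "AnalysisConfig"))
  validObject(config)
  dir.create(config@outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  logLines <- character()
  # log lines carry no timestamps so that identical runs are byte-identical
  note <- function(...) {
    logLines <<- c(logLines, paste0(...))
  }
  out <- function(name) {
    p <- file.path(config@outdir, name)
    written <<- c(written, p)
    p
  }

  result <- tryCatch({
    note("seed = ", config@seed, ", N = ", config@N,
         ", alpha = ", config@alpha)
    bg <- loadBackground(config@background)
    note("background: ", setSize(bg), " symbols from ", config@background)

    tgssRaw <- readTestedSignature(config@tgss)
    refsRaw <- readReferenceCollection(config@refs)
    note("tested signature '", setId(tgssRaw), "': ", setSize(tgssRaw),
         " symbols; ", length(refsRaw), " reference sets read")

    tr <- restrictToBackground(tgssRaw, bg)
    if (length(tr$report@droppedUnmapped))
      note("tested signature: dropped unmapped symbols: ",
           paste(tr$report@droppedUnmapped, collapse = ", "))
    tgss <- tr$geneSet
    if (!setSize(tgss))
      stop("tested signature has no symbols in the background space",
           call. = FALSE)

    refs <- list()
    for (r in refsRaw) {
      rr <- suppressWarnings(restrictToBackground(r, bg))
      if (length(rr$report@droppedUnmapped))
        note("reference '", setId(r), "': dropped unmapped symbols: ",
             paste(rr$report@droppedUnmapped, collapse = ", "))
      if (!setSize(rr$geneSet)) {
        note("reference '", setId(r),
             "' empty after background filtering; skipped")
      } else {
        refs[[setId(r)]] <- rr$geneSet
      }
    }
    refs <- Filter(function(r) !identical(setId(r), setId(tgss)), refs)
    if (!length(refs))
      stop("no usable reference signatures after filtering", call. = FALSE)

    counts <- countCooccurrences(tgss, refs)
    profile <- empiricalDistribution(counts, M = length(refs))
    null <- simulateNull(setSize(tgss),
                         vapply(refs, setSize, integer(1)),
                         bg, N = config@N, seed = config@seed,
                         keepSims = config@keepSims)
    outcome <- withCallingHandlers(
      classifySignature(profile, null, alpha = config@alpha,
                        forcedR = config@forcedR),
      warning = function(w) {
        note("warning: ", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    note("KS statistic = ", signif(outcome@ksStatistic, 4),
         ", p1 = ", signif(outcome@p1, 4),
         ", r* = ", outcome@rStar,
         if (outcome@forced) " (forced)" else "")

    writeLines(renderTable1(profile, null, config@precision),
               out("occurrence_report.tsv"), sep = "")
    utils::write.table(
      data.frame(gene = names(counts), count = as.integer(counts),
                 label = outcome@labels[names(counts)]),
      out("gene_labels.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    nullPath <- out("null_distribution.tsv")
    written <- c(written, paste0(nullPath, ".json"))
    writeNullDistribution(null, nullPath)
    jsonlite::write_json(
      list(ks_statistic = outcome@ksStatistic, p1 = outcome@p1,
           p1_note = "approximate (discrete data)",
           p2 = as.list(stats::setNames(outcome@p2, names(outcome@p2))),
           r_star = if (is.na(outcome@rStar)) NULL else outcome@rStar,
           alpha = outcome@alpha, forced = outcome@forced,
           seed = config@seed, N = config@N),
      out("summary.json"), auto_unbox = TRUE, digits = NA, null = "null")

    fits <- list()
    if (length(config@fitFamilies)) {
      fits <- lapply(config@fitFamilies, function(fam)
        fitCurve(null, fam))
      writeFitSummary(fits, out("fit_summary.tsv"),
                      out("fitted_curves.tsv"))
    }
    writeLines(logLines, out("run.log"))
    list(profile = profile, null = null, outcome = outcome, fits = fits,
         files = written)
  }, error = function(e) {
    unlink(written)
    stop(e)
  })
  invisible(result)
}
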