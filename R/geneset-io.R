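#' @include AllClasses.R
NULL

# Symbol normalization: surrounding whitespace stripped, upper-cased.
# No alias or accession mapping is attempted; identifier conversion is an
# upstream curation step.
normalizeSymbols <- function(x) toupper(trimws(x))

# Read a plain symbol-list file: one symbol per line, blank lines and
# '#'-prefixed lines ignored. Returns the raw (normalized, not yet
# deduplicated) symbol vector.
readSymbolLines <- function(path) {
  if (!file.exists(path))
    stop("cannot read '", path, "': no such file", call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  normalizeSymbols(lines)
}

#' Construct a GeneSet
#'
#' Normalizes (trims, upper-cases) and deduplicates the supplied symbols,
#' preserving first-occurrence order.
#'
#' @param id Short unique identifier.
#' @param symbols Character vector of gene symbols (raw; normalized here).
#' @param label Optional free-text description.
#' @param metadata Optional list of provenance items.
#' @return A [GeneSet] object.
#' @examples
#' GeneSet("S1", c("tp53", "BRCA1", "TP53"))
#' @export
GeneSet <- function(id, symbols, label = "", metadata = list()) {
  symbols <- normalizeSymbols(symbols)
  symbols <- symbols[nzchar(symbols)]
  symbols <- symbols[!duplicated(symbols)]
  new("GeneSet", id = as.character(id), label = as.character(label),
      symbols = symbols, metadata = metadata)
}

#' Load the background biomarker space from a symbol-list file
#'
#' Reads one symbol per line (blank lines and lines starting with `#` are
#' ignored), normalizes and deduplicates. The background defines the
#' universe from which null reference sets are sampled; signatures are
#' restricted to it before analysis.
#'
#' @param path Path to a plain-text symbol list.
#' @return A [BackgroundSpace].
#' @examples
#' f <- tempfile()
#' writeLines(c("TP53", "BRCA1", "tp53"), f)
#' loadBackground(f)   # 2 symbols: case-folded duplicate collapsed
#' @export
loadBackground <- function(path) {
  symbols <- readSymbolLines(path)
  symbols <- symbols[!duplicated(symbols)]
  if (!length(symbols))
    stop("empty background space: '", path,
         "' contains no symbols", call. = FALSE)
  new("BackgroundSpace", symbols = symbols)
}

#' Read gene sets from a GMT file
#'
#' GMT is the tab-delimited gene-set exchange format: each line holds a set
#' name, a description, then one or more member symbols. Within-line
#' duplicate symbols are collapsed; the order of records is preserved.
#'
#' @param path Path to a GMT file.
#' @return A list of [GeneSet] objects, named by set id.
#' @seealso [writeGmt()]
#' @export
readGmt <- function(path) {
  if (!file.exists(path))
    stop("cannot read '", path, "': no such file", call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("GMT line ", which(nf < 3L)[1],
         " has fewer than 3 tab-separated fields", call. = FALSE)
  ids <- vapply(fields, `[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate set name(s) in GMT: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  sets <- lapply(fields, function(f) {
    GeneSet(id = trimws(f[1]), label = trimws(f[2]), symbols = f[-(1:2)])
  })
  names(sets) <- vapply(sets, setId, character(1))
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets A list of [GeneSet] objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeGmt <- function(sets, path) {
  lines <- vapply(sets, function(gs) {
    paste(c(gs@id, if (nzchar(gs@label)) gs@label else gs@id,
            gs@symbols), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a tested signature from a plain symbol-list file
#'
#' As [loadBackground()] but returns a [GeneSet] carrying the given id.
#' A [FilterReport] recording any duplicates collapsed on input is stored
#' in the set's metadata under `"filterReport"`.
#'
#' @param path Path to a plain-text symbol list.
#' @param id Identifier for the resulting set.
#' @param label Optional description.
#' @return A [GeneSet].
#' @export
readSymbolList <- function(path, id, label = "") {
  raw <- readSymbolLines(path)
  if (!length(raw))
    stop("empty gene set: '", path, "' contains no symbols", call. = FALSE)
  dup <- duplicated(raw)
  report <- new("FilterReport", kept = sum(!dup),
                droppedUnmapped = character(),
                droppedDuplicate = raw[dup],
                rawLength = length(raw))
  GeneSet(id = id, symbols = raw[!dup], label = label,
          metadata = list(filterReport = report))
}

#' Restrict a gene set to the background space
#'
#' Any symbol absent from the background is excluded from subsequent
#' analysis. The returned report accounts for every raw symbol. A set that
#' becomes empty is flagged (metadata `empty = TRUE`) with a warning rather
#' than an error; empty reference sets are skipped downstream.
#'
#' @param gs A [GeneSet].
#' @param bg A [BackgroundSpace].
#' @return A list with elements `geneSet` (the restricted [GeneSet], which
#'   also carries the report in its metadata) and `report`
#'   (a [FilterReport]).
#' @examples
#' bg <- new("BackgroundSpace", symbols = c("A", "B", "C"))
#' restrictToBackground(GeneSet("s", c("A", "B", "X")), bg)$report
#' @export
restrictToBackground <- function(gs, bg) {
  stopifnot(is(gs, "GeneSet"), is(bg, "BackgroundSpace"))
  keep <- gs@symbols %in% bg@symbols
  report <- new("FilterReport", kept = sum(keep),
                droppedUnmapped = gs@symbols[!keep],
                droppedDuplicate = character(),
                rawLength = length(gs@symbols))
  meta <- gs@metadata
  meta$filterReport <- report
  if (!any(keep)) {
    warning("gene set '", gs@id,
            "' has no symbols in the background space", call. = FALSE)
    meta$empty <- TRUE
  }
  out <- new("GeneSet", id = gs@id, label = gs@label,
             symbols = gs@symbols[keep], metadata = meta)
  list(geneSet = out, report = report)
}
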