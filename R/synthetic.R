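#' @include AllClasses.R
NULL

#' Construct a synthetic planted-signal scenario
#'
#' Defaults mirror the simulated study conditions used throughout the
#' package: a 20,000-symbol background, a 100-gene tested signature and
#' ten reference signatures of sizes 20, 40, ..., 200.
#'
#' @param bgSize Background-space size.
#' @param n0 Tested-signature size.
#' @param refSizes Reference-signature sizes.
#' @param nCommon Number of genes planted into `plantDepth` references.
#' @param plantDepth Number of distinct references each common gene joins.
#' @param nNovel Number of genes guaranteed absent from all references.
#' @param seed Integer RNG seed.
#' @return A [SyntheticScenario].
#' @export
syntheticScenario <- function(bgSize = 20000L, n0 = 100L,
                              refSizes = seq(20L, 200L, by = 20L),
                              nCommon = 0L, plantDepth = 0L, nNovel = 0L,
                              seed = 1L) {
  new("SyntheticScenario", bgSize = as.integer(bgSize),
      n0 = as.integer(n0), refSizes = as.integer(refSizes),
      nCommon = as.integer(nCommon), plantDepth = as.integer(plantDepth),
      nNovel = as.integer(nNovel), seed = as.integer(seed))
}

#' Generate a deterministic synthetic background space
#'
#' Pseudo-symbols are zero-padded sequential strings (G000001, G000002,
#' ...), so the same size always yields the identical universe.
#'
#' @param size Number of symbols (>= 1).
#' @param seed Accepted for API symmetry; the symbols are deterministic.
#' @return A [BackgroundSpace].
#' @export
makeBackground <- function(size, seed = 1L) {
  size <- as.integer(size)
  if (size < 1L) stop("background size must be at least 1", call. = FALSE)
  width <- max(6L, nchar(as.character(size)))
  new("BackgroundSpace",
      symbols = sprintf(paste0("G%0", width, "d"), seq_len(size)))
}

#' Generate a synthetic reference collection
#'
#' Each reference signature is an independent uniform without-replacement
#' draw of the requested size from the background; reproducible given the
#' seed.
#'
#' @param refSizes Integer vector of set sizes.
#' @param bg A [BackgroundSpace].
#' @param seed Integer RNG seed.
#' @return List of [GeneSet]s with ids `REF01`, `REF02`, ...
#' @export
makeReferenceCollection <- function(refSizes, bg, seed = 1L) {
  refSizes <- as.integer(refSizes)
  if (!length(refSizes)) return(list())
  if (any(refSizes > setSize(bg)))
    stop("reference size exceeds the background size", call. = FALSE)
  set.seed(seed)
  ids <- sprintf("REF%02d", seq_along(refSizes))
  sets <- mapply(function(id, sz) {
    GeneSet(id, sample(bg@symbols, sz),
            label = sprintf("synthetic reference (%d genes)", sz))
  }, ids, refSizes, SIMPLIFY = FALSE)
  names(sets) <- ids
  sets
}

#' Plant SN/SC structure into a synthetic tested signature
#'
#' Builds a tested signature of size `n0` in which `nCommon` genes are
#' inserted into `plantDepth` distinct references (appended, so each of
#' those references grows by at most `nCommon` genes and keeps its other
#' members), `nNovel` genes are guaranteed absent from every reference,
#' and the remaining filler genes are drawn uniformly from the background.
#' Null simulations downstream must use the post-augmentation reference
#' sizes.
#'
#' Truth labels cover the planted genes only (`SC` for planted common,
#' `SN` for planted novel): filler genes acquire stochastic co-occurrence
#' counts and have no planted class.
#'
#' @param scenario A [SyntheticScenario].
#' @param bg The [BackgroundSpace] the scenario was built against.
#' @param refs Reference [GeneSet]s to augment.
#' @return A list: `tgss` (the tested [GeneSet]), `refs` (the augmented
#'   reference collection), `truth` (named character vector of planted
#'   labels).
#' @export
makePlantedTgss <- function(scenario, bg, refs) {
  stopifnot(is(scenario, "SyntheticScenario"), is(bg, "BackgroundSpace"))
  validObject(scenario)
  if (scenario@plantDepth > 0L && scenario@nCommon > 0L &&
      length(refs) < scenario@plantDepth)
    stop("not enough references to plant at depth ", scenario@plantDepth,
         call. = FALSE)
  set.seed(scenario@seed + 1L)
  refUnion <- unique(unlist(lapply(refs, geneIds), use.names = FALSE))

  novelPool <- setdiff(bg@symbols, refUnion)
  if (length(novelPool) < scenario@nNovel)
    stop("background too saturated to plant ", scenario@nNovel,
         " never-occurring genes", call. = FALSE)
  novel <- if (scenario@nNovel) sample(novelPool, scenario@nNovel)
           else character()

  commonPool <- setdiff(bg@symbols, novel)
  common <- if (scenario@nCommon) sample(commonPool, scenario@nCommon)
            else character()
  if (scenario@nCommon > 0L && scenario@plantDepth > 0L) {
    target <- seq_len(scenario@plantDepth)
    refs[target] <- lapply(refs[target], function(r) {
      GeneSet(r@id, c(r@symbols, common), label = r@label,
              metadata = r@metadata)
    })
  }

  nFill <- scenario@n0 - scenario@nCommon - scenario@nNovel
  fillPool <- setdiff(bg@symbols, c(common, novel))
  filler <- if (nFill) sample(fillPool, nFill) else character()

  # with no planting depth there is no SC guarantee: such genes are
  # ordinary background draws and carry an SN truth label
  commonLabel <- if (scenario@plantDepth > 0L) "SC" else "SN"
  truth <- c(stats::setNames(rep(commonLabel, length(common)), common),
             stats::setNames(rep("SN", length(novel)), novel))
  list(
    tgss = GeneSet("TGSS", c(common, novel, filler),
                   label = "synthetic tested signature"),
    refs = refs,
    truth = truth
  )
}

#' Write a synthetic scenario to disk as standard input files
#'
#' Materializes a scenario as the file formats the analysis consumes:
#' the background as a plain symbol list, the (augmented) references as a
#' GMT file, the tested signature as a symbol list, and the planted truth
#' labels as TSV — so the end-to-end pipeline can be exercised from files.
#'
#' @param scenario A [SyntheticScenario].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the file paths written
#'   (`background`, `refs`, `tgss`, `truth`) plus an `objects` element
#'   holding the in-memory counterparts.
#' @export
writeSyntheticScenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bg <- makeBackground(scenario@bgSize, scenario@seed)
  refs <- makeReferenceCollection(scenario@refSizes, bg, scenario@seed)
  planted <- makePlantedTgss(scenario, bg, refs)

  paths <- list(background = file.path(dir, "background.txt"),
                refs = file.path(dir, "references.gmt"),
                tgss = file.path(dir, "tgss.txt"),
                truth = file.path(dir, "truth_labels.tsv"))
  writeLines(bg@symbols, paths$background)
  writeGmt(planted$refs, paths$refs)
  writeLines(planted$tgss@symbols, paths$tgss)
  utils::write.table(
    data.frame(gene = names(planted$truth), label = planted$truth),
    paths$truth, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, list(objects = list(bg = bg, refs = planted$refs,
                                         tgss = planted$tgss,
                                         truth = planted$truth))))
}
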