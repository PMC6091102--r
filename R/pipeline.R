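#' Run the full barcode-locus evaluation
#'
#' Orchestrates, per locus and per requested combination:
#' screening ([filterRecords()]), alignment statistics
#' ([alignmentStats()]), K2P distances ([k2pDistanceMatrix()]) and
#' their intra/inter summaries, the barcoding-gap test
#' ([gapAnalysis()]), the three leave-one-out identification criteria,
#' and the NJ tree with species monophyly (optionally bootstrapped and
#' outgroup-rooted). Combinations are built by strict intersection of
#' individuals ([concatenateLoci()]). A failing candidate does not
#' abort the others: its error is attached to its row.
#'
#' @param loci Named list of [BarcodeAlignment()]/[BarcodeDataset()]
#'   objects or aligned FASTA paths, one per locus.
#' @param combinations List of character vectors of locus names to
#'   concatenate, e.g. `list(c("ITS", "matK"))`; `"all-pairs"` expands
#'   to every pair.
#' @param minLength,requireVoucher Screening parameters, see
#'   [filterRecords()].
#' @param binWidth Gap histogram interval (percent).
#' @param percentile Intraspecific percentile for the close-match
#'   threshold.
#' @param bootstrapReplicates Bootstrap pseudo-replicates for the NJ
#'   tree (0 = no supports).
#' @param outgroupSpecies Optional species name used to root the tree
#'   (its records are excluded from distance/identification summaries);
#'   without it, monophyly is assessed on the unrooted tree.
#' @param includeSingletons Discrimination-rate convention, see
#'   [speciesMonophyly()].
#' @param schema Header schema for FASTA inputs.
#' @param seed Seed controlling the bootstrap resampling.
#' @return An `EvaluationReport`: list with `rows` (one `data.frame`
#'   row per candidate), `details` (per-candidate gap reports, match
#'   tables, trees), and the echoed `config`.
#' @export
runEvaluation <- function(loci, combinations = list(),
                          minLength = 300, requireVoucher = TRUE,
                          binWidth = 0.05, percentile = 95,
                          bootstrapReplicates = 0,
                          outgroupSpecies = NULL,
                          includeSingletons = FALSE,
                          schema = "species|individual|locus|accession",
                          seed = 1) {
  stopifnot(length(loci) >= 1L, !is.null(names(loci)))
  loaded <- lapply(names(loci), function(nm) {
    tryCatch({
      x <- loci[[nm]]
      if (is.character(x)) x <- readBarcodeFasta(x, schema = schema)
      f <- filterRecords(x, minLength = minLength,
                         requireVoucher = requireVoucher)
      validateAlignment(f$kept)
    }, error = function(e) e)
  })
  names(loaded) <- names(loci)
  if (identical(combinations, "all-pairs"))
    combinations <- utils::combn(names(loci), 2L, simplify = FALSE)
  candidates <- c(
    lapply(names(loci), function(nm)
      list(name = nm, aln = loaded[[nm]])),
    lapply(combinations, function(combo) {
      nm <- paste(combo, collapse = "+")
      aln <- tryCatch({
        members <- loaded[combo]
        errs <- vapply(members, inherits, logical(1L), "error")
        if (any(errs)) stop("member locus failed: ",
                            paste(combo[errs], collapse = ", "))
        concatenateLoci(members)
      }, error = function(e) e)
      list(name = nm, aln = aln)
    }))
  details <- list()
  rows <- lapply(candidates, function(cand) {
    if (inherits(cand$aln, "error"))
      return(.errorRow(cand$name, conditionMessage(cand$aln)))
    res <- tryCatch(
      .evaluateCandidate(cand$aln, binWidth, percentile,
                         bootstrapReplicates, outgroupSpecies,
                         includeSingletons, seed),
      error = function(e) e)
    if (inherits(res, "error"))
      return(.errorRow(cand$name, conditionMessage(res)))
    details[[cand$name]] <<- res$detail
    cbind(data.frame(candidate = cand$name), res$row)
  })
  report <- structure(
    list(rows = do.call(rbind, c(rows, list(make.row.names = FALSE))),
         details = details,
         config = list(minLength = minLength,
                       requireVoucher = requireVoucher,
                       binWidth = binWidth, percentile = percentile,
                       bootstrapReplicates = bootstrapReplicates,
                       outgroupSpecies = outgroupSpecies,
                       includeSingletons = includeSingletons,
                       seed = seed)),
    class = "EvaluationReport")
  report
}

.rowTemplate <- function() {
  data.frame(nSpecies = NA_integer_, nIndividuals = NA_integer_,
             alignedLength = NA_integer_, variableSites = NA_integer_,
             parsimonyInformative = NA_integer_,
             intraMin = NA_real_, intraMax = NA_real_,
             intraMean = NA_real_, interMin = NA_real_,
             interMax = NA_real_, interMean = NA_real_,
             gapExists = NA, gapWidth = NA_real_,
             threshold = NA_real_,
             bmCorrect = NA_real_, bmAmbiguous = NA_real_,
             bmIncorrect = NA_real_,
             bcmCorrect = NA_real_, bcmAmbiguous = NA_real_,
             bcmIncorrect = NA_real_, bcmNoMatch = NA_real_,
             asbCorrect = NA_real_, asbAmbiguous = NA_real_,
             asbIncorrect = NA_real_, asbNoMatch = NA_real_,
             discrimination = NA_real_, error = NA_character_)
}

.errorRow <- function(name, msg) {
  row <- .rowTemplate()
  row$error <- msg
  cbind(data.frame(candidate = name), row)
}

.evaluateCandidate <- function(aln, binWidth, percentile,
                               bootstrapReplicates, outgroupSpecies,
                               includeSingletons, seed) {
  row <- .rowTemplate()
  summ <- datasetSummary(aln)
  ogIds <- character()
  ingroup <- aln
  if (!is.null(outgroupSpecies)) {
    sp <- speciesLabels(aln)
    ogIds <- names(sp)[sp == .normalizeSpecies(outgroupSpecies)]
    if (length(ogIds))
      ingroup <- aln[!names(aln) %in% ogIds]
  }
  inSumm <- datasetSummary(ingroup)
  row$nSpecies <- inSumm$nSpecies
  row$nIndividuals <- inSumm$nIndividuals
  st <- alignmentStats(aln)
  row$alignedLength <- st$alignedLength
  row$variableSites <- st$variableSites
  row$parsimonyInformative <- st$parsimonyInformative
  dm <- k2pDistanceMatrix(ingroup)
  ds <- summarizeDistances(dm)
  row$intraMin <- ds$min[1L]; row$intraMax <- ds$max[1L]
  row$intraMean <- ds$mean[1L]
  row$interMin <- ds$min[2L]; row$interMax <- ds$max[2L]
  row$interMean <- ds$mean[2L]
  gap <- gapAnalysis(dm, binWidth = binWidth)
  row$gapExists <- gap$gapExists
  row$gapWidth <- gap$gapWidth
  threshold <- tryCatch(intraspecificThreshold(dm, percentile),
                        error = function(e) NA_real_)
  row$threshold <- threshold
  bm <- bestMatch(dm)
  outcomes <- bm
  sm <- summarizeIdentification(bm)
  row$bmCorrect <- sm$pctCorrect; row$bmAmbiguous <- sm$pctAmbiguous
  row$bmIncorrect <- sm$pctIncorrect
  if (!is.na(threshold)) {
    bcm <- bestCloseMatch(dm, threshold)
    sm <- summarizeIdentification(bcm)
    row$bcmCorrect <- sm$pctCorrect
    row$bcmAmbiguous <- sm$pctAmbiguous
    row$bcmIncorrect <- sm$pctIncorrect
    row$bcmNoMatch <- sm$pctNoMatch
    asb <- allSpeciesBarcodes(dm, threshold)
    outcomes <- rbind(outcomes, bcm, asb)
    if (any(!is.na(asb$verdict))) {
      sm <- summarizeIdentification(asb)
      row$asbCorrect <- sm$pctCorrect
      row$asbAmbiguous <- sm$pctAmbiguous
      row$asbIncorrect <- sm$pctIncorrect
      row$asbNoMatch <- sm$pctNoMatch
    }
  }
  tree <- NULL
  if (length(ingroup) + length(ogIds) >= 3L) {
    treeAln <- aln[c(names(ingroup), ogIds)]
    tree <- if (bootstrapReplicates > 0L)
      bootstrapSupport(treeAln, nReplicates = bootstrapReplicates,
                       seed = seed)
    else neighborJoining(k2pDistanceMatrix(treeAln))
    monoTree <- tree
    if (length(ogIds)) {
      monoTree <- rootWithOutgroup(tree, ogIds)
      monoTree <- ape::drop.tip(monoTree, ogIds)
    }
    mono <- speciesMonophyly(monoTree, speciesLabels(ingroup),
                             includeSingletons = includeSingletons)
    row$discrimination <- mono$rate
  } else mono <- NULL
  list(row = row,
       detail = list(gap = gap, outcomes = outcomes, tree = tree,
                     monophyly = mono, distance = dm,
                     threshold = threshold))
}

#' @export
print.EvaluationReport <- function(x, ...) {
  cat("Barcode locus evaluation (", nrow(x$rows), " candidates)\n",
      sep = "")
  cols <- c("candidate", "nSpecies", "nIndividuals", "gapExists",
            "bmCorrect", "bcmCorrect", "discrimination")
  print(format(x$rows[, cols], digits = 4), row.names = FALSE)
  invisible(x)
}

#' Rank candidate barcodes
#'
#' Orders the report rows by discrimination rate, then best-close-match
#' correct percentage, then gap width (all descending). Rows tied on
#' all three share a rank.
#'
#' @param report An `EvaluationReport` from [runEvaluation()].
#' @return The row `data.frame` with a leading `rank` column, ordered
#'   best first; errored candidates sort last.
#' @export
rankCandidates <- function(report) {
  rows <- report$rows
  stopifnot(nrow(rows) >= 1L)
  keyOrder <- order(-replace(rows$discrimination,
                             is.na(rows$discrimination), -Inf),
                    -replace(rows$bcmCorrect,
                             is.na(rows$bcmCorrect), -Inf),
                    -replace(rows$gapWidth, is.na(rows$gapWidth), -Inf))
  rows <- rows[keyOrder, , drop = FALSE]
  key <- paste(rows$discrimination, rows$bcmCorrect, rows$gapWidth)
  rank <- match(key, unique(key))
  cbind(data.frame(rank = rank), rows, row.names = NULL)
}

#' Write an evaluation report to disk
#'
#' Emits `report.tsv` (one row per candidate, percentages to 2
#' decimals), `report.json` (full precision) and one Newick file per
#' candidate with a tree.
#'
#' @param report An `EvaluationReport`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeEvaluationReport <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- report$rows
  num <- vapply(rows, is.numeric, logical(1L))
  rows[num] <- lapply(rows[num], round, digits = 2)
  utils::write.table(rows, file.path(dir, "report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(rows = report$rows, config = report$config),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  for (nm in names(report$details)) {
    tr <- report$details[[nm]]$tree
    if (!is.null(tr))
      writeSupportNewick(tr, file.path(dir, paste0(
        gsub("[^A-Za-z0-9_+-]", "_", nm), ".nwk")))
  }
  invisible(dir)
}
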