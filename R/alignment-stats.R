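#' Alignment site statistics
#'
#' Column-wise summaries of an alignment: the aligned length in columns,
#' the number of variable sites and the number of parsimony-informative
#' sites. Following the usual convention for these counts, gaps and
#' IUPAC ambiguity codes are excluded from a column's state multiset, so
#' a column is classified on its unambiguous A/C/G/T residues only; a
#' column that is entirely gap/ambiguous contributes to the aligned
#' length but to neither count. Set `gapAsState = TRUE` to treat the gap
#' character as a fifth state instead.
#'
#' A column is *variable* when it holds at least two distinct states,
#' and *parsimony-informative* when at least two states each occur in at
#' least two rows (so alignments of three or fewer rows have no
#' parsimony-informative sites).
#'
#' @param aln A [BarcodeAlignment()].
#' @param gapAsState Count `-` as a fifth character state.
#' @return `countVariableSites()` and `countParsimonyInformative()`
#'   return integers; `alignedLength()` the number of columns;
#'   `alignmentStats()` a one-row `data.frame` with all three.
#' @examples
#' aln <- BarcodeAlignment(c("AAAA", "AAAT", "AAAT", "AAAA"),
#'                         species = c("a", "a", "b", "b"),
#'                         individual = as.character(1:4))
#' countVariableSites(aln)           # 1
#' countParsimonyInformative(aln)    # 1
#' @name alignmentStats
NULL

.siteStateCounts <- function(aln, gapAsState = FALSE) {
  enc <- .encodeAlignment(aln)
  states <- if (gapAsState) 1:5 else 1:4
  m <- vapply(states, function(k) colSums(enc == k), numeric(ncol(enc)))
  if (is.null(dim(m))) dim(m) <- c(1L, length(states))
  m
}

#' @rdname alignmentStats
#' @export
alignedLength <- function(aln) {
  stopifnot(is(aln, "BarcodeAlignment"))
  Biostrings::width(aln@seqs)[1L]
}

#' @rdname alignmentStats
#' @export
countVariableSites <- function(aln, gapAsState = FALSE) {
  stopifnot(is(aln, "BarcodeAlignment"), length(aln) >= 2L)
  counts <- .siteStateCounts(aln, gapAsState)
  sum(rowSums(counts > 0) >= 2L)
}

#' @rdname alignmentStats
#' @export
countParsimonyInformative <- function(aln, gapAsState = FALSE) {
  stopifnot(is(aln, "BarcodeAlignment"), length(aln) >= 2L)
  counts <- .siteStateCounts(aln, gapAsState)
  sum(rowSums(counts >= 2) >= 2L)
}

#' @rdname alignmentStats
#' @export
alignmentStats <- function(aln, gapAsState = FALSE) {
  data.frame(alignedLength = alignedLength(aln),
             variableSites = countVariableSites(aln, gapAsState),
             parsimonyInformative =
               countParsimonyInformative(aln, gapAsState))
}
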