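#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom Biostrings DNAStringSet
#' @importFrom Biostrings DNAStringSet width
#' @importFrom stats setNames quantile runif
#' @importFrom ape read.tree write.tree root drop.tip getMRCA is.rooted
NULL

#' Species-labelled barcode sequence collection
#'
#' `BarcodeDataset` holds one locus worth of nucleotide records together
#' with their species/individual/locus/accession bookkeeping. Sequences
#' live in a [Biostrings::DNAStringSet] named by record id; the metadata
#' is a parallel [S4Vectors::DataFrame] with columns `id`, `species`,
#' `individual`, `locus`, `accession`. `BarcodeAlignment` is the aligned
#' specialisation: all gapped sequences share one width (the aligned
#' length in columns).
#'
#' @slot seqs A `DNAStringSet`, one entry per record, names = record ids.
#' @slot meta A `DataFrame` with one row per record.
#'
#' @aliases BarcodeDataset-class BarcodeAlignment-class
#' @seealso [BarcodeDataset()], [BarcodeAlignment()], [readBarcodeFasta()]
#' @name BarcodeDataset-class
#' @exportClass BarcodeDataset
setClass("BarcodeDataset",
  representation(seqs = "DNAStringSet", meta = "DataFrame"))

setValidity("BarcodeDataset", function(object) {
  msg <- character()
  required <- c("id", "species", "individual", "locus", "accession")
  if (!all(required %in% colnames(object@meta)))
    msg <- c(msg, paste0("meta must have columns: ",
                         paste(required, collapse = ", ")))
  else {
    if (length(object@seqs) != nrow(object@meta))
      msg <- c(msg, "seqs and meta must have the same number of records")
    else if (length(object@seqs)) {
      if (!identical(names(object@seqs), as.character(object@meta$id)))
        msg <- c(msg, "names(seqs) must equal meta$id")
      if (anyDuplicated(object@meta$id))
        msg <- c(msg, "record ids must be unique")
      if (any(!nzchar(object@meta$species)))
        msg <- c(msg, "species must be non-empty for every record")
    }
  }
  if (length(msg)) msg else TRUE
})

#' @exportClass BarcodeAlignment
#' @rdname BarcodeDataset-class
setClass("BarcodeAlignment", contains = "BarcodeDataset")

setValidity("BarcodeAlignment", function(object) {
  if (length(object@seqs) == 0L) return("alignment must have at least one row")
  w <- Biostrings::width(object@seqs)
  if (length(unique(w)) > 1L)
    return(paste0("rows must share one gapped length; saw lengths ",
                  paste(unique(w), collapse = ", ")))
  TRUE
})

#' Multilocus concatenated alignment
#'
#' A `BarcodeAlignment` whose columns are tiled by per-locus spans.
#' `partitions` records, for each member locus in concatenation order,
#' its half-open 0-based column span `[start, end)`; the spans tile
#' `[0, ncols)` without gaps or overlap.
#'
#' @slot partitions A `data.frame` with columns `locus`, `start`, `end`.
#' @seealso [concatenateLoci()]
#' @name ConcatenatedAlignment-class
#' @exportClass ConcatenatedAlignment
setClass("ConcatenatedAlignment", contains = "BarcodeAlignment",
  representation(partitions = "data.frame"))

setValidity("ConcatenatedAlignment", function(object) {
  p <- object@partitions
  if (!all(c("locus", "start", "end") %in% colnames(p)))
    return("partitions must have columns locus, start, end")
  w <- unique(Biostrings::width(object@seqs))
  if (nrow(p)) {
    if (p$start[1L] != 0L) return("first span must start at 0")
    if (p$end[nrow(p)] != w) return("last span must end at the aligned length")
    if (nrow(p) > 1L && any(p$start[-1L] != p$end[-nrow(p)]))
      return("locus spans must tile the columns without gaps or overlap")
  }
  TRUE
})

#' Pairwise K2P distance matrix with species bookkeeping
#'
#' Symmetric matrix of Kimura 2-parameter distances (substitutions/site)
#' between records, with the species of each record carried along so the
#' matrix can be partitioned into intra- and inter-specific sets.
#' Undefined distances (saturated pairs, or no comparable sites after
#' pairwise deletion) are stored as `NA` and counted in `nUndefined`.
#'
#' @slot d Numeric symmetric matrix, ids as dimnames, `NA` = undefined.
#' @slot species Named character vector mapping record id to species.
#' @slot nUndefined Number of undefined unordered pairs.
#' @seealso [k2pDistanceMatrix()], [distancePartition()]
#' @name K2PDistanceMatrix-class
#' @exportClass K2PDistanceMatrix
setClass("K2PDistanceMatrix",
  representation(d = "matrix", species = "character",
                 nUndefined = "integer"))

setValidity("K2PDistanceMatrix", function(object) {
  d <- object@d
  if (nrow(d) != ncol(d)) return("distance matrix must be square")
  if (is.null(rownames(d)) || !identical(rownames(d), colnames(d)))
    return("distance matrix needs identical row/column id names")
  if (!identical(names(object@species), rownames(d)))
    return("species must be named by the matrix ids")
  if (any(diag(d) != 0)) return("diagonal must be zero")
  offd <- d[upper.tri(d)]
  if (any(offd[!is.na(offd)] < 0)) return("distances must be >= 0")
  if (!isTRUE(all.equal(d, t(d)))) return("distance matrix must be symmetric")
  TRUE
})
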