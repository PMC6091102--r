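.matchKey <- function(ds, key) {
  m <- ds@meta
  switch(key,
         "species+individual" = paste(m$species, m$individual, sep = "|"),
         "individual" = as.character(m$individual),
         stop("key must be 'species+individual' or 'individual'"))
}

#' Match individuals across loci
#'
#' Finds the individuals present in *every* supplied per-locus dataset,
#' keyed either by the individual/voucher field alone or (default) by
#' species + individual to avoid cross-species voucher collisions.
#' Combined-locus datasets shrink to this strict intersection, which is
#' why multilocus sample sizes are never larger than any member locus.
#'
#' @param datasets Named list of [BarcodeDataset()]s, one per locus.
#' @param key `"species+individual"` (default) or `"individual"`.
#' @return A list with `matched` (character keys present in all loci)
#'   and `orphans` (named list: keys per locus not shared by all).
#' @export
matchIndividuals <- function(datasets, key = "species+individual") {
  stopifnot(length(datasets) >= 2L)
  keys <- lapply(datasets, .matchKey, key = key)
  for (i in seq_along(keys)) {
    dup <- unique(keys[[i]][duplicated(keys[[i]])])
    if (length(dup))
      stop("duplicate key(s) within locus '", names(datasets)[i], "': ",
           paste(dup, collapse = ", "))
  }
  matched <- Reduce(intersect, keys)
  if (length(matched) == 0L)
    warning("no individual is shared by all loci")
  orphans <- lapply(keys, function(k) setdiff(k, matched))
  names(orphans) <- names(datasets)
  list(matched = matched, orphans = orphans)
}

#' Concatenate per-locus alignments over shared individuals
#'
#' Joins the per-locus gapped sequences of each matched individual in
#' the declared locus order, producing a [ConcatenatedAlignment-class]
#' whose column spans record where each locus sits (half-open, 0-based).
#' The result is a regular alignment and flows through the distance,
#' identification and tree stages unchanged. By default only
#' individuals present in every locus are kept (strict intersection);
#' `gapFill = TRUE` instead keeps the union and pads absent loci with
#' gap columns.
#'
#' @param alignments Named list of [BarcodeAlignment()]s in
#'   concatenation order.
#' @param matched Keys to keep (from [matchIndividuals()]); computed
#'   with the given `key` when `NULL`.
#' @param key Matching key, see [matchIndividuals()].
#' @param name Combined locus label, default e.g. `"ITS+matK"`.
#' @param gapFill Pad individuals absent from a locus with gaps
#'   instead of dropping them.
#' @return A `ConcatenatedAlignment`.
#' @export
concatenateLoci <- function(alignments, matched = NULL,
                            key = "species+individual",
                            name = paste(names(alignments),
                                         collapse = "+"),
                            gapFill = FALSE) {
  stopifnot(length(alignments) >= 2L, !is.null(names(alignments)))
  lapply(alignments, function(a) stopifnot(is(a, "BarcodeAlignment")))
  keys <- lapply(alignments, .matchKey, key = key)
  if (is.null(matched)) {
    matched <- if (gapFill) Reduce(union, keys)
               else matchIndividuals(alignments, key = key)$matched
  }
  if (length(matched) == 0L) stop("no matched individuals to concatenate")
  widths <- vapply(alignments, alignedLength, numeric(1L))
  ends <- cumsum(widths)
  starts <- c(0, ends[-length(ends)])
  segs <- vapply(seq_along(alignments), function(k) {
    idx <- match(matched, keys[[k]])
    if (anyNA(idx) && !gapFill)
      stop("matched individual(s) missing from locus '",
           names(alignments)[k], "': ",
           paste(matched[is.na(idx)], collapse = ", "))
    s <- rep(strrep("-", widths[k]), length(matched))
    s[!is.na(idx)] <-
      as.character(alignments[[k]]@seqs)[idx[!is.na(idx)]]
    s
  }, character(length(matched)))
  if (is.null(dim(segs))) dim(segs) <- c(1L, length(alignments))
  joined <- apply(segs, 1L, paste0, collapse = "")
  # species / individual from the first locus carrying each key
  meta <- do.call(rbind, lapply(seq_along(alignments), function(k) {
    m <- alignments[[k]]@meta
    data.frame(key = keys[[k]], species = as.character(m$species),
               individual = as.character(m$individual))
  }))
  meta <- meta[!duplicated(meta$key), ]
  idx <- match(matched, meta$key)
  metaDF <- S4Vectors::DataFrame(
    id = paste(gsub(" ", "_", meta$species[idx]), meta$individual[idx],
               name, sep = "|"),
    species = meta$species[idx],
    individual = meta$individual[idx],
    locus = name,
    accession = "")
  seqs <- Biostrings::DNAStringSet(joined)
  names(seqs) <- metaDF$id
  new("ConcatenatedAlignment", seqs = seqs, meta = metaDF,
      partitions = data.frame(locus = names(alignments),
                              start = as.integer(starts),
                              end = as.integer(ends)))
}

#' @rdname concatenateLoci
#' @param x A `ConcatenatedAlignment`.
#' @return `locusPartitions()` returns the span `data.frame`.
#' @export
locusPartitions <- function(x) {
  stopifnot(is(x, "ConcatenatedAlignment"))
  x@partitions
}
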