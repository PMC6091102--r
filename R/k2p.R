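#' Pairwise substitution counts under pairwise deletion
#'
#' For one pair of equal-length gapped sequences, counts the sites that
#' remain after pairwise deletion (columns where either member carries a
#' gap or an ambiguity code are dropped for that pair only), and splits
#' the mismatches into transitions (A<->G, C<->T) and transversions
#' (all other base mismatches). `P` and `Q` are the transition and
#' transversion proportions over the comparable sites.
#'
#' @param a,b Gapped nucleotide strings (or `XString`s) of equal length.
#' @return A list with `nSites`, `transitions`, `transversions`, `P`,
#'   `Q`. When no site survives pairwise deletion, `nSites` is 0 and
#'   `P`/`Q` are `NA` (the undefined-distance signal).
#' @examples
#' pairwiseCounts("AAAAAAAAAA", "GAAAAAAAAA")  # P = 0.1
#' @export
pairwiseCounts <- function(a, b) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (nchar(a) != nchar(b))
    stop("sequences have unequal gapped lengths: ", nchar(a), " vs ",
         nchar(b))
  ca <- .encodeChars(strsplit(a, "", fixed = TRUE)[[1L]])
  cb <- .encodeChars(strsplit(b, "", fixed = TRUE)[[1L]])
  ok <- ca >= 1L & ca <= 4L & cb >= 1L & cb <= 4L
  n <- sum(ok)
  if (n == 0L)
    return(list(nSites = 0L, transitions = 0L, transversions = 0L,
                P = NA_real_, Q = NA_real_))
  dif <- ca[ok] - cb[ok]
  ts <- sum(abs(dif) == 2L)          # A(1)<->G(3), C(2)<->T(4)
  tv <- sum(dif != 0L) - ts
  list(nSites = n, transitions = ts, transversions = tv,
       P = ts / n, Q = tv / n)
}

#' Kimura 2-parameter distance from substitution proportions
#'
#' Evaluates `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)`, the K2P
#' estimate of substitutions per site given transition proportion `P`
#' and transversion proportion `Q`. Outside the model's domain
#' (`1 - 2P - Q <= 0` or `1 - 2Q <= 0`, a saturated pair) the distance
#' is undefined and `NA` is returned rather than a clamped value.
#'
#' @param P Transition proportion, or the list from [pairwiseCounts()]
#'   (in which case `Q` is ignored).
#' @param Q Transversion proportion.
#' @return Distance in substitutions/site, or `NA` when undefined.
#' @export
k2p <- function(P, Q = NULL) {
  if (is.list(P)) { Q <- P$Q; P <- P$P }
  if (is.na(P) || is.na(Q)) return(NA_real_)
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(NA_real_)
  -0.5 * log(w1) - 0.25 * log(w2)
}

#' Pairwise K2P distance matrix for an alignment
#'
#' Computes the Kimura 2-parameter distance between every unordered
#' pair of rows under pairwise deletion (see [pairwiseCounts()]), and
#' attaches each record's species so the matrix can be partitioned into
#' intra- and inter-specific sets. Saturated or incomparable pairs are
#' stored as `NA` and counted, never clamped.
#'
#' @param x A [BarcodeAlignment()], or a `DNAStringSet`/character vector
#'   of equal-length gapped sequences with `species` supplied.
#' @param species Species per row (ignored when `x` carries metadata).
#' @param ... Unused.
#' @return A [K2PDistanceMatrix-class] object.
#' @rdname k2pDistanceMatrix
#' @export
setMethod("k2pDistanceMatrix", "BarcodeAlignment", function(x, ...) {
  .k2pMatrix(.encodeAlignment(x), speciesLabels(x))
})

#' @rdname k2pDistanceMatrix
#' @export
setMethod("k2pDistanceMatrix", "ANY", function(x, species, ...) {
  aln <- BarcodeAlignment(x, species = species,
                          individual = as.character(seq_along(x)))
  .k2pMatrix(.encodeAlignment(aln), speciesLabels(aln))
})

.k2pMatrix <- function(enc, species) {
  n <- nrow(enc)
  if (n < 2L) stop("need at least 2 sequences for a distance matrix")
  ids <- names(species)
  valid <- enc >= 1L & enc <= 4L
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  nUndef <- 0L
  for (i in seq_len(n - 1L)) {
    vi <- valid[i, ]; ei <- enc[i, ]
    for (j in (i + 1L):n) {
      ok <- vi & valid[j, ]
      ns <- sum(ok)
      if (ns == 0L) { d[i, j] <- d[j, i] <- NA_real_; nUndef <- nUndef + 1L; next }
      dif <- ei[ok] - enc[j, ok]
      ts <- sum(abs(dif) == 2L)
      tv <- sum(dif != 0L) - ts
      dij <- k2p(ts / ns, tv / ns)
      if (is.na(dij)) nUndef <- nUndef + 1L
      d[i, j] <- d[j, i] <- dij
    }
  }
  new("K2PDistanceMatrix", d = d, species = species,
      nUndefined = nUndef)
}

#' @param x A `K2PDistanceMatrix`.
#' @param percent Return distances multiplied by 100.
#' @param ... Unused.
#' @return `distances()` returns the symmetric numeric matrix
#'   (`NA` = undefined pair).
#' @rdname distances
#' @export
setMethod("distances", "K2PDistanceMatrix",
          function(x, percent = FALSE, ...) {
  if (percent) .toPercent(x@d) else x@d
})

setMethod("show", "K2PDistanceMatrix", function(object) {
  cat("K2PDistanceMatrix with", nrow(object@d), "records,",
      length(unique(object@species)), "species\n")
  if (object@nUndefined)
    cat("  undefined pairs:", object@nUndefined, "\n")
})

#' Partition pairwise distances into intra- and inter-specific sets
#'
#' Every unordered pair with a defined distance lands in exactly one
#' partition: `intra` when both records share a species, `inter`
#' otherwise. Undefined (saturated) pairs are excluded and counted.
#'
#' @param dm A [K2PDistanceMatrix-class] object.
#' @return A list with `intra` and `inter` `data.frame`s (`id1`, `id2`,
#'   `species1`, `species2`, `distance` in substitutions/site) and
#'   `nUndefined`.
#' @export
distancePartition <- function(dm) {
  stopifnot(is(dm, "K2PDistanceMatrix"))
  d <- dm@d
  ids <- rownames(d)
  ut <- upper.tri(d)
  idx <- which(ut, arr.ind = TRUE)
  dist <- d[ut]
  keep <- !is.na(dist)
  idx <- idx[keep, , drop = FALSE]
  dist <- dist[keep]
  sp1 <- dm@species[idx[, 1L]]
  sp2 <- dm@species[idx[, 2L]]
  pairs <- data.frame(id1 = ids[idx[, 1L]], id2 = ids[idx[, 2L]],
                      species1 = unname(sp1), species2 = unname(sp2),
                      distance = dist)
  same <- pairs$species1 == pairs$species2
  list(intra = pairs[same, , drop = FALSE],
       inter = pairs[!same, , drop = FALSE],
       nUndefined = dm@nUndefined)
}

#' Min/max/mean of intra- and inter-specific distances, in percent
#'
#' Summaries are taken over defined distances only and reported on the
#' percent scale (substitutions/site x 100). An empty partition (e.g.
#' no intraspecific pair because every species has one record) yields a
#' row of `NA`s with `n = 0`, marked unavailable rather than zero.
#'
#' @param dm A [K2PDistanceMatrix-class] object.
#' @return A `data.frame` with rows `intra` and `inter` and columns
#'   `partition`, `n`, `min`, `max`, `mean` (percent).
#' @export
summarizeDistances <- function(dm) {
  part <- distancePartition(dm)
  one <- function(name, df) {
    if (nrow(df) == 0L)
      return(data.frame(partition = name, n = 0L, min = NA_real_,
                        max = NA_real_, mean = NA_real_))
    v <- .toPercent(df$distance)
    data.frame(partition = name, n = nrow(df), min = min(v),
               max = max(v), mean = mean(v))
  }
  rbind(one("intra", part$intra), one("inter", part$inter))
}
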