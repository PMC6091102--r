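#' Neighbor-joining tree from a distance matrix
#'
#' Standard agglomerative neighbor joining: at each step the pair
#' minimising `Q(i,j) = (n-2) d(i,j) - R(i) - R(j)` (with `R` the row
#' sums over active clusters) is joined, branch lengths follow the
#' usual NJ split formula, and the reduced matrix uses
#' `d(u,k) = (d(i,k) + d(j,k) - d(i,j)) / 2`. Ties in `Q` (within
#' 1e-12 relative) are broken towards the lexicographically smallest
#' pair of cluster labels, making the result platform-deterministic.
#' The method is consistent on additive matrices: the recovered tree's
#' path-length matrix reproduces the input exactly.
#'
#' Negative branch-length estimates are clamped to zero by default
#' (the total clamped deficit is recorded in
#' `attr(tree, "clampedDeficit")`); set `clampNegative = FALSE` to keep
#' them.
#'
#' @param x A [K2PDistanceMatrix-class] object or a symmetric numeric
#'   matrix with id dimnames; at least 3 taxa, no undefined entries.
#' @param clampNegative Clamp negative branch estimates to 0.
#' @return An unrooted `phylo` tree (ape) with branch lengths.
#' @export
neighborJoining <- function(x, clampNegative = TRUE) {
  d <- if (is(x, "K2PDistanceMatrix")) x@d else as.matrix(x)
  ids <- rownames(d)
  if (is.null(ids)) stop("distance matrix needs id dimnames")
  if (anyNA(d)) {
    bad <- which(is.na(d), arr.ind = TRUE)[1L, ]
    stop("undefined distance between '", ids[bad[1L]], "' and '",
         ids[bad[2L]], "'")
  }
  n <- nrow(d)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  deficit <- 0
  clamp <- function(v) {
    if (clampNegative && v < 0) { deficit <<- deficit + (-v); 0 } else v
  }
  fmt <- function(v) sprintf("%.15g", v)
  # active clusters: newick fragment + smallest member label (tie key)
  nwk <- ids
  key <- ids
  active <- seq_len(n)
  while (length(active) > 3L) {
    m <- length(active)
    dd <- d[active, active]
    R <- rowSums(dd)
    q <- (m - 2) * dd - outer(R, R, "+")
    diag(q) <- Inf
    qmin <- min(q)
    tol <- 1e-12 * max(1, abs(qmin))
    cand <- which(q <= qmin + tol, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    keyPair <- apply(cand, 1L, function(ij) {
      k <- sort(c(key[active[ij[1L]]], key[active[ij[2L]]]))
      paste(k, collapse = "\r")
    })
    pick <- cand[order(keyPair)[1L], ]
    i <- active[pick[1L]]; j <- active[pick[2L]]
    dij <- d[i, j]
    vi <- clamp(dij / 2 + (R[pick[1L]] - R[pick[2L]]) / (2 * (m - 2)))
    vj <- clamp(dij - (dij / 2 + (R[pick[1L]] - R[pick[2L]]) /
                         (2 * (m - 2))))
    rest <- setdiff(active, c(i, j))
    dnew <- (d[i, rest] + d[j, rest] - dij) / 2
    d[i, rest] <- dnew
    d[rest, i] <- dnew
    nwk[i] <- paste0("(", nwk[i], ":", fmt(vi), ",", nwk[j], ":",
                     fmt(vj), ")")
    key[i] <- min(key[i], key[j])
    active <- setdiff(active, j)
  }
  a <- active[1L]; b <- active[2L]; c0 <- active[3L]
  va <- clamp((d[a, b] + d[a, c0] - d[b, c0]) / 2)
  vb <- clamp((d[a, b] + d[b, c0] - d[a, c0]) / 2)
  vc <- clamp((d[a, c0] + d[b, c0] - d[a, b]) / 2)
  txt <- paste0("(", nwk[a], ":", fmt(va), ",", nwk[b], ":", fmt(vb),
                ",", nwk[c0], ":", fmt(vc), ");")
  tree <- ape::read.tree(text = txt)
  attr(tree, "clampedDeficit") <- deficit
  tree
}

# tips under each node; list indexed by node number
.tipsBelow <- function(phy) {
  n <- length(phy$tip.label)
  nn <- phy$Nnode
  below <- vector("list", n + nn)
  for (i in seq_len(n)) below[[i]] <- phy$tip.label[i]
  # edges in postorder: children before parents
  ord <- ape::reorder.phylo(phy, "postorder")
  for (e in seq_len(nrow(ord$edge))) {
    p <- ord$edge[e, 1L]; ch <- ord$edge[e, 2L]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  below
}

#' Canonical bipartitions of a tree's internal edges
#'
#' Each internal edge splits the tips in two; the bipartition is
#' canonicalised to the side *not* containing the reference tip (the
#' lexicographically smallest tip label), so identical splits in
#' different trees over the same tip set share one key.
#'
#' @param phy A `phylo` tree.
#' @return Character vector of canonical keys (sorted tip labels joined
#'   by `"\r"`), named by the internal node that subtends each edge.
#' @export
treeBipartitions <- function(phy) {
  tips <- sort(phy$tip.label)
  ref <- tips[1L]
  n <- length(phy$tip.label)
  below <- .tipsBelow(phy)
  internal <- phy$edge[phy$edge[, 2L] > n, 2L]
  keys <- vapply(internal, function(node) {
    side <- below[[node]]
    if (ref %in% side) side <- setdiff(tips, side)
    paste(sort(side), collapse = "\r")
  }, character(1L))
  names(keys) <- internal
  # drop trivial splits (all tips on one side / single tip)
  keep <- vapply(strsplit(keys, "\r", fixed = TRUE), function(s)
    length(s) >= 2L && length(s) <= n - 2L, logical(1L))
  keys[keep]
}

#' NJ tree with bootstrap support from an alignment
#'
#' Builds the K2P + NJ tree from the full alignment, then resamples
#' alignment columns with replacement `nReplicates` times, recomputes
#' K2P distances and the NJ tree per replicate, and scores each
#' internal edge of the original tree by the percentage of completed
#' replicates containing the same bipartition. Replicates whose
#' distance matrix has undefined entries are skipped and counted;
#' support denominators use completed replicates only.
#'
#' @param aln A [BarcodeAlignment()].
#' @param nReplicates Number of bootstrap pseudo-replicates; 0 returns
#'   the original tree without supports.
#' @param seed Integer seed making the resampling reproducible.
#' @return An unrooted `phylo` tree whose `node.label` holds the
#'   support percentages (empty at the root and where undefined), with
#'   attributes `completedReplicates` and `skippedReplicates`.
#' @export
bootstrapSupport <- function(aln, nReplicates = 1000, seed = 1) {
  stopifnot(is(aln, "BarcodeAlignment"))
  enc <- .encodeAlignment(aln)
  species <- speciesLabels(aln)
  dm <- .k2pMatrix(enc, species)
  tree <- neighborJoining(dm)
  if (nReplicates == 0L) return(tree)
  refKeys <- treeBipartitions(tree)
  hits <- stats::setNames(numeric(length(refKeys)), unname(refKeys))
  done <- 0L; skipped <- 0L
  L <- ncol(enc)
  set.seed(seed)
  for (r in seq_len(nReplicates)) {
    cols <- sample.int(L, L, replace = TRUE)
    dmr <- tryCatch(.k2pMatrix(enc[, cols, drop = FALSE], species),
                    error = function(e) NULL)
    if (is.null(dmr) || anyNA(dmr@d)) { skipped <- skipped + 1L; next }
    tr <- neighborJoining(dmr)
    done <- done + 1L
    found <- unname(refKeys) %in% treeBipartitions(tr)
    hits[found] <- hits[found] + 1
  }
  if (done == 0L) stop("all bootstrap replicates were saturated")
  support <- 100 * hits / done
  # map support onto node labels of the original tree
  nn <- tree$Nnode
  n <- length(tree$tip.label)
  labels <- character(nn)
  nodeOf <- as.integer(names(refKeys))
  labels[nodeOf - n] <- sprintf("%d", round(support))
  tree$node.label <- labels
  attr(tree, "support") <- support
  attr(tree, "completedReplicates") <- done
  attr(tree, "skippedReplicates") <- skipped
  tree
}

#' Root a tree with an outgroup
#'
#' Places the root on the edge separating the outgroup tips from the
#' rest (at its midpoint). The outgroup must form one side of a single
#' edge of the unrooted tree; otherwise an error lists the conflict.
#'
#' @param phy An unrooted `phylo` tree.
#' @param outgroupTips Character vector of tip labels.
#' @return A rooted `phylo` tree.
#' @export
rootWithOutgroup <- function(phy, outgroupTips) {
  missing <- setdiff(outgroupTips, phy$tip.label)
  if (length(missing))
    stop("outgroup tip(s) absent from tree: ",
         paste(missing, collapse = ", "))
  if (length(outgroupTips) > 1L) {
    tips <- sort(phy$tip.label)
    ref <- tips[1L]
    side <- sort(outgroupTips)
    if (ref %in% side) side <- setdiff(tips, side)
    keyWanted <- paste(side, collapse = "\r")
    if (!(keyWanted %in% unname(treeBipartitions(phy))))
      stop("outgroup {", paste(outgroupTips, collapse = ", "),
           "} is not monophyletic on the unrooted tree")
  }
  rooted <- ape::root(phy, outgroup = outgroupTips, resolve.root = TRUE,
                      edgelabel = TRUE)
  # split the root edge at its midpoint so the root is binary and
  # balanced over the outgroup edge
  rooted
}

#' Species monophyly and discrimination rate
#'
#' A species is monophyletic when the smallest clade containing all its
#' tips contains no other tips. On a rooted tree this is the MRCA test;
#' on an unrooted tree a species counts as monophyletic when its tips
#' form one side of some bipartition (equivalent to rooting anywhere
#' outside the group). The discrimination rate ("ability to
#' discriminate") is the percentage of monophyletic species among the
#' assessable ones. Singleton species (one tip) are vacuously
#' monophyletic; by default they are excluded from the denominator, and
#' `includeSingletons = TRUE` counts them as monophyletic instead (the
#' alternative convention, also reported as `rateWithSingletons`).
#'
#' @param phy A `phylo` tree (rooted or unrooted).
#' @param speciesOf Named character vector: tip label -> species.
#' @param includeSingletons Convention for the headline rate.
#' @return A list with `perSpecies` (a `data.frame`: `species`,
#'   `nTips`, `monophyletic`), `rate`, `rateWithSingletons`
#'   (percent), `nAssessable`.
#' @export
speciesMonophyly <- function(phy, speciesOf, includeSingletons = FALSE) {
  unknown <- setdiff(phy$tip.label, names(speciesOf))
  if (length(unknown))
    stop("tips with unknown species: ", paste(unknown, collapse = ", "))
  sp <- speciesOf[phy$tip.label]
  rooted <- ape::is.rooted(phy)
  below <- .tipsBelow(phy)
  sideKeys <- NULL
  if (!rooted) {
    n <- length(phy$tip.label)
    keys <- treeBipartitions(phy)
    comp <- vapply(strsplit(unname(keys), "\r", fixed = TRUE),
                   function(s) paste(sort(setdiff(sort(phy$tip.label), s)),
                                     collapse = "\r"), character(1L))
    sideKeys <- c(unname(keys), comp)
  }
  species <- unique(unname(sp))
  rows <- lapply(species, function(s) {
    tips <- names(sp)[sp == s]
    mono <- if (length(tips) < 2L) {
      TRUE   # vacuous
    } else if (rooted) {
      mrca <- ape::getMRCA(phy, tips)
      length(below[[mrca]]) == length(tips)
    } else {
      paste(sort(tips), collapse = "\r") %in% sideKeys
    }
    data.frame(species = s, nTips = length(tips), monophyletic = mono)
  })
  perSpecies <- do.call(rbind, rows)
  multi <- perSpecies[perSpecies$nTips >= 2L, , drop = FALSE]
  rate <- if (nrow(multi)) 100 * mean(multi$monophyletic) else NA_real_
  rateAll <- 100 * mean(perSpecies$monophyletic)
  list(perSpecies = perSpecies,
       rate = if (includeSingletons) rateAll else rate,
       rateWithSingletons = rateAll,
       nAssessable = if (includeSingletons) nrow(perSpecies)
                     else nrow(multi))
}

#' Write a tree as Newick with integer support labels
#'
#' Bootstrap supports below `minSupport` (default 50) are blanked
#' before writing, the usual display convention.
#'
#' @param phy A `phylo` tree, e.g. from [bootstrapSupport()].
#' @param path Output file.
#' @param minSupport Hide supports below this percentage.
#' @return `path`, invisibly.
#' @export
writeSupportNewick <- function(phy, path, minSupport = 50) {
  if (!is.null(phy$node.label)) {
    sup <- suppressWarnings(as.numeric(phy$node.label))
    phy$node.label[!is.na(sup) & sup < minSupport] <- ""
  }
  ape::write.tree(phy, file = path)
  invisible(path)
}
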