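#' Fixed-interval histogram of pairwise distances
#'
#' Bins distance values (percent scale) into half-open intervals
#' `[k*w, (k+1)*w)`: a value sitting exactly on a boundary falls in the
#' bin it opens. The default interval of 0.05 matches the resolution
#' customarily used when plotting intra- against inter-specific
#' distance distributions.
#'
#' @param values Non-negative distances (percent).
#' @param binWidth Interval width (> 0), same scale as `values`.
#' @return A `data.frame` with `binLow`, `binHigh`, `count`; empty input
#'   yields zero rows. Counts sum to `length(values)`.
#' @export
distanceHistogram <- function(values, binWidth = 0.05) {
  stopifnot(binWidth > 0)
  values <- values[!is.na(values)]
  if (any(values < 0)) stop("distances must be non-negative")
  if (length(values) == 0L)
    return(data.frame(binLow = numeric(), binHigh = numeric(),
                      count = integer()))
  bin <- floor(values / binWidth)
  tab <- table(bin)
  k <- 0:max(bin)
  count <- integer(length(k))
  count[match(as.integer(names(tab)), k)] <- as.integer(tab)
  data.frame(binLow = k * binWidth, binHigh = (k + 1) * binWidth,
             count = count)
}

#' Barcoding-gap analysis
#'
#' A barcoding gap exists when the minimum inter-specific distance is
#' strictly larger than the maximum intra-specific distance; ties count
#' as no gap. The report carries both extremes, the gap width
#' (`minInter - maxIntra` when positive, else 0), and fixed-interval
#' histograms of the two distributions.
#'
#' @param x A [K2PDistanceMatrix-class] object or the list returned by
#'   [distancePartition()].
#' @param binWidth Histogram interval on the percent scale.
#' @return A list of class `GapReport`: `maxIntra`, `minInter`,
#'   `gapExists`, `gapWidth` (all percent; extremes `NA` and
#'   `gapExists`/`gapWidth` `NA` when a partition is empty),
#'   `intraAvailable`, `interAvailable`, `histIntra`, `histInter`,
#'   `nIntra`, `nInter`.
#' @export
gapAnalysis <- function(x, binWidth = 0.05) {
  part <- if (is(x, "K2PDistanceMatrix")) distancePartition(x) else x
  intra <- .toPercent(part$intra$distance)
  inter <- .toPercent(part$inter$distance)
  intraOk <- length(intra) > 0L
  interOk <- length(inter) > 0L
  maxIntra <- if (intraOk) max(intra) else NA_real_
  minInter <- if (interOk) min(inter) else NA_real_
  gapExists <- if (intraOk && interOk) minInter > maxIntra else NA
  gapWidth <- if (isTRUE(gapExists)) minInter - maxIntra
              else if (intraOk && interOk) 0 else NA_real_
  structure(list(maxIntra = maxIntra, minInter = minInter,
                 gapExists = gapExists, gapWidth = gapWidth,
                 intraAvailable = intraOk, interAvailable = interOk,
                 histIntra = distanceHistogram(intra, binWidth),
                 histInter = distanceHistogram(inter, binWidth),
                 nIntra = length(intra), nInter = length(inter)),
            class = "GapReport")
}

#' @export
print.GapReport <- function(x, ...) {
  cat("Barcoding gap report\n")
  cat(sprintf("  max intra: %s%%  min inter: %s%%\n",
              format(x$maxIntra), format(x$minInter)))
  cat(sprintf("  gap exists: %s (width %s%%)\n",
              format(x$gapExists), format(x$gapWidth)))
  invisible(x)
}

#' Per-species local barcoding gap
#'
#' For each species: the maximum intra-specific distance among its own
#' pairs (undefined for singletons) and the minimum distance from any
#' member to any non-member (its nearest-neighbour distance). The local
#' gap holds when the latter strictly exceeds the former. Note that a
#' local gap for every species does not imply a global gap: different
#' species' distance ranges can interleave.
#'
#' @param dm A [K2PDistanceMatrix-class] object.
#' @return A `data.frame` with `species`, `nRecords`, `maxIntra`,
#'   `minInter` (percent; `NA` where undefined) and `localGap`.
#' @export
perSpeciesGap <- function(dm) {
  stopifnot(is(dm, "K2PDistanceMatrix"))
  sp <- dm@species
  if (length(unique(sp)) < 2L) stop("need at least 2 species")
  d <- dm@d
  out <- lapply(unique(sp), function(s) {
    own <- which(sp == s)
    oth <- which(sp != s)
    intra <- if (length(own) >= 2L) {
      v <- d[own, own][upper.tri(diag(length(own)))]
      v <- v[!is.na(v)]
      if (length(v)) max(v) else NA_real_
    } else NA_real_
    v <- d[own, oth, drop = FALSE]
    v <- v[!is.na(v)]
    inter <- if (length(v)) min(v) else NA_real_
    data.frame(species = s, nRecords = length(own),
               maxIntra = .toPercent(intra),
               minInter = .toPercent(inter),
               localGap = if (is.na(intra) || is.na(inter)) NA
                          else inter > intra)
  })
  do.call(rbind, out)
}
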