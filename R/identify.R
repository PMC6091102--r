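#' Intraspecific distance threshold for close-match identification
#'
#' The best-close-match criterion refuses matches beyond a threshold
#' distance, conventionally the 95th percentile of all pairwise
#' intraspecific distances. Percentiles interpolate linearly between
#' order statistics ([stats::quantile()] type 7).
#'
#' @param dm A [K2PDistanceMatrix-class] object.
#' @param percentile Percentile of the intraspecific distances (0-100).
#' @return Threshold on the percent scale.
#' @export
intraspecificThreshold <- function(dm, percentile = 95) {
  part <- distancePartition(dm)
  if (nrow(part$intra) == 0L)
    stop("no intraspecific pairs: supply a manual threshold instead")
  unname(stats::quantile(.toPercent(part$intra$distance),
                         probs = percentile / 100, type = 7))
}

# Leave-one-out machinery shared by the three criteria. For each query
# record, the tied set of nearest non-self records (ties within `tieTol`
# substitutions/site) and its distance.
.nearestSets <- function(dm, tieTol) {
  d <- dm@d
  n <- nrow(d)
  lapply(seq_len(n), function(i) {
    di <- d[i, -i]
    ids <- rownames(d)[-i]
    ok <- !is.na(di)
    if (!any(ok)) return(NULL)   # all distances undefined -> no verdict
    di <- di[ok]; ids <- ids[ok]
    dmin <- min(di)
    list(ids = ids[di <= dmin + tieTol], distance = dmin)
  })
}

.verdictFromTies <- function(querySpecies, tieSpecies) {
  con <- tieSpecies == querySpecies
  if (all(con)) "correct" else if (all(!con)) "incorrect" else "ambiguous"
}

.matchFrame <- function(dm, verdicts, nearest, criterion) {
  ids <- rownames(dm@d)
  data.frame(
    query = ids,
    species = unname(dm@species),
    criterion = criterion,
    verdict = verdicts,
    nearestIds = vapply(nearest, function(x)
      if (is.null(x)) NA_character_ else paste(x$ids, collapse = ";"),
      character(1L)),
    nearestDistance = vapply(nearest, function(x)
      if (is.null(x)) NA_real_ else .toPercent(x$distance), numeric(1L)))
}

#' Leave-one-out identification criteria
#'
#' Each record is queried in turn against all others. Under *best
#' match*, the verdict comes from the tied set of nearest neighbours:
#' `correct` when all are conspecific, `incorrect` when none are, and
#' `ambiguous` when the tie mixes both. *Best close match* additionally
#' refuses any query whose nearest neighbour lies beyond `threshold`
#' (verdict `no_match`). Under *all species barcodes*, a query is
#' `correct` only when every conspecific record is strictly closer than
#' the closest heterospecific one, `ambiguous` when that decisive
#' comparison is a tie, `incorrect` otherwise, and `no_match` beyond
#' the threshold; queries from singleton species are excluded
#' (verdict `NA`).
#'
#' Queries whose distances are all undefined get verdict `NA` and are
#' excluded from summaries. Distances within `tieTol`
#' (substitutions/site) are treated as tied.
#'
#' @param dm A [K2PDistanceMatrix-class] object.
#' @param threshold Distance threshold on the percent scale, e.g. from
#'   [intraspecificThreshold()]; `Inf` disables the refusal rule, under
#'   which best close match reduces exactly to best match.
#' @param tieTol Absolute tie tolerance in substitutions/site.
#' @return A `data.frame` with one row per query: `query`, `species`,
#'   `criterion`, `verdict`, `nearestIds` (";"-joined tied set),
#'   `nearestDistance` (percent).
#' @seealso [summarizeIdentification()]
#' @export
bestMatch <- function(dm, tieTol = 1e-12) {
  stopifnot(is(dm, "K2PDistanceMatrix"), nrow(dm@d) >= 2L)
  nearest <- .nearestSets(dm, tieTol)
  verdicts <- vapply(seq_along(nearest), function(i) {
    x <- nearest[[i]]
    if (is.null(x)) return(NA_character_)
    .verdictFromTies(dm@species[i], dm@species[x$ids])
  }, character(1L))
  .matchFrame(dm, verdicts, nearest, "best_match")
}

#' @rdname bestMatch
#' @export
bestCloseMatch <- function(dm, threshold, tieTol = 1e-12) {
  out <- bestMatch(dm, tieTol)
  out$criterion <- "best_close_match"
  far <- !is.na(out$verdict) & out$nearestDistance > threshold
  out$verdict[far] <- "no_match"
  out
}

#' @rdname bestMatch
#' @export
allSpeciesBarcodes <- function(dm, threshold = Inf, tieTol = 1e-12) {
  stopifnot(is(dm, "K2PDistanceMatrix"), nrow(dm@d) >= 2L)
  d <- dm@d
  ids <- rownames(d)
  sp <- dm@species
  nearest <- .nearestSets(dm, tieTol)
  verdicts <- vapply(seq_along(ids), function(i) {
    x <- nearest[[i]]
    if (is.null(x)) return(NA_character_)
    con <- which(sp == sp[i])
    con <- con[con != i]
    if (length(con) == 0L) return(NA_character_)   # singleton species
    het <- which(sp != sp[i])
    if (.toPercent(x$distance) > threshold) return("no_match")
    dcon <- d[i, con]; dhet <- d[i, het]
    if (anyNA(dcon)) return("incorrect")  # an incomparable conspecific
    dhet <- dhet[!is.na(dhet)]
    if (length(dhet) == 0L) return("correct")
    gapv <- min(dhet) - max(dcon)
    if (abs(gapv) <= tieTol) "ambiguous"
    else if (gapv > 0) "correct" else "incorrect"
  }, character(1L))
  .matchFrame(dm, verdicts, nearest, "all_species_barcodes")
}

#' Summarise identification outcomes as Table-style percentages
#'
#' Percentages of `correct`, `ambiguous`, `incorrect` and `no_match`
#' verdicts over the queried records (rows with verdict `NA` — excluded
#' singletons or all-undefined queries — leave the denominator).
#'
#' @param outcomes A `data.frame` from [bestMatch()],
#'   [bestCloseMatch()] or [allSpeciesBarcodes()], or several
#'   `rbind`-ed together.
#' @return A `data.frame` with one row per criterion: `criterion`, `n`
#'   (denominator), `pctCorrect`, `pctAmbiguous`, `pctIncorrect`,
#'   `pctNoMatch` (summing to 100 up to rounding).
#' @export
summarizeIdentification <- function(outcomes) {
  stopifnot(nrow(outcomes) >= 1L)
  out <- lapply(split(outcomes, outcomes$criterion), function(df) {
    v <- df$verdict[!is.na(df$verdict)]
    n <- length(v)
    pct <- function(w) if (n) 100 * sum(v == w) / n else NA_real_
    data.frame(criterion = df$criterion[1L], n = n,
               pctCorrect = pct("correct"),
               pctAmbiguous = pct("ambiguous"),
               pctIncorrect = pct("incorrect"),
               pctNoMatch = pct("no_match"))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
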