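#' Configuration for the barcode dataset simulator
#'
#' Collects and validates the parameters of the Kimura-process
#' generator. Divergences are expected substitutions per site between
#' *individuals*: `intraDivergence` is the expected pairwise divergence
#' between two conspecific individuals, `interDivergence` the expected
#' pairwise divergence between individuals of different species (so the
#' species-ancestor divergence is `interDivergence - intraDivergence`,
#' making both quantities directly recoverable by the K2P estimator).
#' `kappa` is the transition/transversion *rate* ratio (alpha/beta).
#'
#' @param nSpecies Number of species.
#' @param individualsPerSpecies Integer, or an integer vector of length
#'   `nSpecies` for variable sampling depth.
#' @param seqLength Sites per locus (used when `loci` is `NULL`).
#' @param intraDivergence Expected within-species pairwise divergence.
#' @param interDivergence Expected between-species pairwise divergence
#'   (must be >= `intraDivergence`).
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param loci Named numeric vector of per-locus lengths (default one
#'   locus `ITS` of `seqLength` sites).
#' @param sharedFraction For loci after the first, the probability that
#'   an individual is also sampled for that locus (emulating the
#'   partial overlap of individuals across loci in real multi-locus
#'   reference sets).
#' @param includeOutgroup Append a distant outgroup record.
#' @param outgroupDivergence Expected divergence from the root to the
#'   outgroup tip.
#' @param seed Integer seed.
#' @return A validated list of class `SimulationConfig`.
#' @export
simulationConfig <- function(nSpecies = 10, individualsPerSpecies = 3,
                             seqLength = 1000, intraDivergence = 0.01,
                             interDivergence = 0.10, kappa = 2,
                             loci = NULL, sharedFraction = 0.8,
                             includeOutgroup = FALSE,
                             outgroupDivergence = 0.3, seed = 1) {
  if (is.null(loci)) loci <- stats::setNames(seqLength, "ITS")
  if (is.null(names(loci)) || any(!nzchar(names(loci))))
    stop("loci must be a named vector of lengths")
  nInd <- rep_len(as.integer(individualsPerSpecies), nSpecies)
  bad <- character()
  if (nSpecies < 1L) bad <- c(bad, "nSpecies must be >= 1")
  if (any(nInd < 1L)) bad <- c(bad, "individualsPerSpecies must be >= 1")
  if (any(loci < 1)) bad <- c(bad, "locus lengths must be >= 1")
  if (intraDivergence < 0) bad <- c(bad, "intraDivergence must be >= 0")
  if (interDivergence < intraDivergence)
    bad <- c(bad, "interDivergence must be >= intraDivergence")
  if (kappa <= 0) bad <- c(bad, "kappa must be > 0")
  if (sharedFraction < 0 || sharedFraction > 1)
    bad <- c(bad, "sharedFraction must be in [0, 1]")
  if (length(bad)) stop(paste(bad, collapse = "; "))
  structure(list(nSpecies = as.integer(nSpecies),
                 individualsPerSpecies = nInd,
                 loci = loci, intraDivergence = intraDivergence,
                 interDivergence = interDivergence, kappa = kappa,
                 sharedFraction = sharedFraction,
                 includeOutgroup = isTRUE(includeOutgroup),
                 outgroupDivergence = outgroupDivergence,
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

# Kimura two-parameter site evolution. Branch length b is the expected
# number of substitutions/site; rates are scaled so alpha + 2 beta = 1,
# with alpha = kappa * beta. Closed-form substitution probabilities:
#   P(b) = 1/4 + 1/4 exp(-4 beta b) - 1/2 exp(-2 (alpha + beta) b)
#   Q(b) = 1/2 - 1/2 exp(-4 beta b)
.k2pSubstProbs <- function(b, kappa) {
  beta <- 1 / (kappa + 2)
  alpha <- kappa * beta
  e1 <- exp(-4 * beta * b)
  e2 <- exp(-2 * (alpha + beta) * b)
  c(P = 0.25 + 0.25 * e1 - 0.5 * e2, Q = 0.5 - 0.5 * e1)
}

# integer codes 1..4 = A C G T
.TS_PARTNER <- c(3L, 4L, 1L, 2L)                 # A<->G, C<->T
.TV_PARTNERS <- matrix(c(2L, 4L,   # A -> C/T
                         1L, 3L,   # C -> A/G
                         2L, 4L,   # G -> C/T
                         1L, 3L),  # T -> A/G
                       nrow = 4L, byrow = TRUE)

.evolveCodes <- function(codes, b, kappa) {
  if (b == 0) return(codes)
  pq <- .k2pSubstProbs(b, kappa)
  L <- length(codes)
  u <- stats::runif(L)
  out <- codes
  ts <- u < pq["P"]
  tv <- !ts & u < pq["P"] + pq["Q"]
  out[ts] <- .TS_PARTNER[codes[ts]]
  if (any(tv)) {
    pickSecond <- stats::runif(sum(tv)) < 0.5
    out[tv] <- .TV_PARTNERS[cbind(codes[tv], 1L + pickSecond)]
  }
  out
}

#' Simulate a species-structured barcode dataset
#'
#' Generates aligned, species-labelled sequences under a Kimura
#' two-parameter substitution process on a star species tree: a uniform
#' random root sequence is evolved to each species ancestor and each
#' individual is evolved from its ancestor, with branch lengths chosen
#' so that expected pairwise divergences match the configured
#' `intraDivergence` (conspecific pairs) and `interDivergence`
#' (heterospecific pairs). Loci evolve independently over the same
#' individuals; for loci after the first, each individual is retained
#' with probability `sharedFraction`, emulating the partial overlap of
#' records across loci. Sequences are generated already aligned (no
#' indel process). An optional outgroup tip is evolved straight from
#' the root.
#'
#' @param cfg A [simulationConfig()].
#' @return A list with `datasets` (named list of [BarcodeAlignment()],
#'   one per locus) and `truth` (the config plus the species of every
#'   individual and the expected divergences).
#' @export
simulateBarcodeData <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(cfg$seed)
  nSp <- cfg$nSpecies
  speciesNames <- sprintf("Simulatus species%02d", seq_len(nSp))
  ancBranch <- (cfg$interDivergence - cfg$intraDivergence) / 2
  indBranch <- cfg$intraDivergence / 2
  indSpecies <- rep(seq_len(nSp), cfg$individualsPerSpecies)
  indNames <- unlist(lapply(seq_len(nSp), function(s)
    sprintf("sp%02d_i%d", s, seq_len(cfg$individualsPerSpecies[s]))))
  datasets <- vector("list", length(cfg$loci))
  names(datasets) <- names(cfg$loci)
  for (k in seq_along(cfg$loci)) {
    L <- cfg$loci[[k]]
    root <- sample.int(4L, L, replace = TRUE)
    ancestors <- lapply(seq_len(nSp), function(s)
      .evolveCodes(root, ancBranch, cfg$kappa))
    keep <- if (k == 1L) rep(TRUE, length(indSpecies))
            else stats::runif(length(indSpecies)) < cfg$sharedFraction
    if (!any(keep)) keep[1L] <- TRUE
    codes <- lapply(which(keep), function(i)
      .evolveCodes(ancestors[[indSpecies[i]]], indBranch, cfg$kappa))
    chars <- vapply(codes, function(cc)
      paste0(c("A", "C", "G", "T")[cc], collapse = ""), character(1L))
    species <- speciesNames[indSpecies[keep]]
    individual <- indNames[keep]
    accession <- sprintf("SIM%04d", which(keep))
    if (cfg$includeOutgroup) {
      og <- .evolveCodes(root, cfg$outgroupDivergence, cfg$kappa)
      chars <- c(chars, paste0(c("A", "C", "G", "T")[og], collapse = ""))
      species <- c(species, "Outgroupus distans")
      individual <- c(individual, "og1")
      accession <- c(accession, "SIM0000")
    }
    datasets[[k]] <- BarcodeAlignment(chars, species = species,
                                      individual = individual,
                                      locus = names(cfg$loci)[k],
                                      accession = accession)
  }
  list(datasets = datasets,
       truth = list(config = cfg,
                    species = stats::setNames(speciesNames[indSpecies],
                                              indNames),
                    expectedIntra = cfg$intraDivergence,
                    expectedInter = cfg$interDivergence,
                    speciesTree = "star",
                    ancestorBranch = ancBranch,
                    individualBranch = indBranch))
}
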