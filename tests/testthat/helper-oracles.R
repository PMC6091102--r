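# Independent oracles and fixture builders. Everything here is written
# against the definitions directly (explicit per-character loops, closed
# forms), deliberately not sharing code paths with the package.

# K2P distance by explicit per-site classification
oraclePairK2P <- function(a, b, what = "d") {
  A <- strsplit(a, "")[[1L]]
  B <- strsplit(b, "")[[1L]]
  stopifnot(length(A) == length(B))
  bases <- c("A", "C", "G", "T")
  n <- 0L; ts <- 0L; tv <- 0L
  for (k in seq_along(A)) {
    x <- A[k]; y <- B[k]
    if (!(x %in% bases) || !(y %in% bases)) next
    n <- n + 1L
    if (x != y) {
      purine <- c("A", "G")
      pyrim <- c("C", "T")
      if ((x %in% purine && y %in% purine) ||
          (x %in% pyrim && y %in% pyrim)) ts <- ts + 1L
      else tv <- tv + 1L
    }
  }
  if (what == "counts") return(list(n = n, ts = ts, tv = tv))
  if (n == 0L) return(NA_real_)
  P <- ts / n; Q <- tv / n
  w1 <- 1 - 2 * P - Q; w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(NA_real_)
  -0.5 * log(w1) - 0.25 * log(w2)
}

# brute-force per-column site classifier
oracleSiteClasses <- function(rows) {
  chars <- do.call(rbind, strsplit(rows, ""))
  bases <- c("A", "C", "G", "T")
  variable <- 0L; informative <- 0L
  for (j in seq_len(ncol(chars))) {
    col <- chars[, j]
    col <- col[col %in% bases]
    tab <- table(col)
    if (length(tab) >= 2L) variable <- variable + 1L
    if (sum(tab >= 2L) >= 2L) informative <- informative + 1L
  }
  list(variable = variable, informative = informative)
}

# brute-force best-match verdict: enumerate every pair for a query
oracleBestMatch <- function(d, species, i, tol = 1e-12) {
  others <- setdiff(seq_len(nrow(d)), i)
  di <- d[i, others]
  dmin <- min(di)
  tied <- others[di <= dmin + tol]
  con <- species[tied] == species[i]
  if (all(con)) "correct" else if (all(!con)) "incorrect" else "ambiguous"
}

randSeq <- function(L) paste(sample(c("A", "C", "G", "T"), L,
                                    replace = TRUE), collapse = "")

# distance-matrix fixture with prescribed entries
makeDM <- function(entries, species) {
  ids <- names(species)
  d <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (e in entries) {
    d[e[[1L]], e[[2L]]] <- d[e[[2L]], e[[1L]]] <- as.numeric(e[[3L]])
  }
  new("K2PDistanceMatrix", d = d, species = species, nUndefined = 0L)
}

# random species-labelled alignment for property tests: records are
# independent mutants of one template so pairwise distances stay well
# inside the K2P domain
randAlignment <- function(nSpecies = 3, perSpecies = 2, L = 60,
                          mutRate = 0.12) {
  n <- nSpecies * perSpecies
  template <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  rows <- vapply(seq_len(n), function(i) {
    s <- template
    k <- stats::rbinom(1, L, mutRate)
    if (k > 0) {
      p <- sample(L, k)
      s[p] <- sample(c("A", "C", "G", "T"), k, replace = TRUE)
    }
    paste(s, collapse = "")
  }, character(1L))
  BarcodeAlignment(rows,
                   species = rep(sprintf("Sp %02d", seq_len(nSpecies)),
                                 each = perSpecies),
                   individual = sprintf("v%03d", seq_len(n)),
                   locus = "LOC")
}

# Synthetic accession manifest emulating the published Nepenthes
# sampling structure (synthetic stand-in for the GenBank Table S1 that
# is not bundled): 317 records across ITS/rbcL/matK whose per-locus
# record and species counts and pairwise overlaps match the published
# table. Individuals are typed by which locus set they carry.
syntheticAccessionManifest <- function() {
  # species pools
  spF <- sprintf("Nepenthes triple%02d", 1:8)     # in all three loci
  spD <- sprintf("Nepenthes itsmatk%02d", 1:16)   # ITS + matK only
  spE <- sprintf("Nepenthes rbclmatk%02d", 1:7)   # rbcL + matK only
  spA <- sprintf("Nepenthes itsonly%02d", 1:64)   # ITS only
  spB <- sprintf("Nepenthes matkonly%02d", 1:4)   # matK only
  spC <- sprintf("Nepenthes rbclonly%02d", 1:2)   # rbcL only
  ind <- list()  # rows: species, individual, loci
  add <- function(species, loci, tag) {
    k <- length(ind) + 1L
    ind[[k]] <<- list(species = species,
                      individual = sprintf("%s%03d", tag, k),
                      loci = loci)
  }
  # 5 triple-locus individuals, in F species
  for (s in spF[1:5]) add(s, c("ITS", "rbcL", "matK"), "t")
  # 13 ITS+rbcL individuals: one per F species, extras on spF[1]
  for (s in c(spF, rep(spF[1L], 5))) add(s, c("ITS", "rbcL"), "ir")
  # 13 rbcL+matK individuals: one per E species, 3 to the F species
  # not yet covered for matK, extras on spE[1]
  for (s in c(spE, spF[6:8], rep(spE[1L], 3))) add(s, c("rbcL", "matK"), "rm")
  # 73 ITS+matK individuals: one per D species, one for each F species
  # not yet carrying both ITS and matK, extras spread over D
  for (s in c(spD, spF[6:8], rep(spD, length.out = 54)))
    add(s, c("ITS", "matK"), "im")
  # 2 rbcL-only individuals, one per C species
  for (s in spC) add(s, "rbcL", "r")
  # 92 ITS-only individuals: one per A species, extras over A
  for (s in c(spA, rep(spA, length.out = 28))) add(s, "ITS", "i")
  # 10 matK-only individuals: one per B species, extras over B
  for (s in c(spB, rep(spB, length.out = 6))) add(s, "matK", "m")
  rows <- do.call(rbind, lapply(ind, function(x)
    data.frame(species = x$species, individual = x$individual,
               locus = x$loci)))
  rows
}

# Per-locus BarcodeDataset list from the manifest (dummy 400 bp
# sequences: the manifest tests bookkeeping, not distances)
manifestDatasets <- function() {
  manifest <- syntheticAccessionManifest()
  seq400 <- strrep("ACGT", 100L)
  lapply(split(manifest, manifest$locus), function(df)
    BarcodeDataset(rep(seq400, nrow(df)), species = df$species,
                   individual = df$individual, locus = df$locus[1L]))
}
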