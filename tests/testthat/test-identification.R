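test_that("best match scores conspecific, heterospecific and tied queries", {
  aln <- BarcodeAlignment(c("AAAAAAAAAA", "AAAAAAAAAA",
                            "GGGGGGGGGG", "GGGGGGGGGG"),
                          c("A", "A", "B", "B"),
                          individual = c("1", "2", "3", "4"))
  bm <- bestMatch(k2pDistanceMatrix(aln))
  expect_true(all(bm$verdict == "correct"))
  s <- summarizeIdentification(bm)
  expect_equal(c(s$pctCorrect, s$pctAmbiguous, s$pctIncorrect),
               c(100, 0, 0))

  # unique nearest neighbour is heterospecific -> incorrect
  species <- c(a1 = "A", a2 = "A", b1 = "B")
  dm <- makeDM(list(list("a1", "a2", 0.10), list("a1", "b1", 0.02),
                    list("a2", "b1", 0.15)), species)
  bm <- bestMatch(dm)
  expect_equal(bm$verdict[bm$query == "a1"], "incorrect")

  # exact tie between one conspecific and one heterospecific
  dm <- makeDM(list(list("a1", "a2", 0.05), list("a1", "b1", 0.05),
                    list("a2", "b1", 0.20)), species)
  bm <- bestMatch(dm)
  expect_equal(bm$verdict[bm$query == "a1"], "ambiguous")
  expect_equal(bm$nearestIds[bm$query == "a1"], "a2;b1")
})

test_that("the intraspecific threshold interpolates order statistics", {
  species <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  dmZero <- makeDM(list(list("a1", "b1", 0.5)), species)
  expect_equal(intraspecificThreshold(dmZero), 0)

  # intra distances 1..100 percent across 100 singleton-pair species
  ids <- as.vector(t(outer(sprintf("s%03d", 1:100), c("x", "y"), paste0)))
  species <- setNames(rep(sprintf("S %03d", 1:100), each = 2), ids)
  entries <- lapply(1:100, function(k)
    list(sprintf("s%03dx", k), sprintf("s%03dy", k), k / 100))
  dm <- makeDM(entries, species)
  expect_equal(intraspecificThreshold(dm, 95), 95.05)
  expect_equal(intraspecificThreshold(dm, 100), 100)

  single <- makeDM(list(list("a", "b", 0.1)), c(a = "A", b = "B"))
  expect_error(intraspecificThreshold(single), "manual threshold")
})

test_that("best close match refuses queries beyond the threshold", {
  species <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B",
               c1 = "C", c2 = "C")
  entries <- list(list("a1", "a2", 0.01), list("b1", "b2", 0.02),
                  list("c1", "c2", 0.40))
  pairs <- combn(names(species), 2, simplify = FALSE)
  for (p in pairs)
    if (species[p[1]] != species[p[2]])
      entries <- c(entries, list(list(p[1], p[2], 0.50)))
  dm <- makeDM(entries, species)

  bcm <- bestCloseMatch(dm, threshold = 10)       # percent
  expect_equal(bcm$verdict[bcm$query == "a1"], "correct")
  # c1's nearest (c2, 40%) is beyond 10% -> refused despite conspecific
  expect_equal(bcm$verdict[bcm$query == "c1"], "no_match")
  # the verdict flips as the threshold crosses the nearest distance
  bcm2 <- bestCloseMatch(dm, threshold = 45)
  expect_equal(bcm2$verdict[bcm2$query == "c1"], "correct")
})

test_that("all species barcodes requires every conspecific to be closest", {
  aln <- BarcodeAlignment(c(rep("AAAAAAAAAAAAAAAAAAAA", 3),
                            "AAGGAAGGAAGGAAGGAAGG"),
                          c("A", "A", "A", "B"),
                          individual = c("1", "2", "3", "4"))
  asb <- allSpeciesBarcodes(k2pDistanceMatrix(aln))
  expect_true(all(asb$verdict[asb$species == "A"] == "correct"))
  expect_true(is.na(asb$verdict[asb$species == "B"]))  # singleton

  # a conspecific farther than a heterospecific record -> incorrect
  species <- c(a1 = "A", a2 = "A", a3 = "A", b1 = "B")
  dm <- makeDM(list(list("a1", "a2", 0.01), list("a1", "a3", 0.20),
                    list("a2", "a3", 0.20), list("a1", "b1", 0.05),
                    list("a2", "b1", 0.06), list("a3", "b1", 0.30)),
               species)
  asb <- allSpeciesBarcodes(dm)
  expect_equal(asb$verdict[asb$query == "a1"], "incorrect")
  # decisive tie -> ambiguous
  dm2 <- makeDM(list(list("a1", "a2", 0.01), list("a1", "a3", 0.05),
                     list("a2", "a3", 0.20), list("a1", "b1", 0.05),
                     list("a2", "b1", 0.06), list("a3", "b1", 0.30)),
                species)
  asb2 <- allSpeciesBarcodes(dm2)
  expect_equal(asb2$verdict[asb2$query == "a1"], "ambiguous")
})

test_that("summaries tally verdict percentages over queried records", {
  out <- data.frame(criterion = "best_match",
                    verdict = c(rep("correct", 8), "ambiguous",
                                "incorrect"))
  s <- summarizeIdentification(out)
  expect_equal(c(s$pctCorrect, s$pctAmbiguous, s$pctIncorrect,
                 s$pctNoMatch), c(80, 10, 10, 0))

  s2 <- summarizeIdentification(
    data.frame(criterion = "best_close_match",
               verdict = rep("no_match", 5)))
  expect_equal(s2$pctNoMatch, 100)
  expect_equal(s2$pctCorrect, 0)

  mixed <- data.frame(criterion = "best_close_match",
                      verdict = c("correct", "correct", "no_match",
                                  "incorrect", NA))
  s3 <- summarizeIdentification(mixed)
  expect_equal(s3$n, 4L)   # NA rows leave the denominator
  expect_equal(s3$pctCorrect, 50)
  expect_equal(s3$pctCorrect + s3$pctAmbiguous + s3$pctIncorrect +
                 s3$pctNoMatch, 100)
})

test_that("an infinite threshold reduces best close match to best match", {
  set.seed(55)
  for (rep in 1:20) {
    aln <- randAlignment(nSpecies = sample(2:4, 1),
                         perSpecies = sample(1:3, 1) + 1, L = 40)
    dm <- k2pDistanceMatrix(aln)
    if (anyNA(distances(dm))) next
    bm <- bestMatch(dm)
    bcm <- bestCloseMatch(dm, threshold = Inf)
    expect_equal(bcm$verdict, bm$verdict)
  }
})

test_that("raising the threshold moves no_match straight to the best-match verdict", {
  set.seed(66)
  aln <- randAlignment(nSpecies = 3, perSpecies = 3, L = 50)
  dm <- k2pDistanceMatrix(aln)
  bm <- bestMatch(dm)
  thresholds <- sort(c(0, distances(dm, percent = TRUE)[
    upper.tri(distances(dm))], Inf))
  prev <- NULL
  for (th in thresholds) {
    cur <- bestCloseMatch(dm, th)$verdict
    notRefused <- cur != "no_match"
    expect_equal(cur[notRefused], bm$verdict[notRefused])
    if (!is.null(prev))
      expect_true(all(prev[prev != "no_match"] ==
                        cur[prev != "no_match"]))
    prev <- cur
  }
})

test_that("best match agrees with a pair-enumerating oracle", {
  set.seed(77)
  for (rep in 1:15) {
    nSp <- sample(2:4, 1)
    per <- sample(2:3, 1)
    aln <- randAlignment(nSpecies = nSp, perSpecies = per, L = 30,
                         mutRate = 0.2)
    n <- length(aln)
    dm <- k2pDistanceMatrix(aln)
    if (anyNA(distances(dm))) next
    bm <- bestMatch(dm)
    d <- distances(dm)
    sp <- unname(speciesLabels(dm))
    for (i in seq_len(n))
      expect_equal(bm$verdict[i], oracleBestMatch(d, sp, i))
  }
})
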