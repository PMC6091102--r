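---
title: "Evaluating DNA barcode loci: methods and design notes"
author: "barcodeEval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating DNA barcode loci: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodeEval)
```

This vignette is the package's own account of the methods it
implements: the models and conventions, the tunable parameters and
their defaults, the numerical choices at the edges, what the simulator
does and does not emulate, and the known limitations. It states no
empirical result beyond what the test suite and `scripts/acceptance.R`
themselves compute.

## Input model and screening

The atom of every analysis is a species-labelled sequence record:
nucleotide string (IUPAC alphabet plus `-`), binomial species name,
individual/voucher identifier, locus tag and optional accession. Both
live in a `BarcodeDataset` (a `DNAStringSet` plus a parallel metadata
`DataFrame`); `BarcodeAlignment` adds the constraint that all gapped
sequences share one width. Species names are normalised
(underscores to spaces, whitespace collapsed); no synonym resolution
is attempted.

`filterRecords()` operationalises the customary screen for reference
sets: a record is kept when its **non-gap** length is *strictly*
greater than `minLength` (default 300, so a 300 bp record is rejected)
and, under `requireVoucher = TRUE`, when its individual field is
non-empty. "Has a voucher" is deliberately the only voucher criterion:
nothing else about voucher quality is machine-decidable from a FASTA
header. Whether the length bound should apply to raw or aligned length
is not fixed by convention; we use raw (non-gap) length, since the
screen happens before alignment in practice.

## Alignment site statistics

`countVariableSites()` and `countParsimonyInformative()` classify each
column on its unambiguous A/C/G/T residues: gaps and ambiguity codes
are excluded from the column's state multiset (the default behaviour
of the common matrix-analysis tools for these counts). A column is
variable with ≥ 2 states, parsimony-informative with ≥ 2 states each
in ≥ 2 rows; a column that is entirely gaps/ambiguities counts toward
the aligned length but toward neither statistic. `gapAsState = TRUE`
switches to gap-as-fifth-state counting for users who want the
alternative convention. Alignments themselves are consumed, never
computed: multiple sequence alignment and its manual curation are out
of scope.

## K2P distances

`pairwiseCounts()` implements pairwise deletion: for each pair, any
column where either member carries a gap **or an ambiguity code** is
dropped; ambiguous bases never count as matches or mismatches.
Transitions are A↔G and C↔T; all other base mismatches are
transversions. The distance is the K2P closed form
d = −½·ln(1 − 2P − Q) − ¼·ln(1 − 2Q). Pairwise (rather than
complete) deletion is essential for datasets with heterogeneous
coverage, where complete deletion can empty the alignment.

Saturated pairs (1 − 2P − Q ≤ 0 or 1 − 2Q ≤ 0) and pairs with no
comparable site have no defined distance. They are stored as `NA`,
counted (`nUndefined`), and excluded from all summaries — never
clamped to a ceiling, which would silently bias means and gap bounds.
Distances are kept in substitutions/site internally; every reporting
surface (summaries, thresholds, histograms, match tables) uses the
percent scale, which is how these quantities are conventionally
printed.

## Barcoding gap

`gapAnalysis()` applies the strict rule: a gap exists iff the minimum
inter-specific distance is *strictly greater* than the maximum
intra-specific distance; an exact tie is no gap. The histograms use
half-open bins `[k·w, (k+1)·w)` — a boundary value falls in the bin it
opens — with a default width of 0.05 on the percent scale. The
interval convention for such histograms is ambiguous between the raw
and percent scales in common usage; we default to percent because the
summary tables and distribution figures in this field are printed in
percent, and both width and scale are arguments. `perSpeciesGap()`
refines the rule per species (max own intra vs distance to the nearest
non-member); note that a local gap for every species does not imply a
global gap, since different species' ranges can interleave — the test
suite constructs an explicit counterexample.

## Identification criteria

All three criteria are leave-one-out: every record is queried in turn
against the rest, which matches how reference-library success rates
are conventionally estimated.

* **Best match**: the verdict comes from the tied set of nearest
  neighbours — correct if all conspecific, incorrect if none,
  ambiguous if mixed. Ties are distances equal within `tieTol`
  (default 1e−12 substitutions/site, configurable); an explicit tie
  semantics is required for the ambiguous category to be meaningful.
* **Best close match**: as best match, but a query whose nearest
  neighbour lies beyond a threshold is `no_match`. The threshold
  defaults to the 95th percentile of all intraspecific pairwise
  distances (`intraspecificThreshold()`, linear interpolation between
  order statistics), the convention of the classical implementation;
  it is always carried in the report so runs are auditable. With
  threshold `Inf` the criterion reduces exactly to best match — a
  property test in the suite.
* **All species barcodes**: correct only when *every* conspecific
  record is strictly closer than the closest heterospecific record;
  ambiguous when that decisive comparison ties; otherwise incorrect;
  `no_match` beyond the threshold. Queries from singleton species are
  excluded from this criterion (and from its denominator), since the
  rule is vacuous for them.

Percentages are computed over queried records; excluded records
(singletons under the third criterion, or queries whose distances are
all undefined) leave the denominator, which is reported.

## Neighbor joining, bootstrap, monophyly

`neighborJoining()` is the standard agglomeration: join the pair
minimising Q(i,j) = (n−2)·d(i,j) − R(i) − R(j), split the joined edge
by the usual formula, reduce with
d(u,k) = (d(i,k)+d(j,k)−d(i,j))/2. Two numerical choices make it
deterministic and robust:

* **Tie-break**: among pairs within 1e−12 (relative) of the minimal Q,
  the lexicographically smallest pair of cluster labels is joined, so
  results are identical across platforms and BLAS builds.
* **Negative branch estimates** are clamped to 0 by default with the
  total deficit recorded (`attr(tree, "clampedDeficit")`);
  `clampNegative = FALSE` preserves the raw estimates for users who
  want the unmodified display convention of some tools.

On additive matrices NJ is consistent; the suite verifies exact
path-length recovery (to 1e−10) and topology identity on random
additive matrices, and checks topological agreement with an
independent NJ implementation on non-additive K2P matrices.

`bootstrapSupport()` resamples alignment columns with replacement,
recomputes K2P + NJ per replicate, and scores each internal edge of
the original tree by the percentage of completed replicates containing
the same bipartition (canonicalised to the side not holding the
reference tip). Saturated replicates are skipped and counted, and the
support denominator is the number of completed replicates. Rendered
Newick hides supports below 50% (`writeSupportNewick()`), the usual
display convention.

Rooting uses a declared outgroup; the outgroup set must form one side
of a single edge of the unrooted tree, otherwise the conflict is an
error rather than a silent forced root. `speciesMonophyly()` scores a
species as monophyletic when the smallest clade containing its tips
contains no others (MRCA test on rooted trees; one-side-of-an-edge
test on unrooted trees, which equals rooting anywhere outside the
group). The discrimination rate is the percentage of monophyletic
species among species with ≥ 2 tips; because the conventional
treatment of singletons is not settled, `includeSingletons = TRUE`
counts them as (vacuously) monophyletic instead, and both rates are
always returned.

## Multilocus concatenation

`matchIndividuals()` intersects loci on a key — by default
species + individual, which avoids cross-species voucher collisions;
the voucher-only key is available when vouchers are globally unique.
`concatenateLoci()` joins per-locus segments in declared order into a
`ConcatenatedAlignment` whose column spans are recorded half-open and
0-based. Strict intersection is the default because combined reference
sets genuinely shrink to the individuals sequenced for every locus;
`gapFill = TRUE` pads missing loci with gaps for exploratory use. An
exact identity ties this to the distance stage: pairwise site,
transition and transversion counts over a concatenation equal the sums
of the per-locus counts, so concatenating a locus with itself leaves
K2P distances unchanged. Both identities are property tests.

## The simulator

`simulateBarcodeData()` generates already-aligned, species-structured
data under the same two-parameter substitution process the estimator
assumes, which makes parameter recovery a clean validation surface: a
uniform random root sequence is evolved to each species ancestor and
then to each individual, with exact closed-form substitution
probabilities per branch (rates scaled so α + 2β = 1,
α = κ·β).

Two parameterisation choices matter:

* **Divergences are between individuals.** `intraDivergence` is the
  expected pairwise divergence of conspecific individuals and
  `interDivergence` that of heterospecific individuals; the species
  ancestors are separated by `interDivergence − intraDivergence` so
  that both targets are directly recoverable by the K2P estimator.
  Parameterising the ancestor distance instead would make the
  observable inter-individual divergence exceed the nominal value by
  the intraspecific component, leaving no quantity the estimator
  could be checked against.
* **Star species tree by default**, i.e. equal expected divergence
  between every species pair, because the intra/inter summary
  statistics are then analytically predictable.

Defaults (10 species × 3 individuals, 1000 sites, 1% intra, 10% inter,
κ = 2) describe a genus with a wide barcoding gap — low intraspecific
variation against an order-of-magnitude larger interspecific
divergence, the regime in which barcoding is expected to work — at
sample sizes typical of single-genus reference sets. Multi-locus
configurations share individuals across loci at `sharedFraction`
(default 0.8), emulating the partial overlap of records across loci in
real reference databases; the first locus always carries every
individual. An optional outgroup tip evolves straight from the root at
`outgroupDivergence` (default 0.3).

What the simulator does **not** emulate — and what passing tests
therefore do not establish about real data: indels and alignment
error (sequences are generated aligned), rate heterogeneity across
sites and lineages, base-composition bias, within-species genealogy
(individuals are i.i.d. around their ancestor rather than coalescent),
misidentified or mislabelled reference sequences, and non-star species
trees with very short internal edges. Real barcoding datasets fail for
exactly these reasons even when the idealised pipeline is correct.

## Problem sizes and orchestration

`runEvaluation()` executes screen → site statistics → distances → gap
→ identification → tree (→ concatenation for combinations) and
collects one row per candidate; a failing candidate carries its error
in its row without aborting the rest, and a fixed seed makes the whole
report — including bootstrap supports — byte-reproducible.
`rankCandidates()` orders rows by discrimination rate, then
best-close-match success, then gap width; this tie-break order is an
explicit package convention (the three measures have no canonical
composite), with exact ties reported as ties.

The validation suite and the acceptance script run at deliberately
desk-scale sizes chosen to make the statistical checks sharp but
cheap: 1000 random pairs (200–800 sites) for the closed-form
equivalence, 50 additive matrices (5–10 taxa) for NJ consistency, 20
simulated datasets of 10 species × 3 individuals × 1000 sites for
parameter recovery (mean intra/inter within 3 standard errors of the
generating 1%/10%), and 100-replicate bootstraps for the
reproducibility check. These sizes are the package's own validation
design, not statements about the scale the functions support.

## Known limitations

* K2P with pairwise deletion is the only distance; other models are
  deliberately out of scope, so the package cannot assess model
  misspecification.
* The per-column exclusion convention for site statistics can differ
  from tools that count ambiguity codes as states; the `gapAsState`
  flag covers only the gap convention.
* Published summary tables in this literature are not always
  internally consistent (percentages exceeding 100, intra means above
  inter means, per-locus species counts incompatible with claimed
  totals); the package reports what it computes and makes no attempt
  to reproduce inconsistent cells.
* Bootstrap support is bipartition-based; supports for clades absent
  from the original tree are not reported.
* The simulator's idealisations listed above mean that validation
  here bounds software correctness, not field performance of any
  locus.
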