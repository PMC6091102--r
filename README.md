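# barcodeEval

Distance-, gap-, identification- and tree-based evaluation of candidate
DNA barcode loci and their multilocus combinations.

## The problem

A DNA barcode is a short, standardized genomic region used to tell
species apart by sequence comparison. Whether a locus (or a
concatenation of loci) works as a barcode for a genus is an empirical
question, conventionally answered with four complementary analyses over
a species-labelled reference alignment:

1. **Genetic divergence.** Pairwise distances under the Kimura
   2-parameter (K2P) model with pairwise deletion, partitioned into
   intra- and inter-specific sets and summarised as min/max/mean (%).
   For transition proportion *P* and transversion proportion *Q* over
   the comparable sites of a pair,

   d = −½·ln(1 − 2P − Q) − ¼·ln(1 − 2Q).

2. **Barcoding gap.** A locus has a gap when the *minimum*
   inter-specific distance strictly exceeds the *maximum*
   intra-specific distance; the two distributions are reported as
   fixed-interval histograms.

3. **Identification success.** Leave-one-out nearest-neighbour
   identification under the three classical criteria — *best match*,
   *best close match* (with an intraspecific-percentile distance
   threshold) and *all species barcodes* — scored as
   correct / ambiguous / incorrect / no match percentages.

4. **Tree-based discrimination.** A neighbor-joining tree from the K2P
   matrix (with optional bootstrap support and outgroup rooting); the
   "ability to discriminate" of a locus is the percentage of species
   whose individuals form a monophyletic group.

`barcodeEval` implements all four stages, plus multilocus
concatenation over shared individuals, alignment site statistics
(variable and parsimony-informative sites), the sampling screen used
when assembling reference sets (voucher present, length > 300 bp), and
a Kimura-process simulator that generates species-structured datasets
with controlled intra-/inter-specific divergence so that the whole
pipeline can be exercised and validated without any external download.
It is aimed at systematists comparing candidate barcodes for a genus
and at method developers who need a tested, deterministic reference
implementation of these classical analyses.

## Worked example

Simulate a two-locus reference set (6 species, 3 individuals each,
1% intraspecific / 10% interspecific expected divergence), evaluate
both loci and their concatenation, and rank the candidates:

```r
library(barcodeEval)

cfg <- simulationConfig(nSpecies = 6, individualsPerSpecies = 3,
                        loci = c(ITS = 600, matK = 600),
                        sharedFraction = 0.8, seed = 42)
sim <- simulateBarcodeData(cfg)

report <- runEvaluation(sim$datasets,
                        combinations = list(c("ITS", "matK")),
                        bootstrapReplicates = 100, seed = 42)
report
#> Barcode locus evaluation (3 candidates)
#>  candidate nSpecies nIndividuals gapExists bmCorrect bcmCorrect discrimination
#>        ITS        6           18      TRUE    100.00     100.00            100
#>       matK        6           13      TRUE     92.31      92.31            100
#>   ITS+matK        6           13      TRUE     92.31      92.31            100

rankCandidates(report)[, c("rank", "candidate", "intraMean", "interMean",
                           "gapWidth", "bcmCorrect", "discrimination")]
#>   rank candidate intraMean interMean gapWidth bcmCorrect discrimination
#> 1    1       ITS  1.036108  10.24729 6.595107  100.00000            100
#> 2    2  ITS+matK  1.063669  10.39741 7.398802   92.30769            100
#> 3    3      matK  1.177483  10.57460 6.231066   92.30769            100

report$details$ITS$gap
#> Barcoding gap report
#>   max intra: 1.685561%  min inter: 8.280668%
#>   gap exists: TRUE (width 6.595107%)
```

Reading the output: every candidate shows a clear barcoding gap
(minimum interspecific distance ~8.3% against a maximum intraspecific
distance ~1.7% for ITS); the mean intra/inter distances recover the
simulated 1% and 10%; `matK` and the concatenation carry fewer
individuals because only a random 80% of samples have a second locus,
and one 13-record locus yields an imperfect best-match score while all
species remain monophyletic on the NJ tree (discrimination 100%).
`rankCandidates()` orders candidates by discrimination rate, then
best-close-match success, then gap width.

The same functions work on real data: read per-locus aligned FASTA
with `readBarcodeFasta()` (headers parsed as
`species|individual|locus|accession`, or a TSV metadata sidecar),
screen with `filterRecords()`, and pass the named list of alignments
to `runEvaluation()`.

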