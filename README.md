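# satcons

Conservation analysis of tandem-repeat satellite DNA across related
species, from raw reads to summary statistics.

Satellite DNAs (satDNAs) are noncoding head-to-tail tandem repeats that
usually evolve so fast they are species- or genus-specific. A small number
of families defy this: a 52-bp, A+T-rich monomer conserved across an
entire fish order is the motivating case for this package. Characterizing
such a family requires the same battery of analyses in every study:
per-species copy-number profiles normalized to single-copy genes, variant
profiles against a common consensus, Kimura 2-parameter (K2P) divergence
landscapes, haplotype networks of exact monomer variants, array-length
and repeat-density estimates from noisy long reads, and transcription
quantification. `satcons` packages this battery as tested, reusable
functions, together with a simulator of the *library model* of satellite
evolution (related species share an ancestral repeat collection,
independently amplified or depleted per lineage) so that every stage can
be validated against planted ground truth without touching external
archives.

The models at the core:

* **K2P divergence** `K = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q)` for
  transition/transversion proportions `P`, `Q`; landscapes bin each
  variant's `52 x count` bases at `floor(100 K)`.
* **Copy number** = satellite depth per monomer unit / median single-copy
  gene depth, from a k-mer-seeded banded local aligner against a 208-bp
  concatenated consensus (4 x 52), with deletion-aware depth so that
  deletion subfamilies appear as coverage valleys.
* **Array detection** = local alignment of each long read against the
  infinite cyclic concatenation of the monomer (wraparound dynamic
  programming), reporting segments with noise (edits/columns) <= 0.20.
* **Variant network** = Kruskal MST over Hamming distances between exact
  monomer haplotypes, with a deterministic abundance-aware tie break, and
  an exhaustive-enumeration verifier for small instances.
* **Transcription** = FPKM, Welch's t, and Livak 2^-dCt / 2^-ddCt.

## A worked example

Simulate one species with two planted arrays of 50 monomer copies each
plus a ten-gene single-copy panel, sequence it, and recover the copy
number:

```r
library(satcons)

cfg <- simulationConfig(
    seed = 5,
    species = data.frame(name = "sp", branchLength = 0),
    substitutionRate = 0,
    amplification = data.frame(name = "sp", nArrays = 2L,
                               minCopies = 50L, maxCopies = 50L),
    backgroundLength = 30000L,
    shortRead = list(nPairs = 15000L, errorRate = 0))
g  <- buildGenome(evolveLibrary(cfg), "sp", cfg)
pg <- plantGenes(g$genome, g$truth, seed = 5)
sr <- simulateShortReads(pg$genome, cfg)
reads <- c(as.character(sr$r1), as.character(sr$r2))

ref <- buildConcatemer(cfg@ancestralMonomer, 4)   # 208-bp reference
mp  <- mapReads(reads, c(sat = unclass(ref), pg$genes),
                monomerLength = c(sat = 52L))
copyNumber(mp$profiles$sat, mp$profiles[names(pg$genes)])
#> [1] 98.06448        # planted: 100 copies per 1C
```

Detect a tandem array in a (here: clean) long read and measure K2P
divergence between two monomers one transition apart:

```r
hits <- detectArrays(c(read1 = strrep(cfg@ancestralMonomer, 10)),
                     cfg@ancestralMonomer)
hits
#> GRanges object with 1 range and 3 metadata columns:
#>       seqnames    ranges strand |     noise monomerEquivalents     score
#>   [1]    read1     1-520      + |         0                 10       520
kimura2p(paste0(strrep("A", 51), "A"), paste0(strrep("A", 51), "G"))$K
#> [1] 0.01961036       # 1.9610%
```

`runPipeline(simulationConfig(seed = 7), "out/")` runs the full
eight-species reference study (extraction, profiles, copy numbers,
landscapes, divergence summary, MST, shared variants, long-read arrays,
densities, flanker clusters, FPKM, qPCR) and writes one TSV/BED report
per stage; it completes in a few minutes on one CPU.

## Package tour

| Area | Functions |
| --- | --- |
| Simulation | `simulationConfig`, `evolveLibrary`, `buildGenome`, `plantGenes`, `simulateShortReads`, `simulateLongReads`, `simulateRnaReads`, `simulateStudy`, `writeSimulation` |
| Monomers | `canonicalRotation`, `extractMonomers`, `tallyAndFilter`, `filterPool`, `consensusComposition`, `subsampleByGenomeSize`, `sharedVariants` |
| Profiles | `buildConcatemer`, `mapReads`, `copyNumber`, `variantFraction`, `profileCorrelation`, `findValleys` |
| Divergence | `kimura2p`, `repeatLandscape`, `divergenceSummary`, `columnSummary`, `charSatTable` |
| Networks | `hammingMatrix`, `buildMST`, `poolMST`, `exhaustiveMinWeight` |
| Long reads | `detectArrays`, `repeatDensity`, `extractFlankers`, `clusterFlankers` |
| Expression | `fpkm`, `foldDifference`, `welchT`, `qpcrRelative`, `quantifyExpression` |
| I/O | `readSeqs`, `writeSeqs`, `readBed`, `writeBed`, `readReport`, `writeReport`, `revComp` |

The methods vignette (`vignettes/satcons-methods.Rmd`) documents the
models, parameter choices, numerical decisions and known limitations.
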