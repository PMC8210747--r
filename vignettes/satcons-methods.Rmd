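---
title: "Methods: satellite DNA conservation analysis with satcons"
author: "satcons authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: satellite DNA conservation analysis with satcons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`satcons` analyzes the conservation of a tandem-repeat satellite DNA family
— a 52-bp, A+T-rich monomer of the kind found across Characiformes fishes —
over a set of related species, from raw reads to summary statistics. The
package covers:

* a simulator of the *library model* of satellite evolution (species share
  an ancestral repeat collection that is independently amplified or depleted
  per lineage), producing genomes, paired short reads, and noisy long reads
  with complete ground truth;
* direct monomer extraction from short reads, with rotation handling,
  singleton filtering and per-species tallies;
* copy-number and variant profiling over a concatenated consensus reference
  normalized by single-copy genes;
* Kimura 2-parameter (K2P) divergence, repeat landscapes, and
  intra-/interspecific divergence summaries;
* minimum spanning trees of monomer variants and shared-variant reports;
* noise-bounded tandem-array detection in error-prone long reads, kb/Mb
  repeat densities, and greedy clustering of array flankers;
* transcription quantification: FPKM, Welch tests, and qPCR
  relative quantities (2^-dCt / 2^-ddCt).

Every analysis stage is testable without external data because the
simulator plants known truth: array intervals, variant frequencies, and
copy numbers per genome.

# The simulator and its assumptions

## Library evolution

Each species' consensus monomer diverges from the 52-bp ancestral monomer
by per-site i.i.d. substitution with probability
`branchLength * substitutionRate`; given a mutation, a transition is drawn
with probability `kappa / (kappa + 2)` (default `kappa = 2`), the
Kimura-style bias that downstream K2P distances assume. Within a species,
a copy pool grows by sequential copying: each new copy restarts from the
species consensus with probability `homogenization` (default 0.5, our
abstraction of concerted evolution; the real within-array mutation process
is not identifiable from published data) or copies the previous copy with
per-site probability `substitutionRate * copyDivergence`. `copyDivergence`
(default 0.005 per copy event) is the one knob the field list of a minimal
library model does not pin down; it is gated by `substitutionRate` so that
a zero substitution rate propagates the ancestral monomer exactly — a
useful degenerate case for testing.

## Genomes, reads and truth

Genomes are random backgrounds of configurable A+T content (default 0.65,
matching the A+T-rich satellite context) with arrays planted at uniform
non-overlapping positions by rejection sampling (1000 attempts, then a
sizing error — placement becomes infeasible above roughly 60–70% repeat
fill). Arrays are head-to-tail concatenations of monomers sampled i.i.d.
from the species pool, each array on a random strand. Truth records every
interval (0-based half-open in the writers, `GRanges` internally), the
realized variant tally, and the total copy number; interval lengths always
sum to 52 times the copy number.

Short reads are inward 2 × 101 bp pairs from normal-length fragments
(mean 350, sd 35) with i.i.d. substitution errors. Long-read lengths are
log-normal (the published array-length ranges imply no particular read
length law, so the parameters sit in the configuration); fragments are
placed on the extended axis and clipped at the genome ends so per-base
coverage is uniform — start-uniform placement under-covers genome edges
and measurably biased the clustered-versus-dispersed density ratio upward
by ~15% before this was fixed. Long-read errors hit each source base with
probability `errorRate` (default 0.15), split between substitutions and
single-base indels by `indelFraction` (default 0.6, indel-dominated as in
CLR-style data). Truth intervals are re-expressed in read coordinates
through the error process's coordinate map.

Every output stream (per species, per file) derives its own RNG seed from
the master seed, so adding one output never perturbs another, and a fixed
configuration is byte-reproducible.

## What the simulator does not model

No chemistry-specific error profiles, no quality-score realism (constant
Q40), no chimeric reads, no GC-coverage bias, no transposable-element
landscape around arrays. Passing tests therefore demonstrate algorithmic
correctness on idealized-but-noisy data, not robustness to every artifact
of real libraries.

# Monomer extraction and the phase problem

A 52-bp monomer read out of a tandem array can start at any of 52 phases.
Extraction finds, per read and strand, the best ungapped 52-nt window
against any rotation of the consensus; if that window reaches
`minIdentity` (default 0.70 — the published pipelines do not state their
threshold, so it is exposed), the read's frame is locked and every
complete in-phase window is emitted. Two design points matter:

* **Frame anchoring.** The locked frame is the *consensus frame* implied
  by the best window's rotation offset, so emitted windows are complete
  monomers aligned to consensus coordinates. Locking to the raw window
  offset instead would make every emitted window a chimera of two adjacent
  copies whenever neighboring copies differ — in mixed simulated arrays
  this produced variant-frequency errors of 0.3–0.4 against truth, versus
  0.004 with frame anchoring.
* **A common frame beats independent canonicalization for distances.**
  `canonicalRotation()` (lexicographically minimal rotation) makes
  rotation classes tally together and is idempotent, but it is unstable
  under substitution: one mutation can flip which rotation is minimal, and
  two near-identical variants then compare in misaligned frames with
  absurd columnwise distances. The pipeline therefore keeps extracted
  monomers in the family-consensus frame for divergence, MST and
  shared-variant computations, and uses canonical rotation where only
  rotation-class identity matters.

Variants are exact sequences (haplotypes); ungapped identity means
indel-carrying copies are dropped at extraction and surface instead in
the coverage-valley detector. Singletons (count 1) are discarded by
default. At shallow simulated array sizes, in-phase windows that run past
an array edge into flanking sequence recur across reads and survive
singleton filtering; `filterPool()` (identity to the species' own
majority consensus ≥ 0.85 over the best rotation) removes them. With
realistically long arrays the edge-window mass is negligible and the
filter is a no-op.

# Profiling and copy number

Reads are mapped to a panel of references — the satellite consensus
repeated four times (208 bp, so junction-spanning reads map contiguously)
plus ten single-copy genes — by a k-mer-seeded (11-mer), banded (±8)
local Smith–Waterman aligner (match +2, mismatch −3, gap −4). The
best-scoring alignment wins, ties go to the first-listed reference and
then the leftmost position; alignments below `minIdentity`
(matches/columns, default 0.9) or shorter than 30 columns leave a read
unassigned. Local alignment gives soft-clipping for free: reads
straddling an array/background junction contribute their repeat-derived
part at the reference edge. Gapped alignment is essential here: depth
counts base-aligned columns only, so copies carrying a deletion leave a
depth valley at the deleted positions. An ungapped mapper cannot place
reads from deletion-carrying copies at all and turns the valley into a
uniform depth loss, which is why the deletion subfamily would otherwise
be invisible.

Copy number is the satellite's depth per monomer unit (total aligned
bases / 52) divided by the median of the ten gene depths — the median
resists one mis-annotated gene. Dividing by the 208-bp concatemer instead
would report a quarter of the real copies per 1C. Planted copy numbers of
10, 100 and 1000 are recovered within a few percent from error-free
reads. Valley detection folds concatemer depth to monomer coordinates
(mean over the four images, so the result is invariant to the concatemer
multiplicity), and reports maximal runs of ≥ 2 positions below 0.6 times
the median folded depth, 1-based inclusive.

The scaled profile is depth / max(depth), matching the convention of
coloring coverage relative to the maximum observed; profile correlations
are Pearson r on scaled profiles.

# Divergence statistics

K2P: `K = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q)` with transition and
transversion proportions P and Q; pairs where a log argument is
non-positive are saturated and raise an error (or are skipped and counted
in pool summaries). Distances are reported in percent in all tables.
Landscapes bin each variant's `52 × count` bases at `floor(K%)` in 1%
bins with a saturation overflow bin; bin masses conserve total bases.
Intraspecific divergence is the abundance-weighted (`count_i × count_j`)
mean pairwise K2P over distinct variant pairs within a species;
interspecific divergence weights pairs across species pools. The
published analysis derived divergences from masking alignments whose
exact averaging is not recoverable; the pairwise definition here is
explicit and testable. Column summaries (mean, sample SD with n−1, CV =
100·SD/mean) reproduce the published per-species table's abundance row
exactly at printed precision; the printed CV row is itself derived from
the rounded mean and SD, which the acceptance checks honor by computing
it the same way.

# Variant networks

Distances between variants are Hamming counts (mutational steps) on a
common frame. The MST is Kruskal's algorithm with a fully specified tie
break — distance ascending, then combined endpoint abundance descending,
then lexicographic ids — which imitates founder-first haplotype network
conventions and makes the tree deterministic under input permutation.
`exhaustiveMinWeight()` enumerates all spanning trees of small instances
(n ≤ 10) as an algorithm-independent optimality check; the suite verifies
weight-optimality on random instances and cross-checks a graph-library
MST. Shared variants are exact-sequence intersections across species
pools.

# Long-read array detection

A read is aligned locally against the infinite cyclic concatenation of
the monomer (wraparound DP over 52 cyclic states; the cyclic within-column
dependency is resolved with two relaxation passes). Maximal-scoring
segments are peeled off greedily — best segment first, then recursion on
the flanks; a segment too noisy as a whole is split at its midpoint and
re-searched so that arrays hovering at the noise ceiling degrade to
shorter compliant segments instead of disappearing. Across strands,
overlaps resolve by score, then length, then leftmost; same-strand
segments separated by at most 10 read bases are merged, since a local
error burst can split one array's alignment in two. A segment is reported
when it spans ≥ 52 bases and its noise (edit operations / alignment
columns) is ≤ 0.20, the ceiling commonly used for noisy-read repeat
finding.

Scoring uses match +1 and mismatch/indel −2 (exposed as arguments). Unit
penalties (−1) put local alignment against a short cyclic motif in the
linear, positive-drift regime: measured on 5-kb random backgrounds (A+T
0.5 or 0.65), a unit-cost aligner extends end-to-end with positive score,
accretes hundreds of flank bases onto every true array and pushes realized
noise past the 0.20 ceiling — zero detections at 15% read error. With −2
penalties the background maximum span is zero and planted arrays of
0.5–4 kb are recovered with ≤ 2% boundary error at 15% error. The noise
ratio itself still weighs every edit equally; only the search scoring
changed.

Repeat density is kb annotated per Mb sequenced after merging overlapping
intervals. Flankers are the up-to-10-kb windows each side of a detected
array (truncated at read ends); greedy longest-first clustering joins a
sequence to the first cluster whose founding representative it matches at
≥ 0.8 identity over ≥ 50% of the shorter sequence (local alignment), and
clusters below size 3 are dropped — the screen for sequences recurrently
associated with arrays.

# Transcription

FPKM = count / (length/1000) / (total/10^6), with fragments = read pairs
for paired input. Group comparisons use Welch's t (fractional
Welch–Satterthwaite df; the equal-variance, equal-size case reduces to the
pooled df). qPCR relative quantities average replicate Ct values
arithmetically, then apply 2^-dCt against the reference gene (hprt1-style)
and 2^-ddCt against a calibrator sample. A packaged, clearly synthetic Ct
table exercises the qPCR path.

# The reference study conditions

The default configuration simulates 8 species on 50-kb genomes: branch
lengths 0.02–0.06 substitutions/site (interspecific K2P roughly 5–18%,
the conserved-satellite regime), one clustered species (3 arrays of
80–120 copies, ~16 kb of satellite) against seven dispersed species (4
arrays of 8–25 copies), 20,000 read pairs per species (~80× genome
coverage), and 60 long reads (log-normal, median ~8 kb) at 15% error.
Desk-scale genomes cannot hold many >10-kb arrays, so the
clustered/dispersed contrast is kept in array count and length at reduced
absolute size. The end-to-end default study runs in a few minutes on one
CPU. The pipeline maps at identity 0.80 (species several percent diverged
from the family consensus still map, as with sensitive real-world
mappers) and detects long-read arrays with each species' own extracted
consensus — at 15% read error, detection against the family consensus
would push the most diverged species past the noise ceiling, which is
also a realistic failure mode of the published protocol. RNA libraries
sample the satellite at a ~15-fold muscle-versus-ovary rate contrast
while keeping it a minor library component, so the planted fold survives
within-library FPKM normalization.

# Numerical choices and degenerate inputs

* Identity thresholds: extraction 0.70 (best window), mapping 0.90
  (0.80 in the pipeline), flanker clustering 0.80 over ≥ 50% coverage —
  all exposed.
* Consensus ties (equal base counts in a column) resolve alphabetically
  and are flagged.
* Valley detection requires a non-zero profile; correlation requires
  non-constant profiles; K2P requires equal lengths, ACGT alphabet, and
  non-saturated pairs.
* `copyNumber` errors when every gene depth is zero; `fpkm` and
  `foldDifference` reject non-positive denominators.
* Empty species lists, mixed variant lengths, duplicate reference ids,
  out-of-bounds flanker intervals and oversized array requests raise
  immediate validation errors rather than propagating.

# Known limitations

* The mapper's seeding (11-mers) can miss alignments for reads beyond
  ~10% divergence from every reference; this mirrors real short-read
  mappers but means copy numbers of strongly diverged species are
  underestimated — visible in the default study's most diverged species.
* Hamming distances require the common-frame convention above; variants
  whose true relation involves indels appear only through the valley
  detector, not in the network.
* The greedy flanker clustering is CD-HIT-like but quadratic; the
  pipeline caps the number of clustered flankers and uses a reduced
  window at desk scale.
* Intra/interspecific divergence from extracted pools reflects the
  pairwise, abundance-weighted definition stated here; published values
  derived from alignment-masking pipelines are not numerically
  comparable beyond their order of magnitude.
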