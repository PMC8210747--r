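#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start end strand width reduce
#' @importFrom IRanges IRanges
#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
#' @useDynLib satcons, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Simulation configuration for a multi-species satellite study
#'
#' Describes the study conditions under which genomes, short reads and long
#' reads are simulated: a set of species (tips of a known tree, each with its
#' branch length to the common ancestor), an ancestral 52-bp monomer, a
#' Kimura-style substitution process, a per-species amplification profile
#' (how many arrays, how many copies each), and read-level parameters.
#'
#' @slot seed master seed; every output stream derives its own seed from it.
#' @slot species data.frame with columns `name` and `branchLength`
#'   (substitutions/site from the ancestor to the tip).
#' @slot ancestralMonomer 52-nt character string, the ancestral repeat unit.
#' @slot substitutionRate per-site probability multiplier applied to branch
#'   lengths (and to `copyDivergence` for intragenomic copying).
#' @slot kappa transition/transversion probability ratio; given a mutation,
#'   a transition is drawn with probability `kappa/(kappa + 2)`.
#' @slot copyDivergence per-copy-event branch length of the intragenomic
#'   copying process; effective per-site mutation probability per copy is
#'   `substitutionRate * copyDivergence`.
#' @slot homogenization probability that a newly gained copy is resampled
#'   from the species consensus instead of the previous copy (an abstraction
#'   of concerted evolution).
#' @slot amplification data.frame with columns `name`, `nArrays`,
#'   `minCopies`, `maxCopies`: per-species array counts and per-array copy
#'   number range.
#' @slot backgroundLength length (bp) of the non-repetitive background each
#'   simulated genome is embedded in.
#' @slot backgroundAT A+T fraction of the background sequence.
#' @slot shortRead list: `nPairs`, `readLength` (101), `errorRate`.
#' @slot longRead list: `nReads`, `meanLog`, `sdLog` (log-normal read length
#'   law), `errorRate` (~0.15), `indelFraction` (share of errors that are
#'   indels).
#' @seealso [simulationConfig()]
#' @export
setClass("SatSimConfig", representation(
    seed = "integer",
    species = "data.frame",
    ancestralMonomer = "character",
    substitutionRate = "numeric",
    kappa = "numeric",
    copyDivergence = "numeric",
    homogenization = "numeric",
    amplification = "data.frame",
    backgroundLength = "integer",
    backgroundAT = "numeric",
    shortRead = "list",
    longRead = "list"
))

setValidity("SatSimConfig", function(object) {
    msg <- character()
    if (nrow(object@species) < 1L)
        msg <- c(msg, "at least one species is required")
    if (!all(c("name", "branchLength") %in% names(object@species)))
        msg <- c(msg, "species must have columns 'name' and 'branchLength'")
    if (nchar(object@ancestralMonomer) != 52L)
        msg <- c(msg, "ancestral monomer must be 52 nt")
    if (!grepl("^[ACGT]+$", object@ancestralMonomer))
        msg <- c(msg, "ancestral monomer must be ACGT only")
    probs <- c(object@substitutionRate, object@homogenization,
               object@backgroundAT, object@shortRead$errorRate,
               object@longRead$errorRate, object@longRead$indelFraction)
    if (any(probs < 0) || any(c(object@homogenization, object@backgroundAT,
            object@shortRead$errorRate, object@longRead$errorRate,
            object@longRead$indelFraction) > 1))
        msg <- c(msg, "rates and probabilities must lie in [0, 1]")
    if (anyDuplicated(object@species$name))
        msg <- c(msg, "species names must be unique")
    if (length(msg)) msg else TRUE
})

#' Ground truth of a simulated genome
#'
#' Records everything the simulator planted: array intervals (0-based
#' half-open, strand '+' meaning the monomer as written), the realized
#' monomer-variant frequency table, and the true total copy number per 1C.
#'
#' @slot arrays [GenomicRanges::GRanges] of planted arrays with metadata
#'   column `nCopies`.
#' @slot variantFreq data.frame with columns `sequence` and `count`:
#'   realized counts of each planted monomer variant (as-written phase).
#' @slot copyNumber total planted monomer copies (per 1C).
#' @export
setClass("SimTruth", representation(
    arrays = "GRanges",
    variantFreq = "data.frame",
    copyNumber = "numeric"
))

setValidity("SimTruth", function(object) {
    msg <- character()
    if (length(object@arrays)) {
        if (any(GenomicRanges::width(object@arrays) < 52L))
            msg <- c(msg, "every truth interval must be >= 52 bp")
        red <- GenomicRanges::reduce(object@arrays, ignore.strand = TRUE)
        if (sum(GenomicRanges::width(red)) !=
            sum(GenomicRanges::width(object@arrays)))
            msg <- c(msg, "truth intervals must not overlap")
    }
    if (sum(object@variantFreq$count) != object@copyNumber)
        msg <- c(msg, "copy number must equal the sum of variant counts")
    if (length(msg)) msg else TRUE
})

#' Pool of monomer variants with per-species abundances
#'
#' A tally of distinct, rotation-canonical monomer sequences, one row per
#' (species, sequence) pair with a positive count. Produced by
#' [tallyAndFilter()] on extracted monomers or by the simulator.
#'
#' @slot variants data.frame with columns `species`, `sequence`, `count`.
#' @slot provenance `"genomic"` or `"transcriptomic"`.
#' @export
setClass("VariantPool", representation(
    variants = "data.frame",
    provenance = "character"
))

setValidity("VariantPool", function(object) {
    msg <- character()
    v <- object@variants
    if (!all(c("species", "sequence", "count") %in% names(v)))
        msg <- c(msg, "variants needs columns species, sequence, count")
    if (nrow(v)) {
        if (any(v$count < 1L))
            msg <- c(msg, "counts must be positive")
        if (anyDuplicated(paste(v$species, v$sequence)))
            msg <- c(msg, "sequences must be unique within a species")
    }
    if (!object@provenance %in% c("genomic", "transcriptomic"))
        msg <- c(msg, "provenance must be 'genomic' or 'transcriptomic'")
    if (length(msg)) msg else TRUE
})

#' Per-position coverage over a repeat (or gene) reference
#'
#' Read depth and per-base counts along one mapping reference; for the
#' satellite concatemer the per-base counts feed the variant profile. Depth
#' counts base-aligned columns only, so positions deleted in a read do not
#' contribute (this is what makes deletion subfamilies visible as coverage
#' valleys).
#'
#' @slot reference name of the reference.
#' @slot refSeq reference sequence (character).
#' @slot depth numeric vector, one value per reference position.
#' @slot baseCounts 4 x length matrix (rows A, C, G, T) of aligned read
#'   bases per position; column sums equal depth.
#' @slot monomerLength monomer unit length (52 for the satellite
#'   concatemer; `NA` for gene references).
#' @export
setClass("CoverageProfile", representation(
    reference = "character",
    refSeq = "character",
    depth = "numeric",
    baseCounts = "matrix",
    monomerLength = "integer"
))

setValidity("CoverageProfile", function(object) {
    msg <- character()
    if (length(object@depth) != nchar(object@refSeq))
        msg <- c(msg, "depth length must equal reference length")
    if (!identical(dim(object@baseCounts),
                   c(4L, length(object@depth))))
        msg <- c(msg, "baseCounts must be 4 x reference length")
    if (any(abs(colSums(object@baseCounts) - object@depth) > 1e-8))
        msg <- c(msg, "base counts must sum to depth at every position")
    if (length(msg)) msg else TRUE
})

#' Minimum spanning tree of monomer variants
#'
#' Edges connect variant haplotypes; edge weight is the Hamming distance
#' (mutational steps). Nodes carry the variant sequence and per-species
#' abundances.
#'
#' @slot edges data.frame with columns `from`, `to`, `distance`.
#' @slot nodes data.frame with columns `id`, `sequence`, `total` plus one
#'   count column per species.
#' @export
setClass("SpanningTree", representation(
    edges = "data.frame",
    nodes = "data.frame"
))

setValidity("SpanningTree", function(object) {
    msg <- character()
    n <- nrow(object@nodes)
    if (n >= 2L && nrow(object@edges) != n - 1L)
        msg <- c(msg, "a spanning tree on n nodes needs n - 1 edges")
    if (length(msg)) msg else TRUE
})

setMethod("show", "SatSimConfig", function(object) {
    cat("SatSimConfig:", nrow(object@species), "species, seed",
        object@seed, "\n")
    cat("  monomer:", object@ancestralMonomer, "\n")
    cat("  background:", object@backgroundLength, "bp, A+T",
        object@backgroundAT, "\n")
    cat("  short reads:", object@shortRead$nPairs, "pairs of",
        object@shortRead$readLength, "nt; long reads:",
        object@longRead$nReads, "at error", object@longRead$errorRate, "\n")
})

setMethod("show", "SimTruth", function(object) {
    cat("SimTruth:", length(object@arrays), "arrays,",
        object@copyNumber, "monomer copies,",
        nrow(object@variantFreq), "variants\n")
})

setMethod("show", "VariantPool", function(object) {
    cat("VariantPool (", object@provenance, "): ",
        length(unique(object@variants$species)), " species, ",
        nrow(object@variants), " variants, total count ",
        sum(object@variants$count), "\n", sep = "")
})

setMethod("show", "CoverageProfile", function(object) {
    cat("CoverageProfile over '", object@reference, "' (",
        length(object@depth), " bp): mean depth ",
        round(mean(object@depth), 2), ", covered fraction ",
        round(coveredFraction(object), 4), "\n", sep = "")
})

setMethod("show", "SpanningTree", function(object) {
    cat("SpanningTree:", nrow(object@nodes), "variants,",
        nrow(object@edges), "edges, total weight",
        sum(object@edges$distance), "\n")
})
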