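#' Concatenated consensus mapping reference
#'
#' The satellite mapping reference is the consensus monomer repeated `k`
#' times (208 bp for a 52-bp monomer and `k = 4`), so reads spanning a
#' monomer junction still map contiguously.
#'
#' @param consensus 52-nt consensus (character or [Biostrings::DNAString]).
#' @param k number of repeats (>= 2).
#' @return character string of length `52 * k`, with attributes
#'   `monomerLength` and `k`.
#' @export
buildConcatemer <- function(consensus, k = 4L) {
    consensus <- toupper(as.character(consensus))
    if (nchar(consensus) != 52L)
        stop("configuration error: consensus must be 52 nt")
    if (k < 2L)
        stop("configuration error: k must be >= 2")
    ref <- paste(rep(consensus, k), collapse = "")
    attr(ref, "monomerLength") <- 52L
    attr(ref, "k") <- as.integer(k)
    ref
}

#' Map reads to a set of references
#'
#' A k-mer seeded, banded local aligner: every read (both strands) is
#' assigned to its best-scoring local alignment among all references
#' (ties resolved by reference order, then leftmost position); alignments
#' shorter than `minOverlap` aligned columns or below `minIdentity`
#' (matches / alignment columns) leave the read unassigned. Soft-clipping
#' falls out of the local alignment, so reads straddling an array/background
#' junction still contribute their repeat-derived part. Depth counts
#' base-aligned columns only: positions deleted in a read receive no depth,
#' which is what renders deletion subfamilies as coverage valleys.
#'
#' @param reads [Biostrings::DNAStringSet] or character vector.
#' @param references named character vector of reference sequences, in
#'   priority order (ties go to the first).
#' @param minIdentity minimum identity over aligned columns (default 0.9).
#' @param minOverlap minimum aligned columns (default 30).
#' @param seedLen seed k-mer length (default 11).
#' @param band alignment band half-width around the seeded diagonal
#'   (default 8).
#' @param monomerLength optional named integer vector giving the monomer
#'   unit length of repeat references (e.g. `c(sat = 52L)`); used by
#'   [copyNumber()] and [findValleys()].
#' @return list with elements `assignments` (data.frame, one row per read),
#'   `profiles` (named list of [CoverageProfile-class]) and `meanDepth`
#'   (named numeric, per-position mean depth per reference).
#' @export
mapReads <- function(reads, references, minIdentity = 0.9,
                     minOverlap = 30L, seedLen = 11L, band = 8L,
                     monomerLength = NULL) {
    refs <- vapply(references, function(r) toupper(as.character(r)), "")
    if (is.null(names(refs)) || any(!nzchar(names(refs))))
        stop("references must be named")
    if (anyDuplicated(names(refs)))
        stop("configuration error: duplicate reference ids")
    nms <- names(reads)
    reads <- as.character(reads)
    names(reads) <- nms
    res <- .cppMapReads(unname(reads), unname(refs), minIdentity,
                        as.integer(minOverlap), as.integer(seedLen),
                        as.integer(band))
    asg <- data.frame(
        read = if (is.null(names(reads))) seq_along(reads)
               else names(reads),
        reference = names(refs)[res$ref],
        refStart = res$refStart, refEnd = res$refEnd,
        strand = res$strand, matches = res$matches,
        columns = res$columns, identity = res$identity,
        stringsAsFactors = FALSE)
    profiles <- list()
    meanDepth <- numeric(length(refs))
    names(meanDepth) <- names(refs)
    for (i in seq_along(refs)) {
        nm <- names(refs)[i]
        ml <- NA_integer_
        if (!is.null(monomerLength) && nm %in% names(monomerLength))
            ml <- as.integer(monomerLength[[nm]])
        bc <- res$baseCounts[[i]]
        rownames(bc) <- c("A", "C", "G", "T")
        profiles[[nm]] <- new("CoverageProfile", reference = nm,
                              refSeq = unname(refs[i]),
                              depth = res$depth[[i]], baseCounts = bc,
                              monomerLength = ml)
        meanDepth[nm] <- mean(res$depth[[i]])
    }
    list(assignments = asg, profiles = profiles, meanDepth = meanDepth)
}

#' @rdname profileAccessors
#' @export
depthProfile <- function(profile) profile@depth

#' @rdname profileAccessors
#' @export
baseCounts <- function(profile) profile@baseCounts

#' Accessors and summaries for coverage profiles
#'
#' `scaledProfile` rescales depth to `[0, 1]` relative to the maximum
#' observed value; `coveredFraction` is the share of reference positions
#' with nonzero depth; `meanMonomerDepth` is total aligned bases divided by
#' the monomer unit length, i.e. the depth of a single monomer unit (the
#' quantity that, normalized by single-copy depth, equals copies per 1C).
#'
#' @param profile a [CoverageProfile-class].
#' @name profileAccessors
#' @export
scaledProfile <- function(profile) {
    d <- profile@depth
    m <- max(d)
    if (m == 0) return(d)
    d / m
}

#' @rdname profileAccessors
#' @export
coveredFraction <- function(profile) mean(profile@depth > 0)

#' @rdname profileAccessors
#' @export
meanMonomerDepth <- function(profile) {
    ml <- profile@monomerLength
    if (is.na(ml))
        ml <- length(profile@depth)
    sum(profile@depth) / ml
}

#' Copy number normalized to single-copy coverage
#'
#' The satellite's depth per monomer unit divided by the median single-copy
#' gene depth estimates total monomer copies per 1C. The median (rather
#' than the mean) across the gene panel resists a mis-annotated or
#' duplicated gene.
#'
#' @param sat satellite [CoverageProfile-class], or its mean monomer depth
#'   as a number.
#' @param genes list of gene [CoverageProfile-class] objects, or a numeric
#'   vector of per-gene mean depths.
#' @return estimated copies per 1C.
#' @examples
#' copyNumber(500, c(5, 5, 5))  # 100
#' @export
copyNumber <- function(sat, genes) {
    satDepth <- if (is(sat, "CoverageProfile")) meanMonomerDepth(sat)
                else as.numeric(sat)
    geneDepths <- if (is.list(genes))
        vapply(genes, function(g) mean(depthProfile(g)), 0)
    else as.numeric(genes)
    geneDepths <- geneDepths[!is.na(geneDepths)]
    if (!length(geneDepths) || all(geneDepths == 0))
        stop("normalization error: all gene depths are zero")
    satDepth / stats::median(geneDepths)
}

#' Per-position non-reference fraction
#'
#' For every covered position, the fraction of aligned read bases that
#' differ from the reference base; uncovered positions are `NA` (missing),
#' never 0.
#'
#' @param profile a [CoverageProfile-class].
#' @return numeric vector along the reference (values in `[0, 1]` or `NA`).
#' @export
variantFraction <- function(profile) {
    refChars <- strsplit(profile@refSeq, "")[[1]]
    d <- profile@depth
    idx <- match(refChars, rownames(profile@baseCounts))
    refCount <- profile@baseCounts[cbind(idx, seq_along(d))]
    out <- rep(NA_real_, length(d))
    cov <- which(d > 0)
    out[cov] <- 1 - refCount[cov] / d[cov]
    out
}

#' Pearson correlation of two scaled profiles
#'
#' @param a,b [CoverageProfile-class] objects (or numeric profiles) of
#'   equal length; both must be non-constant.
#' @return Pearson r.
#' @export
profileCorrelation <- function(a, b) {
    av <- if (is(a, "CoverageProfile")) scaledProfile(a) else as.numeric(a)
    bv <- if (is(b, "CoverageProfile")) scaledProfile(b) else as.numeric(b)
    if (length(av) != length(bv))
        stop("validation error: profiles differ in length")
    if (stats::sd(av) == 0 || stats::sd(bv) == 0)
        stop("undefined correlation: constant profile")
    stats::cor(av, bv)
}

#' Detect coverage valleys in monomer coordinates
#'
#' The concatemer depth is folded to monomer coordinates (averaging the `k`
#' images of each monomer position); maximal runs of at least `minRun`
#' positions whose folded depth falls below `drop` times the median folded
#' depth are reported as valleys, in 1-based inclusive monomer coordinates.
#' A valley marks positions deleted in a sizeable fraction of copies.
#'
#' @param profile satellite [CoverageProfile-class] (needs a monomer
#'   length), or a numeric depth vector plus `monomerLength`.
#' @param drop depth threshold as a fraction of the median (default 0.6).
#' @param minRun minimum run length (default 2).
#' @param monomerLength monomer unit length when `profile` is numeric.
#' @return data.frame with columns `start`, `end` (1-based inclusive
#'   monomer positions) and `meanFoldedDepth`.
#' @export
findValleys <- function(profile, drop = 0.6, minRun = 2L,
                        monomerLength = NULL) {
    if (is(profile, "CoverageProfile")) {
        d <- profile@depth
        ml <- profile@monomerLength
    } else {
        d <- as.numeric(profile)
        ml <- monomerLength
    }
    if (is.null(ml) || is.na(ml))
        stop("a monomer length is required to fold the profile")
    if (length(d) %% ml != 0L)
        stop("profile length must be a multiple of the monomer length")
    if (all(d == 0))
        stop("profile is zero everywhere")
    folded <- rowMeans(matrix(d, nrow = ml))
    med <- stats::median(folded)
    low <- folded < drop * med
    runs <- rle(low)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    keep <- which(runs$values & runs$lengths >= minRun)
    data.frame(start = starts[keep], end = ends[keep],
               meanFoldedDepth = vapply(keep, function(i)
                   mean(folded[starts[i]:ends[i]]), 0))
}
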