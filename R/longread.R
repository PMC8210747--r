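#' Detect noise-bounded tandem arrays in long reads
#'
#' Local alignment of each read against the infinite cyclic concatenation
#' of the monomer (wraparound dynamic programming; match +1, mismatch and
#' indel penalties configurable), on both strands. Maximal-scoring segments
#' are peeled off greedily (score, then length, then leftmost); a segment is
#' reported when its span reaches `minSpan` and its noise — edit operations
#' divided by alignment columns — stays at or below `maxNoise`. The default
#' penalties (-2) keep local alignment against non-repetitive sequence in
#' the logarithmic regime, so arrays do not accrete random flanking
#' sequence; the noise ratio itself weighs every edit equally.
#'
#' @param reads [Biostrings::DNAStringSet] or named character vector of
#'   long reads.
#' @param monomer 52-nt monomer (character or [Biostrings::DNAString]).
#' @param maxNoise maximum noise ratio (default 0.20, the usual setting for
#'   error-prone long reads).
#' @param minSpan minimum array span in read bases (default 52, one
#'   monomer).
#' @param mismatchPenalty,gapPenalty positive penalty magnitudes for
#'   mismatches and single-base gaps (defaults 2 and 2).
#' @param maxMergeGap same-strand segments separated by at most this many
#'   read bases are merged into one array (default 10): a local error
#'   burst can split one array's alignment into abutting segments.
#' @param xdrop X-drop split threshold (default 50): the alignment is cut
#'   wherever its running score falls this far below its peak, so a
#'   low-identity bridge between two nearby arrays does not fuse them.
#' @return [GenomicRanges::GRanges] in read coordinates (seqnames = read
#'   ids) with metadata columns `noise`, `monomerEquivalents`, `score`.
#' @export
detectArrays <- function(reads, monomer, maxNoise = 0.20, minSpan = 52L,
                         mismatchPenalty = 2L, gapPenalty = 2L,
                         maxMergeGap = 10L, xdrop = 50L) {
    monomer <- toupper(as.character(monomer))
    if (nchar(monomer) != 52L)
        stop("monomer must be 52 nt")
    nms <- names(reads)
    reads <- as.character(reads)
    names(reads) <- if (is.null(nms)) paste0("read", seq_along(reads))
                    else nms
    if (any(!nzchar(reads)))
        stop("validation error: empty read")
    out <- list()
    for (i in seq_along(reads)) {
        hits <- .cppDetectArrays(reads[[i]], monomer, maxNoise,
                                 as.integer(minSpan),
                                 as.integer(mismatchPenalty),
                                 as.integer(gapPenalty),
                                 as.integer(xdrop))
        if (!nrow(hits)) next
        if (nrow(hits) > 1L) {
            hits <- hits[order(hits$start), , drop = FALSE]
            k <- 1L
            for (j in 2:nrow(hits)) {
                gap <- hits$start[j] - hits$end[k]
                if (hits$strand[j] == hits$strand[k] &&
                    gap <= maxMergeGap) {
                    hits$end[k] <- hits$end[j]
                    hits$edits[k] <- hits$edits[k] + hits$edits[j] +
                        max(0L, gap)
                    hits$columns[k] <- hits$columns[k] +
                        hits$columns[j] + max(0L, gap)
                    hits$score[k] <- hits$score[k] + hits$score[j]
                    hits$start[j] <- NA_integer_
                } else {
                    k <- j
                }
            }
            hits <- hits[!is.na(hits$start), , drop = FALSE]
        }
        out[[length(out) + 1L]] <- GenomicRanges::GRanges(
            names(reads)[i],
            IRanges::IRanges(start = hits$start + 1L, end = hits$end),
            strand = hits$strand,
            noise = hits$edits / hits$columns,
            monomerEquivalents = (hits$end - hits$start) / 52,
            score = hits$score)
    }
    if (!length(out))
        return(GenomicRanges::GRanges())
    sort(suppressWarnings(do.call(c, out)), ignore.strand = TRUE)
}

#' Repeat density in kb annotated per Mb sequenced
#'
#' Overlapping intervals are merged before summation.
#'
#' @param intervals [GenomicRanges::GRanges] of detected arrays (read
#'   coordinates).
#' @param totalBases total sequenced bases the intervals were called in.
#' @return list with elements `kbAnnotated`, `mbSequenced`, `density`
#'   (kb/Mb).
#' @export
repeatDensity <- function(intervals, totalBases) {
    if (totalBases <= 0)
        stop("validation error: total bases must be positive")
    annotated <- if (length(intervals))
        sum(GenomicRanges::width(
            GenomicRanges::reduce(intervals, ignore.strand = TRUE)))
    else 0
    list(kbAnnotated = annotated / 1e3, mbSequenced = totalBases / 1e6,
         density = 1000 * annotated / totalBases)
}

#' Extract flanking windows around a detected array
#'
#' Returns the up-to-`window` bases upstream and downstream of the interval
#' in read coordinates; at read edges the flanker is truncated (possibly
#' empty).
#'
#' @param read one read (character or [Biostrings::DNAString]).
#' @param start,end 0-based half-open interval within the read.
#' @param window flanker size (default 10000).
#' @return list with elements `upstream`, `downstream` (character).
#' @export
extractFlankers <- function(read, start, end, window = 10000L) {
    read <- as.character(read)
    n <- nchar(read)
    if (start < 0L || end > n || start >= end)
        stop("validation error: interval outside read")
    up <- substring(read, max(0L, start - window) + 1L, start)
    down <- substring(read, end + 1L, min(n, end + window))
    list(upstream = up, downstream = down)
}

#' Flankers of every detected array in a read set
#'
#' @param reads named [Biostrings::DNAStringSet] or character vector.
#' @param intervals [GenomicRanges::GRanges] from [detectArrays()].
#' @param window flanker size (default 10000).
#' @return named character vector of non-empty flanker sequences
#'   (`<read>_up`/`<read>_down` per interval).
#' @export
arrayFlankers <- function(reads, intervals, window = 10000L) {
    reads <- as.character(reads)
    out <- character()
    for (i in seq_along(intervals)) {
        rid <- as.character(GenomicRanges::seqnames(intervals)[i])
        if (!rid %in% names(reads)) next
        fl <- extractFlankers(reads[[rid]],
                              GenomicRanges::start(intervals)[i] - 1L,
                              GenomicRanges::end(intervals)[i], window)
        if (nzchar(fl$upstream))
            out[paste0(rid, "_arr", i, "_up")] <- fl$upstream
        if (nzchar(fl$downstream))
            out[paste0(rid, "_arr", i, "_down")] <- fl$downstream
    }
    out
}

## alignment-based identity of two sequences over >= minCoverage of the
## shorter one; local alignment, identity = matches / aligned columns
.flankerMatch <- function(a, b, identity, minCoverage = 0.5) {
    shorter <- min(nchar(a), nchar(b))
    aln <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(a), Biostrings::DNAString(b),
        type = "local")
    cols <- Biostrings::nchar(aln)
    if (cols < minCoverage * shorter)
        return(FALSE)
    Biostrings::nmatch(aln) / cols >= identity
}

#' Greedy identity clustering of flanker sequences
#'
#' Sequences are sorted longest-first; each joins the first cluster whose
#' representative (the founding, longest member) it matches at the identity
#' threshold over at least half of the shorter sequence, otherwise it
#' founds a new cluster. Clusters below `minSize` are dropped from the
#' report. Recurrent clusters flag sequences systematically associated with
#' the satellite arrays.
#'
#' @param sequences named character vector.
#' @param minSize minimum reported cluster size (default 3).
#' @param identity identity threshold (default 0.8).
#' @return data.frame with columns `cluster`, `representative`, `size`,
#'   `members` (comma-separated names).
#' @export
clusterFlankers <- function(sequences, minSize = 3L, identity = 0.8) {
    if (!length(sequences))
        stop("no sequences to cluster")
    if (is.null(names(sequences)))
        names(sequences) <- paste0("seq", seq_along(sequences))
    ord <- order(-nchar(sequences))
    reps <- integer()          # indices (into sequences) of representatives
    members <- list()
    for (i in ord) {
        placed <- FALSE
        for (ci in seq_along(reps)) {
            if (.flankerMatch(sequences[[i]], sequences[[reps[ci]]],
                              identity)) {
                members[[ci]] <- c(members[[ci]], i)
                placed <- TRUE
                break
            }
        }
        if (!placed) {
            reps <- c(reps, i)
            members[[length(reps)]] <- i
        }
    }
    sizes <- lengths(members)
    keep <- which(sizes >= minSize)
    if (!length(keep))
        return(data.frame(cluster = integer(),
                          representative = character(),
                          size = integer(), members = character()))
    out <- data.frame(
        cluster = seq_along(keep),
        representative = names(sequences)[reps[keep]],
        size = sizes[keep],
        members = vapply(members[keep], function(ix)
            paste(names(sequences)[ix], collapse = ","), ""))
    out[order(-out$size), , drop = FALSE]
}
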