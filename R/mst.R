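#' Pairwise Hamming distances between variants
#'
#' @param variants named character vector (or [Biostrings::DNAStringSet])
#'   of unique, equal-length, canonicalized sequences; unnamed input is
#'   labelled `v1, v2, ...`.
#' @return symmetric integer matrix of Hamming distances (mutational
#'   steps), zero diagonal.
#' @export
hammingMatrix <- function(variants) {
    nms <- names(variants)
    seqs <- as.character(variants)
    names(seqs) <- nms
    if (anyDuplicated(seqs))
        stop("validation error: variant sequences must be unique")
    if (length(unique(nchar(seqs))) > 1L)
        stop("validation error: variants must have equal length")
    if (is.null(names(seqs)))
        names(seqs) <- paste0("v", seq_along(seqs))
    d <- as.matrix(Biostrings::stringDist(
        Biostrings::DNAStringSet(seqs), method = "hamming"))
    storage.mode(d) <- "integer"
    dimnames(d) <- list(names(seqs), names(seqs))
    d
}

#' Minimum spanning tree of monomer variants
#'
#' Kruskal's algorithm over edges sorted by (distance ascending, combined
#' endpoint abundance descending, lexicographic endpoint ids): high-
#' abundance haplotypes are linked first among equal-distance edges, which
#' fixes a deterministic tree in the spirit of founder-first haplotype
#' network layouts. Node annotations carry the sequence and per-species
#' counts.
#'
#' @param distances symmetric distance matrix from [hammingMatrix()].
#' @param abundances named numeric vector of total abundance per variant
#'   id (missing ids count 0).
#' @param sequences optional named character vector of the variant
#'   sequences (node annotation).
#' @param speciesCounts optional data.frame with columns `id`, `species`,
#'   `count` for per-species node annotation.
#' @return a [SpanningTree-class].
#' @export
buildMST <- function(distances, abundances = NULL, sequences = NULL,
                     speciesCounts = NULL) {
    ids <- rownames(distances)
    n <- length(ids)
    if (n < 2L)
        stop("at least two variants are required")
    if (is.null(abundances))
        abundances <- stats::setNames(rep(0, n), ids)
    ab <- stats::setNames(rep(0, n), ids)
    ab[names(abundances)[names(abundances) %in% ids]] <-
        abundances[names(abundances) %in% ids]
    pairs <- which(upper.tri(distances), arr.ind = TRUE)
    ed <- data.frame(from = ids[pairs[, 1L]], to = ids[pairs[, 2L]],
                     distance = distances[pairs],
                     stringsAsFactors = FALSE)
    swap <- ed$from > ed$to
    tmp <- ed$from[swap]; ed$from[swap] <- ed$to[swap]; ed$to[swap] <- tmp
    comb <- ab[ed$from] + ab[ed$to]
    ord <- order(ed$distance, -comb, ed$from, ed$to)
    ed <- ed[ord, , drop = FALSE]
    parent <- stats::setNames(seq_len(n), ids)
    find <- function(x) {
        while (parent[x] != x) {
            parent[x] <<- parent[parent[x]]
            x <- parent[x]
        }
        x
    }
    keep <- logical(nrow(ed))
    taken <- 0L
    for (e in seq_len(nrow(ed))) {
        ra <- find(match(ed$from[e], ids))
        rb <- find(match(ed$to[e], ids))
        if (ra != rb) {
            parent[ra] <- rb
            keep[e] <- TRUE
            taken <- taken + 1L
            if (taken == n - 1L) break
        }
    }
    edges <- ed[keep, , drop = FALSE]
    rownames(edges) <- NULL
    nodes <- data.frame(id = ids, total = as.numeric(ab[ids]),
                        stringsAsFactors = FALSE)
    nodes$sequence <- if (!is.null(sequences))
        as.character(sequences[ids]) else NA_character_
    if (!is.null(speciesCounts)) {
        for (sp in unique(speciesCounts$species)) {
            d <- speciesCounts[speciesCounts$species == sp, ]
            cnt <- stats::setNames(rep(0, n), ids)
            cnt[d$id[d$id %in% ids]] <- d$count[d$id %in% ids]
            nodes[[sp]] <- as.numeric(cnt[ids])
        }
    }
    rownames(nodes) <- NULL
    new("SpanningTree", edges = edges, nodes = nodes)
}

#' Build the variant MST of a pool
#'
#' Convenience wrapper: tallies the pool across species, computes the
#' Hamming matrix and calls [buildMST()] with abundance annotations.
#'
#' @param pool a [VariantPool-class] of canonicalized variants.
#' @return a [SpanningTree-class].
#' @export
poolMST <- function(pool) {
    v <- pool@variants
    seqs <- sort(unique(v$sequence))
    ids <- stats::setNames(paste0("v", seq_along(seqs)), seqs)
    ab <- tapply(v$count, v$sequence, sum)
    d <- hammingMatrix(stats::setNames(seqs, ids[seqs]))
    sc <- data.frame(id = ids[v$sequence], species = v$species,
                     count = v$count, stringsAsFactors = FALSE)
    buildMST(d,
             abundances = stats::setNames(as.numeric(ab[seqs]),
                                          ids[seqs]),
             sequences = stats::setNames(seqs, ids[seqs]),
             speciesCounts = sc)
}

#' Total weight of a spanning tree
#'
#' @param tree a [SpanningTree-class].
#' @return sum of edge distances.
#' @export
treeWeight <- function(tree) sum(tree@edges$distance)

#' @rdname treeWeight
#' @export
treeEdges <- function(tree) tree@edges

#' @rdname treeWeight
#' @export
treeNodes <- function(tree) tree@nodes

#' Exhaustive minimum spanning weight (brute-force verifier)
#'
#' Enumerates all spanning trees of a small instance (n <= 10) and returns
#' the minimum total weight; an algorithm-independent check for
#' [buildMST()].
#'
#' @param distances symmetric distance matrix.
#' @return minimum spanning weight.
#' @export
exhaustiveMinWeight <- function(distances) {
    n <- nrow(distances)
    if (n < 2L) stop("need at least two nodes")
    pairs <- which(upper.tri(distances), arr.ind = TRUE)
    .cppEnumMinSpanningWeight(n, pairs[, 1L] - 1L, pairs[, 2L] - 1L,
                              distances[pairs])
}
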