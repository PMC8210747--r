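#' Canonical rotation of a circular sequence
#'
#' Tandem-repeat monomers are read out of reads in arbitrary phase; two
#' windows of the same underlying variant differ only by rotation. The
#' canonical representative is the lexicographically minimal rotation, so
#' identical variants tally together regardless of phase.
#'
#' @param x character vector of ACGT sequences.
#' @return character vector of canonical rotations (idempotent,
#'   rotation-class invariant).
#' @examples
#' canonicalRotation("GATC")  # "ATCG"
#' @export
canonicalRotation <- function(x) {
    if (!length(x)) return(character())
    if (any(!nzchar(x))) stop("sequences must be non-empty")
    .cppCanonicalRotation(x)
}

#' Extract complete satellite monomers directly from short reads
#'
#' For each read (both strands) the best-identity 52-nt window against any
#' rotation of the consensus is located (ungapped identity = matches/52).
#' When that window reaches `minIdentity`, the read's phase is locked to it
#' and every complete in-phase 52-nt window is emitted; windows truncated by
#' the read ends are discarded. Emitted monomers are rotation-canonicalized.
#'
#' @param reads [Biostrings::DNAStringSet] (or character vector) of reads,
#'   each at least 52 nt for a chance to yield a monomer.
#' @param consensus 52-nt consensus monomer (character or
#'   [Biostrings::DNAString]).
#' @param minIdentity minimum ungapped identity of the best window
#'   (default 0.70).
#' @param minWindowIdentity optional per-window identity guard against the
#'   locked rotation: windows below it are not emitted. Default 0 (off):
#'   every complete in-phase window is emitted; at shallow array sizes a
#'   guard (e.g. 0.7) suppresses in-phase windows that run past the array
#'   edge into flanking sequence.
#' @param canonicalize rotation-canonicalize the output (default `TRUE`).
#' @return character vector of monomer sequences (one element per emitted
#'   window; tally with [tallyAndFilter()]).
#' @export
extractMonomers <- function(reads, consensus, minIdentity = 0.70,
                            minWindowIdentity = 0,
                            canonicalize = TRUE) {
    consensus <- toupper(as.character(consensus))
    if (nchar(consensus) != 52L)
        stop("configuration error: consensus must be 52 nt")
    reads <- as.character(reads)
    raw <- .cppExtractMonomers(reads, consensus, minIdentity,
                               minWindowIdentity)
    if (canonicalize && length(raw))
        raw <- canonicalRotation(raw)
    raw
}

#' Tally monomers into a variant pool, dropping singletons
#'
#' Variants are defined by exact sequence identity; sequence variants seen
#' only once (singletons) are discarded by default, mirroring the usual
#' guard against sequencing-error artifacts.
#'
#' @param monomers character vector of (canonicalized) monomer sequences,
#'   or a named list of such vectors (one element per species).
#' @param species species label when `monomers` is a plain vector.
#' @param dropSingletons drop count-1 variants (default `TRUE`).
#' @param provenance `"genomic"` (default) or `"transcriptomic"`.
#' @return a [VariantPool-class].
#' @export
tallyAndFilter <- function(monomers, species = "sample",
                           dropSingletons = TRUE,
                           provenance = "genomic") {
    if (!is.list(monomers)) {
        monomers <- stats::setNames(list(monomers), species)
    }
    rows <- lapply(names(monomers), function(sp) {
        m <- monomers[[sp]]
        if (!length(m))
            return(NULL)
        tab <- table(m)
        if (dropSingletons)
            tab <- tab[tab >= 2L]
        if (!length(tab))
            return(NULL)
        data.frame(species = sp, sequence = names(tab),
                   count = as.integer(tab))
    })
    v <- do.call(rbind, rows)
    if (is.null(v))
        v <- data.frame(species = character(), sequence = character(),
                        count = integer())
    rownames(v) <- NULL
    new("VariantPool", variants = v, provenance = provenance)
}

#' Position frequency matrix, consensus and A+T content of a pool
#'
#' Columnwise base counts weighted by variant abundance; the consensus takes
#' the majority base per column (ties resolved alphabetically and flagged);
#' A+T content is computed on the consensus.
#'
#' @param pool a [VariantPool-class] (all sequences must share one length).
#' @param species optional species subset.
#' @return list with elements `matrix` (4 x L count matrix, rows A,C,G,T),
#'   `consensus` (character), `atFraction` (numeric), `ties` (integer vector
#'   of tied columns, possibly empty).
#' @export
consensusComposition <- function(pool, species = NULL) {
    v <- pool@variants
    if (!is.null(species))
        v <- v[v$species %in% species, ]
    if (nrow(v) == 0L)
        stop("pool holds no variants")
    lens <- unique(nchar(v$sequence))
    if (length(lens) != 1L)
        stop("validation error: variants have mixed lengths")
    L <- lens
    mat <- matrix(0, nrow = 4L, ncol = L,
                  dimnames = list(c("A", "C", "G", "T"), NULL))
    chars <- strsplit(v$sequence, "")
    for (i in seq_len(nrow(v))) {
        idx <- match(chars[[i]], rownames(mat))
        for (p in seq_len(L))
            mat[idx[p], p] <- mat[idx[p], p] + v$count[i]
    }
    top <- apply(mat, 2L, max)
    ties <- which(colSums(mat == rep(top, each = 4L)) > 1L)
    consensus <- paste(rownames(mat)[apply(mat, 2L, which.max)],
                       collapse = "")
    atf <- mean(strsplit(consensus, "")[[1]] %in% c("A", "T"))
    list(matrix = mat, consensus = consensus, atFraction = atf,
         ties = ties)
}

#' Genome-size-proportional read subsampling
#'
#' To keep per-base sampling comparable across species, the number of read
#' pairs is scaled linearly with genome size from a reference library
#' (e.g. 1,000,000 pairs at 1.38 Gb).
#'
#' @param nReferencePairs pairs used for the reference genome.
#' @param referenceGenomeSize,targetGenomeSize genome sizes (same units).
#' @return number of pairs for the target species.
#' @examples
#' subsampleByGenomeSize(1e6, 1.38e9, 2.76e9)  # 2,000,000
#' @export
subsampleByGenomeSize <- function(nReferencePairs, referenceGenomeSize,
                                  targetGenomeSize) {
    if (nReferencePairs <= 0 || referenceGenomeSize <= 0 ||
        targetGenomeSize <= 0)
        stop("validation error: sizes must be positive")
    round(nReferencePairs * targetGenomeSize / referenceGenomeSize)
}

#' Drop pool variants far from their species consensus
#'
#' Computes each species' majority consensus from the pool and removes
#' variants whose ungapped identity to it (over the best rotation) falls
#' below the threshold. At shallow simulated array sizes, in-phase windows
#' running past an array edge carry stretches of flanking sequence; such
#' windows recur across reads, survive singleton filtering, and would
#' otherwise inflate within-species divergence.
#'
#' @param pool a [VariantPool-class].
#' @param minIdentity minimum identity to the species consensus
#'   (default 0.85).
#' @return a filtered [VariantPool-class].
#' @export
filterPool <- function(pool, minIdentity = 0.85) {
    v <- pool@variants
    keep <- logical(nrow(v))
    for (sp in unique(v$species)) {
        idx <- which(v$species == sp)
        cons <- consensusComposition(pool, sp)$consensus
        rots <- vapply(seq_len(nchar(cons)) - 1L, function(r)
            paste0(substring(cons, r + 1L), substring(cons, 1L, r)), "")
        for (i in idx) {
            chars <- strsplit(v$sequence[i], "")[[1]]
            best <- max(vapply(rots, function(rt)
                sum(chars == strsplit(rt, "")[[1]]), 0L))
            keep[i] <- best / nchar(cons) >= minIdentity
        }
    }
    new("VariantPool", variants = v[keep, , drop = FALSE],
        provenance = pool@provenance)
}

#' Variants shared across species
#'
#' Exact-sequence intersection of per-species pools: for every variant
#' carried by at least `minSpecies` species, the carrying species and their
#' counts are reported, sorted by species count (descending).
#'
#' @param pool a [VariantPool-class] with canonicalized sequences.
#' @param minSpecies minimum number of carrying species (default 2).
#' @return data.frame with columns `sequence`, `nSpecies`, `species`
#'   (comma-separated), `totalCount`.
#' @export
sharedVariants <- function(pool, minSpecies = 2L) {
    v <- pool@variants
    if (nrow(v) == 0L)
        return(data.frame(sequence = character(), nSpecies = integer(),
                          species = character(), totalCount = integer()))
    sp <- split(v, v$sequence)
    out <- do.call(rbind, lapply(sp, function(d) {
        data.frame(sequence = d$sequence[1L],
                   nSpecies = length(unique(d$species)),
                   species = paste(sort(unique(d$species)),
                                   collapse = ","),
                   totalCount = sum(d$count))
    }))
    out <- out[out$nSpecies >= minSpecies, , drop = FALSE]
    out <- out[order(-out$nSpecies, -out$totalCount, out$sequence), ,
               drop = FALSE]
    rownames(out) <- NULL
    out
}
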