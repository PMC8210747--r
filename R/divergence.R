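.PURINES <- c("A", "G")

## classify aligned site pairs: returns c(transitions, transversions, L)
.siteClasses <- function(a, b) {
    ca <- strsplit(a, "")[[1]]
    cb <- strsplit(b, "")[[1]]
    diff <- which(ca != cb)
    ts <- sum((ca[diff] %in% .PURINES) == (cb[diff] %in% .PURINES))
    c(transitions = ts, transversions = length(diff) - ts,
      L = length(ca))
}

#' Kimura 2-parameter distance
#'
#' `K = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)` with `P` the transition and
#' `Q` the transversion proportion, for two aligned equal-length ACGT
#' sequences. Distances are reported as proportions; multiply by 100 for
#' the conventional percent scale.
#'
#' @param a,b aligned sequences (character or [Biostrings::DNAString]) of
#'   equal length, ACGT only.
#' @return list with elements `P`, `Q`, `K` (symmetric in `a`, `b`).
#' @examples
#' m <- strrep("A", 51)
#' kimura2p(paste0(m, "A"), paste0(m, "G"))$K  # one transition: 0.019610
#' @export
kimura2p <- function(a, b) {
    a <- toupper(as.character(a)); b <- toupper(as.character(b))
    if (nchar(a) != nchar(b))
        stop("validation error: sequences must have equal length")
    if (!grepl("^[ACGT]+$", a) || !grepl("^[ACGT]+$", b))
        stop("validation error: ACGT alphabet only")
    cl <- .siteClasses(a, b)
    P <- cl[["transitions"]] / cl[["L"]]
    Q <- cl[["transversions"]] / cl[["L"]]
    w1 <- 1 - 2 * P - Q
    w2 <- 1 - 2 * Q
    if (w1 <= 0 || w2 <= 0)
        stop("saturation error: K2P distance undefined (log argument <= 0)")
    list(P = P, Q = Q, K = -0.5 * log(w1) - 0.25 * log(w2))
}

#' Repeat landscape: divergence-binned repeat mass
#'
#' Each monomer variant contributes `52 * count` aligned bases to the 1%
#' divergence bin `floor(100 * K)` of its K2P distance to the consensus;
#' variant/consensus pairs past saturation fall into an overflow bin.
#'
#' @param pool a [VariantPool-class] (or data.frame with columns `sequence`
#'   and `count`).
#' @param consensus consensus monomer of the same length.
#' @param normalize also report each bin as a proportion of total bases.
#' @return data.frame with columns `bin` (lower edge, % divergence; `Inf`
#'   for the saturation overflow), `bases`, and `proportion` when
#'   `normalize = TRUE`.
#' @export
repeatLandscape <- function(pool, consensus, normalize = TRUE) {
    v <- if (is(pool, "VariantPool")) pool@variants else pool
    consensus <- toupper(as.character(consensus))
    if (nrow(v) == 0L)
        stop("pool holds no variants")
    bins <- vapply(seq_len(nrow(v)), function(i) {
        k <- tryCatch(kimura2p(v$sequence[i], consensus)$K * 100,
                      error = function(e) Inf)
        if (is.infinite(k)) Inf else floor(k)
    }, 0)
    mass <- tapply(nchar(v$sequence) * v$count, bins, sum)
    out <- data.frame(bin = as.numeric(names(mass)),
                      bases = as.numeric(mass))
    out <- out[order(out$bin), , drop = FALSE]
    rownames(out) <- NULL
    if (normalize)
        out$proportion <- out$bases / sum(out$bases)
    out
}

## abundance-weighted mean pairwise K over the given variant pairs;
## self-pairs excluded for intra. Returns list(K, skipped).
.weightedPairwiseK <- function(seqA, cntA, seqB = NULL, cntB = NULL) {
    intra <- is.null(seqB)
    if (intra) { seqB <- seqA; cntB <- cntA }
    tot <- 0; wsum <- 0; skipped <- 0L
    for (i in seq_along(seqA)) {
        js <- if (intra) seq_len(i - 1L) else seq_along(seqB)
        for (j in js) {
            k <- tryCatch(kimura2p(seqA[i], seqB[j])$K,
                          error = function(e) NA_real_)
            if (is.na(k)) { skipped <- skipped + 1L; next }
            w <- cntA[i] * cntB[j]
            tot <- tot + w * k
            wsum <- wsum + w
        }
    }
    list(K = if (wsum > 0) tot / wsum else NA_real_, skipped = skipped)
}

#' Intra- and interspecific divergence summary of a variant pool
#'
#' Intraspecific divergence is the abundance-weighted mean pairwise K2P
#' distance over distinct variant pairs within each species (a species fixed
#' for a single variant scores 0); interspecific divergence is the
#' abundance-weighted mean pairwise K2P over variant pairs drawn from
#' different species. Pair weights are `count_i * count_j`. Saturated pairs
#' are skipped and counted.
#'
#' @param pool a [VariantPool-class].
#' @return list with elements `intra` (data.frame: `species`, `n`,
#'   `intraKD` in percent), `inter` (global mean, percent) and
#'   `skippedPairs`.
#' @export
divergenceSummary <- function(pool) {
    v <- pool@variants
    if (nrow(v) == 0L)
        stop("pool holds no variants")
    spl <- split(v, v$species)
    skipped <- 0L
    intra <- do.call(rbind, lapply(names(spl), function(sp) {
        d <- spl[[sp]]
        if (nrow(d) < 2L)
            return(data.frame(species = sp, n = sum(d$count),
                              intraKD = 0))
        r <- .weightedPairwiseK(d$sequence, d$count)
        skipped <<- skipped + r$skipped
        data.frame(species = sp, n = sum(d$count),
                   intraKD = 100 * r$K)
    }))
    inter <- NA_real_
    if (length(spl) >= 2L) {
        tot <- 0; wsum <- 0
        sps <- names(spl)
        for (i in seq_along(sps)) for (j in seq_len(i - 1L)) {
            da <- spl[[sps[i]]]; db <- spl[[sps[j]]]
            r <- .weightedPairwiseK(da$sequence, da$count,
                                    db$sequence, db$count)
            skipped <- skipped + r$skipped
            if (!is.na(r$K)) {
                w <- sum(da$count) * sum(db$count)
                tot <- tot + w * r$K
                wsum <- wsum + w
            }
        }
        if (wsum == 0)
            stop("saturation error: all interspecific pairs saturated")
        inter <- 100 * tot / wsum
    }
    rownames(intra) <- NULL
    list(intra = intra, inter = inter, skippedPairs = skipped)
}

#' Column summary statistics: mean, sample SD, CV
#'
#' The summary used for per-species table columns: arithmetic mean, sample
#' standard deviation (n - 1 denominator) and coefficient of variation
#' `CV = 100 * SD / mean`.
#'
#' @param values numeric vector, `n >= 2`.
#' @return list with elements `n`, `mean`, `sd`, `cv`.
#' @export
columnSummary <- function(values) {
    values <- values[!is.na(values)]
    n <- length(values)
    if (n < 2L)
        stop("insufficient data: need at least two values")
    m <- mean(values)
    s <- stats::sd(values)
    list(n = n, mean = m, sd = s,
         cv = if (m != 0) 100 * s / m else NA_real_)
}

#' Published per-species summary of the conserved 52-bp satellite
#'
#' The per-species monomer counts, A+T content, abundance and
#' intraspecific K2P divergence reported for CharSat01-52 across 14
#' Characiformes species (short-read data), shipped as a plain-text table.
#' These printed values are the input for the summary-statistics
#' reproduction in `scripts/acceptance.R`.
#'
#' @return data.frame with columns `species`, `n`, `monomerSize`,
#'   `atPercent`, `abundance`, `intraKD`.
#' @export
charSatTable <- function() {
    path <- system.file("extdata", "charsat01_species_summary.tsv",
                        package = "satcons")
    readReport(path)
}
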