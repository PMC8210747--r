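## Synthetic multi-species satellite study: the "library model" simulator.
## Every output stream draws from its own RNG seed derived from the master
## seed, so adding one output does not perturb the others.

.BASES <- c("A", "C", "G", "T")
.TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")
.TRANSVERSIONS <- list(A = c("C", "T"), G = c("C", "T"),
                       C = c("A", "G"), T = c("A", "G"))

## deterministic per-stream seed below 2^31
.streamSeed <- function(master, tag) {
    h <- as.double(master) %% 2147483647
    for (k in utf8ToInt(tag)) h <- (h * 131 + k) %% 2147483647
    as.integer(h)
}

#' Build a simulation configuration
#'
#' The defaults are the package's reference study conditions: eight species
#' diverging down a known tree, a 52-bp A+T-rich ancestral monomer, one
#' species with a clustered (high copy number) amplification profile and
#' seven with few short arrays, 50-kb genomes with A+T 0.65 background,
#' 2 x 101 bp short reads, and long reads with ~15% indel-dominated error.
#'
#' @param seed master seed (integer).
#' @param species data.frame with columns `name`, `branchLength`.
#' @param ancestralMonomer 52-nt ACGT string.
#' @param substitutionRate per-site probability multiplier on branch lengths.
#' @param kappa transition/transversion probability ratio (2 gives the
#'   classic Kimura bias).
#' @param copyDivergence per-copy-event branch length of intragenomic
#'   copying; per-site mutation probability per copy event is
#'   `substitutionRate * copyDivergence`.
#' @param homogenization probability a new copy is resampled from the
#'   species consensus rather than its template (concerted evolution knob).
#' @param amplification data.frame with columns `name`, `nArrays`,
#'   `minCopies`, `maxCopies`.
#' @param backgroundLength,backgroundAT background sequence length and A+T
#'   fraction.
#' @param shortRead list(`nPairs`, `readLength`, `errorRate`).
#' @param longRead list(`nReads`, `meanLog`, `sdLog`, `errorRate`,
#'   `indelFraction`).
#' @return a validated [SatSimConfig-class] object.
#' @examples
#' cfg <- simulationConfig(seed = 1)
#' cfg
#' @export
simulationConfig <- function(
    seed = 42L,
    species = data.frame(
        name = paste0("sp", 1:8),
        branchLength = c(0.04, 0.02, 0.03, 0.03, 0.04, 0.05, 0.05, 0.06)),
    ancestralMonomer =
        "GAATCTATTATGTGCTTGGTTCAATAAACCGTGATAACAAGTTCCTAGCAAT",
    substitutionRate = 1,
    kappa = 2,
    copyDivergence = 0.005,
    homogenization = 0.5,
    amplification = NULL,
    backgroundLength = 50000L,
    backgroundAT = 0.65,
    shortRead = list(nPairs = 20000L, readLength = 101L, errorRate = 0.001),
    longRead = list(nReads = 60L, meanLog = log(8000), sdLog = 0.35,
                    errorRate = 0.15, indelFraction = 0.6)) {
    if (is.null(amplification)) {
        amplification <- data.frame(
            name = species$name,
            nArrays = c(3L, rep(4L, nrow(species) - 1L)),
            minCopies = c(80L, rep(8L, nrow(species) - 1L)),
            maxCopies = c(120L, rep(25L, nrow(species) - 1L)))
    }
    sr <- utils::modifyList(
        list(nPairs = 20000L, readLength = 101L, errorRate = 0.001),
        shortRead)
    lr <- utils::modifyList(
        list(nReads = 60L, meanLog = log(8000), sdLog = 0.35,
             errorRate = 0.15, indelFraction = 0.6), longRead)
    new("SatSimConfig", seed = as.integer(seed), species = species,
        ancestralMonomer = ancestralMonomer,
        substitutionRate = substitutionRate, kappa = kappa,
        copyDivergence = copyDivergence, homogenization = homogenization,
        amplification = amplification,
        backgroundLength = as.integer(backgroundLength),
        backgroundAT = backgroundAT, shortRead = sr, longRead = lr)
}

## per-site i.i.d. Kimura-style mutation: given a mutation, transition with
## probability kappa/(kappa+2), else one of the two transversions.
.mutateSeq <- function(seq, pSite, kappa) {
    if (pSite <= 0)
        return(seq)
    chars <- strsplit(seq, "")[[1]]
    hit <- which(stats::runif(length(chars)) < pSite)
    if (!length(hit))
        return(seq)
    isTs <- stats::runif(length(hit)) < kappa / (kappa + 2)
    for (j in seq_along(hit)) {
        b <- chars[hit[j]]
        chars[hit[j]] <- if (isTs[j]) .TRANSITION[[b]]
                         else sample(.TRANSVERSIONS[[b]], 1L)
    }
    paste(chars, collapse = "")
}

#' Evolve the satellite library down the species tree
#'
#' Each species consensus diverges from the ancestral monomer by per-site
#' i.i.d. substitution with probability `branchLength * substitutionRate`
#' (transition:transversion ratio `kappa`). Within each species a copy pool
#' is then grown by sequential copying: each new copy is resampled from the
#' consensus with probability `homogenization`, otherwise it copies the
#' previous copy with per-site mutation probability
#' `substitutionRate * copyDivergence`.
#'
#' @param config a [SatSimConfig-class].
#' @return a [VariantPool-class] (provenance `"genomic"`) tallying the copy
#'   pool of every species; the per-species consensus is attached as
#'   attribute `consensus` of the `variants` slot's parent object, retrieve
#'   it with `metadata`-style accessor [poolConsensus()].
#' @export
evolveLibrary <- function(config) {
    stopifnot(is(config, "SatSimConfig"))
    validObject(config)
    if (nrow(config@species) == 0L)
        stop("configuration error: empty species list")
    rows <- list(); consensus <- character()
    for (i in seq_len(nrow(config@species))) {
        sp <- config@species$name[i]
        bl <- config@species$branchLength[i]
        set.seed(.streamSeed(config@seed, paste0("evolve:", sp)))
        cons <- .mutateSeq(config@ancestralMonomer,
                           bl * config@substitutionRate, config@kappa)
        consensus[[sp]] <- cons
        amp <- config@amplification[config@amplification$name == sp, ]
        if (nrow(amp) != 1L)
            stop("configuration error: no amplification profile for ", sp)
        n <- max(1L, amp$nArrays *
                     as.integer(round((amp$minCopies + amp$maxCopies) / 2)))
        pCopy <- config@substitutionRate * config@copyDivergence
        copies <- character(n)
        copies[1L] <- cons
        if (n > 1L) for (j in 2:n) {
            ## homogenized copies are exact consensus resamples; only
            ## template copying mutates
            copies[j] <- if (stats::runif(1) < config@homogenization) cons
                         else .mutateSeq(copies[j - 1L], pCopy,
                                         config@kappa)
        }
        tab <- table(copies)
        rows[[sp]] <- data.frame(species = sp, sequence = names(tab),
                                 count = as.integer(tab))
    }
    v <- do.call(rbind, rows)
    rownames(v) <- NULL
    pool <- new("VariantPool", variants = v, provenance = "genomic")
    attr(pool@variants, "consensus") <- consensus
    pool
}

#' Per-species consensus sequences recorded by [evolveLibrary()]
#'
#' @param pool a [VariantPool-class] produced by [evolveLibrary()].
#' @return named character vector of species consensus monomers.
#' @export
poolConsensus <- function(pool) attr(pool@variants, "consensus")

#' Variant table of a pool
#'
#' @param pool a [VariantPool-class].
#' @return data.frame with columns `species`, `sequence`, `count`.
#' @export
poolTable <- function(pool) {
    v <- pool@variants
    attr(v, "consensus") <- NULL
    v
}

#' @rdname truthAccessors
#' @export
truthArrays <- function(truth) truth@arrays

#' Accessors for simulation ground truth
#'
#' @param truth a [SimTruth-class].
#' @return `truthArrays`: the planted-array [GenomicRanges::GRanges];
#'   `trueCopyNumber`: total planted monomer copies; `truthVariantFreq`:
#'   data.frame of realized planted variant counts.
#' @name truthAccessors
#' @export
trueCopyNumber <- function(truth) truth@copyNumber

#' @rdname truthAccessors
#' @export
truthVariantFreq <- function(truth) truth@variantFreq

.randomBackground <- function(n, at) {
    paste(sample(.BASES, n, replace = TRUE,
                 prob = c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2)),
          collapse = "")
}

#' Build one simulated genome with planted satellite arrays
#'
#' Arrays are head-to-tail concatenations of monomers sampled i.i.d. from
#' the species pool, planted at uniformly drawn non-overlapping positions
#' (rejection sampling, at most 1000 attempts per array) in a random
#' background of the configured A+T composition; each array carries a
#' random strand. The returned truth records every planted interval, the
#' realized variant tally (plus-phase sequences) and the total copy number.
#'
#' @param pool a [VariantPool-class] (from [evolveLibrary()] or hand-built).
#' @param speciesName which species of the pool to build.
#' @param config a [SatSimConfig-class].
#' @return list with elements `genome` (named [Biostrings::DNAStringSet] of
#'   length 1) and `truth` ([SimTruth-class]).
#' @export
buildGenome <- function(pool, speciesName, config) {
    stopifnot(is(pool, "VariantPool"), is(config, "SatSimConfig"))
    v <- pool@variants[pool@variants$species == speciesName, ]
    if (nrow(v) == 0L)
        stop("pool has no variants for species ", speciesName)
    amp <- config@amplification[config@amplification$name == speciesName, ]
    if (nrow(amp) != 1L)
        stop("configuration error: no amplification profile for ",
             speciesName)
    set.seed(.streamSeed(config@seed, paste0("genome:", speciesName)))
    glen <- config@backgroundLength
    genome <- .randomBackground(glen, config@backgroundAT)
    nArrays <- amp$nArrays
    if (nArrays == 0L) {
        truth <- new("SimTruth", arrays = GenomicRanges::GRanges(),
                     variantFreq = data.frame(sequence = character(),
                                              count = integer()),
                     copyNumber = 0)
        gset <- Biostrings::DNAStringSet(genome)
        names(gset) <- speciesName
        return(list(genome = gset, truth = truth))
    }
    rng <- seq.int(amp$minCopies, amp$maxCopies)
    copiesPer <- rng[sample.int(length(rng), nArrays, replace = TRUE)]
    if (sum(copiesPer) * 52L > glen)
        stop("sizing error: requested arrays (", sum(copiesPer) * 52L,
             " bp) do not fit in background of ", glen, " bp")
    allCopies <- sample(v$sequence, sum(copiesPer), replace = TRUE,
                        prob = v$count / sum(v$count))
    ends <- cumsum(copiesPer)
    starts1 <- c(1L, utils::head(ends, -1L) + 1L)
    placed <- matrix(integer(), ncol = 2L)  # 1-based [start, end]
    gchars <- strsplit(genome, "")[[1]]
    arrGr <- list()
    for (a in seq_len(nArrays)) {
        arrCopies <- allCopies[starts1[a]:ends[a]]
        arrSeq <- paste(arrCopies, collapse = "")
        w <- nchar(arrSeq)
        minus <- stats::runif(1) < 0.5
        ins <- if (minus) revComp(arrSeq) else arrSeq
        ok <- FALSE
        for (try in seq_len(1000L)) {
            s <- sample.int(glen - w + 1L, 1L)
            e <- s + w - 1L
            if (nrow(placed) == 0L ||
                all(e < placed[, 1L] | s > placed[, 2L])) {
                ok <- TRUE
                break
            }
        }
        if (!ok)
            stop("sizing error: could not place array ", a,
                 " after 1000 attempts")
        placed <- rbind(placed, c(s, e))
        gchars[s:e] <- strsplit(ins, "")[[1]]
        arrGr[[a]] <- GenomicRanges::GRanges(
            speciesName, IRanges::IRanges(start = s, end = e),
            strand = if (minus) "-" else "+", nCopies = length(arrCopies))
    }
    tab <- table(allCopies)
    truth <- new("SimTruth",
                 arrays = sort(do.call(c, arrGr)),
                 variantFreq = data.frame(sequence = names(tab),
                                          count = as.integer(tab)),
                 copyNumber = length(allCopies))
    gset <- Biostrings::DNAStringSet(paste(gchars, collapse = ""))
    names(gset) <- speciesName
    list(genome = gset, truth = truth)
}

.substituteErrors <- function(seqs, errorRate) {
    if (errorRate <= 0 || !length(seqs))
        return(seqs)
    chars <- strsplit(seqs, "")
    lens <- lengths(chars)
    flat <- unlist(chars, use.names = FALSE)
    hit <- which(stats::runif(length(flat)) < errorRate)
    if (length(hit)) {
        repl <- vapply(flat[hit], function(b)
            sample(setdiff(.BASES, b), 1L), "")
        flat[hit] <- repl
        seqs <- vapply(split(flat, rep(seq_along(lens), lens)),
                       paste, "", collapse = "")
        names(seqs) <- NULL
    }
    seqs
}

#' Simulate paired-end short reads from a genome
#'
#' Inward-facing 2 x `readLength` pairs from uniformly placed fragments
#' (normal fragment length, mean 350, sd 35, truncated to the read length),
#' from both strands, with i.i.d. per-base substitution errors. With
#' `errorRate = 0` every read is an exact substring of the genome or its
#' reverse complement.
#'
#' @param genome named [Biostrings::DNAStringSet] of length 1 (from
#'   [buildGenome()]), or a character string.
#' @param config a [SatSimConfig-class].
#' @param tag stream tag used to derive the RNG seed (defaults to the
#'   genome name).
#' @return list with elements `r1`, `r2` (named [Biostrings::DNAStringSet]).
#' @export
simulateShortReads <- function(genome, config, tag = NULL) {
    if (is(genome, "DNAStringSet")) {
        gname <- names(genome)[1L]
        gseq <- as.character(genome[[1L]])
    } else {
        gname <- "genome"
        gseq <- as.character(genome)
    }
    if (is.null(tag)) tag <- gname
    L <- config@shortRead$readLength
    n <- config@shortRead$nPairs
    glen <- nchar(gseq)
    if (L > glen)
        stop("sizing error: read length exceeds genome length")
    set.seed(.streamSeed(config@seed, paste0("short:", tag)))
    frag <- pmin(pmax(round(stats::rnorm(n, 350, 35)), L), glen)
    start <- vapply(glen - frag + 1L, function(m) sample.int(m, 1L), 1L)
    left <- substring(gseq, start, start + L - 1L)
    right <- revComp(substring(gseq, start + frag - L, start + frag - 1L))
    flip <- stats::runif(n) < 0.5  # fragment sampled from the minus strand
    r1 <- ifelse(flip, right, left)
    r2 <- ifelse(flip, left, right)
    r1 <- .substituteErrors(r1, config@shortRead$errorRate)
    r2 <- .substituteErrors(r2, config@shortRead$errorRate)
    ids <- sprintf("%s_p%06d", tag, seq_len(n))
    r1 <- Biostrings::DNAStringSet(r1); names(r1) <- paste0(ids, "/1")
    r2 <- Biostrings::DNAStringSet(r2); names(r2) <- paste0(ids, "/2")
    list(r1 = r1, r2 = r2)
}

## one noisy copy of src with per-base error events; returns the read and
## the read coordinate (1-based) of every source base (NA when deleted)
.noisyCopy <- function(src, errorRate, indelFraction) {
    chars <- strsplit(src, "")[[1]]
    n <- length(chars)
    pSub <- errorRate * (1 - indelFraction)
    pIns <- errorRate * indelFraction / 2
    pDel <- errorRate * indelFraction / 2
    ev <- sample(c("M", "S", "I", "D"), n, replace = TRUE,
                 prob = c(1 - pSub - pIns - pDel, pSub, pIns, pDel))
    pieces <- chars
    sub <- which(ev == "S")
    if (length(sub))
        pieces[sub] <- vapply(chars[sub], function(b)
            sample(setdiff(.BASES, b), 1L), "")
    ins <- which(ev == "I")
    if (length(ins))
        pieces[ins] <- paste0(chars[ins],
                              sample(.BASES, length(ins), replace = TRUE))
    pieces[ev == "D"] <- ""
    lens <- nchar(pieces)
    cum <- cumsum(lens)
    startPos <- cum - lens + 1L
    startPos[lens == 0L] <- NA_integer_
    list(read = paste(pieces, collapse = ""), srcStart = startPos,
         srcEnd = cum)
}

#' Simulate noisy long reads from a genome
#'
#' Log-normal read lengths, uniform placement, random strand, and an
#' indel-dominated error process: each source base suffers an error with
#' probability `errorRate`, split between substitutions and (single-base)
#' insertions/deletions by `indelFraction`. Planted-array truth intervals
#' overlapping each read are re-expressed in read coordinates (clipped to
#' the read; kept when the clipped interval still spans >= 52 bp).
#'
#' @param genome named [Biostrings::DNAStringSet] of length 1.
#' @param truth the genome's [SimTruth-class] (or `NULL` for no truth).
#' @param config a [SatSimConfig-class].
#' @param tag stream tag (defaults to the genome name).
#' @return list with elements `reads` (named [Biostrings::DNAStringSet])
#'   and `truth` ([GenomicRanges::GRanges] in read coordinates, metadata
#'   column `nCopies`).
#' @export
simulateLongReads <- function(genome, truth, config, tag = NULL) {
    gname <- names(genome)[1L]
    gseq <- as.character(genome[[1L]])
    if (is.null(tag)) tag <- gname
    glen <- nchar(gseq)
    lr <- config@longRead
    minLen <- 1000L
    if (glen < minLen)
        stop("sizing error: genome shorter than minimum read length")
    set.seed(.streamSeed(config@seed, paste0("long:", tag)))
    lens <- pmin(pmax(round(stats::rlnorm(lr$nReads, lr$meanLog,
                                          lr$sdLog)), minLen), glen)
    ## fragments are placed on the extended axis and clipped at the genome
    ## ends, so per-base sampling is uniform along the genome (molecules
    ## running off the ends come back truncated)
    s0 <- vapply(glen + lens - 1L, function(m) sample.int(m, 1L), 1L) -
        lens + 1L
    starts <- pmax(1L, s0)
    lens <- pmin(glen, s0 + lens - 1L) - starts + 1L
    minus <- stats::runif(lr$nReads) < 0.5
    reads <- character(lr$nReads)
    truthGr <- list()
    ta <- if (is.null(truth)) GenomicRanges::GRanges() else truth@arrays
    for (i in seq_len(lr$nReads)) {
        src <- substring(gseq, starts[i], starts[i] + lens[i] - 1L)
        nc <- .noisyCopy(src, lr$errorRate, lr$indelFraction)
        rd <- nc$read
        rid <- sprintf("%s_lr%04d", tag, i)
        if (length(ta)) {
            ovS <- pmax(GenomicRanges::start(ta), starts[i])
            ovE <- pmin(GenomicRanges::end(ta), starts[i] + lens[i] - 1L)
            keep <- which(ovE - ovS + 1L >= 52L)
            for (k in keep) {
                la <- ovS[k] - starts[i] + 1L
                lb <- ovE[k] - starts[i] + 1L
                rs <- nc$srcStart[la:lb]
                rs <- rs[!is.na(rs)]
                if (!length(rs)) next
                a <- min(rs); b <- max(nc$srcEnd[lb], max(rs))
                st <- as.character(GenomicRanges::strand(ta[k]))
                if (minus[i]) {
                    rl <- nchar(rd)
                    tmp <- a
                    a <- rl - b + 1L
                    b <- rl - tmp + 1L
                    st <- if (st == "+") "-" else "+"
                }
                truthGr[[length(truthGr) + 1L]] <- GenomicRanges::GRanges(
                    rid, IRanges::IRanges(a, b), strand = st,
                    nCopies = ta$nCopies[k])
            }
        }
        reads[i] <- if (minus[i]) revComp(rd) else rd
    }
    rset <- Biostrings::DNAStringSet(reads)
    names(rset) <- sprintf("%s_lr%04d", tag, seq_len(lr$nReads))
    tg <- if (length(truthGr))
        sort(suppressWarnings(do.call(c, truthGr)))
    else GenomicRanges::GRanges()
    list(reads = rset, truth = tg)
}

#' Simulate the full multi-species study
#'
#' Runs [evolveLibrary()], then per species [buildGenome()],
#' [simulateShortReads()] and [simulateLongReads()].
#'
#' @param config a [SatSimConfig-class].
#' @param longReads simulate long reads too (default `TRUE`).
#' @return list with elements `config`, `pool`, `consensus`, and per-species
#'   lists `genomes`, `truths`, `shortReads`, `longReads`.
#' @export
simulateStudy <- function(config = simulationConfig(), longReads = TRUE) {
    pool <- evolveLibrary(config)
    out <- list(config = config, pool = pool,
                consensus = poolConsensus(pool),
                genomes = list(), truths = list(),
                shortReads = list(), longReads = list())
    for (sp in config@species$name) {
        g <- buildGenome(pool, sp, config)
        out$genomes[[sp]] <- g$genome
        out$truths[[sp]] <- g$truth
        out$shortReads[[sp]] <- simulateShortReads(g$genome, config)
        if (longReads)
            out$longReads[[sp]] <- simulateLongReads(g$genome, g$truth,
                                                     config)
    }
    out
}

#' Write a simulated study to disk
#'
#' Emits, per species, the genome FASTA, paired FASTQ short reads, long-read
#' FASTA, a BED6 truth file of planted arrays (score = planted copy count)
#' and a pool TSV of true variant frequencies.
#'
#' @param study result of [simulateStudy()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSimulation <- function(study, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (sp in names(study$genomes)) {
        writeSeqs(study$genomes[[sp]],
                  file.path(dir, paste0(sp, "_genome.fa")))
        sr <- study$shortReads[[sp]]
        writeSeqs(sr$r1, file.path(dir, paste0(sp, "_R1.fastq")), "fastq")
        writeSeqs(sr$r2, file.path(dir, paste0(sp, "_R2.fastq")), "fastq")
        if (!is.null(study$longReads[[sp]]))
            writeSeqs(study$longReads[[sp]]$reads,
                      file.path(dir, paste0(sp, "_longreads.fa")))
        tr <- study$truths[[sp]]
        gr <- truthArrays(tr)
        if (length(gr)) {
            gr$name <- rep("sat_array", length(gr))
            gr$score <- gr$nCopies
        }
        writeBed(gr, file.path(dir, paste0(sp, "_truth.bed")))
    }
    writeReport(poolTable(study$pool), file.path(dir, "true_pool.tsv"))
    invisible(dir)
}
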