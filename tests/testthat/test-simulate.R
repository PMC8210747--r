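test_that("zero substitution rate propagates the ancestral monomer", {
    cfg <- simulationConfig(seed = 3, substitutionRate = 0)
    pool <- evolveLibrary(cfg)
    v <- poolTable(pool)
    expect_setequal(unique(v$sequence), cfg@ancestralMonomer)
    expect_identical(sort(unique(v$species)), sort(cfg@species$name))
})

test_that("full homogenization fixes one variant per species", {
    cfg <- simulationConfig(seed = 4, homogenization = 1,
                            substitutionRate = 1)
    v <- poolTable(evolveLibrary(cfg))
    perSpecies <- table(v$species)
    expect_true(all(perSpecies == 1L))
    expect_identical(unname(vapply(v$species, function(sp)
        poolConsensus(evolveLibrary(cfg))[[sp]], "")), v$sequence)
})

test_that("longer branches accumulate more divergence; the mutation draw
           replays exactly on an independent reimplementation", {
    cfg <- simulationConfig(
        seed = 5,
        species = data.frame(name = c("slow", "fast"),
                             branchLength = c(0.01, 0.1)),
        substitutionRate = 1, kappa = 2,
        amplification = data.frame(name = c("slow", "fast"),
                                   nArrays = 1L, minCopies = 20L,
                                   maxCopies = 20L))
    cons <- poolConsensus(evolveLibrary(cfg))
    hd <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    expect_gt(hd(cons[["fast"]], cfg@ancestralMonomer),
              hd(cons[["slow"]], cfg@ancestralMonomer))

    ## independent replay of the per-species RNG stream: same seed, same
    ## draw order, mutation logic rewritten from the model definition
    replayConsensus <- function(sp, bl) {
        set.seed(satcons:::.streamSeed(cfg@seed, paste0("evolve:", sp)))
        chars <- strsplit(cfg@ancestralMonomer, "")[[1]]
        hit <- which(stats::runif(52) < bl)
        if (length(hit)) {
            isTs <- stats::runif(length(hit)) < 2 / 4
            for (j in seq_along(hit)) {
                b <- chars[hit[j]]
                chars[hit[j]] <- if (isTs[j])
                    c(A = "G", G = "A", C = "T", T = "C")[[b]]
                else sample(list(A = c("C", "T"), G = c("C", "T"),
                                 C = c("A", "G"),
                                 T = c("A", "G"))[[b]], 1L)
            }
        }
        paste(chars, collapse = "")
    }
    expect_identical(cons[["slow"]], replayConsensus("slow", 0.01))
    expect_identical(cons[["fast"]], replayConsensus("fast", 0.1))
})

test_that("planted arrays account exactly for the true copy number", {
    cfg <- oneSpeciesConfig(seed = 6, nArrays = 3L, copies = 15L)
    pool <- evolveLibrary(cfg)
    g <- buildGenome(pool, "sp", cfg)
    tr <- g$truth
    expect_identical(length(truthArrays(tr)), 3L)
    expect_identical(sum(GenomicRanges::width(truthArrays(tr))),
                     52L * as.integer(trueCopyNumber(tr)))
    expect_identical(sum(truthVariantFreq(tr)$count),
                     as.integer(trueCopyNumber(tr)))
    ## a single array of 10 copies gives one 520-bp truth interval
    cfg1 <- oneSpeciesConfig(seed = 6, nArrays = 1L, copies = 10L)
    t1 <- buildGenome(evolveLibrary(cfg1), "sp", cfg1)$truth
    expect_identical(GenomicRanges::width(truthArrays(t1)), 520L)
    expect_equal(trueCopyNumber(t1), 10)
})

test_that("zero arrays give background only; oversized requests error", {
    cfg0 <- oneSpeciesConfig(seed = 7, nArrays = 0L, copies = 10L)
    pool <- new("VariantPool",
                variants = data.frame(species = "sp", sequence = CONS,
                                      count = 1L),
                provenance = "genomic")
    g <- buildGenome(pool, "sp", cfg0)
    expect_length(truthArrays(g$truth), 0)
    expect_identical(trueCopyNumber(g$truth), 0)
    expect_identical(nchar(as.character(g$genome[[1]])), 30000L)
    cfgBig <- oneSpeciesConfig(seed = 7, nArrays = 2L, copies = 400L,
                               bg = 30000L)
    expect_error(buildGenome(pool, "sp", cfgBig), "sizing")
})

test_that("clustered vs dispersed amplification plants a 12.5-fold
           copy-number contrast", {
    cfgC <- oneSpeciesConfig(seed = 8, nArrays = 5L, copies = 250L,
                             bg = 150000L)
    cfgD <- oneSpeciesConfig(seed = 8, nArrays = 5L, copies = 20L,
                             bg = 150000L)
    pool <- evolveLibrary(cfgC)
    cC <- trueCopyNumber(buildGenome(pool, "sp", cfgC)$truth)
    cD <- trueCopyNumber(buildGenome(pool, "sp", cfgD)$truth)
    expect_equal(c(cC, cD), c(1250, 100))
    expect_equal(cC / cD, 12.5)
})

test_that("background composition matches the configured A+T fraction", {
    cfg <- oneSpeciesConfig(seed = 9, nArrays = 0L, copies = 0L,
                            bg = 50000L)
    pool <- new("VariantPool",
                variants = data.frame(species = "sp", sequence = CONS,
                                      count = 1L),
                provenance = "genomic")
    g <- buildGenome(pool, "sp", cfg)
    at <- mean(strsplit(as.character(g$genome[[1]]), "")[[1]] %in%
               c("A", "T"))
    expect_lt(abs(at - 0.65), 0.02)
})

test_that("short reads have the right shape and are exact substrings when
           error-free", {
    cfg <- oneSpeciesConfig(seed = 10, nArrays = 1L, copies = 20L,
                            nPairs = 1000L)
    g <- buildGenome(evolveLibrary(cfg), "sp", cfg)
    sr <- simulateShortReads(g$genome, cfg)
    expect_length(sr$r1, 1000)
    expect_length(sr$r2, 1000)
    expect_true(all(Biostrings::width(sr$r1) == 101L))
    expect_true(all(Biostrings::width(sr$r2) == 101L))
    gs <- as.character(g$genome[[1]])
    rc <- revComp(gs)
    smp <- c(as.character(sr$r1)[1:40], as.character(sr$r2)[1:40])
    expect_true(all(vapply(smp, function(r)
        grepl(r, gs, fixed = TRUE) || grepl(r, rc, fixed = TRUE), TRUE)))
})

test_that("identical seeds give byte-identical FASTQ; streams are
           independent per output", {
    cfg <- oneSpeciesConfig(seed = 11, nArrays = 1L, copies = 20L,
                            nPairs = 200L)
    g <- buildGenome(evolveLibrary(cfg), "sp", cfg)
    f1 <- tempfile(fileext = ".fq"); f2 <- tempfile(fileext = ".fq")
    writeSeqs(simulateShortReads(g$genome, cfg)$r1, f1, "fastq")
    writeSeqs(simulateShortReads(g$genome, cfg)$r1, f2, "fastq")
    expect_identical(readLines(f1), readLines(f2))
    ## long reads from the same config do not perturb the short-read draw
    invisible(simulateLongReads(g$genome, g$truth, cfg))
    f3 <- tempfile(fileext = ".fq")
    writeSeqs(simulateShortReads(g$genome, cfg)$r1, f3, "fastq")
    expect_identical(readLines(f1), readLines(f3))
})

test_that("long reads carry the configured error rate and truth in read
           coordinates", {
    cfg <- oneSpeciesConfig(
        seed = 12, nArrays = 1L, copies = 150L, bg = 14000L,
        longRead = list(nReads = 6L, meanLog = log(10000), sdLog = 0.05,
                        errorRate = 0.15, indelFraction = 0.6))
    g <- buildGenome(evolveLibrary(cfg), "sp", cfg)
    lr <- simulateLongReads(g$genome, g$truth, cfg)
    gseq <- Biostrings::DNAString(as.character(g$genome[[1]]))
    for (i in seq_along(lr$reads)) {
        rd <- lr$reads[[i]]
        if (length(rd) < 5000) next
        aln <- Biostrings::pairwiseAlignment(rd, gseq,
                                             type = "global-local")
        alnB <- Biostrings::pairwiseAlignment(
            Biostrings::reverseComplement(rd), gseq,
            type = "global-local")
        if (Biostrings::score(alnB) > Biostrings::score(aln))
            aln <- alnB
        edits <- Biostrings::nmismatch(aln) +
            Biostrings::nindel(aln)@insertion[2] +
            Biostrings::nindel(aln)@deletion[2]
        err <- edits / Biostrings::nchar(aln)
        expect_gt(err, 0.12)
        expect_lt(err, 0.18)
    }
    ## truth intervals live on read ids within read bounds
    expect_true(all(as.character(GenomicRanges::seqnames(lr$truth)) %in%
                    names(lr$reads)))
    w <- Biostrings::width(lr$reads)[match(
        as.character(GenomicRanges::seqnames(lr$truth)),
        names(lr$reads))]
    expect_true(all(GenomicRanges::end(lr$truth) <= w))
})

test_that("error-free long reads are exact substrings and reads inside an
           array are annotated nearly end to end", {
    cfg <- oneSpeciesConfig(
        seed = 13, nArrays = 1L, copies = 230L, bg = 14000L,
        longRead = list(nReads = 8L, meanLog = log(3000), sdLog = 0.1,
                        errorRate = 0, indelFraction = 0.6))
    g <- buildGenome(evolveLibrary(cfg), "sp", cfg)
    lr <- simulateLongReads(g$genome, g$truth, cfg)
    gs <- as.character(g$genome[[1]]); rc <- revComp(gs)
    expect_true(all(vapply(as.character(lr$reads), function(r)
        grepl(r, gs, fixed = TRUE) || grepl(r, rc, fixed = TRUE), TRUE)))
    ## array is 230*52 = 11960 bp in a 14-kb genome: some 3-kb read lies
    ## fully inside it and its truth annotation covers >= 95% of the read
    cov <- tapply(GenomicRanges::width(lr$truth),
                  as.character(GenomicRanges::seqnames(lr$truth)), sum)
    frac <- cov / Biostrings::width(lr$reads)[match(
        names(cov), names(lr$reads))]
    expect_gte(max(frac), 0.95)
})

test_that("a written simulation emits all study files", {
    cfg <- simulationConfig(
        seed = 14,
        species = data.frame(name = c("a", "b"),
                             branchLength = c(0.02, 0.03)),
        amplification = data.frame(name = c("a", "b"), nArrays = 1L,
                                   minCopies = 10L, maxCopies = 15L),
        backgroundLength = 5000L,
        shortRead = list(nPairs = 50L),
        longRead = list(nReads = 2L, meanLog = log(2000), sdLog = 0.1))
    st <- simulateStudy(cfg)
    dir <- tempfile()
    writeSimulation(st, dir)
    for (sp in c("a", "b"))
        for (suf in c("_genome.fa", "_R1.fastq", "_R2.fastq",
                      "_longreads.fa", "_truth.bed"))
            expect_true(file.exists(file.path(dir, paste0(sp, suf))))
    expect_true(file.exists(file.path(dir, "true_pool.tsv")))
})
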