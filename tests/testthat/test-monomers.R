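test_that("canonical rotation is the lexicographic minimum and a class
           invariant", {
    expect_identical(canonicalRotation("GATC"), "ATCG")
    ## brute-force oracle over all rotations
    set.seed(20)
    for (i in 1:25) {
        x <- randomDna(sample(c(4, 7, 52), 1))
        rots <- vapply(seq_len(nchar(x)) - 1L, rotate, "", x = x)
        expect_identical(canonicalRotation(x), min(rots))
        k <- sample(nchar(x), 1)
        expect_identical(canonicalRotation(rotate(x, k)),
                         canonicalRotation(x))
        expect_identical(canonicalRotation(canonicalRotation(x)),
                         canonicalRotation(x))
    }
    expect_identical(canonicalRotation("AAAA"), "AAAA")
})

test_that("extraction emits complete in-phase monomers only", {
    ## 101-nt read starting in phase: 1.94 copies -> one complete monomer
    rd <- substring(strrep(CONS, 2), 1, 101)
    m <- extractMonomers(rd, CONS, canonicalize = FALSE)
    expect_length(m, 1)
    expect_identical(m, CONS)
    ## 156-nt read = 3 exact copies -> 3 identical monomers
    m3 <- extractMonomers(strrep(CONS, 3), CONS, canonicalize = FALSE)
    expect_length(m3, 3)
    expect_setequal(unique(m3), CONS)
    ## random sequence below the identity floor -> nothing
    set.seed(21)
    expect_length(extractMonomers(randomDna(300), CONS), 0)
    ## non-52 consensus is a configuration error
    expect_error(extractMonomers(rd, substring(CONS, 1, 40)),
                 "configuration")
})

test_that("extraction is phase- and strand-robust", {
    set.seed(22)
    ## reads starting at every offset within the monomer
    arr <- strrep(CONS, 5)
    for (off in c(0, 1, 13, 37, 51)) {
        rd <- substring(arr, off + 1, off + 160)
        m <- extractMonomers(rd, CONS)
        expect_true(length(m) %in% 2:3)
        expect_setequal(unique(m), canonicalRotation(CONS))
        mrc <- extractMonomers(revComp(rd), CONS)
        expect_identical(sort(m), sort(mrc))
    }
})

test_that("reverse-complementing every read leaves the tallied pool
           unchanged", {
    cfg <- oneSpeciesConfig(seed = 23, nArrays = 2L, copies = 60L,
                            bg = 15000L, nPairs = 1500L,
                            branchLength = 0.03, substitutionRate = 1)
    g <- buildGenome(evolveLibrary(cfg), "sp", cfg)
    reads <- as.character(simulateShortReads(g$genome, cfg)$r1)
    t1 <- table(extractMonomers(reads, CONS))
    t2 <- table(extractMonomers(revComp(reads), CONS))
    expect_identical(sort(names(t1)), sort(names(t2)))
    expect_identical(as.integer(t1[sort(names(t1))]),
                     as.integer(t2[sort(names(t1))]))
})

test_that("tallying drops singletons and conserves counts otherwise", {
    m <- c(rep("AAAA", 5), "CCCC")
    p <- tallyAndFilter(m, species = "x")
    expect_identical(poolTable(p)$sequence, "AAAA")
    expect_identical(poolTable(p)$count, 5L)
    p2 <- tallyAndFilter(c(rep("AAAA", 2), rep("CCCC", 2)), species = "x")
    expect_identical(sum(poolTable(p2)$count), 4L)
    p3 <- tallyAndFilter(m, species = "x", dropSingletons = FALSE)
    expect_identical(sum(poolTable(p3)$count), 6L)
})

test_that("consensus and composition summarize the pool columnwise", {
    atOnly <- paste(rep(c("A", "T"), 26), collapse = "")
    p <- tallyAndFilter(rep(atOnly, 3), species = "x")
    cc <- consensusComposition(p)
    expect_identical(cc$atFraction, 1)
    expect_identical(cc$consensus, atOnly)
    ## majority base wins a 3:1 split; column sums conserve total count
    v1 <- CONS
    v2 <- paste0(substring(CONS, 1, 31),
                 setdiff(c("A", "C", "G", "T"),
                         substring(CONS, 32, 32))[1],
                 substring(CONS, 33, 52))
    p2 <- new("VariantPool",
              variants = data.frame(species = "x",
                                    sequence = c(v1, v2),
                                    count = c(3L, 1L)),
              provenance = "genomic")
    cc2 <- consensusComposition(p2)
    expect_identical(cc2$consensus, v1)
    expect_true(all(colSums(cc2$matrix) == 4))
})

test_that("read subsampling scales linearly with genome size", {
    expect_identical(subsampleByGenomeSize(1e6, 1.38e9, 1.38e9), 1e6)
    expect_identical(subsampleByGenomeSize(1e6, 1.38e9, 2.76e9), 2e6)
    expect_identical(subsampleByGenomeSize(1e6, 1.38e9, 0.69e9), 5e5)
    expect_error(subsampleByGenomeSize(1e6, 0, 1e9), "validation")
})

test_that("extracted variant frequencies track the planted truth", {
    cfg <- oneSpeciesConfig(seed = 24, nArrays = 2L, copies = 110L,
                            bg = 25000L, nPairs = 4000L,
                            branchLength = 0.02, substitutionRate = 1)
    g <- buildGenome(evolveLibrary(cfg), "sp", cfg)
    sr <- simulateShortReads(g$genome, cfg)
    mono <- extractMonomers(c(as.character(sr$r1), as.character(sr$r2)),
                            CONS)
    est <- poolTable(tallyAndFilter(mono, species = "sp"))
    tv <- truthVariantFreq(g$truth)
    tf <- tapply(tv$count, canonicalRotation(tv$sequence), sum)
    tf <- tf / sum(tf)
    ef <- stats::setNames(est$count / sum(est$count), est$sequence)
    keys <- union(names(tf), names(ef))
    diff <- abs(ifelse(is.na(tf[keys]), 0, tf[keys]) -
                ifelse(is.na(ef[keys]), 0, ef[keys]))
    expect_lt(max(diff), 0.05)
})

test_that("pool filtering removes variants far from the species
           consensus", {
    junk <- randomDna(52, at = 0.5)
    p <- new("VariantPool",
             variants = data.frame(species = "x",
                                   sequence = c(rep(CONS, 1), junk),
                                   count = c(50L, 3L)),
             provenance = "genomic")
    f <- filterPool(p)
    expect_identical(poolTable(f)$sequence, CONS)
})

test_that("shared variants report exact cross-species intersections", {
    mk <- function(sp, seqs, counts)
        data.frame(species = sp, sequence = seqs, count = counts)
    shared <- canonicalRotation(CONS)
    other <- canonicalRotation(randomDna(52))
    v <- rbind(mk("s1", c(shared, other), c(5L, 2L)),
               mk("s2", shared, 3L),
               mk("s3", shared, 1L),
               mk("s4", other, 4L),
               mk("s5", shared, 9L))
    p <- new("VariantPool", variants = v, provenance = "genomic")
    rep2 <- sharedVariants(p)
    expect_identical(rep2$nSpecies[rep2$sequence == shared], 4L)
    expect_identical(rep2$nSpecies[rep2$sequence == other], 2L)
    rep3 <- sharedVariants(p, minSpecies = 3)
    expect_false(other %in% rep3$sequence)
    empty <- sharedVariants(new("VariantPool",
                                variants = mk("s1", shared, 2L),
                                provenance = "genomic"))
    expect_identical(nrow(empty), 0L)
})
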