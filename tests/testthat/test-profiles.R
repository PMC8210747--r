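test_that("the concatemer reference repeats the consensus", {
    ref <- buildConcatemer(CONS, 4)
    expect_identical(nchar(ref), 208L)
    expect_identical(substring(ref, 1, 52), substring(ref, 53, 104))
    expect_identical(nchar(buildConcatemer(CONS, 2)), 104L)
    expect_error(buildConcatemer(CONS, 1), "configuration")
    expect_error(buildConcatemer(substring(CONS, 1, 50)), "configuration")
})

test_that("exact gene tiles produce the expected depths and leave the
           satellite untouched", {
    set.seed(30)
    gene <- randomDna(1000)
    tiles <- vapply(seq(1, 901, by = 100), function(s)
        substring(gene, s, s + 99), "")
    reads <- rep(tiles, 10)
    names(reads) <- sprintf("t%03d", seq_along(reads))
    ref <- buildConcatemer(CONS, 4)
    mp <- mapReads(reads, c(sat = unclass(ref), gene01 = gene),
                   monomerLength = c(sat = 52L))
    expect_equal(mean(depthProfile(mp$profiles$gene01)), 10)
    expect_equal(sum(depthProfile(mp$profiles$sat)), 0)
    expect_equal(coveredFraction(mp$profiles$gene01), 1)
    expect_equal(coveredFraction(mp$profiles$sat), 0)
})

test_that("a single read increments depth over its aligned span only", {
    ref <- buildConcatemer(CONS, 4)
    rd <- substring(ref, 11, 111)
    mp <- mapReads(c(x = rd), c(sat = unclass(ref)))
    d <- depthProfile(mp$profiles$sat)
    expect_equal(sum(d), 101)
    expect_true(all(d[11:111] == 1))
    expect_true(all(d[-(11:111)] == 0))
    a <- mp$assignments
    expect_identical(a$refStart, 11L)
    expect_identical(a$refEnd, 111L)
})

test_that("identity thresholds gate assignment the way the arithmetic
           says", {
    set.seed(31)
    gene <- randomDna(1000)
    rd <- substring(gene, 101, 201)
    ## plant 6 interior substitutions -> identity 95/101 = 0.9406
    chars <- strsplit(rd, "")[[1]]
    pos <- c(15, 30, 45, 60, 75, 90)
    chars[pos] <- vapply(chars[pos], function(b)
        setdiff(c("A", "C", "G", "T"), b)[1], "")
    rd6 <- paste(chars, collapse = "")
    hit <- mapReads(c(x = rd6), c(g = gene), minIdentity = 0.9)
    expect_identical(hit$assignments$reference, "g")
    miss <- mapReads(c(x = rd6), c(g = gene), minIdentity = 0.95)
    expect_true(is.na(miss$assignments$reference))
    expect_error(mapReads(c(x = rd6), c(g = gene, g = gene)),
                 "duplicate")
})

test_that("copy number normalizes satellite depth by the median gene
           depth", {
    expect_equal(copyNumber(500, rep(5, 10)), 100)
    expect_equal(copyNumber(0, rep(5, 10)), 0)
    expect_equal(copyNumber(50, c(4, 5, 6, 5, 5, 5, 5, 5, 5, 100)), 10)
    expect_error(copyNumber(10, rep(0, 10)), "normalization")
})

test_that("variant fractions separate covered, variant and missing
           positions", {
    ref <- buildConcatemer(CONS, 4)
    ## full-length reads, half carrying a substitution at the four images
    ## of monomer position 32
    img <- 32 + 52 * 0:3
    chars <- strsplit(unclass(ref), "")[[1]]
    chars[img] <- vapply(chars[img], function(b)
        setdiff(c("A", "C", "G", "T"), b)[1], "")
    mut <- paste(chars, collapse = "")
    reads <- c(clean1 = unclass(ref), clean2 = unclass(ref),
               mut1 = mut, mut2 = mut)
    mp <- mapReads(reads, c(sat = unclass(ref)),
                   monomerLength = c(sat = 52L))
    vf <- variantFraction(mp$profiles$sat)
    expect_true(all(vf[img] == 0.5))
    expect_true(all(vf[-img] == 0, na.rm = TRUE))
    ## an uncovered reference yields missing, never zero
    gene <- randomDna(500)
    mp2 <- mapReads(reads, c(sat = unclass(ref), g = gene))
    expect_true(all(is.na(variantFraction(mp2$profiles$g))))
})

test_that("profile correlation behaves like Pearson r on scaled depth", {
    a <- c(1, 2, 3, 4)
    expect_equal(profileCorrelation(a, a), 1)
    expect_equal(profileCorrelation(a, 2 * a), 1)
    expect_equal(profileCorrelation(a, max(a) + min(a) - a), -1)
    expect_error(profileCorrelation(a, rep(1, 4)), "constant")
    expect_error(profileCorrelation(a, c(1, 2)), "length")
})

test_that("valleys are maximal low-depth runs in folded monomer
           coordinates", {
    uniform <- rep(100, 208)
    expect_identical(nrow(findValleys(uniform, monomerLength = 52L)), 0L)
    dip <- rep(100, 208)
    dip[c(22:24, 74:76, 126:128, 178:180)] <- 50
    v <- findValleys(dip, monomerLength = 52L)
    expect_identical(v$start, 22L)
    expect_identical(v$end, 24L)
    ## folding is invariant to the number of concatemer images
    dip2 <- rep(100, 104)
    dip2[c(22:24, 74:76)] <- 50
    v2 <- findValleys(dip2, monomerLength = 52L)
    expect_identical(v2[, 1:2], v[, 1:2])
    ## a single-position dip is below the run-length floor
    single <- rep(100, 208)
    single[c(22, 74, 126, 178)] <- 10
    expect_identical(nrow(findValleys(single, monomerLength = 52L)), 0L)
})

test_that("copy number recovers a planted value from error-free reads", {
    cfg <- oneSpeciesConfig(seed = 32, nArrays = 2L, copies = 50L,
                            bg = 25000L, nPairs = 12000L)
    g <- buildGenome(evolveLibrary(cfg), "sp", cfg)
    pg <- plantGenes(g$genome, g$truth, seed = 32)
    sr <- simulateShortReads(pg$genome, cfg)
    reads <- c(as.character(sr$r1), as.character(sr$r2))
    ref <- buildConcatemer(CONS, 4)
    mp <- mapReads(reads, c(sat = unclass(ref), pg$genes),
                   monomerLength = c(sat = 52L))
    est <- copyNumber(mp$profiles$sat, mp$profiles[names(pg$genes)])
    expect_lt(abs(est - 100) / 100, 0.1)
})

test_that("scaled profiles of two species sharing a monomer correlate
           strongly at depth", {
    mkProfile <- function(seed) {
        cfg <- oneSpeciesConfig(seed = seed, nArrays = 2L, copies = 60L,
                                bg = 20000L, nPairs = 3000L)
        g <- buildGenome(evolveLibrary(cfg), "sp", cfg)
        sr <- simulateShortReads(g$genome, cfg)
        reads <- c(as.character(sr$r1), as.character(sr$r2))
        ref <- buildConcatemer(CONS, 4)
        mapReads(reads, c(sat = unclass(ref)),
                 monomerLength = c(sat = 52L))$profiles$sat
    }
    pa <- mkProfile(33)
    pb <- mkProfile(34)
    expect_gte(profileCorrelation(pa, pb), 0.95)
})
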