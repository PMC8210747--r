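test_that("a clean head-to-tail array is one zero-noise interval", {
    hits <- detectArrays(c(a = strrep(CONS, 10)), CONS)
    expect_length(hits, 1)
    expect_identical(GenomicRanges::start(hits), 1L)
    expect_identical(GenomicRanges::end(hits), 520L)
    expect_identical(hits$noise, 0)
    expect_identical(hits$monomerEquivalents, 10)
    expect_error(detectArrays(c(a = ""), CONS), "empty")
})

test_that("arrays separated by foreign sequence stay separate", {
    set.seed(60)
    insert <- randomDna(500)
    rd <- paste0(strrep(CONS, 5), insert, strrep(CONS, 5))
    hits <- detectArrays(c(a = rd), CONS)
    expect_length(hits, 2)
    s <- GenomicRanges::start(hits); e <- GenomicRanges::end(hits)
    expect_lt(e[1], 261 + 20)
    expect_gt(s[2], 760 - 20)
    ## neither interval reaches into the insert interior
    expect_true(all(e[1] < 400, s[2] > 400))
})

test_that("noise above the ceiling suppresses detection", {
    ## deterministic 25% corruption: every 4th base substituted, so every
    ## window of the array carries ~25% mismatches
    chars <- strsplit(strrep(CONS, 10), "")[[1]]
    pos <- seq(1, length(chars), by = 4)
    chars[pos] <- vapply(chars[pos], function(b)
        setdiff(c("A", "C", "G", "T"), b)[1], "")
    noisy <- paste(chars, collapse = "")
    expect_length(detectArrays(c(a = noisy), CONS, maxNoise = 0.20), 0)
    ## the same read is recovered once the ceiling admits it
    expect_gt(length(detectArrays(c(a = noisy), CONS, maxNoise = 0.35)), 0)
})

test_that("detection is strand-symmetric with mirrored coordinates", {
    set.seed(61)
    rd <- paste0(randomDna(300), strrep(CONS, 8), randomDna(200))
    fw <- detectArrays(c(a = rd), CONS)
    rv <- detectArrays(c(a = revComp(rd)), CONS)
    expect_length(fw, 1)
    expect_length(rv, 1)
    n <- nchar(rd)
    expect_identical(GenomicRanges::start(rv),
                     n - GenomicRanges::end(fw) + 1L)
    expect_identical(GenomicRanges::end(rv),
                     n - GenomicRanges::start(fw) + 1L)
    expect_false(as.character(GenomicRanges::strand(fw)) ==
                 as.character(GenomicRanges::strand(rv)))
})

test_that("planted arrays in 15%-error reads are recovered within 5% of
           their length", {
    cfg <- simulationConfig(
        seed = 62,
        species = data.frame(name = "sp", branchLength = 0),
        amplification = data.frame(name = "sp", nArrays = 4L,
                                   minCopies = 10L, maxCopies = 77L),
        backgroundLength = 40000L,
        longRead = list(nReads = 20L, meanLog = log(9000), sdLog = 0.3,
                        errorRate = 0.15, indelFraction = 0.6))
    g <- buildGenome(evolveLibrary(cfg), "sp", cfg)
    lr <- simulateLongReads(g$genome, g$truth, cfg)
    hits <- detectArrays(lr$reads, cfg@ancestralMonomer)
    ## whole in-read arrays only: read-boundary fragments have no planted
    ## length of their own
    readLen <- stats::setNames(Biostrings::width(lr$reads),
                               names(lr$reads))
    rid <- as.character(GenomicRanges::seqnames(lr$truth))
    whole <- lr$truth[GenomicRanges::width(lr$truth) >= 500 &
                      GenomicRanges::start(lr$truth) > 1 &
                      GenomicRanges::end(lr$truth) < readLen[rid]]
    found <- 0L
    for (i in seq_along(whole)) {
        ri <- as.character(GenomicRanges::seqnames(whole)[i])
        h <- hits[as.character(GenomicRanges::seqnames(hits)) == ri]
        ov <- h[GenomicRanges::start(h) < GenomicRanges::end(whole)[i] &
                GenomicRanges::end(h) > GenomicRanges::start(whole)[i]]
        if (!length(ov)) next
        ov <- ov[which.max(GenomicRanges::width(ov))]
        w <- GenomicRanges::width(whole)[i]
        expect_lt(abs(GenomicRanges::start(ov) -
                      GenomicRanges::start(whole)[i]) / w, 0.05)
        expect_lt(abs(GenomicRanges::end(ov) -
                      GenomicRanges::end(whole)[i]) / w, 0.05)
        found <- found + 1L
    }
    expect_gte(found / length(whole), 0.9)
    expect_true(all(hits$noise <= 0.20))
})

test_that("repeat density merges overlaps and tracks annotation mass", {
    gr <- GenomicRanges::GRanges("r1", IRanges::IRanges(1, 2000))
    expect_equal(repeatDensity(gr, 1e6)$density, 2)
    expect_equal(repeatDensity(GenomicRanges::GRanges(), 1e6)$density, 0)
    over <- GenomicRanges::GRanges(
        "r1", IRanges::IRanges(c(1, 1001), c(1500, 2000)))
    expect_equal(repeatDensity(over, 1e6)$density, 2)
    ## adding an array-free read strictly decreases density
    d1 <- repeatDensity(gr, 1e6)$density
    d2 <- repeatDensity(gr, 1e6 + 5e4)$density
    expect_lt(d2, d1)
    expect_error(repeatDensity(gr, 0), "validation")
})

test_that("flanker extraction clips at read edges", {
    set.seed(63)
    rd <- randomDna(30000)
    fl <- extractFlankers(rd, 12000L, 13000L)
    expect_identical(nchar(fl$upstream), 10000L)
    expect_identical(nchar(fl$downstream), 10000L)
    expect_identical(fl$upstream, substring(rd, 2001, 12000))
    expect_identical(fl$downstream, substring(rd, 13001, 23000))
    edge <- extractFlankers(substring(rd, 1, 15000), 0L, 500L)
    expect_identical(nchar(edge$upstream), 0L)
    expect_identical(nchar(edge$downstream), 10000L)
    short <- extractFlankers(substring(rd, 1, 6000), 2500L, 3000L)
    expect_identical(nchar(short$upstream), 2500L)
    expect_identical(nchar(short$downstream), 3000L)
    expect_error(extractFlankers("ACGT", 2L, 10L), "validation")
})

test_that("greedy clustering respects size and identity thresholds", {
    set.seed(64)
    base <- randomDna(1000)
    other <- randomDna(1000)
    cl <- clusterFlankers(c(a = base, b = base, c = base, d = other))
    expect_identical(nrow(cl), 1L)
    expect_identical(cl$size, 3L)
    expect_identical(nrow(clusterFlankers(c(a = base, b = base))), 0L)
    ## ~10% mutual divergence still clusters at the 0.8 threshold
    mut <- function(x, rate) {
        chars <- strsplit(x, "")[[1]]
        pos <- which(runif(length(chars)) < rate)
        chars[pos] <- vapply(chars[pos], function(b)
            sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
        paste(chars, collapse = "")
    }
    fam <- c(f1 = base, f2 = mut(base, 0.1), f3 = mut(base, 0.1),
             f4 = mut(base, 0.1))
    cl4 <- clusterFlankers(fam)
    expect_identical(cl4$size, 4L)
})
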