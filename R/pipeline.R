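#' Plant single-copy gene references into a simulated genome
#'
#' Generates `nGenes` random gene-like sequences and inserts each exactly
#' once into the genome background, avoiding the planted satellite arrays;
#' the genes double as the single-copy normalization panel for
#' [copyNumber()].
#'
#' @param genome named [Biostrings::DNAStringSet] of length 1.
#' @param truth the genome's [SimTruth-class] (arrays to avoid), or `NULL`.
#' @param nGenes number of genes (default 10).
#' @param geneLength gene length in bp (default 1000).
#' @param seed RNG seed for gene content and placement.
#' @return list with elements `genome` (updated) and `genes` (named
#'   character vector of the planted sequences).
#' @export
plantGenes <- function(genome, truth = NULL, nGenes = 10L,
                       geneLength = 1000L, seed = 1L) {
    gname <- names(genome)[1L]
    gseq <- as.character(genome[[1L]])
    glen <- nchar(gseq)
    set.seed(.streamSeed(seed, paste0("genes:", gname)))
    avoid <- if (!is.null(truth) && length(truth@arrays))
        cbind(GenomicRanges::start(truth@arrays),
              GenomicRanges::end(truth@arrays))
    else matrix(integer(), ncol = 2L)
    genes <- character(nGenes)
    names(genes) <- sprintf("gene%02d", seq_len(nGenes))
    gchars <- strsplit(gseq, "")[[1]]
    for (g in seq_len(nGenes)) {
        genes[g] <- paste(sample(.BASES, geneLength, replace = TRUE),
                          collapse = "")
        ok <- FALSE
        for (try in seq_len(1000L)) {
            s <- sample.int(glen - geneLength + 1L, 1L)
            e <- s + geneLength - 1L
            if (nrow(avoid) == 0L ||
                all(e < avoid[, 1L] | s > avoid[, 2L])) {
                ok <- TRUE
                break
            }
        }
        if (!ok)
            stop("sizing error: could not place gene ", g)
        avoid <- rbind(avoid, c(s, e))
        gchars[s:e] <- strsplit(genes[g], "")[[1]]
    }
    gset <- Biostrings::DNAStringSet(paste(gchars, collapse = ""))
    names(gset) <- gname
    list(genome = gset, genes = genes)
}

#' Simulate single-end RNA-seq reads from target transcripts
#'
#' Each read picks a target with probability proportional to `weights`
#' (per-transcript sampling rate), then a uniform position and strand.
#'
#' @param targets named character vector of transcript sequences (each
#'   longer than `readLength`).
#' @param weights sampling weights, same order as `targets`.
#' @param nReads number of reads.
#' @param readLength read length (default 101).
#' @param seed RNG seed.
#' @return named [Biostrings::DNAStringSet].
#' @export
simulateRnaReads <- function(targets, weights, nReads,
                             readLength = 101L, seed = 1L) {
    stopifnot(length(targets) == length(weights), all(weights >= 0))
    if (any(nchar(targets) < readLength))
        stop("sizing error: targets must exceed the read length")
    set.seed(.streamSeed(seed, "rna"))
    pick <- sample.int(length(targets), nReads, replace = TRUE,
                       prob = weights / sum(weights))
    reads <- character(nReads)
    for (i in seq_len(nReads)) {
        t <- targets[[pick[i]]]
        s <- sample.int(nchar(t) - readLength + 1L, 1L)
        rd <- substring(t, s, s + readLength - 1L)
        if (stats::runif(1) < 0.5)
            rd <- revComp(rd)
        reads[i] <- rd
    }
    out <- Biostrings::DNAStringSet(reads)
    names(out) <- sprintf("rna%06d", seq_len(nReads))
    out
}

#' Run the full satellite-conservation pipeline on a simulated study
#'
#' Simulates the configured species set (genomes with planted arrays and a
#' single-copy gene panel, short reads, long reads), then runs every
#' analysis stage and writes the standard reports to `outdir`:
#'
#' * `pool.tsv` — extracted monomer variants per species (species,
#'   sequence, count)
#' * `<sp>_profile.tsv` — satellite coverage profile (position, depth,
#'   A/C/G/T counts, non-reference fraction)
#' * `copy_number.tsv` — estimated vs true copies per species
#' * `<sp>_landscape.tsv` — divergence landscape
#' * `species_summary.tsv` — per-species n, A+T, abundance, intraKD (%)
#'   plus the interspecific KD
#' * `mst_edges.tsv` / `mst_nodes.tsv` — variant minimum spanning tree
#' * `shared_variants.tsv`
#' * `arrays.bed` — detected long-read arrays (score = 1000 * (1 - noise)),
#'   `density.tsv` — kb/Mb per species
#' * `flanker_clusters.tsv`
#' * `fpkm.tsv` — RNA quantification of two simulated libraries
#' * `qpcr_rq.tsv` — relative quantification of the packaged synthetic Ct
#'   table
#'
#' @param config a [SatSimConfig-class]; the default reproduces the
#'   package's reference study conditions.
#' @param outdir output directory.
#' @param flankerWindow flanker window for clustering (default 1500 bp at
#'   desk scale; the field-standard window is 10 kb).
#' @param maxFlankers cap on the number of flankers clustered.
#' @param minMapIdentity mapping identity threshold for profiling (default
#'   0.80: permissive enough that species several percent diverged from the
#'   family consensus still map, as with sensitive short-read mappers).
#' @return invisible list with the main in-memory results.
#' @export
runPipeline <- function(config = simulationConfig(), outdir,
                        flankerWindow = 1500L, maxFlankers = 30L,
                        minMapIdentity = 0.80) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    consensus <- config@ancestralMonomer
    satRef <- buildConcatemer(consensus, 4L)
    pool0 <- evolveLibrary(config)
    monomers <- list(); profiles <- list(); cn <- list()
    landscapes <- list(); arrays <- list(); density <- list()
    flankers <- character()
    for (sp in config@species$name) {
        g <- buildGenome(pool0, sp, config)
        pg <- plantGenes(g$genome, g$truth, nGenes = 10L,
                         geneLength = 1000L, seed = config@seed)
        sr <- simulateShortReads(pg$genome, config)
        reads <- c(as.character(sr$r1), as.character(sr$r2))
        ## monomers stay in the family-consensus frame (extraction anchors
        ## every window to it): one common frame across species keeps
        ## columnwise distances meaningful, where independent per-variant
        ## canonicalization would compare flipped rotations
        monomers[[sp]] <- extractMonomers(reads, consensus,
                                          minWindowIdentity = 0.7,
                                          canonicalize = FALSE)
        refs <- c(sat = unclass(satRef), pg$genes)
        mp <- mapReads(reads, refs, minIdentity = minMapIdentity,
                       monomerLength = c(sat = 52L))
        profiles[[sp]] <- mp$profiles$sat
        cn[[sp]] <- data.frame(
            species = sp,
            estimatedCopies = copyNumber(mp$profiles$sat,
                                         mp$profiles[names(pg$genes)]),
            trueCopies = trueCopyNumber(g$truth))
        prof <- mp$profiles$sat
        writeReport(data.frame(
            position = seq_along(depthProfile(prof)),
            depth = depthProfile(prof),
            t(baseCounts(prof)),
            nonrefFraction = variantFraction(prof)),
            file.path(outdir, paste0(sp, "_profile.tsv")))
        lr <- simulateLongReads(pg$genome, g$truth, config)
        ## detect with the species' own extracted consensus: long-read
        ## noise plus family-consensus divergence would otherwise push
        ## diverged species past the noise ceiling
        spPool <- filterPool(tallyAndFilter(monomers[[sp]], species = sp))
        spCons <- if (nrow(spPool@variants))
            consensusComposition(spPool)$consensus else consensus
        hits <- detectArrays(lr$reads, spCons)
        arrays[[sp]] <- hits
        density[[sp]] <- data.frame(
            species = sp,
            density = repeatDensity(
                hits, sum(nchar(as.character(lr$reads))))$density)
        if (length(hits))
            flankers <- c(flankers,
                          arrayFlankers(lr$reads, hits, flankerWindow))
    }
    pool <- filterPool(tallyAndFilter(monomers))
    writeReport(poolTable(pool), file.path(outdir, "pool.tsv"))
    writeReport(do.call(rbind, cn), file.path(outdir, "copy_number.tsv"))
    summ <- list()
    for (sp in unique(pool@variants$species)) {
        land <- repeatLandscape(
            pool@variants[pool@variants$species == sp, ], consensus)
        writeReport(land, file.path(outdir, paste0(sp, "_landscape.tsv")))
        landscapes[[sp]] <- land
    }
    ds <- divergenceSummary(pool)
    perSp <- ds$intra
    comp <- vapply(perSp$species, function(sp)
        consensusComposition(pool, sp)$atFraction * 100, 0)
    glen <- config@backgroundLength
    trueAb <- vapply(perSp$species, function(sp)
        52 * cn[[sp]]$trueCopies / glen, 0)
    summary <- data.frame(species = perSp$species, n = perSp$n,
                          atPercent = comp, abundance = trueAb,
                          intraKD = perSp$intraKD,
                          interKD = ds$inter)
    writeReport(summary, file.path(outdir, "species_summary.tsv"))
    tree <- poolMST(pool)
    writeReport(treeEdges(tree), file.path(outdir, "mst_edges.tsv"))
    writeReport(treeNodes(tree), file.path(outdir, "mst_nodes.tsv"))
    writeReport(sharedVariants(pool),
                file.path(outdir, "shared_variants.tsv"))
    allArr <- suppressWarnings(
        do.call(c, unname(arrays[lengths(arrays) > 0])))
    if (length(allArr)) {
        allArr$name <- rep("sat_array", length(allArr))
        allArr$score <- round(1000 * (1 - allArr$noise))
        writeBed(allArr, file.path(outdir, "arrays.bed"))
    } else {
        writeBed(GenomicRanges::GRanges(),
                 file.path(outdir, "arrays.bed"))
    }
    writeReport(do.call(rbind, density), file.path(outdir, "density.tsv"))
    if (length(flankers) > maxFlankers)
        flankers <- flankers[seq_len(maxFlankers)]
    clusters <- if (length(flankers))
        clusterFlankers(flankers)
    else data.frame(cluster = integer(), representative = character(),
                    size = integer(), members = character())
    writeReport(clusters, file.path(outdir, "flanker_clusters.tsv"))
    ## transcription: two libraries, satellite sampled at different rates
    exTargets <- c(sat = unclass(satRef),
                   rpl13a = paste(sample(.BASES, 1000, TRUE),
                                  collapse = ""),
                   rpl32 = paste(sample(.BASES, 1000, TRUE),
                                 collapse = ""),
                   hprt = paste(sample(.BASES, 1000, TRUE),
                                collapse = ""))
    fx <- list()
    for (lib in c("muscle", "ovary")) {
        ## sampling rates keep the satellite a minor library component so
        ## the planted ~15-fold muscle/ovary contrast survives the
        ## within-library FPKM normalization
        w <- c(sat = if (lib == "muscle") 0.2 else 0.0122,
               rpl13a = 1, rpl32 = 1, hprt = 1)
        rna <- simulateRnaReads(exTargets, w, 20000L,
                                seed = config@seed + match(
                                    lib, c("muscle", "ovary")))
        q <- quantifyExpression(rna, references = exTargets,
                                monomerLength = c(sat = 52L))
        q$library <- lib
        fx[[lib]] <- q
    }
    writeReport(do.call(rbind, fx), file.path(outdir, "fpkm.tsv"))
    ctPath <- system.file("extdata", "qpcr_ct_synthetic.tsv",
                          package = "satcons")
    rq <- qpcrRelative(readReport(ctPath), target = "sat",
                       reference = "hprt1", calibrator = "ovary1")
    writeReport(rq, file.path(outdir, "qpcr_rq.tsv"))
    invisible(list(pool = pool, copyNumber = do.call(rbind, cn),
                   summary = summary, tree = tree, arrays = allArr,
                   density = do.call(rbind, density),
                   landscapes = landscapes,
                   expression = do.call(rbind, fx), qpcr = rq))
}
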