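#' Fragments per kilobase per million mapped fragments
#'
#' @param count mapped fragment count for the target.
#' @param lengthBp target length in bp.
#' @param totalFragments total mapped fragments in the library.
#' @return FPKM value.
#' @examples
#' fpkm(10, 208, 1e6)  # 48.0769...
#' @export
fpkm <- function(count, lengthBp, totalFragments) {
    if (any(lengthBp <= 0) || any(totalFragments <= 0))
        stop("validation error: length and total must be positive")
    count / (lengthBp / 1000) / (totalFragments / 1e6)
}

#' Fold difference between two expression groups
#'
#' @param groupA,groupB numeric FPKM vectors.
#' @return `mean(groupA) / mean(groupB)`.
#' @export
foldDifference <- function(groupA, groupB) {
    if (mean(groupB) <= 0)
        stop("validation error: denominator group mean must be positive")
    mean(groupA) / mean(groupB)
}

#' Welch's two-sample t test
#'
#' Unequal-variance t statistic with Welch–Satterthwaite degrees of
#' freedom and a two-sided p value (delegates to [stats::t.test()]).
#'
#' @param xs,ys numeric vectors, at least two values each.
#' @return list with elements `t`, `df`, `p`.
#' @export
welchT <- function(xs, ys) {
    if (length(xs) < 2L || length(ys) < 2L)
        stop("need at least two values per group")
    if (stats::var(xs) == 0 && stats::var(ys) == 0)
        stop("degenerate: both group variances are zero")
    ht <- stats::t.test(xs, ys, var.equal = FALSE)
    list(t = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value)
}

#' qPCR relative quantification (delta-Ct / delta-delta-Ct)
#'
#' Replicate Ct values are averaged arithmetically per (sample, target);
#' `dCt = Ct_target - Ct_reference`, `RQ = 2^-dCt`; given a calibrator
#' sample, `ddCt = dCt_sample - dCt_calibrator` and `fold = 2^-ddCt`.
#'
#' @param ct data.frame with columns `sample`, `target`, `replicate`, `Ct`.
#' @param target name of the target assay (default `"sat"`).
#' @param reference name of the reference gene assay (e.g. `hprt1`).
#' @param calibrator optional calibrator sample name for the delta-delta-Ct
#'   scale.
#' @return data.frame with one row per sample: `sample`, `ctTarget`,
#'   `ctReference`, `dCt`, `RQ`, and (with a calibrator) `ddCt`, `fold`.
#' @export
qpcrRelative <- function(ct, target = "sat", reference = "hprt1",
                         calibrator = NULL) {
    need <- c("sample", "target", "replicate", "Ct")
    if (!all(need %in% names(ct)))
        stop("Ct table needs columns ", paste(need, collapse = ", "))
    means <- stats::aggregate(Ct ~ sample + target, data = ct, FUN = mean)
    samples <- unique(ct$sample)
    out <- do.call(rbind, lapply(samples, function(s) {
        tCt <- means$Ct[means$sample == s & means$target == target]
        rCt <- means$Ct[means$sample == s & means$target == reference]
        if (!length(tCt))
            stop("validation error: sample ", s, " lacks target Ct")
        if (!length(rCt))
            stop("validation error: sample ", s, " lacks reference Ct")
        dCt <- tCt - rCt
        data.frame(sample = s, ctTarget = tCt, ctReference = rCt,
                   dCt = dCt, RQ = 2^(-dCt))
    }))
    if (!is.null(calibrator)) {
        if (!calibrator %in% out$sample)
            stop("validation error: calibrator sample not in table")
        cal <- out$dCt[out$sample == calibrator]
        out$ddCt <- out$dCt - cal
        out$fold <- 2^(-out$ddCt)
    }
    rownames(out) <- NULL
    out
}

#' Quantify expression by mapping RNA-seq reads to target references
#'
#' Reads are mapped with [mapReads()] (best-hit assignment across the
#' satellite concatemer and endogenous gene references); fragments are read
#' pairs when two mate sets are supplied, reads otherwise. FPKM uses the
#' total of mapped fragments across the supplied targets.
#'
#' @param r1 reads ([Biostrings::DNAStringSet] or character).
#' @param r2 optional mate reads; when given, a fragment counts once if
#'   either mate maps (pair assignment by the better-scoring mate).
#' @param references named character vector of target references.
#' @param ... passed to [mapReads()].
#' @return data.frame with columns `target`, `length`, `count`, `fpkm`.
#' @export
quantifyExpression <- function(r1, r2 = NULL, references, ...) {
    m1 <- mapReads(r1, references, ...)
    asg <- m1$assignments$reference
    if (!is.null(r2)) {
        m2 <- mapReads(r2, references, ...)
        better <- !is.na(m2$assignments$matches) &
            (is.na(m1$assignments$matches) |
             m2$assignments$matches > m1$assignments$matches)
        asg[better] <- m2$assignments$reference[better]
    }
    counts <- table(factor(asg, levels = names(references)))
    total <- sum(counts)
    if (total == 0)
        stop("no fragments mapped to any target")
    data.frame(target = names(references),
               length = nchar(unname(references)),
               count = as.integer(counts),
               fpkm = fpkm(as.integer(counts),
                           nchar(unname(references)), total))
}
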