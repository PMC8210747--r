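#' Read sequences from FASTA or FASTQ
#'
#' Thin validating wrapper around Biostrings readers. Sequences are folded
#' to uppercase; FASTQ qualities are decoded (offset 33) but downstream
#' algorithms operate on base calls only.
#'
#' @param path file path.
#' @param format `"fasta"` or `"fastq"`.
#' @param withQualities if `TRUE` and `format = "fastq"`, return a list with
#'   elements `seqs` ([Biostrings::DNAStringSet]) and `qualities` (list of
#'   integer vectors); otherwise just the `DNAStringSet`.
#' @return a [Biostrings::DNAStringSet] (named by record id), or a list as
#'   described above.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "ACGT"), tf)
#' readSeqs(tf)
#' @export
readSeqs <- function(path, format = c("fasta", "fastq"),
                     withQualities = FALSE) {
    format <- match.arg(format)
    if (!file.exists(path))
        stop("file not found: ", path)
    if (format == "fasta") {
        x <- Biostrings::readDNAStringSet(path, format = "fasta")
        names(x) <- sub("\\s.*$", "", names(x))
        return(Biostrings::DNAStringSet(toupper(x)))
    }
    x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
    names(x) <- sub("\\s.*$", "", names(x))
    seqs <- Biostrings::DNAStringSet(toupper(x))
    if (!withQualities)
        return(seqs)
    quals <- lapply(as(Biostrings::quality(x), "IntegerList"), as.integer)
    list(seqs = seqs, qualities = quals)
}

#' Write sequences to FASTA or FASTQ
#'
#' @param seqs named [Biostrings::DNAStringSet] (or named character vector).
#' @param path output path.
#' @param format `"fasta"` or `"fastq"`.
#' @param qualities optional list of per-base integer qualities; when absent
#'   a constant Q40 is written for FASTQ.
#' @return `path`, invisibly.
#' @export
writeSeqs <- function(seqs, path, format = c("fasta", "fastq"),
                      qualities = NULL) {
    format <- match.arg(format)
    if (is.character(seqs))
        seqs <- Biostrings::DNAStringSet(seqs)
    if (is.null(names(seqs)) || anyNA(names(seqs)))
        stop("sequences must be named")
    if (format == "fasta") {
        Biostrings::writeXStringSet(seqs, path, format = "fasta")
        return(invisible(path))
    }
    if (is.null(qualities)) {
        q <- Biostrings::BStringSet(vapply(
            Biostrings::width(seqs),
            function(w) paste(rep("I", w), collapse = ""), ""))
    } else {
        if (length(qualities) != length(seqs))
            stop("qualities must match sequences")
        q <- Biostrings::BStringSet(vapply(
            qualities,
            function(v) intToUtf8(as.integer(v) + 33L), ""))
    }
    Biostrings::writeXStringSet(seqs, path, format = "fastq", qualities = q)
    invisible(path)
}

#' Reverse complement
#'
#' @param x character vector or [Biostrings::DNAStringSet] over ACGTN.
#' @return object of the same kind, reverse-complemented (N maps to N).
#' @examples
#' revComp("AAGG")  # "CCTT"
#' @export
revComp <- function(x) {
    if (is.character(x)) {
        if (!all(grepl("^[ACGTN]*$", x)))
            stop("sequences must be over the ACGTN alphabet")
        return(as.character(Biostrings::reverseComplement(
            Biostrings::DNAStringSet(x))))
    }
    Biostrings::reverseComplement(x)
}

#' Read a BED6 interval file
#'
#' Intervals are returned as a [GenomicRanges::GRanges]; BED's 0-based
#' half-open coordinates become the usual 1-based closed `GRanges` form on
#' import (rtracklayer handles the shift losslessly).
#'
#' @param path BED6 file.
#' @return [GenomicRanges::GRanges] with metadata columns `name`, `score`.
#' @export
readBed <- function(path) {
    if (!file.exists(path))
        stop("file not found: ", path)
    info <- file.info(path)
    if (info$size == 0)
        return(GenomicRanges::GRanges())
    gr <- rtracklayer::import(path, format = "BED")
    if (is.null(gr$score))
        gr$score <- 0
    gr
}

#' Write intervals as BED6
#'
#' @param gr [GenomicRanges::GRanges]; metadata columns `name` and `score`
#'   are used when present.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBed <- function(gr, path) {
    if (length(gr)) {
        if (any(GenomicRanges::width(gr) < 1L))
            stop("intervals must have end > start")
        if (is.null(gr$name))
            gr$name <- rep(".", length(gr))
        if (is.null(gr$score))
            gr$score <- rep(0, length(gr))
    }
    rtracklayer::export(gr, path, format = "BED")
    invisible(path)
}

#' Write a data.frame as a TSV report
#'
#' Header row, UTF-8, `"."` for missing values: the tabular dialect used by
#' every report this package emits.
#'
#' @param df data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeReport <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = ".", fileEncoding = "UTF-8")
    invisible(path)
}

#' Read a TSV report
#'
#' @param path TSV file with a header row; `"."` is read as missing.
#' @return data.frame.
#' @export
readReport <- function(path) {
    utils::read.table(path, sep = "\t", header = TRUE, na.strings = ".",
                      stringsAsFactors = FALSE, check.names = FALSE,
                      comment.char = "", quote = "")
}
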