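#' @include panel.R
NULL

#' Read a FASTQ file
#'
#' Reads single-end FASTQ (optionally gzip-compressed, Sanger Phred+33)
#' into a [Biostrings::QualityScaledDNAStringSet]. On a malformed file the
#' error message reports the line of the first offending record.
#'
#' @param path FASTQ file.
#' @return a `QualityScaledDNAStringSet` (possibly empty), names carrying
#'   the read identifiers.
#' @export
readFastq <- function(path) {
    if (!file.exists(path)) stop("FASTQ file not found: ", path)
    .validate_fastq(path)
    suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
}

# structural 4-line validation; errors name the first offending line
.validate_fastq <- function(path) {
    con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
    lines <- readLines(con, warn = FALSE)
    close(con)
    n <- length(lines)
    if (n == 0L) return(invisible(NULL))
    if (n %% 4L != 0L)
        stop("malformed FASTQ '", path, "': truncated record starting at line ",
             (n %/% 4L) * 4L + 1L)
    hdr <- seq(1L, n, by = 4L)
    bad <- which(!startsWith(lines[hdr], "@"))
    if (length(bad))
        stop("malformed FASTQ '", path, "': expected '@' header at line ",
             hdr[bad[1]])
    bad <- which(!startsWith(lines[hdr + 2L], "+"))
    if (length(bad))
        stop("malformed FASTQ '", path, "': expected '+' separator at line ",
             hdr[bad[1]] + 2L)
    bad <- which(nchar(lines[hdr + 1L]) != nchar(lines[hdr + 3L]))
    if (length(bad))
        stop("malformed FASTQ '", path,
             "': sequence/quality length mismatch in record at line ",
             hdr[bad[1]])
    invisible(NULL)
}

#' Write reads to FASTQ
#'
#' Round-trips exactly with [readFastq()]. Sequences and qualities may be
#' given either as a `QualityScaledDNAStringSet` or as character vectors.
#'
#' @param reads a [Biostrings::QualityScaledDNAStringSet], or a character
#'   vector of sequences.
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @param ids read identifiers (defaults to names of `reads`).
#' @param qualities per-base Phred+33 quality strings (required when
#'   `reads` is a character vector).
#' @return `path`, invisibly.
#' @export
writeFastq <- function(reads, path, ids = names(reads), qualities = NULL) {
    if (is.character(reads)) {
        if (is.null(qualities))
            qualities <- strrep("?", nchar(reads))
        reads <- Biostrings::QualityScaledDNAStringSet(
            Biostrings::DNAStringSet(reads),
            Biostrings::PhredQuality(qualities))
    }
    if (!is.null(ids)) names(reads) <- ids
    if (is.null(names(reads)))
        names(reads) <- paste0("read", seq_along(reads))
    Biostrings::writeQualityScaledXStringSet(reads, path,
                                             compress = grepl("\\.gz$", path))
    invisible(path)
}
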