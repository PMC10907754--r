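#' @include panel.R
NULL

COUNT_COLS <- c("A", "C", "G", "T", "N", "del", "ins")

#' Per-position base-count matrix against an amplicon reference
#'
#' A `CountMatrix` tabulates, for one assay and one read level (`raw` or
#' `consensus`), the number of observed A/C/G/T/N calls and deletions at
#' each reference position, plus insertions anchored to their left-flanking
#' position. Coverage at a position is the number of reads contributing a
#' call there; by construction `A + C + G + T + N + del == coverage` at
#' every position, while insertions are tracked separately (they do not
#' consume a reference position).
#'
#' @slot assay assay name.
#' @slot reference amplicon reference sequence (character).
#' @slot counts integer matrix, one row per reference position, columns
#'   `A`, `C`, `G`, `T`, `N`, `del`, `ins`.
#' @slot coverage integer vector of per-position coverage.
#' @slot level `"raw"` or `"consensus"`.
#' @export
setClass("CountMatrix", representation(
    assay = "character",
    reference = "character",
    counts = "matrix",
    coverage = "integer",
    level = "character"
))

setValidity("CountMatrix", function(object) {
    msg <- character()
    L <- nchar(object@reference)
    if (!identical(colnames(object@counts), COUNT_COLS))
        msg <- c(msg, paste("counts columns must be", paste(COUNT_COLS, collapse = ",")))
    if (nrow(object@counts) != L)
        msg <- c(msg, "counts must have one row per reference position")
    if (length(object@coverage) != L)
        msg <- c(msg, "coverage length must match reference length")
    if (any(object@counts < 0) || any(object@coverage < 0))
        msg <- c(msg, "counts and coverage must be non-negative")
    cons <- rowSums(object@counts[, c("A", "C", "G", "T", "N", "del"), drop = FALSE])
    if (nrow(object@counts) && any(cons != object@coverage))
        msg <- c(msg, "A+C+G+T+N+del must equal coverage at every position")
    if (!object@level %in% c("raw", "consensus"))
        msg <- c(msg, "level must be 'raw' or 'consensus'")
    if (length(msg)) msg else TRUE
})

#' Construct a CountMatrix
#'
#' @param assay assay name.
#' @param reference amplicon reference sequence.
#' @param counts integer matrix with columns `A,C,G,T,N,del,ins`; if `NULL`
#'   an all-zero matrix is created.
#' @param level `"raw"` or `"consensus"`.
#' @return a validated [CountMatrix-class].
#' @export
CountMatrix <- function(assay, reference, counts = NULL, level = "raw") {
    L <- nchar(reference)
    if (is.null(counts)) {
        counts <- matrix(0L, nrow = L, ncol = length(COUNT_COLS),
                         dimnames = list(NULL, COUNT_COLS))
    }
    storage.mode(counts) <- "integer"
    cov <- as.integer(rowSums(counts[, c("A", "C", "G", "T", "N", "del"), drop = FALSE]))
    new("CountMatrix", assay = assay, reference = toupper(reference),
        counts = counts, coverage = cov, level = level)
}

setMethod("show", "CountMatrix", function(object) {
    cat("CountMatrix [", object@level, "] assay ", object@assay,
        ": ", nchar(object@reference), " positions, total coverage ",
        sum(object@coverage), "\n", sep = "")
})

#' CountMatrix accessors
#'
#' @param x a [CountMatrix-class]
#' @return `counts` the position-by-symbol count matrix; `coverage` the
#'   per-position coverage; `refBases` the reference base per position;
#'   `countLevel` `"raw"` or `"consensus"`; `assayName` the assay name.
#' @name countmatrix-accessors
NULL

#' @rdname countmatrix-accessors
#' @export
counts <- function(x) x@counts

#' @rdname countmatrix-accessors
#' @export
coverage <- function(x) x@coverage

#' @rdname countmatrix-accessors
#' @export
refBases <- function(x) strsplit(x@reference, "")[[1]]

#' @rdname countmatrix-accessors
#' @export
countLevel <- function(x) x@level

#' @rdname countmatrix-accessors
#' @export
assayName <- function(x) x@assay

#' @export
#' @method as.data.frame CountMatrix
#' @describeIn CountMatrix-class tabular view with 1-based `pos` and `ref`
#'   columns.
#' @param x a `CountMatrix`; further arguments ignored.
#' @param row.names,optional,... ignored.
as.data.frame.CountMatrix <- function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(assay = x@assay, level = x@level,
               pos = seq_len(nrow(x@counts)), ref = refBases(x),
               as.data.frame(x@counts), coverage = x@coverage,
               stringsAsFactors = FALSE)
}

#' Write / read a count matrix as TSV
#'
#' One row per reference position with 1-based positions, fixed column
#' order `assay, level, pos, ref, A, C, G, T, N, del, ins, coverage`.
#' `readCountMatrix()` reconstructs the object from such a file.
#'
#' @param x a [CountMatrix-class]
#' @param path output (input) TSV path.
#' @return `writeCountMatrix` returns `path` invisibly; `readCountMatrix`
#'   returns a [CountMatrix-class].
#' @export
writeCountMatrix <- function(x, path) {
    write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}

#' @rdname writeCountMatrix
#' @export
readCountMatrix <- function(path) {
    tab <- read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
    stopifnot(all(c("assay", "level", "pos", "ref", COUNT_COLS) %in% names(tab)))
    tab <- tab[order(tab$pos), ]
    m <- as.matrix(tab[, COUNT_COLS])
    dimnames(m) <- list(NULL, COUNT_COLS)
    CountMatrix(assay = tab$assay[1], reference = paste(tab$ref, collapse = ""),
                counts = m, level = tab$level[1])
}
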