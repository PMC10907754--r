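#' @include umiseq-package.R
NULL

#' Panel of targeted amplicon assays
#'
#' A `Panel` bundles the targeted assays of an amplicon sequencing design:
#' per-assay reference insert sequences, their genomic coordinates, optional
#' per-assay excluded positions (known SNPs, pseudogene homology, RNA-editing
#' sites), and the read-structure parameters shared by all assays (UMI
#' length, the fixed anchor sequence between the UMI and the insert, and the
#' minimum number of raw reads required per UMI family to call a consensus
#' read).
#'
#' Coordinate conventions: genomic coordinates (`start`, `end`) are 0-based
#' half-open; amplicon *offsets* (excluded positions, variant positions) are
#' 0-based; *positions* in human-readable reports are 1-based.
#'
#' @slot assays data.frame with columns `name`, `gene`, `contig`, `start`,
#'   `end` (one row per assay; names unique).
#' @slot amplicons [Biostrings::DNAStringSet] of reference insert sequences,
#'   named by assay; alphabet restricted to A, C, G, T, N.
#' @slot excluded named list of integer vectors of 0-based amplicon offsets
#'   excluded from error-rate computation.
#' @slot umiLength integer, UMI length in nucleotides (>= 6).
#' @slot anchorSeq character, fixed sequence between UMI and insert.
#' @slot minReadsPerUmi integer, minimum family size for consensus calling.
#'
#' @seealso [readPanel()], [readExclusionBed()]
#' @export
setClass("Panel", representation(
    assays = "data.frame",
    amplicons = "DNAStringSet",
    excluded = "list",
    umiLength = "integer",
    anchorSeq = "character",
    minReadsPerUmi = "integer"
))

setValidity("Panel", function(object) {
    msg <- character()
    a <- object@assays
    need <- c("name", "gene", "contig", "start", "end")
    if (!all(need %in% names(a)))
        msg <- c(msg, paste("assays must have columns:", paste(need, collapse = ", ")))
    if (nrow(a) < 1L) msg <- c(msg, "a Panel needs at least one assay")
    if (anyDuplicated(a$name)) msg <- c(msg, "assay names must be unique")
    if (!identical(sort(names(object@amplicons)), sort(a$name)))
        msg <- c(msg, "amplicons must be named by assay name")
    if (length(object@amplicons)) {
        w <- Biostrings::width(object@amplicons)
        if (any(w == 0L)) msg <- c(msg, "amplicon sequences must be non-empty")
        freq <- Biostrings::alphabetFrequency(object@amplicons)
        bad <- rowSums(freq[, !colnames(freq) %in% c("A", "C", "G", "T", "N"), drop = FALSE])
        if (any(bad > 0)) msg <- c(msg, "amplicon alphabet restricted to A,C,G,T,N")
    }
    for (nm in names(object@excluded)) {
        if (!nm %in% a$name) { msg <- c(msg, paste0("excluded list names unknown assay '", nm, "'")); next }
        off <- object@excluded[[nm]]
        L <- Biostrings::width(object@amplicons[nm])
        if (length(off) && (min(off) < 0L || max(off) >= L))
            msg <- c(msg, paste0("excluded offsets for '", nm, "' outside [0, ", L, ")"))
    }
    if (object@umiLength < 6L) msg <- c(msg, "umiLength must be >= 6")
    if (nchar(object@anchorSeq) < 1L) msg <- c(msg, "anchorSeq must be non-empty")
    if (object@minReadsPerUmi < 1L) msg <- c(msg, "minReadsPerUmi must be >= 1")
    if (length(msg)) msg else TRUE
})

#' Construct a Panel
#'
#' @param assays data.frame with columns `name`, `gene`, `contig`, `start`,
#'   `end` (0-based half-open genomic coordinates).
#' @param amplicons named character vector or [Biostrings::DNAStringSet] of
#'   reference insert sequences (names matching `assays$name`).
#' @param umiLength UMI length in nucleotides; default 12 (UMIs in this
#'   chemistry are random 6-16 nt sequences).
#' @param anchorSeq fixed sequence between UMI and insert. The real anchor
#'   is assay-design specific; the default is a placeholder used by the
#'   simulator.
#' @param minReadsPerUmi minimum raw reads per UMI family for a consensus
#'   read; default 3.
#' @param excluded named list of integer vectors of 0-based excluded
#'   amplicon offsets.
#' @return a validated [Panel-class] object.
#' @examples
#' p <- Panel(
#'   assays = data.frame(name = "A", gene = "TP53", contig = "chr17",
#'                       start = 100L, end = 140L),
#'   amplicons = c(A = "ACGTACGTAAGGCCTTACGTACGTACGTAAGGCCTTACGT")
#' )
#' umiLength(p)
#' @export
Panel <- function(assays, amplicons, umiLength = 12L,
                  anchorSeq = "CGATGTACGCTA", minReadsPerUmi = 3L,
                  excluded = list()) {
    if (!is(amplicons, "DNAStringSet"))
        amplicons <- Biostrings::DNAStringSet(amplicons)
    assays$name <- as.character(assays$name)
    excluded <- lapply(excluded, function(x) as.integer(sort(unique(x))))
    new("Panel", assays = as.data.frame(assays), amplicons = amplicons,
        excluded = excluded, umiLength = as.integer(umiLength),
        anchorSeq = toupper(anchorSeq), minReadsPerUmi = as.integer(minReadsPerUmi))
}

#' @describeIn Panel-class number of assays
#' @param x,object a `Panel`
#' @export
setMethod("length", "Panel", function(x) nrow(x@assays))

setMethod("show", "Panel", function(object) {
    cat("Panel with", nrow(object@assays), "assay(s)\n")
    cat("  umiLength:", object@umiLength,
        " anchorSeq:", object@anchorSeq,
        " minReadsPerUmi:", object@minReadsPerUmi, "\n")
    w <- Biostrings::width(object@amplicons[object@assays$name])
    nex <- vapply(object@assays$name, function(nm)
        length(object@excluded[[nm]]), integer(1))
    print(cbind(object@assays, width = w, excluded = nex), row.names = FALSE)
})

#' Panel accessors
#'
#' @param panel a [Panel-class]
#' @param assay assay name; if missing, all assays.
#' @return `assayNamesPanel` the assay names; `ampliconSeq` the reference
#'   insert sequence(s) as character; `umiLength`, `anchorSeq`,
#'   `minReadsPerUmi` the shared read-structure parameters;
#'   `excludedOffsets` the 0-based excluded amplicon offsets.
#' @name panel-accessors
NULL

#' @rdname panel-accessors
#' @export
assayNamesPanel <- function(panel) panel@assays$name

#' @rdname panel-accessors
#' @export
ampliconSeq <- function(panel, assay) {
    if (missing(assay)) assay <- panel@assays$name
    setNames(as.character(panel@amplicons[assay]), assay)
}

#' @rdname panel-accessors
#' @export
umiLength <- function(panel) panel@umiLength

#' @rdname panel-accessors
#' @export
anchorSeq <- function(panel) panel@anchorSeq

#' @rdname panel-accessors
#' @export
minReadsPerUmi <- function(panel) panel@minReadsPerUmi

#' @rdname panel-accessors
#' @export
excludedOffsets <- function(panel, assay) {
    off <- panel@excluded[[assay]]
    if (is.null(off)) integer(0) else off
}

#' Read a panel definition file
#'
#' The panel file is a tab-separated table with columns `name`, `gene`,
#' `contig`, `start`, `end` (0-based half-open) and `amplicon` (inline
#' reference insert sequence). Panel-level parameters may be given in
#' leading comment lines of the form `# umi_length=12`,
#' `# anchor_seq=ACGT...`, `# min_reads_per_umi=3`. Alternatively the
#' `amplicon` column may be omitted and sequences supplied through a FASTA
#' file whose record names match the assay names.
#'
#' @param path panel TSV file.
#' @param fasta optional FASTA file with amplicon reference sequences.
#' @return a validated [Panel-class]; missing amplicon sequences or
#'   duplicated assay names are hard errors.
#' @export
readPanel <- function(path, fasta = NULL) {
    if (!file.exists(path)) stop("panel file not found: ", path)
    lines <- readLines(path)
    hdr <- grep("^#", lines, value = TRUE)
    params <- list(umi_length = 12L, anchor_seq = "CGATGTACGCTA",
                   min_reads_per_umi = 3L)
    for (h in hdr) {
        kv <- sub("^#\\s*", "", h)
        if (grepl("=", kv, fixed = TRUE)) {
            key <- trimws(sub("=.*$", "", kv))
            val <- trimws(sub("^[^=]*=", "", kv))
            if (key %in% names(params)) params[[key]] <- val
        }
    }
    tab <- read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                      sep = "\t", stringsAsFactors = FALSE, quote = "")
    need <- c("name", "gene", "contig", "start", "end")
    if (!all(need %in% names(tab)))
        stop("panel file must have columns: ", paste(need, collapse = ", "))
    if (anyDuplicated(tab$name))
        stop("duplicate assay name(s): ",
             paste(unique(tab$name[duplicated(tab$name)]), collapse = ", "))
    if ("amplicon" %in% names(tab)) {
        amp <- setNames(toupper(trimws(tab$amplicon)), tab$name)
    } else {
        amp <- setNames(rep(NA_character_, nrow(tab)), tab$name)
    }
    if (!is.null(fasta)) {
        fa <- Biostrings::readDNAStringSet(fasta)
        hit <- intersect(names(fa), tab$name)
        amp[hit] <- as.character(fa[hit])
    }
    bad <- names(amp)[is.na(amp) | !nzchar(amp)]
    if (length(bad))
        stop("missing amplicon sequence for assay(s): ",
             paste(bad, collapse = ", "))
    Panel(tab[need], amp,
          umiLength = as.integer(params$umi_length),
          anchorSeq = as.character(params$anchor_seq),
          minReadsPerUmi = as.integer(params$min_reads_per_umi))
}

#' Load a BED exclusion list into a panel
#'
#' Intersects BED intervals (0-based half-open) of known single nucleotide
#' polymorphisms, pseudogene homology or RNA-editing sites with each assay's
#' genomic coordinates and records the covered amplicon offsets as excluded
#' from error-rate computation. Intervals on contigs absent from the panel
#' are skipped with a warning. Applying the same BED twice is idempotent.
#'
#' @param path BED file (at least 3 columns: contig, start, end).
#' @param panel a [Panel-class].
#' @return the panel with updated per-assay excluded offsets.
#' @export
readExclusionBed <- function(path, panel) {
    gr <- rtracklayer::import(path, format = "BED")
    if (length(gr) == 0L) return(panel)
    # BED is 0-based half-open; GRanges is 1-based closed
    bed <- data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr) - 1L,
                      end = GenomicRanges::end(gr))
    unknown <- setdiff(unique(bed$contig), panel@assays$contig)
    if (length(unknown))
        warning("skipping BED interval(s) on unknown contig(s): ",
                paste(unknown, collapse = ", "))
    exc <- panel@excluded
    for (i in seq_len(nrow(panel@assays))) {
        a <- panel@assays[i, ]
        hit <- bed[bed$contig == a$contig & bed$end > a$start & bed$start < a$end, , drop = FALSE]
        if (nrow(hit) == 0L) next
        off <- unlist(lapply(seq_len(nrow(hit)), function(j) {
            seq.int(max(hit$start[j], a$start), min(hit$end[j], a$end) - 1L)
        })) - a$start
        exc[[a$name]] <- sort(unique(c(exc[[a$name]], as.integer(off))))
    }
    methods::initialize(panel, excluded = exc)
}
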