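#' @include countmatrix.R io.R
NULL

#' Raw/consensus pileup pair for one assay
#'
#' Bundles the raw-read and consensus-read [CountMatrix-class] of one
#' assay. Consensus coverage can never exceed raw coverage at any
#' position.
#'
#' @slot raw raw-read [CountMatrix-class]
#' @slot consensus consensus-read [CountMatrix-class]
#' @export
setClass("PileupPair", representation(raw = "CountMatrix",
                                      consensus = "CountMatrix"))

setValidity("PileupPair", function(object) {
    msg <- character()
    if (object@raw@assay != object@consensus@assay)
        msg <- c(msg, "raw and consensus must describe the same assay")
    if (object@raw@reference != object@consensus@reference)
        msg <- c(msg, "raw and consensus must share the reference")
    if (object@raw@level != "raw" || object@consensus@level != "consensus")
        msg <- c(msg, "levels must be raw / consensus")
    if (any(object@consensus@coverage > object@raw@coverage))
        msg <- c(msg, "consensus coverage exceeds raw coverage")
    if (length(msg)) msg else TRUE
})

setMethod("show", "PileupPair", function(object) {
    cat("PileupPair for assay", object@raw@assay, "\n  ")
    show(object@raw); cat("  "); show(object@consensus)
})

#' @rdname PileupPair-class
#' @param raw,consensus the two [CountMatrix-class] objects.
#' @export
PileupPair <- function(raw, consensus) new("PileupPair", raw = raw,
                                           consensus = consensus)

#' Result of the UMI error-correction pipeline
#'
#' @slot pileups named list of [PileupPair-class], one per assay.
#' @slot families data.frame: `assay`, `family` (root UMI after directional
#'   clustering), `size` (raw reads), `consensus` (logical: passed the
#'   minimum-reads cutoff).
#' @slot report list of run counters (reads in, rejected, unassigned,
#'   family/consensus counts) and the parameter echo.
#' @export
setClass("PipelineResult", representation(
    pileups = "list", families = "data.frame", report = "list"))

setMethod("show", "PipelineResult", function(object) {
    r <- object$report
    cat("PipelineResult:", r$readsIn, "reads in;",
        r$rejectedShort + r$rejectedAnchor, "rejected;",
        r$unassigned, "unassigned;", r$nFamilies, "UMI families;",
        r$nConsensus, "consensus reads\n")
})

#' @export
setMethod("$", "PipelineResult", function(x, name)
    switch(name, pileups = x@pileups, families = x@families,
           report = x@report, NULL))

#' PipelineResult accessors
#'
#' @param result a [PipelineResult-class]
#' @param assay assay name
#' @return `pileupPair` the [PileupPair-class] of one assay; `runReport`
#'   the run counter list; `familyTable` the per-family table;
#'   `consensusCounts` a named vector of consensus reads per assay.
#' @name pipelineresult-accessors
NULL

#' @rdname pipelineresult-accessors
#' @export
pileupPair <- function(result, assay) result@pileups[[assay]]

#' @rdname pipelineresult-accessors
#' @export
runReport <- function(result) result@report

#' @rdname pipelineresult-accessors
#' @export
familyTable <- function(result) result@families

#' @rdname pipelineresult-accessors
#' @export
consensusCounts <- function(result) {
    fam <- result@families
    an <- names(result@pileups)
    out <- setNames(integer(length(an)), an)
    if (nrow(fam)) {
        tab <- table(fam$assay[fam$consensus])
        out[names(tab)] <- as.integer(tab)
    }
    out
}

#' Extract UMI and insert from reads
#'
#' The UMI is the first `umiLength(panel)` bases; the following fixed
#' anchor is verified allowing at most one mismatch; the remainder is the
#' insert. Reads that are too short or whose anchor has more than one
#' mismatch are rejected with a reason code.
#'
#' @param reads a [Biostrings::QualityScaledDNAStringSet], `DNAStringSet`
#'   or character vector (names used as ids).
#' @param panel a [Panel-class]
#' @return data.frame: `id`, `umi`, `insert`, `status`
#'   (`ok` / `short` / `anchor`).
#' @export
extractUmi <- function(reads, panel) {
    sq <- if (is.character(reads)) reads else as.character(reads)
    ids <- names(sq)
    if (is.null(ids)) ids <- paste0("read", seq_along(sq))
    U <- umiLength(panel); anchor <- anchorSeq(panel); A <- nchar(anchor)
    W <- nchar(sq)
    status <- rep("ok", length(sq))
    status[W <= U + A] <- "short"
    umi <- substr(sq, 1L, U)
    anch <- substr(sq, U + 1L, U + A)
    d <- cpp_hamming(anch, anchor)
    status[status == "ok" & (is.na(d) | d > 1L)] <- "anchor"
    insert <- substr(sq, U + A + 1L, W)
    umi[status != "ok"] <- NA_character_
    insert[status != "ok"] <- NA_character_
    data.frame(id = unname(ids), umi = unname(umi), insert = unname(insert),
               status = status, stringsAsFactors = FALSE)
}

# identity of a pairwise (glocal) alignment: matches over alignment columns
.alnIdentity <- function(al) {
    ins <- sum(Biostrings::width(Biostrings::insertion(Biostrings::indel(al))[[1]]))
    del <- sum(Biostrings::width(Biostrings::deletion(Biostrings::indel(al))[[1]]))
    nm <- Biostrings::nmatch(al); nmm <- Biostrings::nmismatch(al)
    nm / (nm + nmm + ins + del)
}

.alignOne <- function(insert, refStr) {
    Biostrings::pairwiseAlignment(
        Biostrings::DNAStringSet(insert), refStr, type = "global-local",
        substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
            match = 1, mismatch = -2, baseOnly = FALSE),
        gapOpening = 5, gapExtension = 2)
}

#' Assign inserts to panel assays
#'
#' Each insert is assigned to the best-matching amplicon, requiring at
#' least `minIdentity` identity over the aligned span; ties are broken by
#' panel order. Inserts whose length equals an amplicon's are scored by
#' Hamming identity (the substitution-only fast path); remaining inserts
#' are scored by semiglobal alignment against every amplicon.
#'
#' @param inserts character vector of insert sequences.
#' @param panel a [Panel-class]
#' @param minIdentity minimum identity for assignment (default 0.8).
#' @return character vector of assay names, `NA` for unassigned.
#' @export
assignAssay <- function(inserts, panel, minIdentity = 0.8) {
    u <- unique(inserts[!is.na(inserts)])
    if (!length(u)) return(rep(NA_character_, length(inserts)))
    bestAssay <- rep(NA_character_, length(u))
    bestIdent <- rep(-1, length(u))
    nchU <- nchar(u)
    for (a in assayNamesPanel(panel)) {
        refStr <- ampliconSeq(panel, a)
        L <- nchar(refStr)
        same <- which(nchU == L)
        if (!length(same)) next
        ident <- 1 - cpp_hamming(u[same], refStr) / L
        upd <- !is.na(ident) & ident >= minIdentity & ident > bestIdent[same]
        bestAssay[same[upd]] <- a
        bestIdent[same[upd]] <- ident[upd]
    }
    todo <- which(is.na(bestAssay) & nzchar(u))
    if (length(todo)) {
        for (a in assayNamesPanel(panel)) {
            refStr <- ampliconSeq(panel, a)
            al <- .alignOne(u[todo], refStr)
            ident <- vapply(seq_along(todo), function(i)
                .alnIdentity(al[i]), numeric(1))
            upd <- ident >= minIdentity & ident > bestIdent[todo]
            bestAssay[todo[upd]] <- a
            bestIdent[todo[upd]] <- ident[upd]
        }
    }
    bestAssay[match(inserts, u)]
}

#' Align inserts to an amplicon reference
#'
#' Semiglobal alignment (whole insert against a substring of the
#' reference) with affine gaps, encoded sparsely: substitutions (`X`,
#' observed base), deletions (`D`, one per spanned reference position) and
#' insertions (`I`, inserted sequence anchored to the left-flanking
#' reference position). Inserts whose length equals the reference are
#' compared position-wise (identical result for substitution-only reads).
#'
#' @param inserts character vector of assigned inserts.
#' @param reference amplicon reference sequence.
#' @return list with `devs` (data.frame `read`, `pos` 1-based, `op`,
#'   `base`) and `spans` (data.frame `read`, `start`, `end`: covered
#'   reference range).
#' @export
alignToAmplicon <- function(inserts, reference) {
    L <- nchar(reference)
    inserts <- unname(inserts)
    n <- length(inserts)
    spans <- data.frame(read = seq_len(n), start = rep(1L, n),
                        end = rep(L, n))
    eq <- which(nchar(inserts) == L)
    ne <- setdiff(seq_len(n), eq)
    devs <- list()
    if (length(eq)) {
        mm <- cpp_mismatch_table(inserts[eq], reference)
        if (length(mm$read))
            devs$eq <- data.frame(read = eq[mm$read], pos = mm$pos,
                                  op = "X", base = mm$base)
    }
    if (length(ne)) {
        al <- .alignOne(inserts[ne], reference)
        pa <- as.character(Biostrings::alignedPattern(al))
        sa <- as.character(Biostrings::alignedSubject(al))
        st <- Biostrings::start(Biostrings::subject(al))
        en <- Biostrings::end(Biostrings::subject(al))
        spans$start[ne] <- st
        spans$end[ne] <- en
        for (k in seq_along(ne)) {
            pc <- strsplit(pa[k], "")[[1]]
            sc <- strsplit(sa[k], "")[[1]]
            refpos <- st[k] - 1L
            insBuf <- ""
            rows <- list()
            for (j in seq_along(pc)) {
                if (sc[j] != "-") {
                    if (nzchar(insBuf) && refpos >= 1L) {
                        rows[[length(rows) + 1L]] <-
                            c(refpos, "I", insBuf)
                    }
                    insBuf <- ""
                    refpos <- refpos + 1L
                    if (pc[j] == "-") {
                        rows[[length(rows) + 1L]] <- c(refpos, "D", "-")
                    } else if (pc[j] != sc[j]) {
                        rows[[length(rows) + 1L]] <- c(refpos, "X", pc[j])
                    }
                } else {
                    insBuf <- paste0(insBuf, pc[j])
                }
            }
            if (nzchar(insBuf) && refpos >= 1L && refpos < L)
                rows[[length(rows) + 1L]] <- c(refpos, "I", insBuf)
            if (length(rows)) {
                m <- do.call(rbind, rows)
                devs[[paste0("ne", k)]] <- data.frame(
                    read = ne[k], pos = as.integer(m[, 1]),
                    op = m[, 2], base = m[, 3])
            }
        }
    }
    devs <- if (length(devs))
        do.call(rbind, c(devs, list(make.row.names = FALSE)))
    else data.frame(read = integer(), pos = integer(), op = character(),
                    base = character())
    list(devs = devs[order(devs$read, devs$pos), , drop = FALSE], spans = spans)
}

#' Directional UMI clustering
#'
#' Collapses sequencing errors in UMIs: after exact grouping, family B is
#' merged into family A when their UMIs differ at a single position and
#' `count(A) >= 2 * count(B) - 1`, processing merges in descending count
#' order (ties broken lexicographically) and resolving merge chains to
#' their root. With `maxDist = 0` exact grouping is returned.
#'
#' @param umis character vector of per-read UMIs (equal length).
#' @param maxDist 1 (default, substitution neighbours) or 0 (exact only).
#' @return character vector, same length as `umis`, of the root family
#'   UMI for each read.
#' @export
clusterUmis <- function(umis, maxDist = 1L) {
    if (!length(umis)) return(character(0))
    dt <- data.table::data.table(umi = umis)
    tab <- dt[, .N, by = umi]
    if (maxDist == 0L || nrow(tab) < 2L) return(umis)
    data.table::setorder(tab, -N, umi)
    tab[, idx := .I]
    len <- nchar(tab$umi[1])
    # candidate edges: Hamming-1 neighbours present in the table
    nb <- vector("list", 4L * len)
    k <- 0L
    for (p in seq_len(len)) {
        pre <- substr(tab$umi, 1L, p - 1L)
        suf <- substr(tab$umi, p + 1L, len)
        for (b in BASES) {
            cand <- paste0(pre, b, suf)
            hit <- match(cand, tab$umi)
            sel <- which(!is.na(hit) & hit != tab$idx)
            if (!length(sel)) next
            k <- k + 1L
            nb[[k]] <- data.table::data.table(child = tab$idx[sel],
                                              parent = hit[sel])
        }
    }
    if (k == 0L) return(umis)
    edges <- data.table::rbindlist(nb[seq_len(k)])
    nC <- tab$N[edges$child]; nP <- tab$N[edges$parent]
    edges <- edges[nP >= 2L * nC - 1L & edges$parent < edges$child]
    parent <- seq_len(nrow(tab))
    if (nrow(edges)) {
        data.table::setorder(edges, child, parent)  # parent idx order = count desc, lex
        best <- edges[, .(parent = parent[1L]), by = child]
        parent[best$child] <- best$parent
        # resolve chains to roots
        repeat {
            p2 <- parent[parent]
            if (identical(p2, parent)) break
            parent <- p2
        }
    }
    root <- tab$umi[parent]
    root[match(umis, tab$umi)]
}

# Plurality consensus over grouped, aligned reads (table engine).
# members: data.table(fam, read); devs: data.table(read, pos, op, base);
# spans: data.table(read, start, end). Returns consensus deviations,
# ambiguous positions and per-family spans for families of size >= minReads.
.consensusEngine <- function(members, devs, spans, minReads, minFraction) {
    fam <- read <- pos <- op <- base <- N <- size <- NULL  # R CMD check
    sizes <- members[, .(size = .N), by = fam]
    keep <- sizes[size >= minReads]
    if (!nrow(keep))
        return(list(families = sizes[, .(fam, size, consensus = size >= minReads)],
                    devs = data.table::data.table(fam = character(), pos = integer(),
                                                  op = character(), base = character()),
                    ambiguous = data.table::data.table(fam = character(), pos = integer()),
                    spans = data.table::data.table(fam = character(), start = integer(),
                                                   end = integer())))
    mem <- members[fam %in% keep$fam]
    sp <- spans[mem, on = "read"]
    famSpan <- sp[, .(start = min(start), end = max(end)), by = fam]
    fullSpan <- all(spans$start == 1L) && length(unique(spans$end)) == 1L
    dv <- devs[mem, on = "read", nomatch = NULL]
    out <- list(families = sizes[, .(fam, size, consensus = size >= minReads)],
                spans = famSpan)
    if (!nrow(dv)) {
        out$devs <- data.table::data.table(fam = character(), pos = integer(),
                                           op = character(), base = character())
        out$ambiguous <- data.table::data.table(fam = character(), pos = integer())
        return(out)
    }
    # votes per candidate symbol at deviating positions
    dv[, sym := ifelse(op == "D", "-", ifelse(op == "I", paste0("I", base), base))]
    votes <- dv[op != "I", .(n = .N), by = .(fam, pos, sym)]
    # coverage of each deviating position within its family
    posTab <- unique(votes[, .(fam, pos)])
    if (fullSpan) {
        posTab <- keep[posTab, on = "fam"]
        data.table::setnames(posTab, "size", "cov")
    } else {
        covTab <- sp[posTab, on = .(fam, start <= pos, end >= pos),
                     .(cov = .N), by = .EACHI][, .(fam, pos = start, cov)]
        posTab <- covTab[posTab, on = .(fam, pos)]
    }
    agg <- votes[, .(nonrefMax = max(n), totNonref = sum(n),
                     sym = sym[order(-n, sym)][1L]), by = .(fam, pos)]
    agg <- posTab[agg, on = .(fam, pos)]
    agg[, refVotes := cov - totNonref]
    agg[, winnerN := pmax(refVotes, nonrefMax)]
    agg[, winnerRef := refVotes >= nonrefMax]   # ties go to reference
    agg[, frac := winnerN / cov]
    amb <- agg[frac < minFraction, .(fam, pos)]
    consDev <- agg[frac >= minFraction & !winnerRef, .(fam, pos, sym)]
    consDev[, op := ifelse(sym == "-", "D", "X")]
    consDev[, base := ifelse(sym == "-", "-", sym)]
    # insertions: same support rule against family coverage at anchor
    insv <- dv[op == "I", .(n = .N), by = .(fam, pos, base)]
    if (nrow(insv)) {
        ip <- unique(insv[, .(fam, pos)])
        if (fullSpan) {
            ip <- keep[ip, on = "fam"]
            data.table::setnames(ip, "size", "cov")
        } else {
            ipc <- sp[ip, on = .(fam, start <= pos, end >= pos),
                      .(cov = .N), by = .EACHI][, .(fam, pos = start, cov)]
            ip <- ipc[ip, on = .(fam, pos)]
        }
        insv <- ip[insv, on = .(fam, pos)]
        insOk <- insv[n / cov >= minFraction,
                      .(fam, pos, op = "I", base, sym = paste0("I", base))]
        if (nrow(insOk))
            consDev <- rbind(consDev[, .(fam, pos, op, base)],
                             insOk[, .(fam, pos, op, base)])
        else consDev <- consDev[, .(fam, pos, op, base)]
    } else {
        consDev <- consDev[, .(fam, pos, op, base)]
    }
    out$devs <- consDev
    out$ambiguous <- amb
    out
}

#' Call the consensus of one UMI family
#'
#' Per reference position the plurality symbol (base or deletion) among
#' covering members wins; ties go to the reference. Positions whose
#' plurality fraction is below `minFraction` are marked ambiguous and
#' excluded from pileup contribution. Families smaller than `minReads`
#' yield no consensus (`NULL`).
#'
#' @param members character vector of aligned member sequences, all equal
#'   in length to `reference` (use `-` for deletions).
#' @param reference the amplicon reference sequence.
#' @param minReads minimum family size (default 3).
#' @param minFraction minimum plurality fraction (default 0.6).
#' @return `NULL`, or a list with `sequence` (consensus, ambiguous
#'   positions as `?`), `ambiguous` (1-based positions) and `size`.
#' @export
callConsensus <- function(members, reference, minReads = 3L,
                          minFraction = 0.6) {
    n <- length(members)
    if (n < minReads) return(NULL)
    stopifnot(all(nchar(members) == nchar(reference)))
    mm <- cpp_mismatch_table(members, reference)
    members_dt <- data.table::data.table(fam = "f", read = seq_len(n))
    devs <- data.table::data.table(read = mm$read, pos = mm$pos,
                                   op = ifelse(mm$base == "-", "D", "X"),
                                   base = mm$base)
    spans <- data.table::data.table(read = seq_len(n), start = 1L,
                                    end = nchar(reference))
    res <- .consensusEngine(members_dt, devs, spans, minReads, minFraction)
    seqc <- strsplit(reference, "")[[1]]
    if (nrow(res$devs)) {
        sub <- res$devs[res$devs$op != "I", ]
        seqc[sub$pos] <- ifelse(sub$op == "D", "-", sub$base)
    }
    if (nrow(res$ambiguous)) seqc[res$ambiguous$pos] <- "?"
    list(sequence = paste(seqc, collapse = ""),
         ambiguous = sort(res$ambiguous$pos), size = n)
}

# per-position coverage from span table (1-based, length L)
.spanCoverage <- function(starts, ends, L) {
    cov <- integer(L)
    if (!length(starts)) return(cov)
    add <- tabulate(starts, nbins = L)
    rem <- tabulate(pmin(ends + 1L, L + 1L), nbins = L + 1L)[seq_len(L)]
    cumsum(add - rem)
}

# counts matrix from devs + spans
.pileupMatrix <- function(assay, refStr, devs, spans, level,
                          ambiguous = NULL) {
    L <- nchar(refStr)
    refc <- strsplit(refStr, "")[[1]]
    cov <- .spanCoverage(spans$start, spans$end, L)
    m <- matrix(0L, nrow = L, ncol = length(COUNT_COLS),
                dimnames = list(NULL, COUNT_COLS))
    if (!is.null(ambiguous) && nrow(ambiguous)) {
        ambCount <- tabulate(ambiguous$pos, nbins = L)
        cov <- cov - ambCount
    }
    if (nrow(devs)) {
        sub <- devs[devs$op == "X", , drop = FALSE]
        if (nrow(sub)) {
            for (b in c("A", "C", "G", "T", "N")) {
                hit <- sub$pos[sub$base == b]
                if (length(hit)) m[, b] <- m[, b] + tabulate(hit, nbins = L)
            }
        }
        del <- devs$pos[devs$op == "D"]
        if (length(del)) m[, "del"] <- tabulate(del, nbins = L)
        ins <- devs$pos[devs$op == "I"]
        if (length(ins)) m[, "ins"] <- tabulate(ins, nbins = L)
    }
    nonref <- rowSums(m[, c("A", "C", "G", "T", "N", "del"), drop = FALSE])
    refCount <- cov - nonref
    if (any(refCount < 0))
        stop("pileup inconsistency: more deviations than coverage")
    for (b in c("A", "C", "G", "T", "N")) {
        atRef <- which(refc == b)
        m[atRef, b] <- m[atRef, b] + refCount[atRef]
    }
    # reference N positions: fold the reference count into the N column
    CountMatrix(assay, refStr, counts = m, level = level)
}

#' Build raw and consensus pileups for one assay
#'
#' Tabulates aligned raw reads and consensus reads into a
#' [PileupPair-class] of count matrices. Both inputs are sparse alignment
#' encodings as produced by [alignToAmplicon()] (raw) and the consensus
#' engine (consensus): a deviation table (`pos`, `op` in `X`/`D`/`I`,
#' `base`) plus a span table (`start`, `end`). Ambiguous consensus
#' positions are removed from the contributing family's coverage rather
#' than dropping the family.
#'
#' @param assay assay name.
#' @param reference amplicon reference sequence.
#' @param rawDevs,rawSpans raw-read deviations and spans.
#' @param consDevs,consSpans consensus-read deviations and spans.
#' @param ambiguous data.frame of ambiguous (`fam`, `pos`) consensus
#'   positions.
#' @return a [PileupPair-class]
#' @export
buildPileups <- function(assay, reference, rawDevs, rawSpans,
                         consDevs, consSpans, ambiguous = NULL) {
    raw <- .pileupMatrix(assay, reference, rawDevs, rawSpans, "raw")
    cons <- .pileupMatrix(assay, reference, consDevs, consSpans,
                          "consensus", ambiguous = ambiguous)
    PileupPair(raw, cons)
}

#' Run the UMI consensus error-correction pipeline
#'
#' Composes UMI extraction, assay assignment, amplicon alignment,
#' directional UMI clustering, plurality consensus calling with the
#' minimum-reads cutoff, and raw/consensus pileup construction. The run is
#' deterministic for a fixed input.
#'
#' @param reads FASTQ path, or reads as accepted by [extractUmi()].
#' @param panel a [Panel-class]
#' @param minReads minimum reads per UMI family (default:
#'   `minReadsPerUmi(panel)`).
#' @param consensusFraction plurality threshold (default 0.6).
#' @param umiClusterDist 1 (directional clustering, default) or 0 (exact).
#' @param minIdentity assignment identity cutoff (default 0.8).
#' @return a [PipelineResult-class]
#' @export
runPipeline <- function(reads, panel, minReads = NULL,
                        consensusFraction = 0.6, umiClusterDist = 1L,
                        minIdentity = 0.8) {
    fam <- pos <- op <- base <- NULL
    if (is.character(reads) && length(reads) == 1L && file.exists(reads))
        reads <- readFastq(reads)
    if (is.null(minReads)) minReads <- minReadsPerUmi(panel)
    ex <- extractUmi(reads, panel)
    report <- list(readsIn = nrow(ex),
                   rejectedShort = sum(ex$status == "short"),
                   rejectedAnchor = sum(ex$status == "anchor"))
    ok <- ex[ex$status == "ok", , drop = FALSE]
    ok$assay <- if (nrow(ok)) assignAssay(ok$insert, panel, minIdentity)
                else character(0)
    report$unassigned <- sum(is.na(ok$assay))
    report$assigned <- sum(!is.na(ok$assay))
    pileups <- list()
    famList <- list()
    nCons <- 0L
    for (a in assayNamesPanel(panel)) {
        refStr <- ampliconSeq(panel, a)
        sel <- which(!is.na(ok$assay) & ok$assay == a)
        if (!length(sel)) {
            pileups[[a]] <- buildPileups(
                a, refStr,
                data.frame(read = integer(), pos = integer(),
                           op = character(), base = character()),
                data.frame(read = integer(), start = integer(), end = integer()),
                data.frame(fam = character(), pos = integer(),
                           op = character(), base = character()),
                data.frame(fam = character(), start = integer(), end = integer()))
            next
        }
        aln <- alignToAmplicon(ok$insert[sel], refStr)
        roots <- clusterUmis(ok$umi[sel], maxDist = umiClusterDist)
        members <- data.table::data.table(fam = roots,
                                          read = seq_along(sel))
        devs <- data.table::as.data.table(aln$devs)
        spans <- data.table::as.data.table(aln$spans)
        cons <- .consensusEngine(members, devs, spans, minReads,
                                 consensusFraction)
        pileups[[a]] <- buildPileups(
            a, refStr, aln$devs, aln$spans,
            as.data.frame(cons$devs), as.data.frame(cons$spans),
            ambiguous = as.data.frame(cons$ambiguous))
        famdf <- as.data.frame(cons$families)
        famdf <- data.frame(assay = a, family = famdf$fam,
                            size = famdf$size, consensus = famdf$consensus)
        famList[[a]] <- famdf
        nCons <- nCons + sum(famdf$consensus)
    }
    families <- if (length(famList))
        do.call(rbind, c(famList, list(make.row.names = FALSE)))
    else data.frame(assay = character(), family = character(),
                    size = integer(), consensus = logical())
    report$nFamilies <- nrow(families)
    report$nConsensus <- nCons
    report$params <- list(minReads = minReads,
                          consensusFraction = consensusFraction,
                          umiClusterDist = umiClusterDist,
                          minIdentity = minIdentity)
    new("PipelineResult", pileups = pileups, families = families,
        report = report)
}
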