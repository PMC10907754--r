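NT <- c("A", "C", "G", "T")

randomAmplicon <- function(len) paste(sample(NT, len, replace = TRUE),
                                      collapse = "")

# small panel with deterministic random amplicons
testPanel <- function(nAssays = 1L, len = 60L, umiLength = 12L,
                      minReadsPerUmi = 3L, seed = 42L) {
    withr::with_seed(seed, {
        nm <- paste0("A", seq_len(nAssays))
        amps <- setNames(vapply(seq_len(nAssays), function(i)
            randomAmplicon(len), character(1)), nm)
        Panel(data.frame(name = nm, gene = "TP53", contig = "chr17",
                         start = 1000L + (seq_len(nAssays) - 1L) * 200L,
                         end = 1000L + (seq_len(nAssays) - 1L) * 200L + len),
              amps, umiLength = umiLength, minReadsPerUmi = minReadsPerUmi)
    })
}

# assemble raw reads from umi + anchor + insert
assembleReads <- function(panel, umis, inserts) {
    setNames(paste0(umis, anchorSeq(panel), inserts),
             paste0("r", seq_along(umis)))
}

randomUmi <- function(n, len = 12L) vapply(seq_len(n), function(i)
    paste(sample(NT, len, replace = TRUE), collapse = ""), character(1))

# independent per-position majority oracle for consensus calling:
# members are aligned strings (same length as reference, "-" = deletion)
bruteConsensus <- function(members, reference, minReads = 3L,
                           minFraction = 0.6) {
    n <- length(members)
    if (n < minReads) return(NULL)
    refc <- strsplit(reference, "")[[1]]
    mm <- do.call(rbind, strsplit(members, ""))
    out <- character(length(refc))
    amb <- integer(0)
    for (p in seq_along(refc)) {
        tab <- table(mm[, p])
        refVotes <- if (refc[p] %in% names(tab)) tab[[refc[p]]] else 0L
        nonref <- tab[names(tab) != refc[p]]
        nonrefMax <- if (length(nonref)) max(nonref) else 0L
        if (refVotes >= nonrefMax) {
            winner <- refc[p]; wN <- refVotes
        } else {
            cand <- sort(names(nonref)[nonref == nonrefMax])
            winner <- cand[1]; wN <- nonrefMax
        }
        if (wN / n < minFraction) { out[p] <- "?"; amb <- c(amb, p) }
        else out[p] <- winner
    }
    list(sequence = paste(out, collapse = ""), ambiguous = amb, size = n)
}

# affine-gap semiglobal DP (pattern global, subject local): optimal score
oracleSemiglobalScore <- function(pattern, subject, match = 1,
                                  mismatch = -2, gapOpen = 5, gapExt = 2) {
    p <- strsplit(pattern, "")[[1]]; s <- strsplit(subject, "")[[1]]
    m <- length(p); n <- length(s)
    NEG <- -1e9
    M <- matrix(NEG, m + 1, n + 1)   # p_i aligned to s_j
    Ix <- matrix(NEG, m + 1, n + 1)  # p_i aligned to gap
    Iy <- matrix(NEG, m + 1, n + 1)  # s_j aligned to gap
    for (i in seq_len(m)) {
        # whole pattern prefix aligned to gaps before entering the subject
        Ix[i + 1, 1] <- -(gapOpen + gapExt * i)
        fresh <- if (i == 1) 0 else NEG  # free subject prefix
        for (j in seq_len(n)) {
            sub <- if (p[i] == s[j]) match else mismatch
            M[i + 1, j + 1] <- sub + max(M[i, j], Ix[i, j], Iy[i, j], fresh)
            Ix[i + 1, j + 1] <- max(M[i, j + 1] - gapOpen - gapExt,
                                    Iy[i, j + 1] - gapOpen - gapExt,
                                    Ix[i, j + 1] - gapExt,
                                    fresh - gapOpen - gapExt)
            Iy[i + 1, j + 1] <- max(M[i + 1, j] - gapOpen - gapExt,
                                    Ix[i + 1, j] - gapOpen - gapExt,
                                    Iy[i + 1, j] - gapExt)
        }
    }
    max(M[m + 1, ], Ix[m + 1, ])
}

# score implied by a sparse deviation encoding of an alignment
scoreFromDevs <- function(devs, span, match = 1, mismatch = -2,
                          gapOpen = 5, gapExt = 2) {
    S <- span$end - span$start + 1L
    nX <- sum(devs$op == "X")
    delPos <- sort(devs$pos[devs$op == "D"])
    nDel <- length(delPos)
    delRuns <- if (nDel) sum(diff(delPos) > 1L) + 1L else 0L
    insRows <- devs[devs$op == "I", , drop = FALSE]
    insLen <- if (nrow(insRows)) nchar(insRows$base) else integer(0)
    (S - nDel - nX) * match + nX * mismatch -
        delRuns * gapOpen - nDel * gapExt -
        (if (length(insLen)) length(insLen) * gapOpen + sum(insLen) * gapExt else 0)
}

# reconstruct an insert from reference + sparse deviations (oracle for
# alignment encoding consistency)
applyDevs <- function(reference, devs, span) {
    refc <- strsplit(reference, "")[[1]][span$start:span$end]
    names(refc) <- span$start:span$end
    for (k in seq_len(nrow(devs))) {
        p <- as.character(devs$pos[k])
        if (devs$op[k] == "X") refc[p] <- devs$base[k]
        if (devs$op[k] == "D") refc[p] <- ""
        if (devs$op[k] == "I") refc[p] <- paste0(refc[p], devs$base[k])
    }
    paste(refc, collapse = "")
}
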