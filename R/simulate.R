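#' @include simconfig.R countmatrix.R io.R
NULL

BASES <- c("A", "C", "G", "T")

#' Ground-truth template molecules
#'
#' Substitution-only representation of the simulated template molecules:
#' every molecule is its assay's amplicon reference plus a sparse set of
#' per-molecule deviations (spike-in variants, reverse-transcription
#' errors). Single-stranded molecules (RNA, cDNA) have one template strand,
#' double-stranded (genomic DNA) two.
#'
#' @slot molecules data.frame: `assay`, `mol` (lineage id, unique within
#'   assay), `strands` (1 or 2), `type` (`RNA`, `cDNA` or `gDNA`).
#' @slot devs data.frame of deviations vs the amplicon reference: `assay`,
#'   `mol`, `pos` (1-based), `base`, `origin` (`variant` or `rt`; `rt`
#'   deviations are flagged as UMI-uncorrectable in the truth).
#' @export
setClass("MoleculeSet", representation(
    molecules = "data.frame", devs = "data.frame"))

setValidity("MoleculeSet", function(object) {
    m <- object@molecules
    if (nrow(m) && anyDuplicated(m[c("assay", "mol")]))
        "molecule ids must be unique within assay" else TRUE
})

setMethod("show", "MoleculeSet", function(object) {
    m <- object@molecules
    cat("MoleculeSet:", nrow(m), "molecules,",
        nrow(object@devs), "deviations\n")
    if (nrow(m)) print(table(assay = m$assay, type = m$type))
})

#' UMI-tagged barcoding-PCR products
#'
#' One row per UMI lineage: a strand synthesized from an original template
#' strand during barcoding PCR, tagged with a fresh random UMI. At
#' barcoding efficiency 1 a single-stranded origin founds exactly
#' `barcodeCycles` lineages (3 by default) and a double-stranded origin
#' twice that (6).
#'
#' @slot lineages data.frame: `assay`, `lineage`, `mol`, `strand`, `cycle`
#'   (founding cycle), `depth` (remaining barcoding cycles after founding),
#'   `umi`.
#' @slot founderDevs data.frame of polymerase substitutions acquired at
#'   founder synthesis: `assay`, `lineage`, `pos`, `base`.
#' @slot origin the [MoleculeSet-class] the products derive from.
#' @export
setClass("BarcodedProducts", representation(
    lineages = "data.frame", founderDevs = "data.frame",
    origin = "MoleculeSet"))

setMethod("show", "BarcodedProducts", function(object) {
    cat("BarcodedProducts:", nrow(object@lineages), "UMI lineages",
        "(", length(unique(object@lineages$umi)), "distinct UMIs )\n")
})

.nMoleculesFor <- function(config, panel) {
    nm <- config@nMolecules
    an <- assayNamesPanel(panel)
    if (is.null(names(nm))) {
        if (length(nm) == 1L) nm <- rep(nm, length(an))
        if (length(nm) != length(an))
            stop("nMolecules must be scalar or one value per assay")
        names(nm) <- an
    }
    missing <- setdiff(an, names(nm))
    if (length(missing)) stop("nMolecules missing for assay(s): ",
                              paste(missing, collapse = ", "))
    round(nm[an])
}

# sample substitution targets uniformly over a molecules-by-positions grid
.sampleGrid <- function(nUnits, L, rate) {
    total <- as.double(nUnits) * L
    if (total <= 0 || rate <= 0) return(data.frame(unit = integer(), pos = integer()))
    k <- rbinom(1L, size = total, prob = rate)
    if (k == 0L) return(data.frame(unit = integer(), pos = integer()))
    idx <- if (total <= .Machine$integer.max) {
        sample.int(as.integer(total), k)
    } else {
        unique(ceiling(runif(k) * total))  # grids beyond 2^31: with-replacement draw
    }
    data.frame(unit = as.integer((idx - 1) %/% L + 1),
               pos = as.integer((idx - 1) %% L + 1))
}

# uniformly chosen base different from `from`
.altBase <- function(from) {
    k <- length(from)
    if (k == 0L) return(character(0))
    alt <- matrix(c("C", "G", "T",  "A", "G", "T",  "A", "C", "T",
                    "A", "C", "G"), nrow = 4, byrow = TRUE,
                  dimnames = list(BASES, NULL))
    i <- match(from, BASES)
    pick <- sample.int(3L, k, replace = TRUE)
    out <- ifelse(is.na(i), sample(BASES, k, replace = TRUE),
                  alt[cbind(pmax(i, 1L), pick)])
    out
}

.randomUmis <- function(n, len) {
    if (n == 0L) return(character(0))
    m <- matrix(sample(BASES, n * len, replace = TRUE), nrow = n)
    do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Draw ground-truth template molecules
#'
#' For each assay, creates the configured number of template molecules and
#' realizes the spike-in design: each variant of fraction `f` is carried by
#' `Binomial(n, f)` molecules (disjoint across variants at one position).
#'
#' @param config a [SimConfig-class]
#' @param panel a [Panel-class]
#' @return a [MoleculeSet-class] (`RNA` molecules for the single-stranded
#'   workflow, `gDNA` for the double-stranded one).
#' @export
makeMolecules <- function(config, panel) {
    nmol <- .nMoleculesFor(config, panel)
    single <- config@strandedness == "single"
    mols <- list(); devs <- list()
    for (a in assayNamesPanel(panel)) {
        n <- nmol[[a]]
        L <- nchar(ampliconSeq(panel, a))
        v <- config@variants[config@variants$assay == a, , drop = FALSE]
        if (nrow(v) && (min(v$offset) < 0L || max(v$offset) >= L))
            stop("variant offset outside amplicon for assay ", a)
        mols[[a]] <- data.frame(assay = a, mol = seq_len(n),
                                strands = if (single) 1L else 2L,
                                type = if (single) "RNA" else "gDNA")
        if (nrow(v) && n > 0L) {
            taken <- new.env()
            dd <- lapply(seq_len(nrow(v)), function(j) {
                key <- as.character(v$offset[j])
                used <- if (is.null(taken[[key]])) integer(0) else taken[[key]]
                k <- rbinom(1L, n, v$fraction[j])
                pool <- setdiff(seq_len(n), used)
                k <- min(k, length(pool))
                pick <- if (k > 0) sample(pool, k) else integer(0)
                taken[[key]] <- c(used, pick)
                if (k == 0) return(NULL)
                data.frame(assay = a, mol = pick,
                           pos = v$offset[j] + 1L, base = v$alt[j],
                           origin = "variant")
            })
            devs[[a]] <- do.call(rbind, dd)
        }
    }
    new("MoleculeSet",
        molecules = do.call(rbind, c(mols, list(make.row.names = FALSE))),
        devs = .bindDevs(devs))
}

.bindDevs <- function(lst) {
    lst <- Filter(Negate(is.null), lst)
    if (!length(lst))
        return(data.frame(assay = character(), mol = integer(),
                          pos = integer(), base = character(),
                          origin = character()))
    do.call(rbind, c(lst, list(make.row.names = FALSE)))
}

#' Reverse transcription of RNA molecules
#'
#' Each RNA molecule is converted to single-stranded cDNA with probability
#' `rtEfficiency`; each base of a converted molecule is substituted with
#' probability `rtErrorRate` to a uniformly chosen other base. These
#' substitutions precede UMI tagging and are therefore not correctable by
#' consensus; they are flagged `origin = "rt"`. Double-stranded input is
#' returned unchanged.
#'
#' @param molecules a [MoleculeSet-class]
#' @param config a [SimConfig-class]
#' @param panel a [Panel-class]
#' @return a [MoleculeSet-class] of cDNA (or the unchanged input).
#' @export
reverseTranscribe <- function(molecules, config, panel) {
    m <- molecules@molecules
    if (!nrow(m) || !any(m$type == "RNA")) return(molecules)
    keep <- m$type != "RNA" |
        rbinom(nrow(m), 1L, config@rtEfficiency) == 1L
    m2 <- m[keep, , drop = FALSE]
    d2 <- merge(molecules@devs, m2[c("assay", "mol")],
                by = c("assay", "mol"), sort = FALSE)
    newdevs <- list(d2)
    for (a in unique(m2$assay[m2$type == "RNA"])) {
        ref <- strsplit(ampliconSeq(panel, a), "")[[1]]
        ids <- m2$mol[m2$assay == a & m2$type == "RNA"]
        ev <- .sampleGrid(length(ids), length(ref), config@rtErrorRate)
        if (nrow(ev)) {
            newdevs[[a]] <- data.frame(
                assay = a, mol = ids[ev$unit], pos = ev$pos,
                base = .altBase(ref[ev$pos]), origin = "rt")
        }
    }
    m2$type[m2$type == "RNA"] <- "cDNA"
    new("MoleculeSet", molecules = m2, devs = .bindDevs(newdevs))
}

#' Barcoding PCR: UMI tagging
#'
#' Explicit per-cycle bookkeeping of the original template strands: in each
#' of `barcodeCycles` cycles every original template strand is copied with
#' probability `barcodeEfficiency`, and each such copy - primed by a
#' UMI-bearing primer - founds a new product lineage with a fresh random
#' UMI drawn uniformly over `4^umiLength` (collisions between origins are
#' permitted and recorded in the run truth). Copies of already-tagged
#' strands regenerate the existing UMI and therefore found no new lineage;
#' they are accounted for by the lineage `depth`. Polymerase substitutions
#' are injected into each founder strand at `polErrorRate` per base.
#'
#' @param molecules a [MoleculeSet-class] of DNA molecules (cDNA or gDNA).
#' @param config a [SimConfig-class]
#' @param panel a [Panel-class]
#' @return a [BarcodedProducts-class]
#' @export
barcodePcr <- function(molecules, config, panel) {
    if (config@barcodeCycles < 1L) stop("barcodeCycles must be >= 1")
    m <- molecules@molecules
    if (any(m$type == "RNA"))
        stop("RNA molecules must be reverse transcribed before barcoding")
    C <- config@barcodeCycles
    lin <- list(); fdev <- list()
    nextId <- 0L
    for (a in unique(m$assay)) {
        ma <- m[m$assay == a, , drop = FALSE]
        L <- nchar(ampliconSeq(panel, a))
        ref <- strsplit(ampliconSeq(panel, a), "")[[1]]
        # grid: molecule x template strand x cycle
        grid <- expand.grid(i = seq_len(nrow(ma)), strand = seq_len(max(ma$strands)),
                            cycle = seq_len(C))
        grid <- grid[grid$strand <= ma$strands[grid$i], , drop = FALSE]
        keep <- rbinom(nrow(grid), 1L, config@barcodeEfficiency) == 1L
        grid <- grid[keep, , drop = FALSE]
        n <- nrow(grid)
        if (n == 0L) next
        la <- data.frame(assay = a, lineage = nextId + seq_len(n),
                         mol = ma$mol[grid$i], strand = grid$strand,
                         cycle = grid$cycle, depth = C - grid$cycle,
                         umi = .randomUmis(n, umiLength(panel)))
        ev <- .sampleGrid(n, L, config@polErrorRate)
        if (nrow(ev))
            fdev[[a]] <- data.frame(assay = a,
                                    lineage = la$lineage[ev$unit],
                                    pos = ev$pos,
                                    base = .altBase(ref[ev$pos]),
                                    origin = "pol_barcode")
        lin[[a]] <- la
        nextId <- nextId + n
    }
    emptyLin <- data.frame(assay = character(), lineage = integer(),
                           mol = integer(), strand = integer(),
                           cycle = integer(), depth = integer(),
                           umi = character())
    new("BarcodedProducts",
        lineages = if (length(lin)) do.call(rbind, c(lin, list(make.row.names = FALSE))) else emptyLin,
        founderDevs = .bindDevs(fdev),
        origin = molecules)
}

#' Dilution between barcoding and adapter PCR
#'
#' Each UMI lineage is loaded into the adapter PCR independently with
#' probability `dilutionFraction`. At the default one-third dilution the
#' expected number of surviving lineages per original molecule is 1 for
#' single-stranded and 2 for double-stranded templates.
#'
#' @param products a [BarcodedProducts-class]
#' @param config a [SimConfig-class]
#' @return a [BarcodedProducts-class] restricted to surviving lineages.
#' @export
diluteProducts <- function(products, config) {
    lin <- products@lineages
    if (!nrow(lin)) return(products)
    keep <- rbinom(nrow(lin), 1L, config@dilutionFraction) == 1L
    lin2 <- lin[keep, , drop = FALSE]
    fd <- products@founderDevs
    fd <- fd[fd$lineage %in% lin2$lineage, , drop = FALSE]
    new("BarcodedProducts", lineages = lin2, founderDevs = fd,
        origin = products@origin)
}

#' Adapter PCR and sequencing
#'
#' For each surviving UMI lineage the first `jackpotCycles` adapter cycles
#' are treated as an explicit doubling tree: polymerase errors arising in
#' cycle `c` (among the `2^(c-1)` strand syntheses of that cycle) are
#' inherited by each sequenced read of the lineage with probability
#' `2^-c`, which is how early shared errors can survive consensus calling.
#' The remaining `adapterCycles - jackpotCycles` cycles contribute
#' independent per-read polymerase substitutions, and sequencing adds
#' substitutions at `seqErrorRate` per base over the full read
#' (UMI + anchor + insert). The number of reads per lineage is
#' `Poisson(meanReadsPerFamily)`. Emitted reads are
#' `UMI | anchor | insert` with a constant Phred quality.
#'
#' @param products a [BarcodedProducts-class] (post-dilution).
#' @param config a [SimConfig-class]
#' @param panel a [Panel-class]
#' @return list with elements `reads` (a
#'   [Biostrings::QualityScaledDNAStringSet]; ids encode
#'   `assay:lineage:read`) and `readMap` (data.frame `id`, `assay`,
#'   `lineage`).
#' @export
adapterPcrSequence <- function(products, config, panel) {
    lin <- products@lineages
    if (!nrow(lin)) {
        warning("no surviving products; emitting empty read set")
        return(list(reads = Biostrings::QualityScaledDNAStringSet(
                        Biostrings::DNAStringSet(character(0)),
                        Biostrings::PhredQuality(character(0))),
                    readMap = data.frame(id = character(), assay = character(),
                                         lineage = integer())))
    }
    U <- umiLength(panel); anchor <- anchorSeq(panel); A <- nchar(anchor)
    qchar <- rawToChar(as.raw(33L + config@phred))
    molDevs <- products@origin@devs
    allSeq <- character(0); allId <- character(0); allMap <- list()
    for (a in unique(lin$assay)) {
        la <- lin[lin$assay == a, , drop = FALSE]
        refStr <- ampliconSeq(panel, a)
        ref <- strsplit(refStr, "")[[1]]
        L <- length(ref)
        nlin <- nrow(la)
        nr <- rpois(nlin, config@meanReadsPerFamily)
        R <- sum(nr)
        if (R == 0L) next
        rdLineage <- rep.int(seq_len(nlin), nr)   # row of la per read
        dev <- list()
        # 1. molecule-level deviations (variant + rt)
        md <- molDevs[molDevs$assay == a, , drop = FALSE]
        if (nrow(md)) {
            rdMol <- la$mol[rdLineage]
            hitIdx <- which(rdMol %in% md$mol)
            if (length(hitIdx)) {
                mm <- merge(data.frame(read = hitIdx, mol = rdMol[hitIdx]),
                            md[c("mol", "pos", "base")], by = "mol")
                dev$mol <- data.frame(read = mm$read, pos = mm$pos,
                                      base = mm$base, prio = 1L)
            }
        }
        # 2. founder (barcoding) deviations per lineage
        fd <- products@founderDevs
        fd <- fd[fd$assay == a, , drop = FALSE]
        if (nrow(fd)) {
            rdLin <- la$lineage[rdLineage]
            hitIdx <- which(rdLin %in% fd$lineage)
            if (length(hitIdx)) {
                mm <- merge(data.frame(read = hitIdx, lineage = rdLin[hitIdx]),
                            fd[c("lineage", "pos", "base")], by = "lineage")
                dev$founder <- data.frame(read = mm$read, pos = mm$pos,
                                          base = mm$base, prio = 2L)
            }
        }
        # 3. jackpot tree errors in early adapter cycles
        if (config@jackpotCycles > 0L && config@polErrorRate > 0) {
            for (cyc in seq_len(config@jackpotCycles)) {
                ev <- .sampleGrid(nlin * 2^(cyc - 1L), L, config@polErrorRate)
                if (!nrow(ev)) next
                ev$lineage <- (ev$unit - 1L) %% nlin + 1L
                ev$base <- .altBase(ref[ev$pos])
                hitIdx <- which(rdLineage %in% ev$lineage)
                if (!length(hitIdx)) next
                hit <- merge(data.frame(read = hitIdx, li = rdLineage[hitIdx]),
                             data.frame(li = ev$lineage, pos = ev$pos,
                                        base = ev$base), by = "li")
                if (!nrow(hit)) next
                inherit <- rbinom(nrow(hit), 1L, 2^-cyc) == 1L
                if (any(inherit))
                    dev[[paste0("jack", cyc)]] <-
                        data.frame(read = hit$read[inherit],
                                   pos = hit$pos[inherit],
                                   base = hit$base[inherit], prio = 3L)
            }
        }
        # 4. residual per-read polymerase errors (remaining cycles)
        rem <- config@adapterCycles - config@jackpotCycles
        if (rem > 0L && config@polErrorRate > 0) {
            pres <- 1 - (1 - config@polErrorRate)^rem
            ev <- .sampleGrid(R, L, pres)
            if (nrow(ev))
                dev$residual <- data.frame(read = ev$unit, pos = ev$pos,
                                           base = .altBase(ref[ev$pos]),
                                           prio = 4L)
        }
        # 5. sequencing errors over the whole emitted read
        W <- U + A + L
        umis <- la$umi[rdLineage]
        anchors <- NULL  # modified lazily
        sev <- .sampleGrid(R, W, config@seqErrorRate)
        if (nrow(sev)) {
            inUmi <- sev$pos <= U
            inAnchor <- !inUmi & sev$pos <= U + A
            inIns <- sev$pos > U + A
            if (any(inUmi)) {
                e <- sev[inUmi, , drop = FALSE]
                e <- e[order(e$unit, e$pos), , drop = FALSE]
                cur <- substring(umis[e$unit], e$pos, e$pos)
                umis <- cpp_apply_subs(umis, e$unit, e$pos, .altBase(cur))
            }
            if (any(inAnchor)) {
                e <- sev[inAnchor, , drop = FALSE]
                e$pos <- e$pos - U
                anchors <- rep(anchor, R)
                e <- e[order(e$unit, e$pos), , drop = FALSE]
                cur <- substring(anchors[e$unit], e$pos, e$pos)
                anchors <- cpp_apply_subs(anchors, e$unit, e$pos, .altBase(cur))
            }
            if (any(inIns)) {
                e <- sev[inIns, , drop = FALSE]
                dev$seq <- data.frame(read = e$unit, pos = e$pos - U - A,
                                      base = .altBase(ref[e$pos - U - A]),
                                      prio = 5L)
            }
        }
        # build insert strings
        inserts <- rep(refStr, R)
        dd <- if (length(dev)) do.call(rbind, c(dev, list(make.row.names = FALSE))) else NULL
        if (!is.null(dd) && nrow(dd)) {
            dd <- dd[order(dd$read, dd$prio, dd$pos), , drop = FALSE]
            inserts <- cpp_apply_subs(inserts, dd$read, dd$pos, dd$base)
        }
        # optional sequencing indels (single-base), applied right-to-left
        if (config@indelRate > 0) {
            iev <- .sampleGrid(R, L, config@indelRate)
            if (nrow(iev)) {
                iev$del <- runif(nrow(iev)) < 0.5
                iev$ins <- .randomBases(nrow(iev))
                iev <- iev[order(iev$unit, -iev$pos), , drop = FALSE]
                for (j in seq_len(nrow(iev))) {
                    r <- iev$unit[j]; p <- iev$pos[j]
                    s <- inserts[r]
                    inserts[r] <- if (iev$del[j]) {
                        paste0(substr(s, 1L, p - 1L), substr(s, p + 1L, nchar(s)))
                    } else {
                        paste0(substr(s, 1L, p), iev$ins[j],
                               substr(s, p + 1L, nchar(s)))
                    }
                }
            }
        }
        if (is.null(anchors)) anchors <- rep(anchor, R)
        seqs <- paste0(umis, anchors, inserts)
        rdIdx <- sequence(nr)
        ids <- paste0(a, ":l", la$lineage[rdLineage], ":r", rdIdx)
        allSeq <- c(allSeq, seqs)
        allId <- c(allId, ids)
        allMap[[a]] <- data.frame(id = ids, assay = a,
                                  lineage = la$lineage[rdLineage])
    }
    quals <- strrep(qchar, nchar(allSeq))
    reads <- Biostrings::QualityScaledDNAStringSet(
        Biostrings::DNAStringSet(setNames(allSeq, allId)),
        Biostrings::PhredQuality(quals))
    list(reads = reads,
         readMap = if (length(allMap))
             do.call(rbind, c(allMap, list(make.row.names = FALSE)))
         else data.frame(id = character(), assay = character(),
                         lineage = integer()))
}

.randomBases <- function(k) sample(BASES, k, replace = TRUE)

#' Run the full library simulation
#'
#' Composes [makeMolecules()], [reverseTranscribe()], [barcodePcr()],
#' [diluteProducts()] and [adapterPcrSequence()] under the master seed of
#' `config`. The same seed and configuration give byte-identical output.
#'
#' @param config a [SimConfig-class]
#' @param panel a [Panel-class]
#' @param outDir optional directory; if given, `reads.fastq` and
#'   `truth.json` (summary ground truth + full parameter echo) are written
#'   there.
#' @return (invisibly when writing) a list with elements `reads`
#'   (QualityScaledDNAStringSet), `truth` (see below), `readMap`,
#'   `lineages` (pre-dilution), `survivors` (post-dilution lineage table)
#'   and `molecules`. `truth` holds the parameter echo and per-assay
#'   summaries: molecule counts, realized variant counts/fractions, UMI
#'   lineage counts per origin, UMI collisions, dilution survivors and
#'   read counts.
#' @export
simulateRun <- function(config, panel, outDir = NULL) {
    methods::validObject(config)
    set.seed(config@seed)
    mols0 <- makeMolecules(config, panel)
    mols <- reverseTranscribe(mols0, config, panel)
    prods <- barcodePcr(mols, config, panel)
    surv <- diluteProducts(prods, config)
    seqd <- adapterPcrSequence(surv, config, panel)

    truth <- list(params = configAsList(config), assays = list())
    for (a in assayNamesPanel(panel)) {
        m0 <- mols0@molecules[mols0@molecules$assay == a, , drop = FALSE]
        m1 <- mols@molecules[mols@molecules$assay == a, , drop = FALSE]
        lina <- prods@lineages[prods@lineages$assay == a, , drop = FALSE]
        sva <- surv@lineages[surv@lineages$assay == a, , drop = FALSE]
        vdev <- mols@devs[mols@devs$assay == a &
                          mols@devs$origin == "variant", , drop = FALSE]
        vr <- config@variants[config@variants$assay == a, , drop = FALSE]
        variants <- if (nrow(vr)) {
            rc <- vapply(seq_len(nrow(vr)), function(j)
                sum(vdev$pos == vr$offset[j] + 1L & vdev$base == vr$alt[j]),
                integer(1))
            data.frame(offset = vr$offset, alt = vr$alt,
                       expectedFraction = vr$fraction, realizedCount = rc,
                       realizedFraction = if (nrow(m1)) rc / nrow(m1) else NA_real_)
        } else data.frame(offset = integer(), alt = character(),
                          expectedFraction = numeric(),
                          realizedCount = integer(),
                          realizedFraction = numeric())
        linPerOrigin <- if (nrow(lina)) table(factor(lina$mol, levels = m1$mol)) else table(integer(0))
        svPerOrigin <- if (nrow(m1)) tabulate(match(sva$mol, m1$mol), nbins = nrow(m1)) else integer(0)
        truth$assays[[a]] <- list(
            nMolecules = nrow(m0),
            nAfterRt = nrow(m1),
            nRtErrors = sum(mols@devs$assay == a & mols@devs$origin == "rt"),
            variants = variants,
            nLineages = nrow(lina),
            lineagesPerOrigin = as.vector(linPerOrigin),
            umisPerOrigin = if (nrow(lina))
                as.vector(tapply(lina$umi, factor(lina$mol, levels = m1$mol),
                                 function(u) length(unique(u)),
                                 default = 0L))
            else integer(0),
            nUmiCollisions = nrow(lina) - length(unique(lina$umi)),
            nSurvivors = nrow(sva),
            survivorsPerOrigin = svPerOrigin,
            meanSurvivorsPerOrigin = if (nrow(m1)) nrow(sva) / nrow(m1) else NA_real_,
            nReads = sum(seqd$readMap$assay == a)
        )
    }
    out <- list(reads = seqd$reads, truth = truth, readMap = seqd$readMap,
                lineages = prods@lineages, survivors = surv@lineages,
                molecules = mols)
    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        writeFastq(out$reads, file.path(outDir, "reads.fastq"))
        jtruth <- truth
        jtruth$assays <- lapply(truth$assays, function(x) {
            u <- x$umisPerOrigin
            x$lineagesPerOrigin <- NULL
            x$survivorsPerOrigin <- NULL
            x$umisPerOrigin <- if (length(u))
                list(min = min(u), mean = mean(u), max = max(u))
            else list(min = NA, mean = NA, max = NA)
            x
        })
        jsonlite::write_json(jtruth, file.path(outDir, "truth.json"),
                             auto_unbox = TRUE, digits = NA, dataframe = "rows")
        return(invisible(out))
    }
    out
}
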