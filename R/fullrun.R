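#' @include simulate.R pipeline.R quantstats.R
NULL

#' End-to-end simulated run: simulate, correct, quantify
#'
#' Chains [simulateRun()], [runPipeline()] and the quantification layer
#' under one seed, then scores recovery against the simulation ground
#' truth. The returned summary carries every headline quantity of a
#' digital-sequencing experiment: UMI multiplicities per origin, surviving
#' lineages per origin, raw and consensus mean error rates, the error
#' correction factor, consensus reads and molecule counts per assay, and
#' per-variant estimated versus realized mutant allele frequencies.
#'
#' @param config a [SimConfig-class]
#' @param panel a [Panel-class]
#' @param outDir optional output directory; if given, the FASTQ, truth
#'   JSON, per-assay raw/consensus count-matrix TSVs and the run summary
#'   JSON are written there.
#' @param minReads,consensusFraction,umiClusterDist pipeline parameters,
#'   see [runPipeline()].
#' @return list: `sim` (simulation output), `pipeline`
#'   ([PipelineResult-class]) and `summary` (the quantities above).
#' @export
fullRun <- function(config, panel, outDir = NULL, minReads = NULL,
                    consensusFraction = 0.6, umiClusterDist = 1L) {
    sim <- simulateRun(config, panel, outDir = outDir)
    res <- runPipeline(sim$reads, panel, minReads = minReads,
                       consensusFraction = consensusFraction,
                       umiClusterDist = umiClusterDist)
    strand <- config@strandedness
    cc <- consensusCounts(res)
    perAssay <- list()
    rawRates <- list(); consRates <- list()
    for (a in assayNamesPanel(panel)) {
        pp <- pileupPair(res, a)
        exc <- excludedOffsets(panel, a)
        rawRates[[a]] <- positionErrorRates(pp@raw, exc)
        consRates[[a]] <- positionErrorRates(pp@consensus, exc)
        ta <- sim$truth$assays[[a]]
        variants <- ta$variants
        if (nrow(variants)) {
            est <- lapply(seq_len(nrow(variants)), function(j)
                estimateMaf(pp@consensus, variants$offset[j],
                            variants$alt[j]))
            variants$estimatedMaf <- vapply(est, `[[`, numeric(1), "maf")
            variants$consensusCount <- vapply(est, `[[`, numeric(1), "count")
            variants$consensusCoverage <- vapply(est, `[[`, numeric(1), "coverage")
        }
        perAssay[[a]] <- list(
            consensusReads = unname(cc[a]),
            molecules = consensusToMolecules(unname(cc[a]), strand),
            trueMolecules = ta$nAfterRt,
            meanUmisPerOrigin = if (length(ta$umisPerOrigin))
                mean(ta$umisPerOrigin) else NA_real_,
            meanSurvivorsPerOrigin = ta$meanSurvivorsPerOrigin,
            rawMeanError = meanErrorRate(rawRates[[a]]),
            consensusMeanError = meanErrorRate(consRates[[a]]),
            variants = variants)
    }
    rawMean <- meanErrorRate(rawRates)
    consMean <- meanErrorRate(consRates)
    summary <- list(
        seed = config@seed,
        strandedness = strand,
        report = res$report,
        panelRawMeanError = rawMean,
        panelConsensusMeanError = consMean,
        errorCorrectionFactor = errorCorrectionFactor(rawMean, consMean),
        assays = perAssay)
    if (!is.null(outDir)) {
        for (a in assayNamesPanel(panel)) {
            pp <- pileupPair(res, a)
            writeCountMatrix(pp@raw, file.path(outDir, paste0(a, "_raw.tsv")))
            writeCountMatrix(pp@consensus,
                             file.path(outDir, paste0(a, "_consensus.tsv")))
        }
        jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                             auto_unbox = TRUE, digits = NA,
                             dataframe = "rows", force = TRUE)
    }
    list(sim = sim, pipeline = res, summary = summary)
}

# ---- thin command-line wrappers (used by inst/scripts/umiseq-cli.R) ----

# parse "--key value" pairs into a named list
.parseArgs <- function(args) {
    out <- list()
    i <- 1L
    while (i <= length(args)) {
        if (!startsWith(args[i], "--"))
            stop("unexpected argument: ", args[i])
        key <- sub("^--", "", args[i])
        if (i == length(args) || startsWith(args[i + 1L], "--")) {
            out[[key]] <- TRUE; i <- i + 1L
        } else {
            out[[key]] <- args[i + 1L]; i <- i + 2L
        }
    }
    out
}

.configFromJson <- function(path, seedOverride = NULL) {
    cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!is.null(seedOverride)) cfg$seed <- as.integer(seedOverride)
    if (!is.null(cfg$variants) && length(cfg$variants))
        cfg$variants <- as.data.frame(cfg$variants)
    else cfg$variants <- NULL
    do.call(SimConfig, Filter(Negate(is.null), cfg))
}

#' Command-line entry points
#'
#' Thin wrappers around [simulateRun()], [runPipeline()] and [fullRun()]
#' for the `umiseq-cli.R` script shipped in `inst/scripts/`. Each takes a
#' character vector of `--flag value` arguments and returns an exit code
#' (0 ok, 1 runtime error, 2 usage error).
#'
#' `cmdSimulate`: `--config <json> --panel <tsv> --out-dir <dir>
#' [--seed <int>]`. `cmdCorrect`: `--fastq <path> --panel <tsv>
#' --out-dir <dir> [--min-reads-per-umi 3] [--consensus-fraction 0.6]
#' [--umi-cluster-distance 1]`. `cmdStats`: `--raw <tsv> --consensus
#' <tsv> --out <json>`. `cmdFullRun`: `--config <json> --panel <tsv>
#' --out-dir <dir> [--seed <int>]`.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit code.
#' @name cli
NULL

#' @rdname cli
#' @export
cmdSimulate <- function(args) {
    a <- tryCatch(.parseArgs(args), error = function(e) e)
    if (inherits(a, "error") || is.null(a$config) || is.null(a$panel) ||
        is.null(a$`out-dir`)) {
        message("usage: simulate --config cfg.json --panel panel.tsv ",
                "--out-dir DIR [--seed INT]")
        return(2L)
    }
    tryCatch({
        panel <- readPanel(a$panel)
        config <- .configFromJson(a$config, a$seed)
        simulateRun(config, panel, outDir = a$`out-dir`)
        0L
    }, error = function(e) { message("error: ", conditionMessage(e)); 1L })
}

#' @rdname cli
#' @export
cmdCorrect <- function(args) {
    a <- tryCatch(.parseArgs(args), error = function(e) e)
    if (inherits(a, "error") || is.null(a$fastq) || is.null(a$panel) ||
        is.null(a$`out-dir`)) {
        message("usage: correct --fastq reads.fastq --panel panel.tsv ",
                "--out-dir DIR [--min-reads-per-umi 3] ",
                "[--consensus-fraction 0.6] [--umi-cluster-distance 1]")
        return(2L)
    }
    tryCatch({
        panel <- readPanel(a$panel)
        res <- runPipeline(a$fastq, panel,
                           minReads = if (!is.null(a$`min-reads-per-umi`))
                               as.integer(a$`min-reads-per-umi`) else NULL,
                           consensusFraction = if (!is.null(a$`consensus-fraction`))
                               as.numeric(a$`consensus-fraction`) else 0.6,
                           umiClusterDist = if (!is.null(a$`umi-cluster-distance`))
                               as.integer(a$`umi-cluster-distance`) else 1L)
        dir.create(a$`out-dir`, showWarnings = FALSE, recursive = TRUE)
        for (nm in names(res$pileups)) {
            pp <- res$pileups[[nm]]
            writeCountMatrix(pp@raw, file.path(a$`out-dir`, paste0(nm, "_raw.tsv")))
            writeCountMatrix(pp@consensus,
                             file.path(a$`out-dir`, paste0(nm, "_consensus.tsv")))
        }
        jsonlite::write_json(res$report,
                             file.path(a$`out-dir`, "report.json"),
                             auto_unbox = TRUE, digits = NA)
        0L
    }, error = function(e) { message("error: ", conditionMessage(e)); 1L })
}

#' @rdname cli
#' @export
cmdStats <- function(args) {
    a <- tryCatch(.parseArgs(args), error = function(e) e)
    if (inherits(a, "error") || is.null(a$raw) || is.null(a$consensus) ||
        is.null(a$out)) {
        message("usage: stats --raw raw.tsv --consensus cons.tsv --out out.json")
        return(2L)
    }
    tryCatch({
        raw <- readCountMatrix(a$raw)
        cons <- readCountMatrix(a$consensus)
        if (assayName(raw) != assayName(cons))
            stop("raw and consensus matrices describe different assays")
        rr <- positionErrorRates(raw)
        cr <- positionErrorRates(cons)
        rm <- meanErrorRate(rr); cm <- meanErrorRate(cr)
        out <- list(assay = assayName(raw),
                    rawMeanError = rm, consensusMeanError = cm,
                    errorCorrectionFactor = errorCorrectionFactor(rm, cm),
                    errorTypesRaw = classifyErrors(raw),
                    errorTypesConsensus = classifyErrors(cons))
        jsonlite::write_json(out, a$out, auto_unbox = TRUE, digits = NA)
        0L
    }, error = function(e) { message("error: ", conditionMessage(e)); 1L })
}

#' @rdname cli
#' @export
cmdFullRun <- function(args) {
    a <- tryCatch(.parseArgs(args), error = function(e) e)
    if (inherits(a, "error") || is.null(a$config) || is.null(a$panel) ||
        is.null(a$`out-dir`)) {
        message("usage: full-run --config cfg.json --panel panel.tsv ",
                "--out-dir DIR [--seed INT]")
        return(2L)
    }
    tryCatch({
        panel <- readPanel(a$panel)
        config <- .configFromJson(a$config, a$seed)
        fullRun(config, panel, outDir = a$`out-dir`)
        0L
    }, error = function(e) { message("error: ", conditionMessage(e)); 1L })
}
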