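# cache for simulation scenarios shared by several test blocks
.simCache <- new.env(parent = emptyenv())

cachedEval <- function(key, expr) {
    if (!exists(key, envir = .simCache, inherits = FALSE))
        assign(key, force(expr), envir = .simCache)
    get(key, envir = .simCache, inherits = FALSE)
}

# single-assay endpoint panel for the spike-in dilution series
spikePanel <- function() cachedEval("spikePanel",
    testPanel(nAssays = 1L, len = 150L, seed = 7L))

# one simulated spike-in replicate pushed through the consensus pipeline
spikeRun <- function(seed, nMol, fraction, altOffset = 70L) {
    panel <- spikePanel()
    ref <- ampliconSeq(panel, "A1")
    alt <- setdiff(NT, substr(ref, altOffset + 1L, altOffset + 1L))[1]
    variants <- if (fraction > 0)
        data.frame(assay = "A1", offset = altOffset, alt = alt,
                   fraction = fraction)
    else data.frame(assay = character(), offset = integer(),
                    alt = character(), fraction = numeric())
    cfg <- SimConfig(seed = seed, nMolecules = nMol,
                     strandedness = "single", variants = variants,
                     rtErrorRate = 0, polErrorRate = 3e-7,
                     seqErrorRate = 2e-3, meanReadsPerFamily = 6)
    sim <- simulateRun(cfg, panel)
    res <- runPipeline(sim$reads, panel)
    pp <- pileupPair(res, "A1")
    maf <- estimateMaf(pp@consensus, altOffset, alt)
    rawMaf <- estimateMaf(pp@raw, altOffset, alt)
    rawRates <- positionErrorRates(pp@raw)
    consRates <- positionErrorRates(pp@consensus)
    ta <- sim$truth$assays$A1
    list(maf = maf$maf, count = maf$count, coverage = maf$coverage,
         rawMaf = rawMaf$maf,
         realizedFraction = if (nrow(ta$variants))
             ta$variants$realizedFraction else 0,
         realizedCount = if (nrow(ta$variants)) ta$variants$realizedCount else 0L,
         nAfterRt = ta$nAfterRt,
         rawMean = meanErrorRate(rawRates),
         consMean = meanErrorRate(consRates),
         pileups = pp, report = runReport(res), truth = sim$truth)
}

cachedSpikeRun <- function(seed, nMol, fraction)
    cachedEval(sprintf("spike_%d_%d_%g", seed, nMol, fraction),
               spikeRun(seed, nMol, fraction))

# 5-assay low-error panel run (RT 5e-5) for the error-suppression bound
lowErrorPanelRun <- function(seed = 1L) cachedEval(
    paste0("lowerr_", seed), {
    panel <- testPanel(nAssays = 5L, len = 100L, seed = 11L)
    cfg <- SimConfig(seed = seed, nMolecules = 20000,
                     strandedness = "single", rtErrorRate = 5e-5,
                     polErrorRate = 3e-7, seqErrorRate = 2e-3,
                     meanReadsPerFamily = 6)
    sim <- simulateRun(cfg, panel)
    res <- runPipeline(sim$reads, panel)
    rawR <- list(); consR <- list()
    for (a in assayNamesPanel(panel)) {
        pp <- pileupPair(res, a)
        rawR[[a]] <- positionErrorRates(pp@raw)
        consR[[a]] <- positionErrorRates(pp@consensus)
    }
    list(panel = panel, sim = sim, res = res,
         rawMean = meanErrorRate(rawR), consMean = meanErrorRate(consR))
})
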