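#' @include panel.R
NULL

#' Simulation configuration
#'
#' Parameters of the generative library simulator. Defaults are anchored to
#' the protocol this package models: 3 barcoding cycles, a one-third
#' dilution into a 30-cycle adapter PCR, a high-fidelity polymerase
#' (substitution rate 3e-7 per base per synthesis event, >300-fold better
#' than standard Taq at about 1e-4), and reverse-transcriptase fidelity in
#' the published 9e-5 to 1e-4 range. The sequencing substitution rate is a
#' free parameter (no instrument value is modelled); its default of 2e-3
#' per base is a typical short-read figure.
#'
#' @slot seed master RNG seed; a fixed seed gives bit-identical output.
#' @slot nMolecules named integer vector of template molecules per assay
#'   (or a single value recycled over the panel).
#' @slot strandedness `"single"` (RNA/cDNA workflow) or `"double"`
#'   (genomic DNA).
#' @slot variants data.frame with columns `assay`, `offset` (0-based
#'   amplicon offset), `alt`, `fraction`: spike-in variant design.
#' @slot rtErrorRate substitutions per base during reverse transcription
#'   (applied once, single-stranded workflow only).
#' @slot rtEfficiency fraction of RNA molecules converted to cDNA.
#' @slot barcodeCycles barcoding PCR cycles (default 3).
#' @slot barcodeEfficiency per-strand per-cycle copy probability
#'   (default 1; at 1 every ss molecule yields exactly 3 UMI lineages and
#'   every ds molecule exactly 6).
#' @slot polErrorRate polymerase substitutions per base per synthesis event.
#' @slot dilutionFraction fraction of barcoded products loaded into the
#'   adapter PCR (default 1/3).
#' @slot adapterCycles adapter PCR cycles (default 30).
#' @slot jackpotCycles number of early adapter cycles simulated as an
#'   explicit doubling tree so that shared ("jackpot") polymerase errors
#'   can survive consensus (default 3).
#' @slot meanReadsPerFamily Poisson mean of sequenced reads per UMI lineage.
#' @slot seqErrorRate sequencing substitutions per base per read.
#' @slot indelRate optional single-base deletion/insertion rate per base
#'   per read at the sequencing step (default 0).
#' @slot phred constant Phred quality emitted for every base.
#' @export
setClass("SimConfig", representation(
    seed = "integer",
    nMolecules = "numeric",
    strandedness = "character",
    variants = "data.frame",
    rtErrorRate = "numeric",
    rtEfficiency = "numeric",
    barcodeCycles = "integer",
    barcodeEfficiency = "numeric",
    polErrorRate = "numeric",
    dilutionFraction = "numeric",
    adapterCycles = "integer",
    jackpotCycles = "integer",
    meanReadsPerFamily = "numeric",
    seqErrorRate = "numeric",
    indelRate = "numeric",
    phred = "integer"
))

setValidity("SimConfig", function(object) {
    msg <- character()
    rates <- c(rtErrorRate = object@rtErrorRate,
               rtEfficiency = object@rtEfficiency,
               barcodeEfficiency = object@barcodeEfficiency,
               polErrorRate = object@polErrorRate,
               dilutionFraction = object@dilutionFraction,
               seqErrorRate = object@seqErrorRate,
               indelRate = object@indelRate)
    bad <- names(rates)[rates < 0 | rates > 1]
    if (length(bad)) msg <- c(msg, paste("rates must be in [0,1]:",
                                         paste(bad, collapse = ", ")))
    if (!object@strandedness %in% c("single", "double"))
        msg <- c(msg, "strandedness must be 'single' or 'double'")
    if (any(object@nMolecules < 0)) msg <- c(msg, "nMolecules must be >= 0")
    if (object@barcodeCycles < 0L || object@adapterCycles < 0L ||
        object@jackpotCycles < 0L)
        msg <- c(msg, "cycle counts must be >= 0")
    if (object@jackpotCycles > object@adapterCycles)
        msg <- c(msg, "jackpotCycles cannot exceed adapterCycles")
    if (object@meanReadsPerFamily < 0) msg <- c(msg, "meanReadsPerFamily must be >= 0")
    v <- object@variants
    if (nrow(v)) {
        if (!all(c("assay", "offset", "alt", "fraction") %in% names(v)))
            msg <- c(msg, "variants needs columns assay, offset, alt, fraction")
        else {
            if (any(v$fraction < 0 | v$fraction > 1))
                msg <- c(msg, "variant fractions must be in [0,1]")
            tot <- tapply(v$fraction, paste(v$assay, v$offset), sum)
            if (any(tot > 1 + 1e-12))
                msg <- c(msg, "variant fractions per position must sum to <= 1")
            if (!all(v$alt %in% c("A", "C", "G", "T")))
                msg <- c(msg, "variant alt bases must be A/C/G/T")
        }
    }
    if (length(msg)) msg else TRUE
})

#' @rdname SimConfig-class
#' @param seed,nMolecules,strandedness,variants,rtErrorRate,rtEfficiency
#'   see slots.
#' @param barcodeCycles,barcodeEfficiency,polErrorRate,dilutionFraction
#'   see slots.
#' @param adapterCycles,jackpotCycles,meanReadsPerFamily,seqErrorRate see
#'   slots.
#' @param indelRate,phred see slots.
#' @return a validated `SimConfig`.
#' @export
SimConfig <- function(seed = 1L, nMolecules = 1000, strandedness = "single",
                      variants = data.frame(assay = character(),
                                            offset = integer(),
                                            alt = character(),
                                            fraction = numeric()),
                      rtErrorRate = 1e-4, rtEfficiency = 1,
                      barcodeCycles = 3L, barcodeEfficiency = 1,
                      polErrorRate = 3e-7, dilutionFraction = 1 / 3,
                      adapterCycles = 30L, jackpotCycles = 3L,
                      meanReadsPerFamily = 6, seqErrorRate = 2e-3,
                      indelRate = 0, phred = 30L) {
    new("SimConfig", seed = as.integer(seed), nMolecules = nMolecules,
        strandedness = strandedness, variants = variants,
        rtErrorRate = rtErrorRate, rtEfficiency = rtEfficiency,
        barcodeCycles = as.integer(barcodeCycles),
        barcodeEfficiency = barcodeEfficiency, polErrorRate = polErrorRate,
        dilutionFraction = dilutionFraction,
        adapterCycles = as.integer(adapterCycles),
        jackpotCycles = as.integer(jackpotCycles),
        meanReadsPerFamily = meanReadsPerFamily, seqErrorRate = seqErrorRate,
        indelRate = indelRate, phred = as.integer(phred))
}

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig (seed ", object@seed, ", ", object@strandedness,
        "-stranded)\n", sep = "")
    cat("  molecules/assay:", paste(object@nMolecules, collapse = ","),
        " spike-in variants:", nrow(object@variants), "\n")
    cat("  RT err", object@rtErrorRate, "eff", object@rtEfficiency,
        "| pol err", object@polErrorRate,
        "| seq err", object@seqErrorRate, "\n")
    cat("  cycles: barcode", object@barcodeCycles,
        "(eff", object@barcodeEfficiency, ") adapter", object@adapterCycles,
        "(jackpot", object@jackpotCycles, ") dilution",
        signif(object@dilutionFraction, 4),
        "| reads/family", object@meanReadsPerFamily, "\n")
})

# echo all slots as a plain list (for truth/report serialization)
configAsList <- function(config) {
    sn <- methods::slotNames(class(config))
    out <- lapply(sn, function(s) {
        v <- slot(config, s)
        if (is.data.frame(v)) v else unname(v)
    })
    names(out) <- sn
    out$nMolecules <- slot(config, "nMolecules")
    out
}
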