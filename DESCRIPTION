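Package: umiseq
Title: Digital RNA and DNA Sequencing with Unique Molecular Identifiers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of targeted amplicon deep sequencing
    with unique molecular identifiers (UMIs). Provides a generative
    simulator of the two-step barcoded-library process (reverse
    transcription, 3-cycle UMI barcoding PCR, one-third dilution, adapter
    PCR, sequencing) with full ground truth; a UMI consensus
    error-correction pipeline (UMI extraction, amplicon assignment,
    directional UMI clustering, plurality consensus with a minimum-family
    cutoff, raw and consensus pileups); and the quantification statistics
    of digital sequencing: per-position and mean error rates, error
    correction factors, strand-aware molecule counting, input-mass
    normalization, coefficients of variation, mutant allele frequency
    estimation with replicate significance testing, error-type profiles,
    dilution linearity and plasma normalization.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    rtracklayer,
    data.table,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'RcppExports.R'
    'umiseq-package.R'
    'panel.R'
    'countmatrix.R'
    'io.R'
    'pipeline.R'
    'quantstats.R'
    'simconfig.R'
    'simulate.R'
    'fullrun.R'
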