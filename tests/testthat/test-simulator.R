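test_that("spike-in design is realized by binomial draws", {
    p <- testPanel(len = 40L)
    alt <- setdiff(NT, substr(ampliconSeq(p, "A1"), 6, 6))[1]
    mkcfg <- function(frac, n = 2000) SimConfig(
        seed = 11L, nMolecules = n, strandedness = "single",
        variants = data.frame(assay = "A1", offset = 5L, alt = alt,
                              fraction = frac))
    set.seed(11)
    ms <- makeMolecules(mkcfg(0.05), p)
    k <- sum(ms@devs$origin == "variant")
    # Binomial(2000, 0.05): mean 100, 4 sigma ~ 39
    expect_true(abs(k - 100) < 4 * sqrt(2000 * 0.05 * 0.95))
    set.seed(1); expect_equal(nrow(makeMolecules(mkcfg(0), p)@devs), 0L)
    set.seed(1); expect_equal(nrow(makeMolecules(mkcfg(1), p)@devs), 2000L)
    # offset outside the amplicon is a hard error
    bad <- SimConfig(seed = 1L, nMolecules = 10,
                     variants = data.frame(assay = "A1", offset = 40L,
                                           alt = "A", fraction = 0.1))
    expect_error(makeMolecules(bad, p), "offset")
})

test_that("reverse transcription obeys its binomial error and retention oracles", {
    p <- testPanel(len = 150L)
    n <- 20000L
    cfg0 <- SimConfig(seed = 3L, nMolecules = n, rtErrorRate = 0,
                      rtEfficiency = 1)
    set.seed(3)
    ms <- makeMolecules(cfg0, p)
    out <- reverseTranscribe(ms, cfg0, p)
    expect_equal(nrow(out@molecules), n)        # identity when rates are 0/1
    expect_equal(nrow(out@devs), 0L)
    expect_true(all(out@molecules$type == "cDNA"))

    cfg1 <- SimConfig(seed = 4L, nMolecules = n, rtErrorRate = 1e-3,
                      rtEfficiency = 1)
    set.seed(4)
    out1 <- reverseTranscribe(makeMolecules(cfg1, p), cfg1, p)
    lam <- n * 150 * 1e-3                        # Binomial mean 3000
    expect_true(abs(nrow(out1@devs) - lam) < 4 * sqrt(lam))
    expect_true(all(out1@devs$origin == "rt"))
    # substituted bases differ from the reference
    refc <- strsplit(ampliconSeq(p, "A1"), "")[[1]]
    expect_true(all(out1@devs$base != refc[out1@devs$pos]))

    cfg2 <- SimConfig(seed = 5L, nMolecules = n, rtEfficiency = 0.5)
    set.seed(5)
    out2 <- reverseTranscribe(makeMolecules(cfg2, p), cfg2, p)
    expect_true(abs(nrow(out2@molecules) - n / 2) < 4 * sqrt(n * 0.25))
})

test_that("barcoding yields exactly 3 UMIs per ss and 6 per ds origin at full efficiency", {
    p <- testPanel(len = 30L)
    for (seed in 1:3) {
        for (strand in c("single", "double")) {
            cfg <- SimConfig(seed = seed, nMolecules = 50,
                             strandedness = strand, rtErrorRate = 0)
            set.seed(seed)
            ms <- reverseTranscribe(makeMolecules(cfg, p), cfg, p)
            bp <- barcodePcr(ms, cfg, p)
            perOrigin <- table(bp@lineages$mol)
            expected <- if (strand == "single") 3L else 6L
            expect_true(all(perOrigin == expected))
            # UMIs within an origin are distinct (fresh draw per founding)
            distinct <- tapply(bp@lineages$umi, bp@lineages$mol,
                               function(u) length(unique(u)))
            expect_true(all(distinct == expected))
        }
    }
    # efficiency 0: no products
    cfg0 <- SimConfig(seed = 1L, nMolecules = 50, barcodeEfficiency = 0)
    set.seed(1)
    ms <- reverseTranscribe(makeMolecules(cfg0, p), cfg0, p)
    expect_equal(nrow(barcodePcr(ms, cfg0, p)@lineages), 0L)
})

test_that("dilution keeps each lineage independently and hits the 1 (ss) / 2 (ds) expectation", {
    p <- testPanel(len = 30L)
    n <- 100000L
    for (strand in c("single", "double")) {
        cfg <- SimConfig(seed = 21L, nMolecules = n, strandedness = strand,
                         rtErrorRate = 0)
        set.seed(21)
        ms <- reverseTranscribe(makeMolecules(cfg, p), cfg, p)
        bp <- barcodePcr(ms, cfg, p)
        sv <- diluteProducts(bp, cfg)
        lper <- if (strand == "single") 3 else 6
        expect_equal(nrow(bp@lineages), n * lper)
        mean_surv <- nrow(sv@lineages) / n
        expected <- lper / 3
        sigma <- sqrt(lper * (1 / 3) * (2 / 3) / n)
        expect_true(abs(mean_surv - expected) < 4 * sigma)
    }
    cfg <- SimConfig(seed = 1L, nMolecules = 100, dilutionFraction = 1)
    set.seed(1)
    bp <- barcodePcr(reverseTranscribe(makeMolecules(cfg, p), cfg, p), cfg, p)
    expect_equal(nrow(diluteProducts(bp, cfg)@lineages), nrow(bp@lineages))
    cfg0 <- SimConfig(seed = 1L, nMolecules = 100, dilutionFraction = 0)
    expect_equal(nrow(diluteProducts(bp, cfg0)@lineages), 0L)
})

test_that("sequencing emits Poisson family depths and error-free reads when rates are zero", {
    p <- testPanel(len = 40L)
    cfg <- SimConfig(seed = 31L, nMolecules = 350, rtErrorRate = 0,
                     polErrorRate = 0, seqErrorRate = 0,
                     meanReadsPerFamily = 6, dilutionFraction = 1)
    set.seed(31)
    sim <- simulateRun(cfg, p)
    nFam <- sim$truth$assays$A1$nSurvivors
    expect_equal(nFam, 350L * 3L)
    lam <- nFam * 6
    expect_true(abs(length(sim$reads) - lam) < 4 * sqrt(lam))
    # with all error rates zero every insert equals the reference
    ins <- substr(as.character(sim$reads), 12 + nchar(anchorSeq(p)) + 1L,
                  nchar(as.character(sim$reads)))
    expect_true(all(ins == ampliconSeq(p, "A1")))
})

test_that("per-base read error frequency scales with adapter cycles when jackpot is off", {
    p <- testPanel(len = 100L)
    e <- 2e-4
    cfg <- SimConfig(seed = 41L, nMolecules = 1500, rtErrorRate = 0,
                     polErrorRate = e, seqErrorRate = 0, jackpotCycles = 0L,
                     adapterCycles = 30L, meanReadsPerFamily = 3)
    set.seed(41)
    sim <- simulateRun(cfg, p)
    U <- umiLength(p); A <- nchar(anchorSeq(p))
    sq <- as.character(sim$reads)
    ins <- substr(sq, U + A + 1L, nchar(sq))
    nerr <- sum(umiseq:::cpp_hamming(ins, ampliconSeq(p, "A1")))
    tot <- sum(nchar(ins))
    pexp <- 1 - (1 - e)^30                       # ~ 30 e
    expect_true(abs(nerr - tot * pexp) < 4 * sqrt(tot * pexp))
})

test_that("simulated runs are seed-reproducible and seed-sensitive", {
    p <- testPanel(nAssays = 2L, len = 30L)
    cfg <- SimConfig(seed = 99L, nMolecules = 150)
    s1 <- simulateRun(cfg, p)
    s2 <- simulateRun(cfg, p)
    expect_identical(as.character(s1$reads), as.character(s2$reads))
    expect_identical(s1$truth, s2$truth)
    cfg2 <- SimConfig(seed = 100L, nMolecules = 150)
    s3 <- simulateRun(cfg2, p)
    expect_false(identical(as.character(s1$reads), as.character(s3$reads)))
    # double-stranded truth reports 6 UMIs per origin pre-dilution
    cfgd <- SimConfig(seed = 5L, nMolecules = 100, strandedness = "double")
    sd1 <- simulateRun(cfgd, p)
    expect_true(all(sd1$truth$assays$A1$umisPerOrigin == 6L))
    # every emitted read maps to exactly one barcoded product
    expect_true(all(sd1$readMap$lineage %in% sd1$survivors$lineage))
    expect_equal(nrow(sd1$readMap), length(sd1$reads))
})

test_that("simulateRun writes FASTQ plus truth JSON deterministically", {
    p <- testPanel(len = 25L)
    d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
    cfg <- SimConfig(seed = 8L, nMolecules = 60)
    simulateRun(cfg, p, outDir = d1)
    simulateRun(cfg, p, outDir = d2)
    expect_identical(readLines(file.path(d1, "reads.fastq")),
                     readLines(file.path(d2, "reads.fastq")))
    tr <- jsonlite::read_json(file.path(d1, "truth.json"),
                              simplifyVector = TRUE)
    expect_equal(tr$params$seed, 8L)
    expect_true("A1" %in% names(tr$assays))
})
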