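mkmat <- function(ref, level = "consensus", fill = 0L) {
    m <- matrix(0L, nchar(ref), 7,
                dimnames = list(NULL, c("A", "C", "G", "T", "N", "del", "ins")))
    refc <- strsplit(ref, "")[[1]]
    m[cbind(seq_along(refc), match(refc, c("A", "C", "G", "T")))] <- fill
    list(m = m, refc = refc)
}

test_that("per-position error rates follow the non-reference/coverage formula", {
    ref <- "ACGTACGTAC"
    x <- mkmat(ref, fill = 1000L)
    # position 1 (ref A): A:997, G:2, del:1 -> e = 3/1000
    x$m[1, "A"] <- 997L; x$m[1, "G"] <- 2L; x$m[1, "del"] <- 1L
    cm <- CountMatrix("A1", ref, counts = x$m, level = "consensus")
    rates <- positionErrorRates(cm)
    expect_equal(rates$errorRate[1], 0.003)
    expect_true(all(rates$errorRate[-1] == 0))     # all-reference positions
    # insertions count as non-reference at their anchor position
    x$m[5, "ins"] <- 10L
    cm <- CountMatrix("A1", ref, counts = x$m, level = "consensus")
    expect_equal(positionErrorRates(cm)$errorRate[5], 10 / 1000)
    # excluded SNP position omitted from the report
    x$m[3, "T"] <- 500L; x$m[3, match(x$refc[3], NT)] <- 500L
    cm <- CountMatrix("A1", ref, counts = x$m, level = "consensus")
    rates <- positionErrorRates(cm, excluded = 2L)  # 0-based offset of pos 3
    expect_false(rates$included[3])
    expect_true(is.na(rates$errorRate[3]))
})

test_that("mean error rate is the unweighted mean over included positions", {
    df <- data.frame(errorRate = c(0.001, rep(0, 9)),
                     included = rep(TRUE, 10))
    expect_equal(meanErrorRate(df), 1e-4)
    expect_equal(meanErrorRate(data.frame(errorRate = 0, included = TRUE)), 0)
    expect_equal(meanErrorRate(data.frame(errorRate = 0.42,
                                          included = TRUE)), 0.42)
    # panel scope pools positions across assays, unweighted
    a <- data.frame(errorRate = c(0.01, 0.01), included = c(TRUE, TRUE))
    b <- data.frame(errorRate = 0.04, included = TRUE)
    expect_equal(meanErrorRate(list(a, b)), 0.02)
})

test_that("error-correction factor is raw/consensus, undefined at zero consensus error", {
    expect_equal(errorCorrectionFactor(1e-3, 1e-5), 100)
    expect_equal(errorCorrectionFactor(5e-4, 5e-4), 1)
    expect_true(is.na(errorCorrectionFactor(1e-3, 0)))
    # consistency: raw == F * consensus whenever defined
    set.seed(20)
    for (i in 1:20) {
        raw <- runif(1, 1e-5, 1e-2); cons <- runif(1, 1e-7, 1e-3)
        expect_equal(errorCorrectionFactor(raw, cons) * cons, raw)
    }
})

test_that("consensus reads convert to molecules by strandedness", {
    expect_equal(consensusToMolecules(22400, "double"), 11200)
    expect_equal(consensusToMolecules(100, "single"), 100)
    expect_equal(consensusToMolecules(0, "double"), 0)
})

test_that("yield normalization scales counts to the reference input mass", {
    expect_equal(normalizeYield(100, 50, 200), 400)   # factor of four
    expect_equal(normalizeYield(100, 200, 200), 100)
    expect_equal(normalizeYield(100, 100, 200), 200)
    expect_error(normalizeYield(100, 0), "loadedNg")
})

test_that("replicate CV is 100*sd/mean with degenerate flagging", {
    expect_equal(replicateCv(c(10, 10, 10)), 0)
    expect_equal(replicateCv(c(8, 10, 12)), 20)       # sd 2, mean 10
    expect_warning(v <- replicateCv(5), "undefined")
    expect_true(is.na(v))
})

test_that("MAF estimation divides variant by total consensus reads", {
    ref <- strrep("A", 5)
    x <- mkmat(ref, fill = 100000L)
    x$m[3, "G"] <- 78L; x$m[3, "A"] <- 100000L - 78L
    cm <- CountMatrix("A1", ref, counts = x$m, level = "consensus")
    expect_equal(estimateMaf(cm, 2L, "G")$maf, 0.00078)
    expect_equal(estimateMaf(cm, 1L, "G")$maf, 0)
    x$m[5, "T"] <- 100000L; x$m[5, "A"] <- 0L
    cm <- CountMatrix("A1", ref, counts = x$m, level = "consensus")
    expect_equal(estimateMaf(cm, 4L, "T")$maf, 1)
})

test_that("the replicate t-test separates clear spike-ins and flags degenerate arms", {
    case <- c(0.0008, 0.0007, 0.0009)
    control <- c(0.00001, 0, 0.00002)
    tt <- testVariant(case, control)
    expect_false(tt$degenerate)
    expect_lt(tt$p.value, 0.01)
    # identical arms: non-significant
    same <- testVariant(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3))
    expect_gt(same$p.value, 0.9)
    # both arms all-zero: degenerate, flagged, no crash
    zz <- testVariant(c(0, 0, 0), c(0, 0, 0))
    expect_true(zz$degenerate)
    expect_equal(zz$p.value, 1)
})

test_that("the panel-wide two-way ANOVA flags only the variant position", {
    set.seed(21)
    P <- 10L
    control <- matrix(abs(rnorm(P * 3, 1e-4, 3e-5)), P, 3)
    case <- matrix(abs(rnorm(P * 3, 1e-4, 3e-5)), P, 3)
    case[4, ] <- case[4, ] + 8e-4                     # spiked position
    out <- testVariantPanel(case, control)
    expect_true(out$comparisons$significant[4])
    expect_false(any(out$comparisons$significant[-4]))
    expect_true(all(out$comparisons$pSidak >= out$comparisons$p - 1e-12))
})

test_that("binomial background test behaves as a one-sided exceedance test", {
    expect_equal(testVariantBinomial(0, 1000, 1e-3), 1)
    expect_lt(testVariantBinomial(10, 1000, 1e-3), 1e-5)
    expect_equal(testVariantBinomial(1, 1000, 0), 0)
})

test_that("error classification bins transitions, transversions and indels", {
    ref <- "AACC"
    x <- mkmat(ref, fill = 100L)
    x$m[1, "G"] <- 5L; x$m[1, "A"] <- 95L    # A->G transition
    x$m[2, "T"] <- 3L; x$m[2, "A"] <- 97L    # A->T transversion
    x$m[3, "T"] <- 2L; x$m[3, "C"] <- 98L    # C->T transition
    x$m[4, "del"] <- 4L; x$m[4, "C"] <- 96L
    x$m[2, "ins"] <- 6L
    cm <- CountMatrix("A1", ref, counts = x$m, level = "raw")
    cls <- classifyErrors(cm)
    expect_equal(cls$transition, 7 / 400)
    expect_equal(cls$transversion, 3 / 400)
    expect_equal(cls$deletion, 4 / 400)
    expect_equal(cls$insertion, 6 / 400)
    # conservation: bins partition all non-reference events
    expect_equal(cls$transition + cls$transversion + cls$deletion +
                     cls$insertion + cls$other, cls$overall)
    rates <- positionErrorRates(cm)
    pooled <- sum(rates$nonref) / sum(rates$coverage)
    expect_equal(cls$overall, pooled)
})

test_that("bin conservation holds on simulated pileups", {
    run <- lowErrorPanelRun()
    for (a in assayNamesPanel(run$panel)) {
        pp <- pileupPair(run$res, a)
        for (mat in list(pp@raw, pp@consensus)) {
            cls <- classifyErrors(mat)
            rates <- positionErrorRates(mat)
            pooled <- sum(rates$nonref[rates$included]) /
                sum(rates$coverage[rates$included])
            expect_equal(cls$transition + cls$transversion + cls$deletion +
                             cls$insertion + cls$other, pooled)
        }
    }
})

test_that("error-profile correlation recovers rank structure", {
    a <- c(0.001, 0.002, 0.0005, 0.004, 0.003, 0.0011, 0.0021)
    expect_equal(errorProfileCorrelation(a, a)$rho, 1)
    expect_equal(errorProfileCorrelation(a, -a)$rho, -1)
    const <- errorProfileCorrelation(a, rep(1e-3, length(a)))
    expect_false(const$defined)
    # independent profiles are usually uncorrelated (property over seeds)
    set.seed(22)
    hits <- 0L
    for (i in 1:20) {
        x <- runif(50); y <- runif(50)
        ct <- errorProfileCorrelation(x, y)
        if (abs(ct$rho) > 0.5) hits <- hits + 1L
    }
    expect_lte(hits, 1L)
})

test_that("dilution linearity fits the lowest amounts and flags saturation", {
    loaded <- c(8.75, 17.5, 35, 70, 140)
    prop <- 100 * loaded
    fit <- dilutionLinearity(loaded, prop)
    expect_equal(fit$r.squared, 1)
    expect_equal(fit$slope, 100)
    expect_lt(abs(fit$intercept), 1e-9)
    expect_false(fit$saturated)
    # top point halved: saturation detected
    sat <- prop; sat[5] <- sat[5] / 2
    expect_true(dilutionLinearity(loaded, sat)$saturated)
    # constant counts: slope 0
    expect_equal(dilutionLinearity(loaded, rep(50, 5))$slope, 0)
    expect_error(dilutionLinearity(c(1, 2, 3), c(1, 2, 3)), "distinct")
})

test_that("plasma normalization accounts for volume and carried fractions", {
    expect_equal(moleculesPerMlPlasma(1000, 1), 1000)
    expect_equal(moleculesPerMlPlasma(1000, 2, 0.5, 1), 1000)
    expect_equal(moleculesPerMlPlasma(0, 3, 0.2, 0.4), 0)
    expect_error(moleculesPerMlPlasma(10, 0), "volume")
})
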