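#' @include pipeline.R
NULL

#' Per-position error rates of a count matrix
#'
#' The error rate at a nucleotide position is the number of non-reference
#' reads divided by the total number of reads at that position; insertion
#' events are counted as non-reference at their left-anchor position while
#' coverage remains the denominator. Positions on the exclusion list
#' (known SNPs, pseudogene homology, RNA-editing sites) and positions with
#' zero coverage are omitted from the report (flagged `included = FALSE`,
#' rate `NA`).
#'
#' @param mat a [CountMatrix-class]
#' @param excluded integer vector of 0-based excluded amplicon offsets
#'   (e.g. [excludedOffsets()]).
#' @return data.frame: `assay`, `level`, `pos` (1-based), `ref`,
#'   `coverage`, `nonref`, `ins`, `errorRate`, `included`.
#' @export
positionErrorRates <- function(mat, excluded = integer(0)) {
    cov <- coverage(mat)
    cnt <- counts(mat)
    refc <- refBases(mat)
    refCount <- cnt[cbind(seq_along(refc),
                          match(refc, colnames(cnt), nomatch = 5L))]
    nonref <- cov - refCount + cnt[, "ins"]
    rate <- ifelse(cov > 0, nonref / cov, NA_real_)
    included <- cov > 0
    if (length(excluded)) included[excluded + 1L] <- FALSE
    rate[!included] <- NA_real_
    data.frame(assay = assayName(mat), level = countLevel(mat),
               pos = seq_along(cov), ref = refc, coverage = cov,
               nonref = as.integer(nonref), ins = cnt[, "ins"],
               errorRate = rate, included = included,
               stringsAsFactors = FALSE)
}

#' Mean error rate over included positions
#'
#' Unweighted arithmetic mean of the per-position error rates over all
#' included positions of one assay or of a whole panel (a list of
#' per-assay reports is pooled position-wise, not averaged per assay).
#'
#' @param rates a data.frame from [positionErrorRates()] or a list of
#'   them.
#' @return the mean rate; `NA` (with a warning) when no position is
#'   included.
#' @export
meanErrorRate <- function(rates) {
    if (is.data.frame(rates)) rates <- list(rates)
    r <- unlist(lapply(rates, function(x) x$errorRate[x$included]))
    if (!length(r)) {
        warning("no included positions; mean error rate undefined")
        return(NA_real_)
    }
    mean(r)
}

#' Error-correction factor
#'
#' Ratio between the mean error rate of raw reads and of consensus reads.
#' When no consensus errors were detected the factor cannot be calculated
#' and `NA` is returned (the undefined flag).
#'
#' @param rawMean,consensusMean mean error rates (raw, consensus).
#' @return the factor, or `NA` when undefined.
#' @export
errorCorrectionFactor <- function(rawMean, consensusMean) {
    stopifnot(rawMean >= 0, consensusMean >= 0)
    ifelse(consensusMean > 0, rawMean / consensusMean, NA_real_)
}

#' Convert consensus reads to molecules
#'
#' One consensus read corresponds to one cDNA molecule (single-stranded
#' template), while two consensus reads correspond to one genomic DNA
#' molecule (double-stranded template: each strand founds its own UMI
#' lineages).
#'
#' @param consensusCount number of consensus reads.
#' @param strandedness `"single"` or `"double"`.
#' @return molecule count.
#' @export
consensusToMolecules <- function(consensusCount, strandedness) {
    stopifnot(all(consensusCount >= 0))
    strandedness <- match.arg(strandedness, c("single", "double"))
    consensusCount / if (strandedness == "double") 2 else 1
}

#' Normalize a yield for loaded input mass
#'
#' Scales a molecule or consensus-read count to a common reference input
#' mass: `count * referenceNg / loadedNg` (e.g. a factor of four for 50 ng
#' loaded against a 200 ng reference).
#'
#' @param count observed count.
#' @param loadedNg loaded input mass (ng), must be > 0.
#' @param referenceNg reference input mass (ng), default 200.
#' @return the scaled count.
#' @export
normalizeYield <- function(count, loadedNg, referenceNg = 200) {
    if (any(loadedNg <= 0)) stop("loadedNg must be > 0")
    count * referenceNg / loadedNg
}

#' Coefficient of variation across replicates
#'
#' @param counts numeric vector of replicate measurements.
#' @return 100 * sample standard deviation / mean (percent); `NA` with a
#'   warning for fewer than two replicates or a zero mean.
#' @export
replicateCv <- function(counts) {
    if (length(counts) < 2L || mean(counts) == 0) {
        warning("CV undefined: need >= 2 replicates and nonzero mean")
        return(NA_real_)
    }
    100 * sd(counts) / mean(counts)
}

#' Estimate a mutant allele frequency from a consensus pileup
#'
#' MAF = variant consensus reads / total consensus reads at the position.
#'
#' @param mat a consensus-level [CountMatrix-class]
#' @param offset 0-based amplicon offset of the variant.
#' @param alt alternative base (`A`/`C`/`G`/`T`) or `"del"`.
#' @return list: `count`, `coverage`, `maf` (`NA` at zero coverage).
#' @export
estimateMaf <- function(mat, offset, alt) {
    pos <- offset + 1L
    stopifnot(pos >= 1L, pos <= nrow(counts(mat)), alt %in% COUNT_COLS)
    cov <- unname(coverage(mat)[pos])
    cnt <- unname(counts(mat)[pos, alt])
    list(count = as.integer(cnt), coverage = as.integer(cov),
         maf = if (cov > 0) cnt / cov else NA_real_)
}

#' Replicate significance test for a variant
#'
#' Unpaired two-sample Student's t-test of per-replicate variant measures
#' (MAFs or counts) in case versus control samples. Degenerate designs
#' (identical zero-variance arms) are flagged and return p = 1 rather
#' than failing.
#'
#' @param case,control numeric vectors of per-replicate values (>= 2
#'   each).
#' @return list: `statistic`, `p.value`, `df`, `degenerate`, `method`.
#' @export
testVariant <- function(case, control) {
    stopifnot(length(case) >= 2L, length(control) >= 2L)
    if (sd(case) == 0 && sd(control) == 0) {
        same <- isTRUE(all.equal(mean(case), mean(control)))
        return(list(statistic = NA_real_,
                    p.value = if (same) 1 else NA_real_,
                    df = NA_real_, degenerate = TRUE,
                    method = "unpaired Student's t-test (degenerate)"))
    }
    tt <- t.test(case, control, var.equal = TRUE)
    list(statistic = unname(tt$statistic), p.value = tt$p.value,
         df = unname(tt$parameter), degenerate = FALSE,
         method = "unpaired Student's t-test")
}

#' Panel-wide variant screen: two-way ANOVA with Sidak correction
#'
#' Fits a two-way fixed-effects ANOVA (position x condition with
#' interaction) to per-replicate, per-position measures (typically MAFs or
#' error rates) of case and control samples, then performs per-position
#' case-vs-control comparisons using the pooled residual error, adjusting
#' p-values with the Sidak correction for the number of positions.
#'
#' @param case,control numeric matrices, positions x replicates (same row
#'   order; >= 2 replicates per arm).
#' @return list: `anova` (the `aov` summary table) and `comparisons`
#'   (data.frame per position: `position`, `meanCase`, `meanControl`,
#'   `t`, `p`, `pSidak`, `significant` at 0.05).
#' @export
testVariantPanel <- function(case, control) {
    stopifnot(is.matrix(case), is.matrix(control),
              nrow(case) == nrow(control),
              ncol(case) >= 2L, ncol(control) >= 2L)
    P <- nrow(case)
    long <- data.frame(
        y = c(as.vector(case), as.vector(control)),
        position = factor(c(rep(seq_len(P), times = ncol(case)),
                            rep(seq_len(P), times = ncol(control)))),
        condition = factor(c(rep("case", length(case)),
                             rep("control", length(control)))))
    fit <- stats::aov(y ~ position * condition, data = long)
    ms <- summary(fit)[[1]]
    mse <- ms["Residuals", "Mean Sq"]
    dfres <- ms["Residuals", "Df"]
    n1 <- ncol(case); n2 <- ncol(control)
    mc <- rowMeans(case); mctl <- rowMeans(control)
    se <- sqrt(mse * (1 / n1 + 1 / n2))
    tval <- (mc - mctl) / se
    p <- 2 * pt(abs(tval), dfres, lower.tail = FALSE)
    pSidak <- 1 - (1 - p)^P
    list(anova = ms,
         comparisons = data.frame(position = seq_len(P), meanCase = mc,
                                  meanControl = mctl, t = tval, p = p,
                                  pSidak = pmin(pSidak, 1),
                                  significant = pSidak < 0.05))
}

#' One-sided binomial test of a variant against a background rate
#'
#' Single-sample companion to [testVariant()] for designs without
#' replicates: tests whether the variant consensus count exceeds what the
#' background consensus error rate would produce. This is an extension of
#' the replicate t-test workflow, not a replacement.
#'
#' @param count variant consensus reads at the position.
#' @param coverage total consensus reads at the position.
#' @param backgroundRate panel background consensus error rate.
#' @return one-sided p-value, `P[X >= count]` for
#'   `X ~ Binomial(coverage, backgroundRate)`.
#' @export
testVariantBinomial <- function(count, coverage, backgroundRate) {
    stopifnot(count >= 0, coverage >= count,
              backgroundRate >= 0, backgroundRate <= 1)
    pbinom(count - 1, coverage, backgroundRate, lower.tail = FALSE)
}

#' Classify non-reference events by error type
#'
#' Bins every non-reference event of a count matrix into transitions
#' (A<->G, C<->T), transversions (all other base exchanges), deletions and
#' insertions; `N` calls are reported in a separate `other` bin. Each
#' bin's rate is its event count divided by the total coverage over
#' included positions, so the bin rates sum to the pooled
#' (coverage-weighted) non-reference rate.
#'
#' @param mat a [CountMatrix-class]
#' @param excluded integer vector of 0-based excluded offsets.
#' @return list of rates: `transition`, `transversion`, `deletion`,
#'   `insertion`, `other`, `overall` (pooled), and `totalCoverage`.
#' @export
classifyErrors <- function(mat, excluded = integer(0)) {
    cnt <- counts(mat)
    cov <- coverage(mat)
    refc <- refBases(mat)
    inc <- cov > 0
    if (length(excluded)) inc[excluded + 1L] <- FALSE
    cnt <- cnt[inc, , drop = FALSE]
    refc <- refc[inc]
    tot <- sum(cov[inc])
    if (tot == 0)
        return(list(transition = NA_real_, transversion = NA_real_,
                    deletion = NA_real_, insertion = NA_real_,
                    other = NA_real_, overall = NA_real_,
                    totalCoverage = 0L))
    partner <- c(A = "G", G = "A", C = "T", T = "C")
    nTs <- 0L; nTv <- 0L
    for (b in BASES) {
        atRef <- refc == b
        others <- setdiff(BASES, b)
        for (o in others) {
            k <- sum(cnt[atRef, o])
            if (partner[[b]] == o) nTs <- nTs + k else nTv <- nTv + k
        }
    }
    nOther <- sum(cnt[, "N"][refc != "N"])
    nDel <- sum(cnt[, "del"])
    nIns <- sum(cnt[, "ins"])
    list(transition = nTs / tot, transversion = nTv / tot,
         deletion = nDel / tot, insertion = nIns / tot,
         other = nOther / tot,
         overall = (nTs + nTv + nDel + nIns + nOther) / tot,
         totalCoverage = tot)
}

#' Spearman correlation of two error profiles
#'
#' Rank correlation of matched per-position error rates of two samples or
#' conditions, with a significance flag at p < 0.05. A constant profile
#' has no ranks to correlate and is flagged undefined.
#'
#' @param a,b numeric vectors of per-position rates (matched positions,
#'   length >= 5).
#' @return list: `rho`, `p.value`, `n`, `significant`, `defined`.
#' @export
errorProfileCorrelation <- function(a, b) {
    stopifnot(length(a) == length(b))
    keep <- !is.na(a) & !is.na(b)
    a <- a[keep]; b <- b[keep]
    if (length(a) < 5L) stop("need >= 5 matched positions")
    if (sd(a) == 0 || sd(b) == 0)
        return(list(rho = NA_real_, p.value = NA_real_, n = length(a),
                    significant = NA, defined = FALSE))
    ct <- suppressWarnings(cor.test(a, b, method = "spearman",
                                    exact = FALSE))
    list(rho = unname(ct$estimate), p.value = ct$p.value, n = length(a),
         significant = ct$p.value < 0.05, defined = TRUE)
}

#' Dilution-series linearity
#'
#' Ordinary least-squares regression of molecule counts on loaded input
#' amount, fitted over the `kLowest` smallest distinct amounts (where the
#' response is expected to be linear); saturation is diagnosed when the
#' observed count at the largest amount falls below the regression
#' prediction.
#'
#' @param loaded numeric vector of loaded amounts (e.g. ng).
#' @param counts molecule counts, same length.
#' @param kLowest number of lowest distinct amounts to fit (default 4).
#' @return list: `slope`, `intercept`, `r.squared`, `saturated`,
#'   `fitAmounts`.
#' @export
dilutionLinearity <- function(loaded, counts, kLowest = 4L) {
    stopifnot(length(loaded) == length(counts))
    amounts <- sort(unique(loaded))
    if (length(amounts) < kLowest)
        stop("need at least ", kLowest, " distinct loaded amounts")
    fitAmounts <- amounts[seq_len(kLowest)]
    sel <- loaded %in% fitAmounts
    fit <- lm(y ~ x, data = data.frame(x = loaded[sel], y = counts[sel]))
    top <- max(amounts)
    pred <- unname(predict(fit, data.frame(x = top)))
    obsTop <- mean(counts[loaded == top])
    tol <- 1e-8 * max(1, abs(pred))  # guard exact fits against fp noise
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r.squared = suppressWarnings(summary(fit)$r.squared),
         saturated = obsTop < pred - tol, fitAmounts = fitAmounts)
}

#' Molecules per millilitre of blood plasma
#'
#' Converts detected molecules to molecules per mL plasma, accounting for
#' the fraction of the extract and of the RT reaction actually carried
#' into the library.
#'
#' @param molecules detected molecule count.
#' @param plasmaVolumeMl plasma volume (mL), > 0.
#' @param fractionExtractUsed,fractionRtUsed fractions in (0, 1],
#'   defaults 1.
#' @return molecules per mL plasma.
#' @export
moleculesPerMlPlasma <- function(molecules, plasmaVolumeMl,
                                 fractionExtractUsed = 1,
                                 fractionRtUsed = 1) {
    if (any(plasmaVolumeMl <= 0)) stop("plasma volume must be > 0")
    stopifnot(fractionExtractUsed > 0, fractionExtractUsed <= 1,
              fractionRtUsed > 0, fractionRtUsed <= 1)
    molecules / (plasmaVolumeMl * fractionExtractUsed * fractionRtUsed)
}
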