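test_that("panel file round-trips with defaults and validates", {
    tmp <- withr::local_tempfile(fileext = ".tsv")
    amps <- withr::with_seed(1, vapply(1:5, function(i) randomAmplicon(80),
                                       character(1)))
    writeLines(c("# umi_length=12",
                 "# anchor_seq=CGATGTACGCTA",
                 paste("name", "gene", "contig", "start", "end", "amplicon",
                       sep = "\t"),
                 vapply(1:5, function(i)
                     paste(paste0("TP53_", LETTERS[i]), "TP53", "chr17",
                           7675000 + i * 200, 7675080 + i * 200, amps[i],
                           sep = "\t"), character(1))), tmp)
    p <- readPanel(tmp)
    expect_s4_class(p, "Panel")
    expect_length(p, 5L)
    expect_equal(minReadsPerUmi(p), 3L)      # default cutoff
    expect_equal(umiLength(p), 12L)
    expect_equal(unname(ampliconSeq(p, "TP53_C")), amps[3])

    # identity round-trip of explicit parameters
    writeLines(c("# umi_length=14", "# min_reads_per_umi=5",
                 paste("name", "gene", "contig", "start", "end", "amplicon",
                       sep = "\t"),
                 paste("X", "HBB", "chr11", 100, 160, amps[1], sep = "\t")),
               tmp)
    p1 <- readPanel(tmp)
    expect_equal(umiLength(p1), 14L)
    expect_equal(minReadsPerUmi(p1), 5L)
})

test_that("panel validation rejects bad configurations", {
    amp <- withr::with_seed(2, randomAmplicon(40))
    df <- data.frame(name = "A", gene = "G", contig = "c", start = 0L,
                     end = 40L)
    expect_error(Panel(df, c(A = amp), umiLength = 4L), "umiLength")
    expect_error(Panel(rbind(df, df), c(A = amp)), "unique")
    expect_error(Panel(df, c(A = "ACGR")), "alphabet")
    expect_error(Panel(df, c(A = amp), minReadsPerUmi = 0L), "minReadsPerUmi")

    tmp <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c(paste("name", "gene", "contig", "start", "end", "amplicon",
                       sep = "\t"),
                 paste("A", "G", "c", 0, 40, "", sep = "\t")), tmp)
    expect_error(readPanel(tmp), "missing amplicon.*A")
    writeLines(c(paste("name", "gene", "contig", "start", "end", "amplicon",
                       sep = "\t"),
                 paste("A", "G", "c", 0, 40, amp, sep = "\t"),
                 paste("A", "G", "c", 50, 90, amp, sep = "\t")), tmp)
    expect_error(readPanel(tmp), "duplicate")
})

test_that("panel amplicons can come from a FASTA reference", {
    tmp <- withr::local_tempfile(fileext = ".tsv")
    fa <- withr::local_tempfile(fileext = ".fasta")
    amp <- withr::with_seed(3, randomAmplicon(50))
    writeLines(c(paste("name", "gene", "contig", "start", "end", sep = "\t"),
                 paste("A", "G", "c", 0, 50, sep = "\t")), tmp)
    writeLines(c(">A", amp), fa)
    p <- readPanel(tmp, fasta = fa)
    expect_equal(unname(ampliconSeq(p, "A")), amp)
})

test_that("FASTQ round-trip preserves records exactly", {
    tmp <- withr::local_tempfile(fileext = ".fastq")
    n <- 100L
    seqs <- withr::with_seed(4, vapply(seq_len(n), function(i)
        randomAmplicon(sample(20:60, 1)), character(1)))
    substr(seqs[7], 3, 3) <- "N"  # N bases preserved verbatim
    quals <- strrep("J", nchar(seqs))
    writeFastq(seqs, tmp, ids = sprintf("rd%03d", seq_len(n)),
               qualities = quals)
    back <- readFastq(tmp)
    expect_length(back, n)
    expect_identical(as.character(back), setNames(seqs, sprintf("rd%03d", 1:n)))
    expect_identical(unname(as.character(Biostrings::quality(back))), quals)
})

test_that("FASTQ reader handles empty and malformed files", {
    tmp <- withr::local_tempfile(fileext = ".fastq")
    writeLines(character(0), tmp)
    expect_length(readFastq(tmp), 0L)
    # truncated record: error names the offending line
    writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT"), tmp)
    expect_error(readFastq(tmp), "line 5")
    # bad separator line
    writeLines(c("@r1", "ACGT", "x", "IIII"), tmp)
    expect_error(readFastq(tmp), "line 3")
})

test_that("BED exclusion intervals map to per-assay amplicon offsets", {
    p <- testPanel(nAssays = 2L, len = 60L)
    # assay A1 spans [1000,1060), A2 spans [1200,1260)
    bed <- withr::local_tempfile(fileext = ".bed")
    writeLines("chr17\t1010\t1011", bed)
    p1 <- readExclusionBed(bed, p)
    expect_equal(excludedOffsets(p1, "A1"), 10L)
    expect_equal(excludedOffsets(p1, "A2"), integer(0))
    # idempotent
    p2 <- readExclusionBed(bed, p1)
    expect_identical(excludedOffsets(p2, "A1"), excludedOffsets(p1, "A1"))
    # empty BED: no exclusions
    writeLines(character(0), bed)
    expect_identical(excludedOffsets(readExclusionBed(bed, p), "A1"),
                     integer(0))
    # unknown contig: warning, skipped
    writeLines("chrX\t0\t100", bed)
    expect_warning(p3 <- readExclusionBed(bed, p), "unknown contig")
    expect_identical(excludedOffsets(p3, "A1"), integer(0))
})

test_that("whole-amplicon exclusion leaves the mean error rate undefined", {
    p <- testPanel(nAssays = 1L, len = 30L)
    bed <- withr::local_tempfile(fileext = ".bed")
    writeLines("chr17\t1000\t1030", bed)
    p <- readExclusionBed(bed, p)
    expect_length(excludedOffsets(p, "A1"), 30L)
    mat <- CountMatrix("A1", ampliconSeq(p, "A1"), level = "consensus")
    rates <- positionErrorRates(mat, excludedOffsets(p, "A1"))
    expect_false(any(rates$included))
    expect_warning(m <- meanErrorRate(rates), "undefined")
    expect_true(is.na(m))
})

test_that("count matrices conserve coverage and round-trip as TSV", {
    ref <- withr::with_seed(5, randomAmplicon(10))
    m <- matrix(0L, 10, 7, dimnames = list(NULL, c("A", "C", "G", "T", "N",
                                                   "del", "ins")))
    refc <- strsplit(ref, "")[[1]]
    m[cbind(1:10, match(refc, c("A", "C", "G", "T")))] <- 50L
    m[4, "del"] <- 3L; m[4, match(refc[4], c("A","C","G","T"))] <- 47L
    m[7, "ins"] <- 2L
    cm <- CountMatrix("A1", ref, counts = m, level = "raw")
    expect_equal(coverage(cm), rowSums(m[, 1:6]))
    df <- as.data.frame(cm)
    expect_equal(nrow(df), 10L)           # one row per position
    expect_equal(df$pos, 1:10)            # 1-based positions
    tmp <- withr::local_tempfile(fileext = ".tsv")
    writeCountMatrix(cm, tmp)
    back <- readCountMatrix(tmp)
    expect_equal(counts(back), counts(cm))
    expect_equal(countLevel(back), "raw")
    # all-reference matrix: non-reference columns all zero
    m0 <- matrix(0L, 10, 7, dimnames = dimnames(m))
    m0[cbind(1:10, match(refc, c("A", "C", "G", "T")))] <- 20L
    cm0 <- CountMatrix("A1", ref, counts = m0, level = "consensus")
    nonref <- positionErrorRates(cm0)$nonref
    expect_true(all(nonref == 0L))
    # violating conservation is rejected
    mbad <- m; mbad[1, "N"] <- 5L
    expect_error(methods::new("CountMatrix", assay = "A1", reference = ref,
                              counts = mbad, coverage = coverage(cm),
                              level = "raw"), "coverage")
})

test_that("raw and consensus matrices for one assay are distinguished by level", {
    ref <- withr::with_seed(6, randomAmplicon(12))
    raw <- CountMatrix("A1", ref, level = "raw")
    cons <- CountMatrix("A1", ref, level = "consensus")
    t1 <- withr::local_tempfile(fileext = ".tsv")
    t2 <- withr::local_tempfile(fileext = ".tsv")
    writeCountMatrix(raw, t1); writeCountMatrix(cons, t2)
    expect_equal(readCountMatrix(t1)@level, "raw")
    expect_equal(readCountMatrix(t2)@level, "consensus")
})
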