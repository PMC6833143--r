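# Percent identity from alignments: CIGAR/MD walking and segment labels.

test_that("segment identity counts exact matches over read bases in range", {
    mask <- c(rep(TRUE, 18), rep(FALSE, 2))
    expect_equal(segmentIdentity(mask, 0, 20), 0.9)
    expect_equal(segmentIdentity(mask, 0, 18), 1)
    expect_equal(segmentIdentity(NULL, 0, 20), 0)       # unaligned read
    expect_error(segmentIdentity(mask, 5, 5), "empty")
    expect_error(segmentIdentity(mask, 0, 25), "exceeds")
})

test_that("insertions count against identity: 10=2I8= gives 18/20", {
    rec <- samRecord("r", "10=2I8=")
    mask <- alignmentMatchMask(rec)
    expect_length(mask, 20L)
    expect_equal(segmentIdentity(mask, 0, 20), 0.9)
    expect_identical(which(!mask), 11:12)
})

test_that("clipped ranges contribute only to the denominator", {
    rec <- samRecord("r", "10S10=")
    mask <- alignmentMatchMask(rec)
    expect_equal(segmentIdentity(mask, 0, 10), 0)   # fully clipped range
    expect_equal(segmentIdentity(mask, 10, 20), 1)
    # hard clips extend the mask to the original read length
    rec2 <- samRecord("r", "5H10=")
    expect_length(alignmentMatchMask(rec2), 15L)
})

test_that("X and D operations affect the mask as defined", {
    mask <- alignmentMatchMask(samRecord("r", "4=2X3D4="))
    expect_length(mask, 10L)  # D consumes no read bases
    expect_identical(unname(which(!mask)), 5:6)
})

test_that("MD tags resolve ambiguous M operations", {
    rec <- samRecord("r", "20M", md = "10A9")
    mask <- expect_silent(alignmentMatchMask(rec))
    expect_identical(which(!mask), 11L)
    # without MD, M degrades to match with a warning
    expect_warning(m2 <- alignmentMatchMask(samRecord("r", "20M")),
                   "MD")
    expect_true(all(m2))
    # MD deletions consume no M columns
    rec3 <- samRecord("r", "5M2D5M", md = "5^AC3T1")
    mask3 <- alignmentMatchMask(rec3)
    expect_identical(which(!mask3), 9L)
})

test_that("reverse-strand masks are flipped into read orientation", {
    rec <- samRecord("r", "3=2X5=", flag = 16L)
    mask <- alignmentMatchMask(rec)
    # SEQ-orientation mismatches at 4:5 map to read positions 6:7
    expect_identical(unname(which(!mask)), c(6L, 7L))
    rec2 <- samRecord("r", "2S3=1X4=", flag = 16L)
    mask2 <- alignmentMatchMask(rec2)
    # SEQ: clip 1:2, mismatch 6 -> read orientation: 5 and 9:10
    expect_identical(unname(which(!mask2)), c(5L, 9L, 10L))
})

test_that("labels fall back to zero for unaligned reads and error on unknown ids", {
    aln <- samRecord("r1", "10=")
    info <- data.frame(refId = c("r1", "r2"), segmentIndex = 1L,
                       baseStart = 0L, baseEnd = c(10L, 8L))
    labs <- labelSegments(aln, info, c(r1 = 10L, r2 = 8L))
    expect_equal(labs$identity, c(1, 0))
    expect_error(labelSegments(aln, info, c(r1 = 10L)), "absent")
})

test_that("primary selection keeps the record with the most aligned bases", {
    aln <- rbind(samRecord("r1", "5=15S"),
                 samRecord("r1", "15=5S"),
                 samRecord("r1", "20=", flag = 256L))   # secondary: ignored
    info <- data.frame(refId = "r1", segmentIndex = 1L, baseStart = 0L,
                       baseEnd = 20L)
    labs <- labelSegments(aln, info, c(r1 = 20L))
    expect_equal(labs$identity, 15 / 20)
})

test_that("whole-read identity is the length-weighted mean of its segments", {
    set.seed(21)
    sp <- SimParam(genomeLengths = 15000, coverage = 4, chimeraRate = 0,
                   seed = 33, readLengthMeanLog = log(900))
    genomes <- simulateGenome(sp)
    sim <- simulateReads(genomes, sp)
    sam <- withr::local_tempfile(fileext = ".sam")
    truthToSam(sim$truth, sim$reads, genomes, sam)
    aln <- readSamAlignments(sam)
    rl <- stats::setNames(Biostrings::width(sim$reads), names(sim$reads))
    ids <- names(sim$reads)[1:20]
    segInfo <- do.call(rbind, lapply(ids, function(id) {
        b <- unique(c(seq(0L, rl[[id]], by = 157L), rl[[id]]))
        data.frame(refId = id, segmentIndex = seq_len(length(b) - 1L),
                   baseStart = head(b, -1L), baseEnd = b[-1L])
    }))
    segLab <- labelSegments(aln, segInfo, rl)
    wholeLab <- labelSegments(aln, data.frame(refId = ids, segmentIndex = 1L,
                                              baseStart = 0L,
                                              baseEnd = rl[ids]), rl)
    for (id in ids) {
        s <- segLab[segLab$refId == id, ]
        w <- sum(s$identity * (s$baseEnd - s$baseStart)) /
            sum(s$baseEnd - s$baseStart)
        expect_equal(w, wholeLab$identity[wholeLab$refId == id],
                     tolerance = 1e-12)
    }
})

test_that("alignment labels equal mask labels on the simulator's own truth", {
    set.seed(22)
    sp <- SimParam(genomeLengths = 20000, coverage = 5, chimeraRate = 0,
                   seed = 44)
    genomes <- simulateGenome(sp)
    sim <- simulateReads(genomes, sp)
    sam <- withr::local_tempfile(fileext = ".sam")
    truthToSam(sim$truth, sim$reads, genomes, sam)
    aln <- readSamAlignments(sam)
    rl <- stats::setNames(Biostrings::width(sim$reads), names(sim$reads))
    segInfo <- do.call(rbind, lapply(names(sim$reads), function(id) {
        b <- unique(c(seq(0L, rl[[id]], by = 211L), rl[[id]]))
        data.frame(refId = id, segmentIndex = seq_len(length(b) - 1L),
                   baseStart = head(b, -1L), baseEnd = b[-1L])
    }))
    la <- labelSegments(aln, segInfo, rl)
    lt <- truthLabels(sim$truth, segInfo)
    expect_equal(la$identity, lt$identity, tolerance = 1e-12)
})

test_that("labeling error-free reads yields identity 1 everywhere", {
    sp <- SimParam(genomeLengths = 5000, coverage = 2, errorRate = 0,
                   readErrorSdLog = 0, junkRate = 0, chimeraRate = 0,
                   seed = 5)
    genomes <- simulateGenome(sp)
    sim <- simulateReads(genomes, sp)
    sam <- withr::local_tempfile(fileext = ".sam")
    truthToSam(sim$truth, sim$reads, genomes, sam)
    rl <- stats::setNames(Biostrings::width(sim$reads), names(sim$reads))
    info <- data.frame(refId = names(sim$reads), segmentIndex = 1L,
                       baseStart = 0L, baseEnd = rl)
    labs <- labelSegments(readSamAlignments(sam), info, rl)
    expect_true(all(labs$identity == 1))
})

test_that("PAF records with cg tags label like their SAM equivalents", {
    paf <- withr::local_tempfile(fileext = ".paf")
    writeLines(paste("r1", 30, 5, 25, "+", "t", 1000, 100, 120,
                     18, 20, 60, "cg:Z:10=2X8=", sep = "\t"), paf)
    aln <- readPafAlignments(paf)
    mask <- alignmentMatchMask(aln[1, ])
    expect_length(mask, 30L)
    expect_equal(sum(mask), 18)
    expect_identical(unname(which(!mask)), c(1:5, 16:17, 26:30))
    # reverse strand: clips and mask flip into original orientation
    writeLines(paste("r2", 30, 5, 25, "-", "t", 1000, 100, 120,
                     18, 20, 60, "cg:Z:2X18=", sep = "\t"), paf)
    aln2 <- readPafAlignments(paf)
    mask2 <- alignmentMatchMask(aln2[1, ])
    expect_equal(sum(mask2), 18)
    expect_identical(unname(which(!mask2)), c(1:5, 24:30))
})
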