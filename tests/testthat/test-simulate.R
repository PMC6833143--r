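# The seeded long-read simulator and its ground truth.

test_that("genome simulation is deterministic with ~uniform composition", {
    sp <- SimParam(genomeLengths = c(20000, 5000), seed = 11)
    g1 <- simulateGenome(sp)
    g2 <- simulateGenome(sp)
    expect_identical(as.character(g1), as.character(g2))
    expect_identical(Biostrings::width(g1), c(20000L, 5000L))
    big <- simulateGenome(SimParam(genomeLengths = 100000, seed = 12))
    gc <- Biostrings::letterFrequency(big, "GC", as.prob = TRUE)[1]
    expect_lt(abs(gc - 0.5), 0.02)
})

test_that("read simulation is fully deterministic per seed", {
    sp <- SimParam(genomeLengths = 10000, coverage = 3, seed = 13)
    g <- simulateGenome(sp)
    s1 <- simulateReads(g, sp)
    s2 <- simulateReads(g, sp)
    expect_identical(as.character(s1$reads), as.character(s2$reads))
    expect_identical(as.character(Biostrings::quality(s1$reads)),
                     as.character(Biostrings::quality(s2$reads)))
    expect_identical(s1$truth, s2$truth)
    s3 <- simulateReads(g, SimParam(genomeLengths = 10000, coverage = 3,
                                    seed = 14))
    expect_false(identical(as.character(s1$reads), as.character(s3$reads)))
})

test_that("error-free reads are exact genome substrings", {
    sp <- SimParam(genomeLengths = 8000, coverage = 3, errorRate = 0,
                   readErrorSdLog = 0, junkRate = 0, chimeraRate = 0,
                   seed = 15)
    g <- simulateGenome(sp)
    sim <- simulateReads(g, sp)
    gs <- as.character(g)
    for (id in names(sim$reads)) {
        tr <- sim$truth[[id]]
        expect_false(any(tr$mask))
        iv <- tr$intervals[1, ]
        sub <- substr(gs[[iv$genome]], iv$gStart + 1, iv$gEnd)
        if (iv$strand == "-") sub <- revComp(sub)
        expect_identical(as.character(sim$reads[[id]]), sub)
    }
})

test_that("realized error events match the configured rate within 3 SE", {
    sp <- SimParam(genomeLengths = 40000, coverage = 8, errorRate = 0.15,
                   readErrorSdLog = 0, junkRate = 0, chimeraRate = 0,
                   seed = 16)
    sim <- simulateReads(simulateGenome(sp), sp)
    expect_gte(length(sim$reads), 100L)
    # count substitution/insertion/deletion events and template bases from
    # the exact per-read CIGARs
    ops <- lapply(sim$truth, function(tr) {
        o <- GenomicAlignments::explodeCigarOps(tr$cigars[1])[[1]]
        l <- GenomicAlignments::explodeCigarOpLengths(tr$cigars[1])[[1]]
        c(events = sum(l[o %in% c("X", "I", "D")]),
          template = sum(l[o %in% c("X", "D", "=")]))
    })
    events <- sum(vapply(ops, `[[`, numeric(1), "events"))
    template <- sum(vapply(ops, `[[`, numeric(1), "template"))
    p <- 0.15
    se <- sqrt(p * (1 - p) / template)
    expect_lt(abs(events / template - p), 3 * se)
})

test_that("indels dominate the error spectrum at the configured split", {
    sp <- SimParam(genomeLengths = 40000, coverage = 5, errorRate = 0.2,
                   readErrorSdLog = 0, junkRate = 0, chimeraRate = 0,
                   indelFraction = 0.6, seed = 17)
    sim <- simulateReads(simulateGenome(sp), sp)
    counts <- c(X = 0, I = 0, D = 0)
    for (tr in sim$truth) {
        o <- GenomicAlignments::explodeCigarOps(tr$cigars[1])[[1]]
        l <- GenomicAlignments::explodeCigarOpLengths(tr$cigars[1])[[1]]
        for (k in c("X", "I", "D"))
            counts[k] <- counts[k] + sum(l[o == k])
    }
    indelFrac <- (counts["I"] + counts["D"]) / sum(counts)
    expect_lt(abs(indelFrac - 0.6), 0.03)
})

test_that("every read is chimeric when the chimera rate is 1", {
    sp <- SimParam(genomeLengths = c(10000, 10000), coverage = 1,
                   chimeraRate = 1, seed = 18)
    sim <- simulateReads(simulateGenome(sp), sp)
    for (tr in sim$truth) {
        expect_gte(nrow(tr$intervals), 2L)
        iv <- tr$intervals
        distinct <- nrow(unique(iv[, c("genome", "gStart")])) > 1L
        expect_true(distinct)
        expect_identical(iv$readStart[1], 0L)
        expect_identical(iv$readEnd[nrow(iv)], length(tr$mask))
    }
})

test_that("realized coverage is within 10% of the request", {
    sp <- SimParam(genomeLengths = 20000, coverage = 20, seed = 19)
    sim <- simulateReads(simulateGenome(sp), sp)
    tplBases <- sum(vapply(sim$truth, function(tr)
        sum(tr$intervals$gEnd - tr$intervals$gStart), numeric(1)))
    expect_lt(abs(tplBases / (20 * 20000) - 1), 0.1)
})

test_that("junk segments carry distinctly lower truth identity", {
    sp <- SimParam(genomeLengths = 30000, coverage = 10, junkRate = 1,
                   chimeraRate = 0, seed = 20)
    sim <- simulateReads(simulateGenome(sp), sp)
    junkIdent <- c(); cleanIdent <- c()
    for (tr in sim$truth) {
        j <- tr$junk
        if (nrow(j) == 0 || j$readEnd[1] - j$readStart[1] < 50) next
        outside <- setdiff(seq_along(tr$mask),
                           (j$readStart[1] + 1):j$readEnd[1])
        if (length(outside) < 50) next  # junk may swallow a short read
        junkIdent <- c(junkIdent,
                       mean(!tr$mask[(j$readStart[1] + 1):j$readEnd[1]]))
        cleanIdent <- c(cleanIdent, mean(!tr$mask[outside]))
    }
    expect_gt(length(junkIdent), 50)
    expect_lt(mean(junkIdent), mean(cleanIdent) - 0.1)
    # pure junk at ~40% error keeps roughly the sub+ins fraction marked
    expect_lt(mean(junkIdent), 0.85)
})

test_that("truth labels come straight from the error mask", {
    sp <- SimParam(genomeLengths = 10000, coverage = 3, seed = 21)
    sim <- simulateReads(simulateGenome(sp), sp)
    id <- names(sim$reads)[1]
    L <- length(sim$truth[[id]]$mask)
    info <- data.frame(refId = id, segmentIndex = 1:2,
                       baseStart = c(0L, 100L), baseEnd = c(100L, L))
    lab <- truthLabels(sim$truth, info)
    expect_equal(lab$identity[1], mean(!sim$truth[[id]]$mask[1:100]))
    expect_error(truthLabels(sim$truth,
                             transform(info, refId = "nope")), "unknown")
})

test_that("the truth track round-trips through TSV", {
    sp <- SimParam(genomeLengths = 8000, coverage = 2, chimeraRate = 0.5,
                   junkRate = 0.8, seed = 22)
    sim <- simulateReads(simulateGenome(sp), sp)
    path <- withr::local_tempfile(fileext = ".tsv")
    writeTruthTsv(sim$truth, path)
    back <- readTruthTsv(path)
    expect_identical(names(back), names(sim$truth))
    for (id in names(back)) {
        expect_identical(back[[id]]$mask, sim$truth[[id]]$mask)
        expect_identical(back[[id]]$cigars, sim$truth[[id]]$cigars)
        expect_identical(back[[id]]$intervals$gStart,
                         sim$truth[[id]]$intervals$gStart)
        expect_identical(back[[id]]$junk$readStart,
                         sim$truth[[id]]$junk$readStart)
    }
})

test_that("zero coverage produces empty outputs", {
    sp <- SimParam(genomeLengths = 5000, coverage = 0, seed = 23)
    sim <- simulateReads(simulateGenome(sp), sp)
    expect_identical(length(sim$reads), 0L)
    expect_length(sim$truth, 0L)
})

test_that("quality scores track the local error rate", {
    sp <- SimParam(genomeLengths = 30000, coverage = 5, errorRate = 0.15,
                   readErrorSdLog = 0, junkRate = 1,
                   junkErrorRange = c(0.4, 0.4), chimeraRate = 0, seed = 24)
    sim <- simulateReads(simulateGenome(sp), sp)
    qJunk <- c(); qClean <- c()
    for (id in names(sim$reads)) {
        tr <- sim$truth[[id]]
        if (nrow(tr$junk) == 0) next
        q <- utf8ToInt(as.character(Biostrings::quality(sim$reads))[[id]]) - 33L
        jr <- (tr$junk$readStart[1] + 1):tr$junk$readEnd[1]
        qJunk <- c(qJunk, q[jr])
        qClean <- c(qClean, q[-jr])
    }
    # expected Phred targets: -10 log10(0.4) ~ 4.0 vs -10 log10(0.15) ~ 8.2
    expect_equal(mean(qJunk), 4.0, tolerance = 0.15)
    expect_equal(mean(qClean), 8.2, tolerance = 0.15)
})
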