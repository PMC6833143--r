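test_that("index over an empty or single read set is as expected", {
    expect_identical(nrow(minimizerIndex(character())), 0L)
    set.seed(1)
    r <- c(a = randomSeq(100))
    idx <- minimizerIndex(r)
    mm <- extractMinimizers(r[["a"]])
    expect_identical(nrow(idx), nrow(mm))
    expect_setequal(idx$hash, mm$hash)
    expect_true(all(idx$readId == "a"))
})

test_that("two identical reads index every hash in both reads", {
    set.seed(2)
    s <- randomSeq(200)
    idx <- minimizerIndex(c(a = s, b = s))
    byHash <- split(idx$readId, idx$hash)
    expect_true(all(vapply(byHash, function(x) all(c("a", "b") %in% x),
                           logical(1))))
})

test_that("duplicate read identifiers are rejected", {
    expect_error(minimizerIndex(c(a = "ACGTACGTACGTACGTACGT",
                                  a = "ACGTACGTACGTACGTACGT")),
                 "duplicate")
})

test_that("identical reads overlap fully in both directions", {
    set.seed(3)
    s <- randomSeq(400)
    ov <- findReadOverlaps(c(a = s, b = s))
    expect_identical(nrow(ov), 2L)
    expect_setequal(ov$refId, c("a", "b"))
    expect_true(all(ov$strand == "+"))
    nm <- nrow(extractMinimizers(s))
    expect_true(all(ov$nShared == nm))
})

test_that("reads without a shared k-mer produce no overlap", {
    # poly-A vs poly-C share no canonical 15-mer on either strand
    a <- strrep("A", 200)
    b <- strrep("C", 200)
    ov <- findReadOverlaps(c(a = a, b = b))
    expect_identical(nrow(ov), 0L)
})

test_that("a reverse-complement read is overlapped on the opposite strand", {
    set.seed(4)
    s <- randomSeq(400)
    ov <- findReadOverlaps(c(a = s, b = revComp(s)))
    expect_identical(nrow(ov), 2L)
    expect_true(all(ov$strand == "-"))
    nm <- nrow(extractMinimizers(s))
    # all canonical minimizers match across orientations
    expect_true(all(ov$nShared == nm))
    m <- ov$matches[[which(ov$refId == "a")]]
    expect_false(is.unsorted(m$refIndex, strictly = TRUE))
    expect_false(is.unsorted(rev(m$queryPos), strictly = TRUE)) # decreasing
})

test_that("detection is symmetric above the match threshold", {
    set.seed(6)
    genome <- randomSeq(3000)
    starts <- sample(1:2200, 12)
    reads <- stats::setNames(substring(genome, starts, starts + 799),
                             paste0("r", seq_along(starts)))
    ov <- findReadOverlaps(reads)
    key <- paste(ov$refId, ov$queryId)
    rkey <- paste(ov$queryId, ov$refId)
    expect_setequal(key, rkey)
})

test_that("chain length equals the exhaustive optimum on small instances", {
    set.seed(7)
    for (i in 1:40) {
        n <- sample(3:11, 1)
        neg <- i %% 2 == 0
        refIndex <- sort(sample(1:30, n))
        refPos <- refIndex * 3L
        queryPos <- sample(0:200, n)
        ord <- order(refIndex, queryPos)
        maxGap <- 60L
        res <- PileupScrub:::chain_matches_cpp(
            c(0L, n), refIndex[ord], refPos[ord], queryPos[ord], neg, maxGap)
        expect_identical(res$chainLength,
                         bruteChainLength(refIndex, refPos, queryPos, neg,
                                          maxGap))
    }
})

test_that("every error-free read from one genome overlaps another at 30x", {
    set.seed(8)
    sp <- SimParam(genomeLengths = 6000, coverage = 30, errorRate = 0,
                   readErrorSdLog = 0, junkRate = 0, chimeraRate = 0,
                   readLengthMeanLog = log(700), seed = 81)
    sim <- simulateReads(simulateGenome(sp), sp)
    ov <- findReadOverlaps(sim$reads,
                           overlapParam = OverlapParam(maxOccurrence = 1000))
    expect_setequal(unique(ov$refId), names(sim$reads))
})

test_that("overlap serialization round-trips losslessly", {
    set.seed(9)
    g <- randomSeq(1500)
    reads <- c(a = substr(g, 1, 900), b = substr(g, 401, 1300),
               c = revComp(substr(g, 701, 1500)))
    sk <- readSketches(reads)
    ov <- findReadOverlaps(reads, sketches = sk)
    expect_gt(nrow(ov), 0L)
    path <- withr::local_tempfile(fileext = ".tsv")
    writeOverlaps(ov, path)
    back <- readOverlaps(path, sketches = sk)
    expect_identical(back$refId, ov$refId)
    expect_identical(back$queryId, ov$queryId)
    expect_identical(back$strand, ov$strand)
    expect_identical(back$nShared, ov$nShared)
    expect_identical(back$refStart, ov$refStart)
    expect_identical(back$queryEnd, ov$queryEnd)
    for (i in seq_len(nrow(ov)))
        expect_identical(back$matches[[i]], ov$matches[[i]])
})

test_that("an empty overlap set writes a header-only file", {
    path <- withr::local_tempfile(fileext = ".tsv")
    writeOverlaps(findReadOverlaps(c(a = strrep("AC", 50))), path)
    expect_length(readLines(path), 1L)
    expect_identical(nrow(readOverlaps(path)), 0L)
})

test_that("a hand-written two-match file parses to one overlap", {
    path <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c(
        "ref_id\tquery_id\tstrand\tk\tref_start\tref_end\tquery_start\tquery_end\tmatches",
        "r1\tr2\t+\t15\t10\t85\t5\t80\t3:5,9:40"), path)
    ov <- readOverlaps(path)
    expect_identical(nrow(ov), 1L)
    m <- ov$matches[[1L]]
    expect_identical(nrow(m), 2L)
    expect_identical(m$refIndex, c(4L, 10L))  # 1-based in memory
    expect_identical(m$queryPos, c(5L, 40L))
})

test_that("malformed match files are rejected with a line number", {
    path <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c(
        "ref_id\tquery_id\tstrand\tk\tref_start\tref_end\tquery_start\tquery_end\tmatches",
        "r1\tr2\t+\t15\t10\t85\t5\t80\t3:5,borked"), path)
    expect_error(readOverlaps(path), "line 2")
    writeLines(c("wrong\theader"), path)
    expect_error(readOverlaps(path), "line 1")
})

test_that("PAF records are parsed and bad rows located", {
    path <- withr::local_tempfile(fileext = ".paf")
    writeLines(paste("q1", 1000, 10, 900, "+", "t1", 2000, 100, 1000, 700,
                     890, 60, "tp:A:P", sep = "\t"), path)
    paf <- readPaf(path)
    expect_identical(paf$qname, "q1")
    expect_identical(paf$tstart, 100L)
    expect_identical(paf$tags, "tp:A:P")
    writeLines("q1\t1000\tnot-enough-fields", path)
    expect_error(readPaf(path), "line 1")
})

test_that("external PAF intervals recover the native minimizer matches", {
    set.seed(10)
    g <- randomSeq(1600)
    reads <- c(a = substr(g, 1, 1000), b = substr(g, 501, 1500))
    native <- findReadOverlaps(reads)
    ab <- native[native$refId == "a" & native$queryId == "b", ]
    # write the pair as a PAF record (target = reference read)
    path <- withr::local_tempfile(fileext = ".paf")
    writeLines(paste("b", 1000, ab$queryStart, ab$queryEnd, "+", "a", 1000,
                     ab$refStart, ab$refEnd, ab$nShared * 15, 500, 60,
                     sep = "\t"), path)
    recovered <- pafOverlaps(readPaf(path), reads)
    expect_identical(nrow(recovered), 1L)
    expect_identical(recovered$matches[[1L]], ab$matches[[1L]])
})
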