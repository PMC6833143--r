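# Shared fixture builders; everything is generated in code.

randomSeq <- function(n, alphabet = c("A", "C", "G", "T")) {
    paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

revComp <- function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# a QualityScaledDNAStringSet from parallel named character vectors
makeReads <- function(seqs, quals = NULL) {
    if (is.null(quals))
        quals <- vapply(seqs, function(s) strrep("I", nchar(s)), character(1))
    ids <- names(seqs)
    Biostrings::QualityScaledDNAStringSet(
        stats::setNames(Biostrings::DNAStringSet(unname(seqs)), ids),
        Biostrings::PhredQuality(stats::setNames(
            Biostrings::BStringSet(unname(quals)), ids)))
}

# one SAM-record row shaped like readSamAlignments() output
samRecord <- function(readId, cigar, flag = 0L, target = "ref", pos = 0L,
                      md = NA_character_, seqLen = NA_integer_) {
    data.frame(readId = readId, flag = flag, target = target, pos = pos,
               mapq = 60L, cigar = cigar, md = md, seqLen = seqLen,
               reverse = bitwAnd(flag, 16L) > 0L,
               unmapped = bitwAnd(flag, 4L) > 0L,
               secondary = bitwAnd(flag, 256L) > 0L,
               supplementary = bitwAnd(flag, 2048L) > 0L,
               stringsAsFactors = FALSE)
}

# exhaustive longest co-linear chain over shared matches (independent
# oracle for the chaining DP; subset enumeration, no DP recurrences)
bruteChainLength <- function(refIndex, refPos, queryPos, neg, maxGap) {
    n <- length(refIndex)
    stopifnot(n <= 14)
    best <- 0L
    for (bits in seq_len(2^n) - 1L) {
        sel <- which(bitwAnd(bits, 2^(seq_len(n) - 1L)) > 0L)
        if (length(sel) <= best) next
        sel <- sel[order(refIndex[sel], queryPos[sel])]
        ok <- TRUE
        if (length(sel) > 1L) {
            for (j in seq_len(length(sel) - 1L)) {
                a <- sel[j]; b <- sel[j + 1L]
                if (refIndex[b] <= refIndex[a] ||
                    refPos[b] - refPos[a] > maxGap) { ok <- FALSE; break }
                if (!neg && (queryPos[b] <= queryPos[a] ||
                             queryPos[b] - queryPos[a] > maxGap)) {
                    ok <- FALSE; break
                }
                if (neg && (queryPos[b] >= queryPos[a] ||
                            queryPos[a] - queryPos[b] > maxGap)) {
                    ok <- FALSE; break
                }
            }
        }
        if (ok) best <- length(sel)
    }
    best
}

# tiny SegmentSet with constant-intensity images, labels = intensity/255
constantSegments <- function(n, depth = 8L, len = 16L, values = NULL) {
    if (is.null(values)) values <- stats::runif(n)
    arr <- array(0L, c(n, depth, len, 3L))
    for (i in seq_len(n)) arr[i, , , ] <- as.integer(round(values[i] * 255))
    list(segments = methods::new("SegmentSet", data = arr,
             info = data.frame(refId = sprintf("r%03d", seq_len(n)),
                               segmentIndex = 1L, baseStart = 0L,
                               baseEnd = 100L, stringsAsFactors = FALSE)),
         labels = data.frame(refId = sprintf("r%03d", seq_len(n)),
                             segmentIndex = 1L, identity = values,
                             stringsAsFactors = FALSE))
}
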