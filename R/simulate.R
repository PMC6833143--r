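# Seeded long-read simulator with a ground-truth error track. Emulates the
# error structure of noisy long reads: baseline per-base error with
# indel-dominant errors, clustered elevated-error "junk" segments, chimeric
# joins, and quality scores that noisily track the local error rate.

BASES <- c("A", "C", "G", "T")

#' Simulate reference genomes
#'
#' Uniform random A/C/G/T sequences of the configured lengths;
#' deterministic per seed.
#'
#' @param param a [SimParam()].
#' @return A named [Biostrings::DNAStringSet] (`genome1`, `genome2`, ...).
#' @export
simulateGenome <- function(param = SimParam()) {
    .withSeed(param@seed, {
        seqs <- vapply(param@genomeLengths, function(n) {
            paste(sample(BASES, n, replace = TRUE), collapse = "")
        }, character(1))
        names(seqs) <- paste0("genome", seq_along(seqs))
        Biostrings::DNAStringSet(seqs)
    })
}

# one source interval: oriented template characters + coordinates
.drawChunk <- function(genomeChars, len) {
    g <- sample.int(length(genomeChars), 1L)
    glen <- length(genomeChars[[g]])
    len <- min(len, glen)
    gStart <- sample.int(glen - len + 1L, 1L) - 1L
    strand <- sample(c("+", "-"), 1L)
    tpl <- genomeChars[[g]][(gStart + 1L):(gStart + len)]
    if (strand == "-") tpl <- rev(c(T = "A", G = "C", C = "G", A = "T")[tpl])
    list(genome = g, strand = strand, gStart = gStart, gEnd = gStart + len,
         tpl = unname(tpl))
}

#' Simulate noisy long reads with ground truth
#'
#' Reads are drawn from the genomes to the requested coverage with
#' log-normal lengths. Each read receives baseline errors (substitutions
#' and single-base insertions/deletions at the configured indel split);
#' with probability `junkRate` one clustered junk segment gets an elevated
#' error rate; with probability `chimeraRate` the read joins two
#' independently drawn loci. Per-base Phred qualities are sampled from a
#' normal around `-10 log10(local error rate)` truncated to \[0, 40\], so
#' the quality channel is informative but imperfect. The truth track
#' records every source interval, the per-base error mask, and the exact
#' per-chunk extended CIGAR of the errored read against its source.
#'
#' @param genomes a [simulateGenome()] result (or any named DNAStringSet).
#' @param param a [SimParam()].
#' @return A list: `reads` (a [Biostrings::QualityScaledDNAStringSet]),
#'   `truth` (one record per read: `readId`, `intervals` data.frame with
#'   genome/strand/genomic and read coordinates, `junk` data.frame, `mask`
#'   logical error-per-base vector, `cigars` per-chunk extended CIGAR).
#' @export
simulateReads <- function(genomes, param = SimParam()) {
    genomeChars <- lapply(as.character(genomes),
                          function(s) strsplit(s, "", fixed = TRUE)[[1L]])
    gnames <- names(genomes)
    .withSeed(param@seed + 1L, {
        lens <- integer()
        for (g in seq_along(genomeChars)) {
            target <- param@coverage * length(genomeChars[[g]])
            if (target <= 0) next
            got <- 0
            while (got < target) {
                l <- max(100L, as.integer(round(stats::rlnorm(
                    1, param@readLengthMeanLog, param@readLengthSdLog))))
                lens <- c(lens, l)
                got <- got + l
            }
        }
        nReads <- length(lens)
        seqs <- character(nReads)
        quals <- character(nReads)
        truth <- vector("list", nReads)
        for (i in seq_len(nReads)) {
            len <- lens[i]
            chimeric <- stats::runif(1) < param@chimeraRate
            chunks <- if (chimeric) {
                split <- stats::runif(1, 0.3, 0.7)
                l1 <- max(50L, as.integer(round(len * split)))
                list(.drawChunk(genomeChars, l1),
                     .drawChunk(genomeChars, max(50L, len - l1)))
            } else {
                list(.drawChunk(genomeChars, len))
            }
            tpl <- unlist(lapply(chunks, `[[`, "tpl"), use.names = FALSE)
            nT <- length(tpl)
            # per-read baseline error rate: log-normal around the configured
            # mean (reads of this platform span roughly 5-40% error)
            eBase <- if (param@readErrorSdLog > 0 && param@errorRate > 0) {
                mu <- log(param@errorRate) - param@readErrorSdLog^2 / 2
                min(max(stats::rlnorm(1, mu, param@readErrorSdLog), 0.02), 0.45)
            } else param@errorRate
            eRate <- rep(eBase, nT)
            junk <- data.frame(tplStart = integer(), tplEnd = integer(),
                               errorRate = numeric())
            if (stats::runif(1) < param@junkRate) {
                jlen <- min(nT, sample(
                    param@junkLengthRange[1L]:param@junkLengthRange[2L], 1L))
                jstart <- sample.int(nT - jlen + 1L, 1L)
                jerr <- stats::runif(1, param@junkErrorRange[1L],
                                     param@junkErrorRange[2L])
                eRate[jstart:(jstart + jlen - 1L)] <- jerr
                junk <- data.frame(tplStart = jstart - 1L,
                                   tplEnd = jstart + jlen - 1L,
                                   errorRate = jerr)
            }
            isErr <- stats::runif(nT) < eRate
            typ <- stats::runif(nT)
            subFrac <- 1 - param@indelFraction
            isSub <- isErr & typ < subFrac
            isIns <- isErr & typ >= subFrac & typ < subFrac + param@indelFraction / 2
            isDel <- isErr & !isSub & !isIns
            counts <- rep(1L, nT)
            counts[isDel] <- 0L
            counts[isIns] <- 2L
            emitted <- rep(seq_len(nT), counts)
            nR <- length(emitted)
            insFlag <- c(FALSE, emitted[-1L] == emitted[-nR])
            codes <- match(tpl[emitted], BASES) - 1L
            subHere <- isSub[emitted] & !insFlag
            nSub <- sum(subHere)
            if (nSub > 0L)  # substitute with one of the three other bases
                codes[subHere] <- (codes[subHere] +
                                   sample.int(3L, nSub, replace = TRUE)) %% 4L
            nIns <- sum(insFlag)
            if (nIns > 0L)
                codes[insFlag] <- sample.int(4L, nIns, replace = TRUE) - 1L
            mask <- subHere | insFlag
            # quality tracks the configured local error rate, noisily
            eLocal <- pmax(eRate[emitted], 1e-4)
            phred <- as.integer(round(stats::rnorm(
                nR, -10 * log10(eLocal), param@qualitySd)))
            phred <- pmin(pmax(phred, 0L), 40L)
            seqs[i] <- paste(BASES[codes + 1L], collapse = "")
            quals[i] <- intToUtf8(phred + 33L)
            # coordinates and per-chunk CIGAR
            cumCounts <- cumsum(counts)
            tplEnds <- cumsum(vapply(chunks, function(ch) length(ch$tpl),
                                     integer(1)))
            tplStarts <- c(0L, utils::head(tplEnds, -1L))
            readEnds <- cumCounts[tplEnds]
            readStarts <- c(0L, utils::head(readEnds, -1L))
            opCounts <- counts
            opCounts[isDel] <- 1L
            opEmit <- rep(seq_len(nT), opCounts)
            opIns <- c(FALSE, opEmit[-1L] == opEmit[-length(opEmit)])
            ops <- rep("=", length(opEmit))
            ops[isDel[opEmit]] <- "D"
            ops[isSub[opEmit]] <- "X"
            ops[opIns] <- "I"
            opBreaks <- cumsum(opCounts)[tplEnds]
            opStarts <- c(0L, utils::head(opBreaks, -1L))
            cigars <- vapply(seq_along(chunks), function(j) {
                o <- ops[(opStarts[j] + 1L):opBreaks[j]]
                if (chunks[[j]]$strand == "-") o <- rev(o)
                r <- rle(o)
                paste0(r$lengths, r$values, collapse = "")
            }, character(1))
            if (nrow(junk) > 0L) {
                junk$readStart <- if (junk$tplStart == 0L) 0L
                                  else cumCounts[junk$tplStart]
                junk$readEnd <- cumCounts[junk$tplEnd]
            } else {
                junk$readStart <- integer()
                junk$readEnd <- integer()
            }
            truth[[i]] <- list(
                readId = sprintf("read%05d", i),
                intervals = data.frame(
                    genome = gnames[vapply(chunks, `[[`, integer(1), "genome")],
                    strand = vapply(chunks, `[[`, character(1), "strand"),
                    gStart = vapply(chunks, `[[`, integer(1), "gStart"),
                    gEnd = vapply(chunks, `[[`, integer(1), "gEnd"),
                    readStart = readStarts, readEnd = readEnds,
                    stringsAsFactors = FALSE),
                junk = junk, mask = mask, cigars = cigars)
        }
        ids <- vapply(truth, `[[`, character(1), "readId")
        reads <- Biostrings::QualityScaledDNAStringSet(
            stats::setNames(Biostrings::DNAStringSet(seqs), ids),
            Biostrings::PhredQuality(stats::setNames(
                Biostrings::BStringSet(quals), ids)))
        names(truth) <- ids
        list(reads = reads, truth = truth)
    })
}

#' Reference-free truth labels for segments of simulated reads
#'
#' Identity of a segment = fraction of its read bases that are not
#' simulator-introduced errors, straight from the truth error mask.
#'
#' @param truth the `truth` element of [simulateReads()] output.
#' @param segments a [SegmentSet-class] or its info data.frame.
#' @return A label data.frame shaped like [labelSegments()] output.
#' @export
truthLabels <- function(truth, segments) {
    info <- if (methods::is(segments, "SegmentSet")) segments@info else segments
    miss <- setdiff(unique(info$refId), names(truth))
    if (length(miss))
        stop("unknown read id(s) in segments: ",
             paste(utils::head(miss, 5L), collapse = ", "))
    identity <- vapply(seq_len(nrow(info)), function(i) {
        mask <- truth[[info$refId[i]]]$mask
        segmentIdentity(!mask, info$baseStart[i], info$baseEnd[i])
    }, numeric(1))
    data.frame(refId = info$refId, segmentIndex = info$segmentIndex,
               baseStart = info$baseStart, baseEnd = info$baseEnd,
               identity = identity, stringsAsFactors = FALSE)
}

#' Emit the simulator's truth track as SAM alignments
#'
#' Writes one record per read aligning its primary (longest) source chunk
#' with the exact extended CIGAR the simulator recorded; any other chunk
#' (the far side of a chimeric junction) becomes a soft clip. This gives
#' the alignment-label path a perfect mapper to consume, without wrapping
#' an external aligner.
#'
#' @param truth the `truth` element of [simulateReads()] output.
#' @param reads the matching reads.
#' @param genomes the genomes the reads were simulated from.
#' @param path output SAM path.
#' @return `path`, invisibly.
#' @export
truthToSam <- function(truth, reads, genomes, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("@HD\tVN:1.6\tSO:unknown",
                 sprintf("@SQ\tSN:%s\tLN:%d", names(genomes),
                         Biostrings::width(genomes))), con)
    seqs <- as.character(reads)
    quals <- as.character(Biostrings::quality(reads))
    for (id in names(truth)) {
        tr <- truth[[id]]
        iv <- tr$intervals
        primary <- which.max(iv$readEnd - iv$readStart)
        rec <- iv[primary, ]
        readLen <- nchar(seqs[[id]])
        pre <- rec$readStart
        post <- readLen - rec$readEnd
        seq <- seqs[[id]]
        qual <- quals[[id]]
        flag <- 0L
        if (rec$strand == "-") {
            seq <- as.character(Biostrings::reverseComplement(
                Biostrings::DNAString(seq)))
            qual <- intToUtf8(rev(utf8ToInt(qual)))
            tmp <- pre; pre <- post; post <- tmp
            flag <- 16L
        }
        cigar <- paste0(if (pre > 0L) paste0(pre, "S") else "",
                        tr$cigars[primary],
                        if (post > 0L) paste0(post, "S") else "")
        writeLines(paste(id, flag, rec$genome, rec$gStart + 1L, 60L, cigar,
                         "*", 0L, 0L, seq, qual, sep = "\t"), con)
    }
    invisible(path)
}

#' Serialize / restore the truth track as TSV
#'
#' One row per read: `read_id`, the source intervals
#' (`genome:strand:gStart:gEnd:readStart:readEnd` separated by `;`), junk
#' intervals (`readStart:readEnd:errorRate`), per-chunk CIGARs, and the
#' run-length-encoded error mask (`length:value` pairs, value 1 = error).
#'
#' @param truth the `truth` element of [simulateReads()] output.
#' @param path file path.
#' @return `writeTruthTsv`: `path`, invisibly. `readTruthTsv`: the truth
#'   list.
#' @export
writeTruthTsv <- function(truth, path) {
    rows <- vapply(truth, function(tr) {
        iv <- tr$intervals
        ivs <- paste(sprintf("%s:%s:%d:%d:%d:%d", iv$genome, iv$strand,
                             iv$gStart, iv$gEnd, iv$readStart, iv$readEnd),
                     collapse = ";")
        jk <- if (nrow(tr$junk)) paste(sprintf("%d:%d:%g", tr$junk$readStart,
                                               tr$junk$readEnd,
                                               tr$junk$errorRate),
                                       collapse = ";") else "."
        r <- rle(as.integer(tr$mask))
        paste(tr$readId, ivs, jk, paste(tr$cigars, collapse = ";"),
              paste(sprintf("%d:%d", r$lengths, r$values), collapse = ","),
              sep = "\t")
    }, character(1))
    writeLines(c("read_id\tintervals\tjunk\tcigars\tmask_rle", rows), path)
    invisible(path)
}

#' @rdname writeTruthTsv
#' @export
readTruthTsv <- function(path) {
    lines <- readLines(path)
    if (length(lines) == 0L || lines[1L] != "read_id\tintervals\tjunk\tcigars\tmask_rle")
        stop("malformed truth file: ", path)
    truth <- lapply(seq_along(lines)[-1L], function(ln) {
        f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]
        if (length(f) != 5L) stop(sprintf("line %d: expected 5 fields", ln))
        ivParts <- strsplit(strsplit(f[2L], ";", fixed = TRUE)[[1L]], ":",
                            fixed = TRUE)
        iv <- data.frame(
            genome = vapply(ivParts, `[`, character(1), 1L),
            strand = vapply(ivParts, `[`, character(1), 2L),
            gStart = as.integer(vapply(ivParts, `[`, character(1), 3L)),
            gEnd = as.integer(vapply(ivParts, `[`, character(1), 4L)),
            readStart = as.integer(vapply(ivParts, `[`, character(1), 5L)),
            readEnd = as.integer(vapply(ivParts, `[`, character(1), 6L)),
            stringsAsFactors = FALSE)
        junk <- if (f[3L] == ".") {
            data.frame(tplStart = integer(), tplEnd = integer(),
                       errorRate = numeric(), readStart = integer(),
                       readEnd = integer())
        } else {
            jp <- strsplit(strsplit(f[3L], ";", fixed = TRUE)[[1L]], ":",
                           fixed = TRUE)
            data.frame(tplStart = NA_integer_, tplEnd = NA_integer_,
                       errorRate = as.numeric(vapply(jp, `[`, character(1), 3L)),
                       readStart = as.integer(vapply(jp, `[`, character(1), 1L)),
                       readEnd = as.integer(vapply(jp, `[`, character(1), 2L)))
        }
        mr <- strsplit(strsplit(f[5L], ",", fixed = TRUE)[[1L]], ":",
                       fixed = TRUE)
        mask <- inverse.rle(list(
            lengths = as.integer(vapply(mr, `[`, character(1), 1L)),
            values = as.integer(vapply(mr, `[`, character(1), 2L)))) == 1L
        list(readId = f[1L], intervals = iv, junk = junk, mask = mask,
             cigars = strsplit(f[4L], ";", fixed = TRUE)[[1L]])
    })
    names(truth) <- vapply(truth, `[[`, character(1), "readId")
    truth
}
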