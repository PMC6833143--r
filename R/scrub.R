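# Scrubbing: remove below-threshold segments, split reads there, drop short
# fragments, write FASTQ.

#' Scrub one read
#'
#' Maximal runs of kept segments (prediction >= threshold) become
#' fragments, with sequence and quality sliced in sync; fragments shorter
#' than `minLength` are discarded. The whole below-threshold segment is
#' removed (no trimming into it); a below-threshold final segment removes
#' through the read end, padded tail columns included. A read whose
#' segments are all kept is emitted unchanged under its original id;
#' otherwise emitted fragments are renamed `<id>:<n>`, numbered 1..m left
#' to right.
#'
#' @param id read identifier.
#' @param seq,qual sequence and quality strings (equal length).
#' @param predictions data.frame with `baseStart`, `baseEnd`, `prediction`
#'   whose ranges partition `[0, nchar(seq))`.
#' @param param a [ScrubParam()].
#' @return A list: `fragments` data.frame (`id`, `seq`, `qual`,
#'   `baseStart`, `baseEnd`), `basesRemoved`, `fragmentsDropped`.
#' @export
scrubRead <- function(id, seq, qual, predictions, param = ScrubParam()) {
    len <- nchar(seq)
    if (nchar(qual) != len) stop("sequence/quality length mismatch for ", id)
    p <- predictions[order(predictions$baseStart), , drop = FALSE]
    p$baseStart <- as.integer(p$baseStart)
    p$baseEnd <- as.integer(p$baseEnd)
    if (nrow(p) == 0L ||
        p$baseStart[1L] != 0L || p$baseEnd[nrow(p)] != len ||
        (nrow(p) > 1L && any(p$baseStart[-1L] != p$baseEnd[-nrow(p)])))
        stop("segment ranges do not partition [0, ", len, ") for read ", id)
    keep <- p$prediction >= param@threshold
    runs <- rle(keep)
    ends <- cumsum(runs$lengths)
    starts <- c(0L, utils::head(ends, -1L)) + 1L
    frag <- data.frame(id = character(), seq = character(), qual = character(),
                       baseStart = integer(), baseEnd = integer(),
                       stringsAsFactors = FALSE)
    dropped <- 0L
    n <- 0L
    allKept <- all(keep)
    for (r in seq_along(runs$values)) {
        if (!runs$values[r]) next
        b0 <- p$baseStart[starts[r]]
        b1 <- p$baseEnd[ends[r]]
        if (b1 - b0 < param@minLength) { dropped <- dropped + 1L; next }
        n <- n + 1L
        frag <- rbind(frag, data.frame(
            id = if (allKept) id else paste0(id, ":", n),
            seq = substr(seq, b0 + 1L, b1), qual = substr(qual, b0 + 1L, b1),
            baseStart = b0, baseEnd = b1, stringsAsFactors = FALSE))
    }
    list(fragments = frag, basesRemoved = len - sum(nchar(frag$seq)),
         fragmentsDropped = dropped)
}

#' Scrub a read set against a prediction table
#'
#' Reads absent from the prediction table pass through unmodified with a
#' warning. Record order is preserved (fragments of one read stay
#' left-to-right in its position).
#'
#' @param reads a [Biostrings::QualityScaledDNAStringSet].
#' @param predictions data.frame with `refId`, `baseStart`, `baseEnd`,
#'   `prediction` (see [predictionTable()]).
#' @param param a [ScrubParam()].
#' @return A list: `reads` (the scrubbed
#'   [Biostrings::QualityScaledDNAStringSet]) and `stats` (named list:
#'   `readsIn`, `readsOut`, `basesIn`, `basesOut`, `basesRemoved`,
#'   `fragmentsDroppedLength`; `basesOut + basesRemoved == basesIn`).
#' @export
scrubReads <- function(reads, predictions, param = ScrubParam()) {
    rs <- .readStrings(reads)
    ids <- names(rs$seq)
    noPred <- setdiff(ids, unique(predictions$refId))
    if (length(noPred))
        warning(length(noPred), " read(s) have no predictions and pass ",
                "through unmodified", call. = FALSE)
    outFrag <- vector("list", length(ids))
    basesRemoved <- 0
    dropped <- 0L
    for (i in seq_along(ids)) {
        id <- ids[i]
        if (id %in% noPred) {
            outFrag[[i]] <- data.frame(id = id, seq = rs$seq[[id]],
                                       qual = rs$qual[[id]],
                                       stringsAsFactors = FALSE)
            next
        }
        sc <- scrubRead(id, rs$seq[[id]], rs$qual[[id]],
                        predictions[predictions$refId == id, , drop = FALSE],
                        param)
        outFrag[[i]] <- sc$fragments[, c("id", "seq", "qual")]
        basesRemoved <- basesRemoved + sc$basesRemoved
        dropped <- dropped + sc$fragmentsDropped
    }
    frag <- do.call(rbind, outFrag)
    out <- if (is.null(frag) || nrow(frag) == 0L) {
        Biostrings::QualityScaledDNAStringSet(
            Biostrings::DNAStringSet(), Biostrings::PhredQuality(character()))
    } else {
        Biostrings::QualityScaledDNAStringSet(
            stats::setNames(Biostrings::DNAStringSet(frag$seq), frag$id),
            Biostrings::PhredQuality(stats::setNames(
                Biostrings::BStringSet(frag$qual), frag$id)))
    }
    basesIn <- sum(nchar(rs$seq))
    basesOut <- sum(Biostrings::width(out))
    stats <- list(readsIn = length(ids), readsOut = length(out),
                  basesIn = basesIn, basesOut = basesOut,
                  basesRemoved = basesIn - basesOut,
                  fragmentsDroppedLength = dropped)
    list(reads = out, stats = stats)
}

#' Scrub a FASTQ file to a new FASTQ file
#'
#' @param inPath input FASTQ (4-line records, Phred+33).
#' @param predictions prediction table (see [scrubReads()]), or a TSV path
#'   written by [writePredictionsTsv()].
#' @param param a [ScrubParam()].
#' @param outPath output FASTQ path.
#' @return The stats list (see [scrubReads()]), invisibly.
#' @export
scrubFastq <- function(inPath, predictions, param = ScrubParam(), outPath) {
    if (is.character(predictions) && length(predictions) == 1L)
        predictions <- readPredictionsTsv(predictions)
    reads <- readFastq(inPath)
    res <- scrubReads(reads, predictions, param)
    writeFastq(res$reads, outPath)
    invisible(res$stats)
}

#' Write / read a prediction table as TSV
#'
#' Columns `ref_id`, `segment_index`, `base_start`, `base_end`,
#' `prediction`.
#'
#' @param predictions a [predictionTable()] data.frame.
#' @param path file path.
#' @return `path` / the table.
#' @export
writePredictionsTsv <- function(predictions, path) {
    utils::write.table(
        data.frame(ref_id = predictions$refId,
                   segment_index = predictions$segmentIndex,
                   base_start = predictions$baseStart,
                   base_end = predictions$baseEnd,
                   prediction = predictions$prediction),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writePredictionsTsv
#' @export
readPredictionsTsv <- function(path) {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    need <- c("ref_id", "segment_index", "base_start", "base_end",
              "prediction")
    if (!all(need %in% names(tab)))
        stop("malformed predictions file: ", path)
    data.frame(refId = as.character(tab$ref_id),
               segmentIndex = tab$segment_index,
               baseStart = tab$base_start, baseEnd = tab$base_end,
               prediction = tab$prediction, stringsAsFactors = FALSE)
}
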