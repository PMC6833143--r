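#' Minimizer sketches for a read set
#'
#' @param reads a named character vector, [Biostrings::DNAStringSet] or
#'   [Biostrings::QualityScaledDNAStringSet] with unique names.
#' @param param a [MinimizerParam()].
#' @return A named list with one `data.frame` per read (see
#'   [extractMinimizers()]).
#' @export
readSketches <- function(reads, param = MinimizerParam()) {
    if (length(reads) == 0L) return(stats::setNames(list(), character()))
    ids <- names(reads)
    if (is.null(ids) || anyNA(ids) || any(ids == ""))
        stop("reads must have non-empty names")
    if (anyDuplicated(ids))
        stop("duplicate read identifiers: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    seqs <- as.character(reads)
    out <- lapply(seqs, extractMinimizers, param = param)
    names(out) <- ids
    out
}

#' Build the hash index over all minimizer occurrences
#'
#' Every extracted minimizer occurrence of every read appears exactly once.
#'
#' @inheritParams readSketches
#' @param sketches optional precomputed [readSketches()] result.
#' @return A [data.table::data.table] keyed by `hash` with columns `hash`,
#'   `readId`, `ordinal` (1-based index into that read's minimizer list),
#'   `pos` (0-based base start), `strand`.
#' @export
minimizerIndex <- function(reads, param = MinimizerParam(), sketches = NULL) {
    if (is.null(sketches)) sketches <- readSketches(reads, param)
    ids <- names(sketches)
    if (length(sketches) == 0L) {
        idx <- data.table::data.table(
            hash = numeric(), readId = character(), ordinal = integer(),
            pos = integer(), strand = character())
        data.table::setkeyv(idx, "hash")
        return(idx[])
    }
    n <- vapply(sketches, nrow, integer(1))
    idx <- data.table::data.table(
        hash = unlist(lapply(sketches, `[[`, "hash"), use.names = FALSE),
        readId = rep(ids, n),
        ordinal = unlist(lapply(n, seq_len), use.names = FALSE),
        pos = unlist(lapply(sketches, `[[`, "start"), use.names = FALSE),
        strand = unlist(lapply(sketches, `[[`, "strand"), use.names = FALSE))
    data.table::setkeyv(idx, "hash")
    idx[]
}

#' All-vs-all read overlapping by shared co-linear minimizers
#'
#' Each read serves as a reference once; for every (reference, query) pair
#' sharing minimizer hashes, the longest co-linear chain (strictly
#' increasing reference minimizer index, query positions strictly increasing
#' on `+` pairs and strictly decreasing on `-` pairs, base gaps on both
#' reads capped at `maxGap`) is kept, and the pair is reported when the
#' chain holds at least `minShared` matches. Matching is strand-agnostic
#' because k-mers are canonical at extraction time; the relative orientation
#' is recovered from the occurrence strands. Minimizers occurring in more
#' than `maxOccurrence` reads are skipped (repeat guard). Self-pairs are
#' excluded.
#'
#' @inheritParams readSketches
#' @param overlapParam an [OverlapParam()].
#' @param sketches optional precomputed [readSketches()] result.
#' @return A [data.table::data.table] with one row per reported overlap:
#'   `refId`, `queryId`, `strand` (relative), `nShared`, `refStart`,
#'   `refEnd`, `queryStart`, `queryEnd` (0-based half-open spans covering
#'   all matched minimizer bases), and `matches`, a list column of
#'   `data.frame(refIndex, refPos, queryPos)` ordered by `refIndex`.
#' @export
findReadOverlaps <- function(reads, param = MinimizerParam(),
                             overlapParam = OverlapParam(),
                             sketches = NULL) {
    if (is.null(sketches)) sketches <- readSketches(reads, param)
    occ <- minimizerIndex(reads, param, sketches = sketches)
    empty <- .emptyOverlaps()
    if (nrow(occ) == 0L) return(empty)
    # repeat guard: hashes present in too many distinct reads
    nReads <- occ[, list(nr = length(unique(readId))), by = "hash"]
    keepHash <- nReads[nReads$nr <= overlapParam@maxOccurrence, ]$hash
    occ <- occ[occ$hash %in% keepHash, ]
    if (nrow(occ) == 0L) return(empty)
    pairs <- occ[occ, on = "hash", allow.cartesian = TRUE]
    pairs <- pairs[pairs$readId != pairs$i.readId, ]
    if (nrow(pairs) == 0L) return(empty)
    mt <- data.table::data.table(
        refId = pairs$readId, queryId = pairs$i.readId,
        strand = ifelse(pairs$strand == pairs$i.strand, "+", "-"),
        refIndex = pairs$ordinal, refPos = pairs$pos,
        queryPos = pairs$i.pos)
    rm(pairs)
    data.table::setorderv(mt, c("refId", "queryId", "strand", "refIndex",
                                "queryPos"))
    grp <- mt[, list(.n = .N), by = c("refId", "queryId", "strand")]
    offsets <- c(0L, cumsum(grp$.n))
    chained <- chain_matches_cpp(offsets, mt$refIndex, mt$refPos, mt$queryPos,
                                 grp$strand == "-", overlapParam@maxGap)
    grp$nShared <- chained$chainLength
    keepGrp <- grp$nShared >= overlapParam@minShared
    mt <- mt[chained$keep & rep(keepGrp, grp$.n), ]
    grp <- grp[keepGrp, ]
    if (nrow(mt) == 0L) return(empty)
    k <- param@k
    ov <- mt[, list(
        nShared = .N,
        refStart = min(refPos), refEnd = max(refPos) + k,
        queryStart = min(queryPos), queryEnd = max(queryPos) + k,
        matches = list(data.frame(refIndex = refIndex, refPos = refPos,
                                  queryPos = queryPos))),
        by = c("refId", "queryId", "strand")]
    data.table::setorderv(ov, c("refId", "queryId", "strand"))
    ov[]
}

.emptyOverlaps <- function() {
    data.table::data.table(
        refId = character(), queryId = character(), strand = character(),
        nShared = integer(), refStart = integer(), refEnd = integer(),
        queryStart = integer(), queryEnd = integer(), matches = list())
}

#' Write overlaps to the native match-file format
#'
#' TSV with header; columns `ref_id`, `query_id`, `strand`, `k`, the spans,
#' and the chained matches as comma-separated `refIndex:queryPos` pairs
#' (both 0-based on output; `refIndex` is the 0-based index into the
#' reference read's minimizer list). Rows are ordered by
#' (`ref_id`, `query_id`, `strand`). `refPos` is recovered on parse from
#' the reference sketch when available; [readOverlaps()] otherwise leaves
#' it `NA`.
#'
#' @param overlaps a [findReadOverlaps()] table.
#' @param path output path.
#' @param param the [MinimizerParam()] the overlaps were computed with.
#' @return `path`, invisibly.
#' @export
writeOverlaps <- function(overlaps, path, param = MinimizerParam()) {
    pairsStr <- vapply(overlaps$matches, function(m) {
        paste(sprintf("%d:%d", m$refIndex - 1L, m$queryPos), collapse = ",")
    }, character(1))
    tab <- data.frame(ref_id = overlaps$refId, query_id = overlaps$queryId,
                      strand = overlaps$strand, k = rep(param@k, nrow(overlaps)),
                      ref_start = overlaps$refStart, ref_end = overlaps$refEnd,
                      query_start = overlaps$queryStart,
                      query_end = overlaps$queryEnd,
                      matches = pairsStr, stringsAsFactors = FALSE)
    if (nrow(tab)) tab <- tab[order(tab$ref_id, tab$query_id, tab$strand), ]
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Parse a native match file
#'
#' @param path a file written by [writeOverlaps()].
#' @param sketches optional [readSketches()] result used to restore `refPos`
#'   for each match.
#' @return An overlap table shaped like [findReadOverlaps()] output.
#' @export
readOverlaps <- function(path, sketches = NULL) {
    lines <- readLines(path)
    if (length(lines) == 0L) stop("empty overlap file (missing header): ", path)
    header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
    need <- c("ref_id", "query_id", "strand", "k", "ref_start", "ref_end",
              "query_start", "query_end", "matches")
    if (!identical(header, need))
        stop("line 1: malformed overlap file header")
    if (length(lines) == 1L) return(.emptyOverlaps())
    rows <- lapply(seq_along(lines)[-1L], function(ln) {
        f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]
        if (length(f) != length(need))
            stop(sprintf("line %d: expected %d fields, found %d", ln,
                         length(need), length(f)))
        pieces <- strsplit(f[9L], ",", fixed = TRUE)[[1L]]
        pm <- regmatches(pieces, regexec("^([0-9]+):([0-9]+)$", pieces))
        if (any(lengths(pm) != 3L))
            stop(sprintf("line %d: malformed match pair '%s'", ln,
                         pieces[which(lengths(pm) != 3L)[1L]]))
        refIndex <- as.integer(vapply(pm, `[`, character(1), 2L)) + 1L
        queryPos <- as.integer(vapply(pm, `[`, character(1), 3L))
        refPos <- rep(NA_integer_, length(refIndex))
        if (!is.null(sketches) && f[1L] %in% names(sketches))
            refPos <- sketches[[f[1L]]]$start[refIndex]
        nums <- suppressWarnings(as.integer(f[4:8]))
        if (anyNA(nums)) stop(sprintf("line %d: non-numeric coordinate", ln))
        data.table::data.table(
            refId = f[1L], queryId = f[2L], strand = f[3L],
            nShared = length(refIndex), refStart = nums[2L], refEnd = nums[3L],
            queryStart = nums[4L], queryEnd = nums[5L],
            matches = list(data.frame(refIndex = refIndex, refPos = refPos,
                                      queryPos = queryPos)))
    })
    data.table::rbindlist(rows)[]
}

#' Read a standard PAF file
#'
#' Standard 12+ column pairwise-mapping format; extra columns (SAM-style
#' tags) are collected into a `tags` column.
#'
#' @param path PAF file path.
#' @return A [data.table::data.table] with the 12 standard columns
#'   (`qname`, `qlen`, `qstart`, `qend`, `strand`, `tname`, `tlen`,
#'   `tstart`, `tend`, `nmatch`, `alen`, `mapq`) plus `tags`.
#' @export
readPaf <- function(path) {
    lines <- readLines(path)
    cols <- c("qname", "qlen", "qstart", "qend", "strand", "tname", "tlen",
              "tstart", "tend", "nmatch", "alen", "mapq")
    if (length(lines) == 0L) {
        out <- data.table::as.data.table(
            c(stats::setNames(list(character(), integer(), integer(),
                                   integer(), character(), character(),
                                   integer(), integer(), integer(),
                                   integer(), integer(), integer()), cols),
              list(tags = character())))
        return(out)
    }
    rows <- lapply(seq_along(lines), function(ln) {
        f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]
        if (length(f) < 12L)
            stop(sprintf("line %d: PAF record has %d fields (need >= 12)",
                         ln, length(f)))
        num <- suppressWarnings(as.integer(f[c(2:4, 7:12)]))
        if (anyNA(num))
            stop(sprintf("line %d: malformed numeric PAF field", ln))
        data.table::data.table(
            qname = f[1L], qlen = num[1L], qstart = num[2L], qend = num[3L],
            strand = f[5L], tname = f[6L], tlen = num[4L], tstart = num[5L],
            tend = num[6L], nmatch = num[7L], alen = num[8L], mapq = num[9L],
            tags = paste(f[-(1:12)], collapse = "\t"))
    })
    data.table::rbindlist(rows)[]
}

#' Recover minimizer-level overlaps from external PAF records
#'
#' Alternative input path: take pair and interval calls from an external
#' overlapper's PAF and rebuild the matched minimizer positions by
#' intersecting the two reads' sketches inside the reported intervals, then
#' chaining as in [findReadOverlaps()]. The PAF target is treated as the
#' reference read of each overlap.
#'
#' @param paf a [readPaf()] table.
#' @inheritParams findReadOverlaps
#' @return An overlap table shaped like [findReadOverlaps()] output.
#' @export
pafOverlaps <- function(paf, reads, param = MinimizerParam(),
                        overlapParam = OverlapParam(), sketches = NULL) {
    if (is.null(sketches)) sketches <- readSketches(reads, param)
    out <- vector("list", nrow(paf))
    for (i in seq_len(nrow(paf))) {
        rec <- paf[i, ]
        if (!rec$tname %in% names(sketches) || !rec$qname %in% names(sketches))
            stop("PAF names a read absent from the read set: ",
                 rec$tname, " / ", rec$qname)
        if (rec$tname == rec$qname) next
        sr <- sketches[[rec$tname]]
        sq <- sketches[[rec$qname]]
        rIn <- which(sr$start >= rec$tstart & sr$start + param@k <= rec$tend)
        qIn <- which(sq$start >= rec$qstart & sq$start + param@k <= rec$qend)
        if (length(rIn) == 0L || length(qIn) == 0L) next
        shared <- merge(
            data.frame(hash = sr$hash[rIn], refIndex = rIn,
                       refPos = sr$start[rIn], rs = sr$strand[rIn]),
            data.frame(hash = sq$hash[qIn], queryPos = sq$start[qIn],
                       qs = sq$strand[qIn]),
            by = "hash")
        rel <- ifelse(shared$rs == shared$qs, "+", "-")
        shared <- shared[rel == rec$strand, ]
        if (nrow(shared) == 0L) next
        shared <- shared[order(shared$refIndex, shared$queryPos), ]
        ch <- chain_matches_cpp(c(0L, nrow(shared)), shared$refIndex,
                                shared$refPos, shared$queryPos,
                                rec$strand == "-", overlapParam@maxGap)
        m <- shared[ch$keep, ]
        if (nrow(m) < overlapParam@minShared) next
        out[[i]] <- data.table::data.table(
            refId = rec$tname, queryId = rec$qname, strand = rec$strand,
            nShared = nrow(m),
            refStart = min(m$refPos), refEnd = max(m$refPos) + param@k,
            queryStart = min(m$queryPos), queryEnd = max(m$queryPos) + param@k,
            matches = list(data.frame(refIndex = m$refIndex,
                                      refPos = m$refPos,
                                      queryPos = m$queryPos)))
    }
    out <- out[!vapply(out, is.null, logical(1))]
    if (length(out) == 0L) return(.emptyOverlaps())
    ov <- data.table::rbindlist(out)
    data.table::setorderv(ov, c("refId", "queryId", "strand"))
    ov[]
}
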