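# Training labels: per-segment percent identity from read-to-reference
# alignments. Identity of a range = (read bases aligned as exact matches) /
# (read bases in the range); clipped or unaligned bases count only in the
# denominator.

#' Read alignment records from a SAM file
#'
#' A light tab-split reader for plain-text SAM (header lines are skipped);
#' CIGAR arithmetic downstream is done with the GenomicAlignments CIGAR
#' utilities. The `MD` tag is captured when present so that ambiguous `M`
#' operations can be resolved into matches and mismatches.
#'
#' @param path SAM file path.
#' @return A `data.frame` with one row per record: `readId`, `flag`,
#'   `target`, `pos` (0-based target start), `mapq`, `cigar`, `md` (`NA` if
#'   absent), `seqLen`, and decoded flag bits `reverse`, `unmapped`,
#'   `secondary`, `supplementary`.
#' @export
readSamAlignments <- function(path) {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "@")]
    recs <- lapply(seq_along(lines), function(i) {
        f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
        if (length(f) < 11L)
            stop(sprintf("SAM record %d: %d fields (need >= 11)", i, length(f)))
        flag <- suppressWarnings(as.integer(f[2L]))
        pos <- suppressWarnings(as.integer(f[4L]))
        if (is.na(flag) || is.na(pos))
            stop(sprintf("SAM record %d: malformed FLAG or POS", i))
        tags <- f[-(1:11)]
        md <- sub("^MD:Z:", "", grep("^MD:Z:", tags, value = TRUE))
        data.frame(readId = f[1L], flag = flag, target = f[3L],
                   pos = pos - 1L, mapq = suppressWarnings(as.integer(f[5L])),
                   cigar = f[6L],
                   md = if (length(md)) md[1L] else NA_character_,
                   seqLen = if (f[10L] == "*") NA_integer_ else nchar(f[10L]),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, recs)
    if (is.null(out))
        out <- data.frame(readId = character(), flag = integer(),
                          target = character(), pos = integer(),
                          mapq = integer(), cigar = character(),
                          md = character(), seqLen = integer(),
                          stringsAsFactors = FALSE)
    out$reverse <- bitwAnd(out$flag, 16L) > 0L
    out$unmapped <- bitwAnd(out$flag, 4L) > 0L
    out$secondary <- bitwAnd(out$flag, 256L) > 0L
    out$supplementary <- bitwAnd(out$flag, 2048L) > 0L
    out
}

# per-aligned-column match verdicts from an MD tag (TRUE = exact match);
# deletions (^ACGT) consume no column
.mdVerdicts <- function(md) {
    toks <- regmatches(md, gregexpr("[0-9]+|\\^[A-Za-z]+|[A-Za-z]", md))[[1L]]
    out <- logical(0)
    for (t in toks) {
        if (startsWith(t, "^")) next
        if (grepl("^[0-9]+$", t)) out <- c(out, rep(TRUE, as.integer(t)))
        else out <- c(out, FALSE)
    }
    out
}

#' Per-base exact-match mask of one alignment record
#'
#' Walks the CIGAR (and MD tag, when present) and returns a logical vector
#' over the original read: `TRUE` where the base is aligned as an exact
#' match to the reference. Soft-clipped, hard-clipped, inserted and
#' mismatched bases are `FALSE`. Plain `M` operations without an MD tag are
#' counted as matches, with a warning, so minimal SAM degrades gracefully.
#' For reverse-strand records the mask is flipped back into original read
#' orientation.
#'
#' @param record one row of [readSamAlignments()] output.
#' @return A logical vector whose length is the original read length
#'   (SEQ length plus hard-clipped bases).
#' @export
alignmentMatchMask <- function(record) {
    ops <- GenomicAlignments::explodeCigarOps(record$cigar)[[1L]]
    lens <- GenomicAlignments::explodeCigarOpLengths(record$cigar)[[1L]]
    mdv <- if (!is.na(record$md)) .mdVerdicts(record$md) else NULL
    mdAt <- 0L
    warned <- FALSE
    parts <- vector("list", length(ops))
    for (i in seq_along(ops)) {
        op <- ops[i]; len <- lens[i]
        if (op %in% c("D", "N", "P")) next
        if (op == "H") { parts[[i]] <- rep(FALSE, len); next }
        if (op %in% c("I", "S")) { parts[[i]] <- rep(FALSE, len); next }
        if (op == "=") { parts[[i]] <- rep(TRUE, len); mdAt <- mdAt + len; next }
        if (op == "X") { parts[[i]] <- rep(FALSE, len); mdAt <- mdAt + len; next }
        # op == "M": ambiguous; resolve via MD when available
        if (!is.null(mdv)) {
            if (mdAt + len > length(mdv))
                stop("MD tag shorter than aligned CIGAR length")
            parts[[i]] <- mdv[mdAt + seq_len(len)]
            mdAt <- mdAt + len
        } else {
            if (!warned) {
                warning("CIGAR 'M' without MD tag: counting M as match",
                        call. = FALSE)
                warned <- TRUE
            }
            parts[[i]] <- rep(TRUE, len)
        }
    }
    mask <- unlist(parts, use.names = FALSE)
    if (is.null(mask)) mask <- logical(0)
    if (isTRUE(record$reverse)) mask <- rev(mask)
    mask
}

#' Percent identity of a read range under an alignment mask
#'
#' @param mask logical per-base match mask (see [alignmentMatchMask()]),
#'   or `NULL` for an unaligned read (identity 0).
#' @param baseStart,baseEnd 0-based half-open read range.
#' @return Fraction of read bases in the range aligned as exact matches.
#' @examples
#' mask <- c(rep(TRUE, 18), rep(FALSE, 2))
#' segmentIdentity(mask, 0, 20)  # 0.9
#' @export
segmentIdentity <- function(mask, baseStart, baseEnd) {
    if (baseEnd <= baseStart) stop("empty segment range")
    if (is.null(mask)) return(0)
    if (baseEnd > length(mask))
        stop(sprintf("range [%d,%d) exceeds read length %d", baseStart,
                     baseEnd, length(mask)))
    mean(mask[(baseStart + 1L):baseEnd])
}

# pick one primary alignment per read: drop unmapped/secondary/supplementary,
# then keep the record with the most aligned read bases (M/=/X)
.primaryAlignments <- function(aln) {
    aln <- aln[!aln$unmapped & !aln$secondary & !aln$supplementary, ,
               drop = FALSE]
    if (nrow(aln) == 0L) return(aln)
    aligned <- vapply(seq_len(nrow(aln)), function(i) {
        ops <- GenomicAlignments::explodeCigarOps(aln$cigar[i])[[1L]]
        lens <- GenomicAlignments::explodeCigarOpLengths(aln$cigar[i])[[1L]]
        sum(lens[ops %in% c("M", "=", "X")])
    }, numeric(1))
    aln <- aln[order(aln$readId, -aligned), , drop = FALSE]
    aln[!duplicated(aln$readId), , drop = FALSE]
}

#' Label segments with alignment-derived percent identity
#'
#' One label per segment. Reads without any primary alignment get identity
#' 0 for all their segments. A read's whole-read identity equals the
#' length-weighted mean of its segment identities exactly, because match
#' counts are additive over the partition.
#'
#' @param alignments [readSamAlignments()] output (or any data.frame of the
#'   same shape, e.g. from [truthToSam()] via a file).
#' @param segments a [SegmentSet-class] or its [segmentInfo()] data.frame.
#' @param readLengths named integer vector of original read lengths, used
#'   to validate masks; reads absent from `alignments` must appear here.
#' @return A `data.frame`: `refId`, `segmentIndex`, `baseStart`, `baseEnd`,
#'   `identity`.
#' @export
labelSegments <- function(alignments, segments, readLengths) {
    info <- if (methods::is(segments, "SegmentSet")) segments@info else segments
    miss <- setdiff(unique(info$refId), names(readLengths))
    if (length(miss))
        stop("segments name reads absent from the read set: ",
             paste(utils::head(miss, 5L), collapse = ", "))
    prim <- .primaryAlignments(alignments)
    masks <- new.env(parent = emptyenv())
    for (i in seq_len(nrow(prim))) {
        m <- alignmentMatchMask(prim[i, ])
        want <- readLengths[[prim$readId[i]]]
        if (!is.null(want) && length(m) != want)
            stop(sprintf(
                "alignment of '%s' accounts for %d bases but the read has %d",
                prim$readId[i], length(m), want))
        assign(prim$readId[i], m, envir = masks)
    }
    identity <- vapply(seq_len(nrow(info)), function(i) {
        id <- info$refId[i]
        mask <- if (exists(id, envir = masks, inherits = FALSE))
            get(id, envir = masks) else NULL
        segmentIdentity(mask, info$baseStart[i], info$baseEnd[i])
    }, numeric(1))
    data.frame(refId = info$refId, segmentIndex = info$segmentIndex,
               baseStart = info$baseStart, baseEnd = info$baseEnd,
               identity = identity, stringsAsFactors = FALSE)
}

#' Read PAF records carrying a cg (CIGAR) tag as alignment records
#'
#' Converts PAF-with-CIGAR rows into the same record shape as
#' [readSamAlignments()] so [labelSegments()] accepts either. The query is
#' the read; bases outside `[qstart, qend)` become soft clips.
#'
#' @param path PAF file path (rows must carry `cg:Z:` tags).
#' @return A `data.frame` shaped like [readSamAlignments()] output.
#' @export
readPafAlignments <- function(path) {
    paf <- readPaf(path)
    n <- nrow(paf)
    cg <- rep(NA_character_, n)
    if (n > 0L) {
        hit <- regmatches(paf$tags, regexpr("cg:Z:[0-9MIDNSHP=X]+", paf$tags))
        has <- grepl("cg:Z:", paf$tags, fixed = TRUE)
        if (any(!has)) stop("PAF rows without cg:Z: CIGAR tag")
        cg <- sub("^cg:Z:", "", hit)
    }
    # synthesize SAM-style records in original read orientation: clip the
    # unaligned prefix/suffix; reverse the CIGAR for '-' strand so it walks
    # the read forward after the mask flip
    cigar <- character(n)
    for (i in seq_len(n)) {
        pre <- paf$qstart[i]
        post <- paf$qlen[i] - paf$qend[i]
        if (paf$strand[i] == "-") { tmp <- pre; pre <- post; post <- tmp }
        cigar[i] <- paste0(if (pre > 0L) paste0(pre, "S") else "", cg[i],
                           if (post > 0L) paste0(post, "S") else "")
    }
    md <- rep(NA_character_, n)
    hasMd <- grepl("MD:Z:", paf$tags, fixed = TRUE)
    md[hasMd] <- sub("^.*MD:Z:([^\t]+).*$", "\\1", paf$tags[hasMd])
    data.frame(readId = paf$qname, flag = ifelse(paf$strand == "-", 16L, 0L),
               target = paf$tname, pos = paf$tstart, mapq = paf$mapq,
               cigar = cigar, md = md, seqLen = paf$qlen,
               reverse = paf$strand == "-", unmapped = FALSE,
               secondary = FALSE, supplementary = FALSE,
               stringsAsFactors = FALSE)
}

#' Write segment labels to TSV
#'
#' @param labels a [labelSegments()] (or [truthLabels()]) data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeLabelsTsv <- function(labels, path) {
    utils::write.table(
        data.frame(ref_id = labels$refId, segment_index = labels$segmentIndex,
                   base_start = labels$baseStart, base_end = labels$baseEnd,
                   identity = labels$identity),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
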