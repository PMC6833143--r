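# Pileup image encoding: one RGB image per reference read, one column per
# reference minimizer, one row per (sampled) matching read.

.withSeed <- function(seed, expr) {
    env <- globalenv()
    had <- exists(".Random.seed", envir = env, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
    on.exit({
        if (had) assign(".Random.seed", old, envir = env)
        else if (exists(".Random.seed", envir = env, inherits = FALSE))
            rm(".Random.seed", envir = env)
    })
    set.seed(seed)
    expr
}

# deterministic per-read scramble of the user seed (kept below 2^31)
.readSeed <- function(seed, refId) {
    h <- sum(utf8ToInt(refId) * (seq_len(nchar(refId)) %% 97L + 1L))
    as.integer((as.numeric(seed) * 131071 + h) %% 2147483647)
}

.readStrings <- function(reads) {
    if (methods::is(reads, "QualityScaledXStringSet")) {
        list(seq = stats::setNames(as.character(reads), names(reads)),
             qual = stats::setNames(as.character(Biostrings::quality(reads)),
                                    names(reads)))
    } else if (is.list(reads) && all(c("seq", "qual") %in% names(reads))) {
        reads
    } else {
        stop("'reads' must be a QualityScaledDNAStringSet or a ",
             "list(seq=, qual=) of named character vectors")
    }
}

#' Encode one reference read's overlap pile as an RGB pileup image
#'
#' Row 1 is the reference read; rows 2..`depth` hold matching reads from
#' `overlaps`, sorted by descending shared-minimizer count and sampled
#' uniformly without replacement (seeded) when the pile exceeds
#' `depth - 1`. Per pixel of a matching read inside its matched span:
#' red = 255 where the read's chain contains the column's minimizer and 70
#' elsewhere; green = twice the average Phred+33 quality character value
#' over the pixel's base interval on that read, clamped to \[66, 254\];
#' blue = the base distance to the next minimizer, capped at 255. The base
#' interval of a non-matched column inside the span is inferred by linear
#' interpolation between the flanking matched minimizers, which preserves
#' the indel signal in the blue channel without base-level alignment.
#' Pixels outside the matched span, and rows without a matching read, are
#' black.
#'
#' @param refId identifier of the reference read.
#' @param overlaps overlap table from [findReadOverlaps()] (rows with
#'   `refId` equal to `refId` form the pile).
#' @param reads the read set ([Biostrings::QualityScaledDNAStringSet]).
#' @param param a [PileupParam()].
#' @param minimizerParam the [MinimizerParam()] used for the overlaps.
#' @param sketches optional precomputed [readSketches()].
#' @return A [PileupImage-class] object.
#' @export
encodePileup <- function(refId, overlaps, reads, param = PileupParam(),
                         minimizerParam = MinimizerParam(), sketches = NULL) {
    rs <- .readStrings(reads)
    if (!refId %in% names(rs$seq)) stop("unknown reference read: ", refId)
    refSeq <- rs$seq[[refId]]
    L <- nchar(refSeq)
    k <- minimizerParam@k
    sk <- if (!is.null(sketches)) sketches[[refId]]
          else extractMinimizers(refSeq, minimizerParam)
    C <- nrow(sk)
    depth <- param@depth
    grid <- array(0L, dim = c(depth, C, 3L))
    if (C == 0L) {
        return(methods::new("PileupImage", grid = grid, refId = refId,
                            rowReads = refId, columnStarts = integer(),
                            readLength = as.integer(L)))
    }
    starts <- as.integer(sk$start)
    bounds <- c(starts, as.integer(L))          # column i covers [b[i], b[i+1])
    widths <- diff(bounds)
    # reference row
    qref <- cumsum(c(0, utf8ToInt(rs$qual[[refId]])))
    meanQ <- (qref[bounds[-1L] + 1L] - qref[bounds[-(C + 1L)] + 1L]) / widths
    grid[1L, , 1L] <- 255L
    grid[1L, , 2L] <- pmin(pmax(as.integer(round(2 * meanQ)), 66L), 254L)
    grid[1L, , 3L] <- pmin(widths, 255L)
    # pile: sort by support, sample if necessary
    inPile <- overlaps[["refId"]] == refId
    pile <- overlaps[inPile, , drop = FALSE]
    rowReads <- refId
    if (nrow(pile) > 0L) {
        ord <- order(-pile$nShared, pile$queryId, pile$strand)
        pile <- pile[ord, ]
        if (nrow(pile) > depth - 1L && depth > 1L) {
            sel <- .withSeed(.readSeed(param@seed, refId),
                             sort(sample.int(nrow(pile), depth - 1L)))
            pile <- pile[sel, ]
        }
        nUse <- min(nrow(pile), depth - 1L)
        for (r in seq_len(nUse)) {
            m <- pile$matches[[r]]
            qid <- pile$queryId[r]
            neg <- pile$strand[r] == "-"
            qlen <- nchar(rs$seq[[qid]])
            qcum <- cumsum(c(0, utf8ToInt(rs$qual[[qid]])))
            cmin <- min(m$refIndex); cmax <- max(m$refIndex)
            cols <- cmin:cmax
            qi <- if (nrow(m) >= 2L) {
                round(stats::approx(m$refIndex, m$queryPos, xout = cols)$y)
            } else m$queryPos
            if (!neg) {
                lo <- qi
                hi <- c(qi[-1L], qi[length(qi)] + k)
            } else {
                hi <- qi + k
                lo <- c(qi[-1L] + k, qi[length(qi)])
            }
            lo <- pmin(pmax(lo, 0L), qlen)
            hi <- pmin(pmax(hi, 0L), qlen)
            bad <- hi <= lo
            if (any(bad)) {     # degenerate interpolation: single-base pixel
                lo[bad] <- pmin(pmax(pmin(lo[bad], hi[bad]), 0L), qlen - 1L)
                hi[bad] <- lo[bad] + 1L
            }
            red <- rep(70L, length(cols))
            red[match(m$refIndex, cols)] <- 255L
            green <- pmin(pmax(as.integer(round(
                2 * (qcum[hi + 1L] - qcum[lo + 1L]) / (hi - lo))), 66L), 254L)
            blue <- pmin(hi - lo, 255L)
            grid[r + 1L, cols, 1L] <- red
            grid[r + 1L, cols, 2L] <- green
            grid[r + 1L, cols, 3L] <- as.integer(blue)
        }
        rowReads <- c(refId, pile$queryId[seq_len(nUse)])
    }
    methods::new("PileupImage", grid = grid, refId = refId,
                 rowReads = rowReads, columnStarts = starts,
                 readLength = as.integer(L))
}

#' @describeIn PileupImage-class the pixel grid (`depth x columns x 3`).
#' @param x,object a `PileupImage`.
#' @export
imageGrid <- function(x) x@grid

#' @describeIn PileupImage-class per-column half-open base intervals in the
#'   reference read.
#' @export
columnCoords <- function(x) {
    b <- c(x@columnStarts, x@readLength)
    data.frame(column = seq_along(x@columnStarts),
               baseStart = b[-length(b)], baseEnd = b[-1L])
}

setMethod("show", "PileupImage", function(object) {
    cat(sprintf("PileupImage '%s': %d x %d x 3, %d populated row(s), read %d bp\n",
                object@refId, dim(object@grid)[1L], dim(object@grid)[2L],
                length(object@rowReads), object@readLength))
})

#' Cut a pileup image into fixed-width segments
#'
#' Consecutive non-overlapping windows of `segmentLength` columns; the final
#' partial window is right-padded with black columns. Segment base ranges
#' are taken from the column coordinates, extended so that one read's
#' segments exactly partition `[0, read length)` (the first segment reaches
#' back to base 0, the last to the read end).
#'
#' @param img a [PileupImage-class].
#' @param param a [PileupParam()].
#' @return A [SegmentSet-class].
#' @export
segmentPileup <- function(img, param = PileupParam()) {
    sl <- param@segmentLength
    depth <- dim(img@grid)[1L]
    C <- dim(img@grid)[2L]
    nseg <- if (C == 0L) 0L else as.integer(ceiling(C / sl))
    data <- array(0L, dim = c(nseg, depth, sl, 3L))
    info <- data.frame(refId = rep(img@refId, nseg),
                       segmentIndex = seq_len(nseg),
                       baseStart = integer(nseg), baseEnd = integer(nseg),
                       stringsAsFactors = FALSE)
    for (j in seq_len(nseg)) {
        c0 <- (j - 1L) * sl + 1L
        c1 <- min(j * sl, C)
        data[j, , seq_len(c1 - c0 + 1L), ] <- img@grid[, c0:c1, , drop = FALSE]
        info$baseStart[j] <- if (j == 1L) 0L else img@columnStarts[c0]
        info$baseEnd[j] <- if (c1 == C) img@readLength
                           else img@columnStarts[c1 + 1L]
    }
    methods::new("SegmentSet", data = data, info = info)
}

#' Combine segment sets
#'
#' @param sets a list of [SegmentSet-class] objects with identical depth and
#'   segment length.
#' @return A single [SegmentSet-class].
#' @export
bindSegments <- function(sets) {
    sets <- sets[vapply(sets, function(s) nrow(s@info) > 0L, logical(1))]
    if (length(sets) == 0L)
        return(methods::new("SegmentSet",
                            data = array(0L, c(0L, 1L, 1L, 3L)),
                            info = data.frame(refId = character(),
                                              segmentIndex = integer(),
                                              baseStart = integer(),
                                              baseEnd = integer())))
    dims <- vapply(sets, function(s) dim(s@data)[2:3], integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
        stop("segment sets have differing depth or segment length")
    ns <- vapply(sets, function(s) dim(s@data)[1L], integer(1))
    total <- sum(ns)
    data <- array(0L, dim = c(total, dims[1, 1], dims[2, 1], 3L))
    at <- 0L
    for (s in sets) {
        n <- dim(s@data)[1L]
        if (n > 0L) data[at + seq_len(n), , , ] <- s@data
        at <- at + n
    }
    info <- do.call(rbind, lapply(sets, function(s) s@info))
    rownames(info) <- NULL
    methods::new("SegmentSet", data = data, info = info)
}

#' @describeIn SegmentSet-class per-segment coordinates.
#' @param x,object a `SegmentSet`.
#' @export
segmentInfo <- function(x) x@info

#' @describeIn SegmentSet-class the raw array (`n x depth x length x 3`).
#' @export
segmentData <- function(x) x@data

#' @describeIn SegmentSet-class number of segments.
#' @export
setMethod("length", "SegmentSet", function(x) dim(x@data)[1L])

#' @describeIn SegmentSet-class subset segments.
#' @param i segment indices.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "SegmentSet", function(x, i, j, ..., drop = FALSE) {
    methods::new("SegmentSet", data = x@data[i, , , , drop = FALSE],
                 info = x@info[i, , drop = FALSE])
})

setMethod("show", "SegmentSet", function(object) {
    d <- dim(object@data)
    cat(sprintf("SegmentSet: %d segment(s) of %d x %d x 3 from %d read(s)\n",
                d[1L], d[2L], d[3L],
                length(unique(object@info$refId))))
})

#' Persist segments as PNG images plus a coordinate sidecar
#'
#' Writes one lossless PNG per segment (`<refId>_<segmentIndex>.png`) and a
#' `segments.tsv` sidecar with `ref_id`, `segment_index`, `base_start`,
#' `base_end`.
#'
#' @param segments a [SegmentSet-class].
#' @param dir output directory (created if needed).
#' @return The sidecar path, invisibly.
#' @export
writeSegmentsPng <- function(segments, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    info <- segments@info
    for (i in seq_len(nrow(info))) {
        img <- segments@data[i, , , ] / 255
        fn <- file.path(dir, sprintf("%s_%d.png",
                                     gsub("[^A-Za-z0-9._-]", "_", info$refId[i]),
                                     info$segmentIndex[i]))
        png::writePNG(img, fn)
    }
    sidecar <- file.path(dir, "segments.tsv")
    utils::write.table(
        data.frame(ref_id = info$refId, segment_index = info$segmentIndex,
                   base_start = info$baseStart, base_end = info$baseEnd),
        sidecar, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(sidecar)
}
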