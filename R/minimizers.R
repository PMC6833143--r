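#' Extract (w,k)-minimizers from a nucleotide sequence
#'
#' Scans every window of `w` consecutive k-mers and keeps each window's
#' minimum-order k-mer occurrence. The order key is an invertible integer
#' mixing hash of the canonical k-mer (the lesser of the forward and
#' reverse-complement 2-bit encodings), which avoids the poly-A bias of
#' plain alphabetical order; ties within a window select all tied
#' occurrences. K-mers containing a non-ACGT base are ineligible and simply
#' drop out of their windows.
#'
#' Sequences shorter than `w + k - 1` contain no complete window and yield
#' no minimizers.
#'
#' @param seq a single character string or [Biostrings::DNAString] over
#'   A/C/G/T/N (case-insensitive).
#' @param param a [MinimizerParam()].
#' @return A `data.frame` with one row per minimizer occurrence, ordered by
#'   strictly increasing `start`: `start` (0-based base position), `strand`
#'   (`"+"` if the canonical k-mer is the forward one), `hash` (the order
#'   key, a non-negative double below 2^53).
#' @examples
#' extractMinimizers("ACGTACGTACGTACGTACGT", MinimizerParam(w = 2, k = 5))
#' @seealso [bruteForceMinimizers()] for the reference implementation used
#'   as a test oracle.
#' @export
extractMinimizers <- function(seq, param = MinimizerParam()) {
    seq <- .asSequenceString(seq)
    extract_minimizers_cpp(seq, param@w, param@k)
}

#' Brute-force minimizer extraction (test oracle)
#'
#' Enumerates every window of `w` consecutive k-mers explicitly, ranks the
#' eligible k-mers of each window by the same canonical order key as
#' [extractMinimizers()], and collects the union of per-window minima (all
#' tied occurrences). No sliding-window machinery is shared with the
#' production path beyond the k-mer order key itself.
#'
#' @inheritParams extractMinimizers
#' @return Same shape as [extractMinimizers()].
#' @export
bruteForceMinimizers <- function(seq, param = MinimizerParam()) {
    seq <- toupper(.asSequenceString(seq))
    w <- param@w
    k <- param@k
    n <- nchar(seq)
    nk <- n - k + 1L
    empty <- data.frame(start = integer(), strand = character(),
                        hash = numeric(), stringsAsFactors = FALSE)
    if (nk < 1L) return(empty)
    kmers <- substring(seq, seq_len(nk), seq_len(nk) + k - 1L)
    keys <- kmer_order_key_cpp(kmers)          # NA for k-mers containing N
    selected <- rep(FALSE, nk)
    if (nk >= w) {
        for (j in seq_len(nk - w + 1L)) {
            win <- keys[j:(j + w - 1L)]
            if (all(is.na(win))) next
            m <- min(win, na.rm = TRUE)
            hit <- which(!is.na(win) & win == m)
            selected[j + hit - 1L] <- TRUE
        }
    }
    idx <- which(selected)
    if (length(idx) == 0L) return(empty)
    data.frame(start = idx - 1L,
               strand = ifelse(.kmerIsCanonicalForward(kmers[idx]), "+", "-"),
               hash = keys[idx],
               stringsAsFactors = FALSE)
}

# forward 2-bit code <= reverse-complement 2-bit code?  (A<C<G<T makes the
# 2-bit order identical to lexicographic order on ACGT strings)
.kmerIsCanonicalForward <- function(kmers) {
    rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(kmers)))
    code <- function(x) {
        m <- matrix(match(unlist(strsplit(x, "", fixed = TRUE)),
                          c("A", "C", "G", "T")) - 1,
                    ncol = length(x))
        colSums(m * 4^((nrow(m) - 1):0))
    }
    code(kmers) <= code(rc)
}

.asSequenceString <- function(seq) {
    if (methods::is(seq, "XString") || methods::is(seq, "XStringSet"))
        seq <- as.character(seq)
    if (length(seq) != 1L || !is.character(seq))
        stop("'seq' must be a single sequence")
    seq
}

#' Write minimizer occurrences to a TSV file
#'
#' One row per occurrence: `read_id`, `start`, `strand`, `hash`.
#'
#' @param reads a named list or [Biostrings::DNAStringSet] of sequences.
#' @param path output file path.
#' @param param a [MinimizerParam()].
#' @return The path, invisibly.
#' @export
writeMinimizerTsv <- function(reads, path, param = MinimizerParam()) {
    ids <- names(reads)
    if (is.null(ids)) stop("reads must be named")
    rows <- lapply(ids, function(id) {
        mm <- extractMinimizers(as.character(reads[[id]]), param)
        if (nrow(mm) == 0L) return(NULL)
        cbind(read_id = id, mm)
    })
    tab <- do.call(rbind, rows)
    if (is.null(tab))
        tab <- data.frame(read_id = character(), start = integer(),
                          strand = character(), hash = numeric())
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
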