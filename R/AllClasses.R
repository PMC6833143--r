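#' @useDynLib PileupScrub, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @import data.table
#' @importFrom stats cor rnorm runif rlnorm approx setNames
#' @importFrom utils head tail
NULL

.datatable.aware <- TRUE

utils::globalVariables(c("refId", "queryId", "refIndex", "refPos",
                         "queryPos", "readId", ".N", "nShared"))

setClassUnion("ListOrNULL", c("list", "NULL"))

#' Minimizer sketching parameters
#'
#' A (w,k)-minimizer is the minimum-order k-mer among `w` consecutive k-mers;
#' two reads sharing an identical stretch of `w + k - 1` bases are guaranteed
#' to share a minimizer inside it. Defaults follow the method's standard
#' setting of `w = 5`, `k = 15`; `(7, 17)` is the tested sparser variant.
#'
#' @param w window size, in k-mers.
#' @param k k-mer length, in bases (at most 31).
#' @return A `MinimizerParam` object.
#' @examples
#' MinimizerParam()
#' MinimizerParam(w = 7L, k = 17L)
#' @export MinimizerParam
#' @exportClass MinimizerParam
#' @aliases MinimizerParam-class
setClass("MinimizerParam",
    representation(w = "integer", k = "integer"),
    prototype(w = 5L, k = 15L))

setValidity("MinimizerParam", function(object) {
    if (length(object@w) != 1L || is.na(object@w) || object@w < 1L)
        return("'w' must be a single integer >= 1")
    if (length(object@k) != 1L || is.na(object@k) || object@k < 1L)
        return("'k' must be a single integer >= 1")
    if (object@k > 31L)
        return("'k' must be <= 31 (2-bit packed in a 64-bit word)")
    TRUE
})

#' Overlap detection parameters
#'
#' @param minShared minimum number of co-linear shared minimizers needed to
#'   report a read pair. The default of 4 suppresses spurious single-hash
#'   hits at `k = 15`.
#' @param maxGap maximum base distance, on either read, between consecutive
#'   chained minimizer matches.
#' @param maxOccurrence minimizers occurring in more than this many reads are
#'   skipped during matching (repeat guard).
#' @return An `OverlapParam` object.
#' @export OverlapParam
#' @exportClass OverlapParam
#' @aliases OverlapParam-class
setClass("OverlapParam",
    representation(minShared = "integer", maxGap = "integer",
                   maxOccurrence = "integer"),
    prototype(minShared = 4L, maxGap = 500L, maxOccurrence = 200L))

setValidity("OverlapParam", function(object) {
    if (object@minShared < 1L) return("'minShared' must be >= 1")
    if (object@maxGap < 1L) return("'maxGap' must be >= 1")
    if (object@maxOccurrence < 1L) return("'maxOccurrence' must be >= 1")
    TRUE
})

#' Pileup image parameters
#'
#' A pileup image has one column per reference-read minimizer and `depth`
#' rows: the reference read on row 1 plus up to `depth - 1` matching reads.
#' Images are cut into segments of `segmentLength` columns for the
#' regressor. Defaults are the standard (Length, Depth) = (48, 24); (36, 36)
#' is the tested alternative.
#'
#' @param depth rows per image, reference read included.
#' @param segmentLength columns (minimizers) per segment.
#' @param seed seed controlling the sampling of matching reads when a pile
#'   exceeds `depth - 1`.
#' @return A `PileupParam` object.
#' @export PileupParam
#' @exportClass PileupParam
#' @aliases PileupParam-class
setClass("PileupParam",
    representation(depth = "integer", segmentLength = "integer",
                   seed = "integer"),
    prototype(depth = 24L, segmentLength = 48L, seed = 1L))

setValidity("PileupParam", function(object) {
    if (object@depth < 1L) return("'depth' must be >= 1")
    if (object@segmentLength < 1L) return("'segmentLength' must be >= 1")
    TRUE
})

#' Training parameters for the convolutional regressor
#'
#' Defaults mirror the published training recipe: Adam with learning rate
#' 1e-4, mean-squared-error loss, Glorot-uniform initialization, five
#' epochs. The `"small"` variant (3 conv blocks + 1 hidden dense layer)
#' trains in minutes on a CPU; `"vgg16_adapted"` is the 13-convolution,
#' 3-dense fidelity architecture.
#'
#' @param learningRate Adam step size.
#' @param epochs training epochs.
#' @param batchSize minibatch size.
#' @param variant `"small"` or `"vgg16_adapted"`.
#' @param seed seed for weight init, shuffling and the train/validation
#'   split.
#' @param valFraction fraction of reference reads held out for validation
#'   (split by read, not by segment, so correlated segments never leak).
#' @return A `TrainParam` object.
#' @export TrainParam
#' @exportClass TrainParam
#' @aliases TrainParam-class
setClass("TrainParam",
    representation(learningRate = "numeric", epochs = "integer",
                   batchSize = "integer", variant = "character",
                   seed = "integer", valFraction = "numeric"),
    prototype(learningRate = 1e-4, epochs = 5L, batchSize = 64L,
              variant = "small", seed = 1L, valFraction = 0.1))

setValidity("TrainParam", function(object) {
    if (object@learningRate <= 0) return("'learningRate' must be > 0")
    if (object@epochs < 1L) return("'epochs' must be >= 1")
    if (object@batchSize < 1L) return("'batchSize' must be >= 1")
    if (!object@variant %in% c("small", "vgg16_adapted"))
        return("'variant' must be 'small' or 'vgg16_adapted'")
    if (object@valFraction < 0 || object@valFraction >= 1)
        return("'valFraction' must be in [0, 1)")
    TRUE
})

#' Scrubbing parameters
#'
#' Segments whose predicted identity falls below `threshold` are removed and
#' the read is split there; fragments shorter than `minLength` bases are
#' discarded. Defaults: threshold 0.8, minimum length 500.
#'
#' @param threshold identity cutoff in \[0, 1\].
#' @param minLength minimum emitted fragment length in bases.
#' @return A `ScrubParam` object.
#' @export ScrubParam
#' @exportClass ScrubParam
#' @aliases ScrubParam-class
setClass("ScrubParam",
    representation(threshold = "numeric", minLength = "integer"),
    prototype(threshold = 0.8, minLength = 500L))

setValidity("ScrubParam", function(object) {
    if (object@threshold < 0 || object@threshold > 1)
        return("'threshold' must be in [0, 1]")
    if (object@minLength < 0L) return("'minLength' must be >= 0")
    TRUE
})

#' Long-read simulation parameters
#'
#' The simulator emulates the error structure of noisy long reads: a
#' baseline per-base error rate with indel-dominant errors, clustered
#' low-quality "junk" segments with strongly elevated error, chimeric joins
#' of two independent loci, and per-base quality scores that track (noisily)
#' the local error rate. Read lengths are log-normal with median
#' `exp(readLengthMeanLog)` (default ~2 kb).
#'
#' @param genomeLengths integer vector of genome lengths (bases).
#' @param coverage target per-genome coverage.
#' @param readLengthMeanLog,readLengthSdLog log-normal read-length
#'   parameters.
#' @param errorRate mean per-base error rate across reads.
#' @param readErrorSdLog log-normal spread of per-read error rates around
#'   `errorRate`; the default reproduces the platform's published per-read
#'   range of roughly 5--40%.
#' @param indelFraction fraction of errors that are indels (insertions and
#'   deletions split evenly); indels dominate on this platform.
#' @param junkRate probability that a read carries one junk segment.
#' @param junkLengthRange junk segment length bounds, bases.
#' @param junkErrorRange junk segment error-rate bounds.
#' @param chimeraRate probability that a read is a chimera of two loci.
#' @param qualitySd standard deviation of the Phred quality noise around the
#'   local-error target.
#' @param seed RNG seed; all outputs are deterministic given it.
#' @return A `SimParam` object.
#' @export SimParam
#' @exportClass SimParam
#' @aliases SimParam-class
setClass("SimParam",
    representation(genomeLengths = "integer", coverage = "numeric",
                   readLengthMeanLog = "numeric", readLengthSdLog = "numeric",
                   errorRate = "numeric", readErrorSdLog = "numeric",
                   indelFraction = "numeric",
                   junkRate = "numeric", junkLengthRange = "integer",
                   junkErrorRange = "numeric", chimeraRate = "numeric",
                   qualitySd = "numeric", seed = "integer"),
    prototype(genomeLengths = 50000L, coverage = 30,
              readLengthMeanLog = log(2000), readLengthSdLog = 0.4,
              errorRate = 0.15, readErrorSdLog = 0.35, indelFraction = 0.6,
              junkRate = 0.3, junkLengthRange = c(100L, 1000L),
              junkErrorRange = c(0.3, 0.5), chimeraRate = 0.05,
              qualitySd = 3, seed = 1L))

setValidity("SimParam", function(object) {
    rates <- c(object@errorRate, object@indelFraction, object@junkRate,
               object@chimeraRate, object@junkErrorRange)
    if (any(rates < 0 | rates > 1)) return("all rates must be in [0, 1]")
    if (any(object@genomeLengths < 1L)) return("genome lengths must be positive")
    if (object@coverage < 0) return("'coverage' must be >= 0")
    if (length(object@junkLengthRange) != 2L ||
        any(object@junkLengthRange < 1L) ||
        diff(object@junkLengthRange) < 0L)
        return("'junkLengthRange' must be an increasing pair of positive lengths")
    if (length(object@junkErrorRange) != 2L || diff(object@junkErrorRange) < 0)
        return("'junkErrorRange' must be an increasing pair of rates")
    TRUE
})

#' Pileup image for one reference read
#'
#' An RGB grid with `depth` rows and one column per reference-read
#' minimizer. Row 1 is the reference read itself (red channel 255 at every
#' column); further rows are matching reads from the overlap pile. Channels:
#' red encodes minimizer sharing (255 shared / 70 not shared within the
#' matched span), green twice the average Phred+33 quality character over
#' the pixel's base interval (range 66--254), blue the base distance to the
#' next minimizer capped at 255. Pixels outside a matching read's matched
#' span are black (0,0,0).
#'
#' @slot grid integer array `depth x columns x 3`, values 0--255.
#' @slot refId reference read identifier.
#' @slot rowReads identifiers of the reads occupying each populated row
#'   (row 1 = reference).
#' @slot columnStarts 0-based start of each column's minimizer in the
#'   reference read.
#' @slot readLength reference read length in bases.
#' @exportClass PileupImage
#' @aliases PileupImage-class
setClass("PileupImage",
    representation(grid = "array", refId = "character",
                   rowReads = "character", columnStarts = "integer",
                   readLength = "integer"))

setValidity("PileupImage", function(object) {
    d <- dim(object@grid)
    if (length(d) != 3L || d[3] != 3L)
        return("'grid' must be a depth x columns x 3 array")
    if (d[2] != length(object@columnStarts))
        return("column count must equal the number of reference minimizers")
    if (any(object@grid < 0L | object@grid > 255L))
        return("pixel values must lie in [0, 255]")
    if (d[2] > 0L && any(object@grid[1L, , 1L] != 255L))
        return("reference row red channel must be 255 at every column")
    if (is.unsorted(object@columnStarts, strictly = TRUE))
        return("'columnStarts' must be strictly increasing")
    TRUE
})

#' A set of fixed-size pileup segments
#'
#' Container for the `depth x segmentLength x 3` image segments cut from one
#' or more pileup images, with per-segment coordinates. The base ranges of
#' one read's segments partition `[0, read length)`.
#'
#' @slot data integer array `n x depth x segmentLength x 3`.
#' @slot info `data.frame` with columns `refId`, `segmentIndex` (1-based),
#'   `baseStart`, `baseEnd` (0-based half-open read coordinates).
#' @exportClass SegmentSet
#' @aliases SegmentSet-class
setClass("SegmentSet",
    representation(data = "array", info = "data.frame"))

setValidity("SegmentSet", function(object) {
    d <- dim(object@data)
    if (length(d) != 4L || d[4] != 3L)
        return("'data' must be an n x depth x segmentLength x 3 array")
    if (d[1] != nrow(object@info))
        return("'info' must have one row per segment")
    need <- c("refId", "segmentIndex", "baseStart", "baseEnd")
    if (!all(need %in% names(object@info)))
        return(paste("'info' must have columns:", paste(need, collapse = ", ")))
    TRUE
})

#' A trained (or freshly initialized) scrubbing model
#'
#' Bundles the network weights with the exact sketching and imaging
#' parameters it was trained under; prediction refuses segments whose shape
#' disagrees with the stored configuration.
#'
#' @slot weights list of per-layer `W`/`b` matrices.
#' @slot arch list of layer descriptors.
#' @slot variant architecture variant name.
#' @slot minimizerParam,pileupParam,trainParam the parameter objects the
#'   model is bound to.
#' @slot history numeric vector of per-epoch mean training loss (empty for
#'   an untrained model).
#' @exportClass ScrubModel
#' @aliases ScrubModel-class
setClass("ScrubModel",
    representation(weights = "list", arch = "list", variant = "character",
                   minimizerParam = "MinimizerParam",
                   pileupParam = "PileupParam", trainParam = "TrainParam",
                   history = "numeric"))

#' Regression and classification metrics for identity predictions
#'
#' @slot mse mean squared error.
#' @slot pearson,spearman correlations between predictions and labels
#'   (`NA` when either side has zero variance).
#' @slot sensitivity fraction of truly above-cutoff segments predicted
#'   above the cutoff (high-quality segments retained).
#' @slot specificity fraction of truly below-cutoff segments predicted
#'   below it (low-quality segments removed).
#' @slot cutoff the identity cutoff used.
#' @exportClass EvalReport
#' @aliases EvalReport-class
setClass("EvalReport",
    representation(mse = "numeric", pearson = "numeric", spearman = "numeric",
                   sensitivity = "numeric", specificity = "numeric",
                   cutoff = "numeric"))

setValidity("EvalReport", function(object) {
    if (!is.na(object@mse) && object@mse < 0) return("'mse' must be >= 0")
    ok <- function(x) is.na(x) || (x >= -1 && x <= 1)
    if (!ok(object@pearson) || !ok(object@spearman))
        return("correlations must lie in [-1, 1]")
    ok01 <- function(x) is.na(x) || (x >= 0 && x <= 1)
    if (!ok01(object@sensitivity) || !ok01(object@specificity))
        return("sensitivity/specificity must lie in [0, 1]")
    TRUE
})
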