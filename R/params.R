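# User-facing constructors: coerce plain numerics into the typed slots so
# MinimizerParam(w = 7, k = 17) works without explicit integer literals.

#' @rdname MinimizerParam-class
#' @export
MinimizerParam <- function(w = 5, k = 15) {
    new("MinimizerParam", w = as.integer(w), k = as.integer(k))
}

#' @rdname OverlapParam-class
#' @export
OverlapParam <- function(minShared = 4, maxGap = 500, maxOccurrence = 200) {
    new("OverlapParam", minShared = as.integer(minShared),
        maxGap = as.integer(maxGap), maxOccurrence = as.integer(maxOccurrence))
}

#' @rdname PileupParam-class
#' @export
PileupParam <- function(depth = 24, segmentLength = 48, seed = 1) {
    new("PileupParam", depth = as.integer(depth),
        segmentLength = as.integer(segmentLength), seed = as.integer(seed))
}

#' @rdname TrainParam-class
#' @export
TrainParam <- function(learningRate = 1e-4, epochs = 5, batchSize = 64,
                       variant = c("small", "vgg16_adapted"), seed = 1,
                       valFraction = 0.1) {
    new("TrainParam", learningRate = as.numeric(learningRate),
        epochs = as.integer(epochs), batchSize = as.integer(batchSize),
        variant = match.arg(variant), seed = as.integer(seed),
        valFraction = as.numeric(valFraction))
}

#' @rdname ScrubParam-class
#' @export
ScrubParam <- function(threshold = 0.8, minLength = 500) {
    new("ScrubParam", threshold = as.numeric(threshold),
        minLength = as.integer(minLength))
}

#' @rdname SimParam-class
#' @export
SimParam <- function(genomeLengths = 50000, coverage = 30,
                     readLengthMeanLog = log(2000), readLengthSdLog = 0.4,
                     errorRate = 0.15, readErrorSdLog = 0.35,
                     indelFraction = 0.6, junkRate = 0.3,
                     junkLengthRange = c(100, 1000),
                     junkErrorRange = c(0.3, 0.5), chimeraRate = 0.05,
                     qualitySd = 3, seed = 1) {
    new("SimParam", genomeLengths = as.integer(genomeLengths),
        coverage = as.numeric(coverage),
        readLengthMeanLog = as.numeric(readLengthMeanLog),
        readLengthSdLog = as.numeric(readLengthSdLog),
        errorRate = as.numeric(errorRate),
        readErrorSdLog = as.numeric(readErrorSdLog),
        indelFraction = as.numeric(indelFraction),
        junkRate = as.numeric(junkRate),
        junkLengthRange = as.integer(junkLengthRange),
        junkErrorRange = as.numeric(junkErrorRange),
        chimeraRate = as.numeric(chimeraRate),
        qualitySd = as.numeric(qualitySd), seed = as.integer(seed))
}

#' @describeIn MinimizerParam-class show method
#' @param object a parameter object
#' @export
setMethod("show", "MinimizerParam", function(object) {
    cat(sprintf("MinimizerParam: w=%d k=%d (window guarantee span %d bases)\n",
                object@w, object@k, object@w + object@k - 1L))
})

setMethod("show", "OverlapParam", function(object) {
    cat(sprintf("OverlapParam: minShared=%d maxGap=%d maxOccurrence=%d\n",
                object@minShared, object@maxGap, object@maxOccurrence))
})

setMethod("show", "PileupParam", function(object) {
    cat(sprintf("PileupParam: depth=%d segmentLength=%d seed=%d\n",
                object@depth, object@segmentLength, object@seed))
})

setMethod("show", "TrainParam", function(object) {
    cat(sprintf(
        "TrainParam: %s, Adam lr=%g, %d epochs, batch %d, seed %d, val %.0f%%\n",
        object@variant, object@learningRate, object@epochs, object@batchSize,
        object@seed, 100 * object@valFraction))
})

setMethod("show", "ScrubParam", function(object) {
    cat(sprintf("ScrubParam: threshold=%.2f minLength=%d\n",
                object@threshold, object@minLength))
})

setMethod("show", "SimParam", function(object) {
    cat(sprintf(
        "SimParam: %d genome(s) (%s bp) at %gx, error %.2f (indel %.0f%%),\n  junk %.2f @ %.2f-%.2f over %d-%d bp, chimera %.2f, seed %d\n",
        length(object@genomeLengths),
        paste(object@genomeLengths, collapse = ","), object@coverage,
        object@errorRate, 100 * object@indelFraction, object@junkRate,
        object@junkErrorRange[1], object@junkErrorRange[2],
        object@junkLengthRange[1], object@junkLengthRange[2],
        object@chimeraRate, object@seed))
})
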