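# Convolutional regressor: pileup segment -> percent identity in [0, 1].
# Training recipe: Adam (lr 1e-4), MSE loss, Glorot-uniform init, 5 epochs.

# layer plan per variant; pooling is reduced from the canonical VGG16
# schedule because a 24-pixel depth axis cannot survive five 2x poolings:
# after the third block we pool along the length axis only
.modelArch <- function(variant, depth, segmentLength) {
    conv <- function(f) list(type = "conv", filters = f)
    pool <- function(ph, pw) list(type = "pool", ph = ph, pw = pw)
    dense <- function(u) list(type = "dense", units = u)
    arch <- switch(variant,
        small = list(conv(8L), pool(2L, 2L),
                     conv(16L), pool(2L, 2L),
                     conv(32L), pool(2L, 2L),
                     dense(64L), dense(1L)),
        vgg16_adapted = c(
            list(conv(64L), conv(64L), pool(2L, 2L)),
            list(conv(128L), conv(128L), pool(2L, 2L)),
            list(conv(256L), conv(256L), conv(256L), pool(2L, 2L)),
            list(conv(512L), conv(512L), conv(512L), pool(1L, 2L)),
            list(conv(512L), conv(512L), conv(512L), pool(1L, 2L)),
            list(dense(256L), dense(64L), dense(1L))),
        stop("unknown variant: ", variant))
    # shape check (mirrors the compiled-side check, but fails early with
    # the offending dimensions)
    d <- depth; l <- segmentLength
    for (lay in arch) {
        if (lay$type == "pool") {
            d <- d %/% lay$ph; l <- l %/% lay$pw
            if (d < 1L || l < 1L)
                stop(sprintf(
                    "input %d x %d is incompatible with variant '%s': a spatial axis collapses below 1",
                    depth, segmentLength, variant))
        }
    }
    arch
}

#' Build an untrained scrubbing model
#'
#' Initializes Glorot-uniform weights (seeded; two builds with the same
#' seed are identical) for the requested architecture over
#' `depth x segmentLength x 3` input. `"vgg16_adapted"` is a 13-convolution
#' / 3-dense stack of 3x3 filters whose final unit passes through a sigmoid
#' so predictions are bounded to \[0, 1\]; `"small"` is a 3-block network
#' for CPU-scale work.
#'
#' @param minimizerParam,pileupParam the sketching and imaging parameters
#'   the model is bound to.
#' @param trainParam a [TrainParam()] (provides variant and seed).
#' @return An untrained [ScrubModel-class].
#' @export
buildScrubModel <- function(minimizerParam = MinimizerParam(),
                            pileupParam = PileupParam(),
                            trainParam = TrainParam()) {
    arch <- .modelArch(trainParam@variant, pileupParam@depth,
                       pileupParam@segmentLength)
    weights <- cnn_init_cpp(arch, pileupParam@depth,
                            pileupParam@segmentLength, 3L, trainParam@seed)
    methods::new("ScrubModel", weights = weights, arch = arch,
                 variant = trainParam@variant,
                 minimizerParam = minimizerParam, pileupParam = pileupParam,
                 trainParam = trainParam, history = numeric())
}

# flatten a SegmentSet into the sample-major matrix the compiled network
# consumes; pixel values scaled to [0, 1]
.segmentMatrix <- function(segments) {
    x <- segments@data
    n <- dim(x)[1L]
    if (n == 0L) return(matrix(numeric(), 0L, prod(dim(x)[2:4])))
    t(matrix(as.double(aperm(x, c(2L, 3L, 4L, 1L))), ncol = n)) / 255
}

#' Train the convolutional regressor on labeled segments
#'
#' Minimizes mean squared error between predicted and labeled identity with
#' Adam. The validation split is made by reference read, not by segment, so
#' the correlated segments of one read never straddle the split. Training
#' is deterministic given the seed (single-threaded compiled code, seeded
#' shuffling and init).
#'
#' @param segments a [SegmentSet-class].
#' @param labels a label data.frame ([labelSegments()] / [truthLabels()])
#'   covering every segment, matched by (`refId`, `segmentIndex`).
#' @param trainParam a [TrainParam()].
#' @param minimizerParam the sketching parameters to stamp into the model.
#' @param model optionally, an existing [buildScrubModel()] result to start
#'   from (its architecture and parameters win).
#' @param pileupParam the imaging parameters to stamp into the model; must
#'   match the segment dimensions.
#' @return A trained [ScrubModel-class]; `lossHistory()` has one mean
#'   training-MSE entry per epoch.
#' @export
trainScrubModel <- function(segments, labels, trainParam = TrainParam(),
                            minimizerParam = MinimizerParam(),
                            pileupParam = PileupParam(),
                            model = NULL) {
    if (length(segments) == 0L) stop("empty training set")
    info <- segments@info
    key <- paste(info$refId, info$segmentIndex)
    lkey <- paste(labels$refId, labels$segmentIndex)
    hit <- match(key, lkey)
    if (anyNA(hit))
        stop("labels missing for ", sum(is.na(hit)), " segment(s)")
    y <- labels$identity[hit]
    if (any(y < 0 | y > 1)) stop("labels must lie in [0, 1]")
    if (is.null(model))
        model <- buildScrubModel(minimizerParam, pileupParam, trainParam)
    d <- dim(segments@data)
    .checkShape(model, d)
    # hold out whole reads for validation
    ids <- unique(info$refId)
    nVal <- floor(length(ids) * model@trainParam@valFraction)
    valIds <- if (nVal > 0L)
        .withSeed(model@trainParam@seed,
                  sample(ids, nVal)) else character()
    isVal <- info$refId %in% valIds
    X <- .segmentMatrix(segments)
    fit <- cnn_train_cpp(model@arch, model@weights,
                         X[!isVal, , drop = FALSE], y[!isVal],
                         d[2L], d[3L], 3L,
                         model@trainParam@epochs, model@trainParam@batchSize,
                         model@trainParam@learningRate,
                         model@trainParam@seed)
    model@weights <- fit$weights
    model@history <- as.numeric(fit$history)
    if (any(isVal)) {
        pv <- cnn_predict_cpp(model@arch, model@weights,
                              X[isVal, , drop = FALSE], d[2L], d[3L], 3L)
        message(sprintf(
            "validation MSE %.5f over %d held-out segments (%d reads)",
            mean((pv - y[isVal])^2), sum(isVal), length(valIds)))
    }
    model
}

.checkShape <- function(model, d) {
    pd <- model@pileupParam@depth
    pl <- model@pileupParam@segmentLength
    if (d[2L] != pd || d[3L] != pl)
        stop(sprintf(
            "segment shape %d x %d x 3 does not match the model's %d x %d x 3",
            d[2L], d[3L], pd, pl))
}

#' Predict per-segment identity
#'
#' Order-preserving and deterministic; refuses segments whose shape differs
#' from the configuration the model was trained with.
#'
#' @param model a [ScrubModel-class].
#' @param segments a [SegmentSet-class].
#' @return Numeric vector of predictions in \[0, 1\], one per segment.
#' @export
predictIdentity <- function(model, segments) {
    d <- dim(segments@data)
    .checkShape(model, d)
    as.numeric(cnn_predict_cpp(model@arch, model@weights,
                               .segmentMatrix(segments), d[2L], d[3L], 3L))
}

#' Predictions joined to segment coordinates
#'
#' Convenience wrapper producing the table [scrubReads()] consumes.
#'
#' @inheritParams predictIdentity
#' @return `segmentInfo(segments)` plus a `prediction` column.
#' @export
predictionTable <- function(model, segments) {
    out <- segments@info
    out$prediction <- predictIdentity(model, segments)
    out
}

#' Evaluate identity predictions against labels
#'
#' Sensitivity is the fraction of segments with label >= cutoff that are
#' also predicted >= cutoff (high-quality segments retained); specificity
#' the fraction with label < cutoff predicted < cutoff (low-quality
#' segments removed). Zero-variance inputs leave the correlations `NA`.
#'
#' @param predictions,labels equal-length numeric vectors (length >= 2).
#' @param cutoff identity cutoff (default 0.8).
#' @return An [EvalReport-class].
#' @examples
#' evaluatePredictions(c(0.9, 0.7, 0.5), c(0.9, 0.9, 0.5))
#' @export
evaluatePredictions <- function(predictions, labels, cutoff = 0.8) {
    if (length(predictions) != length(labels))
        stop("predictions and labels differ in length")
    if (length(predictions) < 2L) stop("need at least 2 observations")
    safeCor <- function(m) {
        if (stats::sd(predictions) == 0 || stats::sd(labels) == 0)
            return(NA_real_)
        stats::cor(predictions, labels, method = m)
    }
    pos <- labels >= cutoff
    sens <- if (any(pos)) mean(predictions[pos] >= cutoff) else NA_real_
    spec <- if (any(!pos)) mean(predictions[!pos] < cutoff) else NA_real_
    methods::new("EvalReport", mse = mean((predictions - labels)^2),
                 pearson = safeCor("pearson"), spearman = safeCor("spearman"),
                 sensitivity = sens, specificity = spec, cutoff = cutoff)
}

#' @describeIn EvalReport-class metrics as a named numeric vector.
#' @param x,object an `EvalReport`.
#' @export
evalMetrics <- function(x) {
    c(mse = x@mse, pearson = x@pearson, spearman = x@spearman,
      sensitivity = x@sensitivity, specificity = x@specificity,
      cutoff = x@cutoff)
}

setMethod("show", "EvalReport", function(object) {
    cat(sprintf(
        "EvalReport (cutoff %.2f): MSE %.5f, Pearson %.3f, Spearman %.3f\n  sensitivity %.3f, specificity %.3f\n",
        object@cutoff, object@mse, object@pearson, object@spearman,
        object@sensitivity, object@specificity))
})

#' @describeIn ScrubModel-class per-epoch mean training loss.
#' @param x,object a `ScrubModel`.
#' @export
lossHistory <- function(x) x@history

#' @describeIn ScrubModel-class the layer plan (list of conv/pool/dense
#'   descriptors).
#' @export
modelArchitecture <- function(x) x@arch

setMethod("show", "ScrubModel", function(object) {
    nConv <- sum(vapply(object@arch, function(l) l$type == "conv", logical(1)))
    nDense <- sum(vapply(object@arch, function(l) l$type == "dense", logical(1)))
    cat(sprintf(
        "ScrubModel '%s': %d conv + %d dense layers for %d x %d x 3 input (%s)\n",
        object@variant, nConv, nDense, object@pileupParam@depth,
        object@pileupParam@segmentLength,
        if (length(object@history)) sprintf("trained %d epoch(s), final loss %.5f",
                                            length(object@history),
                                            utils::tail(object@history, 1L))
        else "untrained"))
})

#' Save / load a scrubbing model
#'
#' The weights and bound parameter objects are serialized to a single RDS
#' container; a human-readable JSON sidecar (`<path>.json`) records the
#' variant, architecture and parameters. Loading restores a model whose
#' predictions are bit-identical to the saved one's.
#'
#' @param model a [ScrubModel-class].
#' @param path destination file.
#' @return `saveScrubModel`: `path`, invisibly. `loadScrubModel`: the model.
#' @export
saveScrubModel <- function(model, path) {
    saveRDS(model, path)
    meta <- list(
        variant = model@variant,
        architecture = model@arch,
        minimizer = list(w = model@minimizerParam@w, k = model@minimizerParam@k),
        pileup = list(depth = model@pileupParam@depth,
                      segmentLength = model@pileupParam@segmentLength,
                      seed = model@pileupParam@seed),
        training = list(learningRate = model@trainParam@learningRate,
                        epochs = model@trainParam@epochs,
                        batchSize = model@trainParam@batchSize,
                        seed = model@trainParam@seed),
        lossHistory = model@history)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    invisible(path)
}

#' @rdname saveScrubModel
#' @export
loadScrubModel <- function(path) {
    model <- readRDS(path)
    if (!methods::is(model, "ScrubModel"))
        stop("'", path, "' does not contain a ScrubModel")
    model
}
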