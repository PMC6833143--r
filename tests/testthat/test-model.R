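# The convolutional regressor: architecture, training, prediction, metrics.

smallParams <- function(seed = 3) {
    list(pp = PileupParam(depth = 8, segmentLength = 16, seed = 1),
         tp = TrainParam(epochs = 5, batchSize = 8, learningRate = 2e-3,
                         seed = seed, valFraction = 0))
}

test_that("predictions are bounded to [0, 1] for arbitrary input", {
    p <- smallParams()
    mdl <- buildScrubModel(pileupParam = p$pp, trainParam = p$tp)
    set.seed(1)
    arr <- array(sample(0:255, 5 * 8 * 16 * 3, replace = TRUE),
                 c(5, 8, 16, 3))
    arr[5, , , ] <- 0L  # all-black segment must not crash
    segs <- methods::new("SegmentSet", data = arr,
        info = data.frame(refId = paste0("s", 1:5), segmentIndex = 1L,
                          baseStart = 0L, baseEnd = 1L))
    pred <- predictIdentity(mdl, segs)
    expect_length(pred, 5L)
    expect_true(all(pred >= 0 & pred <= 1))
})

test_that("two builds from one seed are identical; seeds change weights", {
    p <- smallParams()
    a <- buildScrubModel(pileupParam = p$pp, trainParam = p$tp)
    b <- buildScrubModel(pileupParam = p$pp, trainParam = p$tp)
    expect_identical(a@weights, b@weights)
    c <- buildScrubModel(pileupParam = p$pp,
                         trainParam = TrainParam(seed = 99))
    expect_false(identical(a@weights, c@weights))
})

test_that("the adapted VGG16 variant has 13 conv and 3 dense layers of 3x3 filters", {
    mdl <- buildScrubModel(trainParam = TrainParam(variant = "vgg16_adapted"))
    arch <- modelArchitecture(mdl)
    types <- vapply(arch, `[[`, character(1), "type")
    expect_identical(sum(types == "conv"), 13L)
    expect_identical(sum(types == "dense"), 3L)
    convW <- mdl@weights[which(types[types != "pool"] == "conv")]
    # each conv weight row covers a 3x3 patch over its input channels
    expect_identical(ncol(convW[[1]]$W), 9L * 3L)
    # final dense layer is the single bounded output unit
    expect_identical(arch[[length(arch)]]$units, 1L)
})

test_that("incompatible input shapes are refused naming both shapes", {
    expect_error(buildScrubModel(pileupParam = PileupParam(depth = 6,
                                                           segmentLength = 12)),
                 "6 x 12")
    p <- smallParams()
    mdl <- buildScrubModel(pileupParam = p$pp, trainParam = p$tp)
    segs <- constantSegments(3, depth = 4L, len = 16L)$segments
    expect_error(predictIdentity(mdl, segs), "4 x 16.*8 x 16")
})

test_that("a small training set is memorized within 200 epochs", {
    set.seed(31)
    fix <- constantSegments(50)
    tp <- TrainParam(epochs = 200, batchSize = 8, learningRate = 2e-3,
                     seed = 3, valFraction = 0)
    mdl <- trainScrubModel(fix$segments, fix$labels, tp,
                           pileupParam = PileupParam(depth = 8,
                                                     segmentLength = 16))
    expect_lt(tail(lossHistory(mdl), 1), 0.01)
    expect_length(lossHistory(mdl), 200L)
    pred <- predictIdentity(mdl, fix$segments)
    expect_lt(mean((pred - fix$labels$identity)^2), 0.01)
})

test_that("constant labels pull predictions toward the constant", {
    set.seed(32)
    fix <- constantSegments(30, values = rep(0.35, 30))
    # images vary, labels do not
    d <- fix$segments@data
    d[] <- as.integer(sample(0:255, length(d), replace = TRUE))
    segs <- methods::new("SegmentSet", data = d, info = fix$segments@info)
    tp <- TrainParam(epochs = 60, batchSize = 8, learningRate = 2e-3,
                     seed = 4, valFraction = 0)
    mdl <- trainScrubModel(segs, fix$labels, tp,
                           pileupParam = PileupParam(depth = 8,
                                                     segmentLength = 16))
    pred <- predictIdentity(mdl, segs)
    expect_lt(max(abs(pred - 0.35)), 0.1)
})

test_that("training loss decreases over epochs on learnable data", {
    set.seed(33)
    fix <- constantSegments(60)
    tp <- TrainParam(epochs = 5, batchSize = 8, learningRate = 2e-3,
                     seed = 5, valFraction = 0)
    mdl <- trainScrubModel(fix$segments, fix$labels, tp,
                           pileupParam = PileupParam(depth = 8,
                                                     segmentLength = 16))
    h <- lossHistory(mdl)
    expect_length(h, 5L)
    expect_gte(sum(diff(h) <= 0), 3L)
})

test_that("training is deterministic given the seed and refuses empty input", {
    set.seed(34)
    fix <- constantSegments(20)
    p <- smallParams()
    m1 <- trainScrubModel(fix$segments, fix$labels, p$tp, pileupParam = p$pp)
    m2 <- trainScrubModel(fix$segments, fix$labels, p$tp, pileupParam = p$pp)
    expect_identical(m1@weights, m2@weights)
    expect_identical(lossHistory(m1), lossHistory(m2))
    empty <- fix$segments[integer()]
    expect_error(trainScrubModel(empty, fix$labels, p$tp,
                                 pileupParam = p$pp), "empty")
})

test_that("prediction is order-preserving under permutation and repeatable", {
    set.seed(35)
    fix <- constantSegments(12)
    p <- smallParams()
    mdl <- buildScrubModel(pileupParam = p$pp, trainParam = p$tp)
    pred <- predictIdentity(mdl, fix$segments)
    expect_identical(predictIdentity(mdl, fix$segments), pred)
    perm <- sample(12)
    expect_identical(predictIdentity(mdl, fix$segments[perm]), pred[perm])
})

test_that("a saved model reloads with bit-identical predictions", {
    set.seed(36)
    fix <- constantSegments(15)
    p <- smallParams()
    mdl <- trainScrubModel(fix$segments, fix$labels,
                           TrainParam(epochs = 2, batchSize = 8,
                                      learningRate = 1e-3, seed = 7,
                                      valFraction = 0),
                           pileupParam = p$pp)
    path <- withr::local_tempfile(fileext = ".rds")
    saveScrubModel(mdl, path)
    back <- loadScrubModel(path)
    expect_identical(predictIdentity(back, fix$segments),
                     predictIdentity(mdl, fix$segments))
    meta <- jsonlite::read_json(paste0(path, ".json"))
    expect_identical(meta$variant, "small")
    expect_identical(meta$pileup$depth, 8L)
})

test_that("evaluation metrics match their definitions", {
    x <- c(0.9, 0.85, 0.5, 0.7)
    perfect <- evaluatePredictions(x, x)
    expect_equal(evalMetrics(perfect)[c("mse", "pearson", "spearman",
                                        "sensitivity", "specificity")],
                 c(mse = 0, pearson = 1, spearman = 1, sensitivity = 1,
                   specificity = 1))
    r <- evaluatePredictions(c(0.9, 0.7, 0.5), c(0.9, 0.9, 0.5), 0.8)
    expect_equal(r@sensitivity, 0.5)
    expect_equal(r@specificity, 1)
    anti <- evaluatePredictions(c(1, 2, 3) / 4, c(3, 2, 1) / 4)
    expect_equal(anti@pearson, -1)
    flat <- evaluatePredictions(rep(0.5, 4), c(0.1, 0.9, 0.2, 0.8))
    expect_true(is.na(flat@pearson) && is.na(flat@spearman))
    expect_error(evaluatePredictions(0.5, 0.4), "at least 2")
    expect_error(evaluatePredictions(c(0.5, 0.4), 0.4), "length")
})
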