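# FASTQ I/O and the file-to-file pipeline driver. Coordinates everywhere
# are 0-based half-open; strands are "+"/"-".

#' Read a FASTQ file
#'
#' Phred+33, 4-line records. Malformed files are rejected with the index
#' of the offending record.
#'
#' @param path FASTQ path.
#' @return A [Biostrings::QualityScaledDNAStringSet].
#' @export
readFastq <- function(path) {
    .validateFastq(path)
    withCallingHandlers(
        Biostrings::readQualityScaledDNAStringSet(path),
        warning = function(w) {   # mcols() are dropped by design here
            if (grepl("metadata columns", conditionMessage(w)))
                invokeRestart("muffleWarning")
        })
}

.validateFastq <- function(path) {
    lines <- readLines(path)
    if (length(lines) %% 4L != 0L)
        stop(sprintf("truncated FASTQ '%s': record %d is incomplete", path,
                     length(lines) %/% 4L + 1L))
    n <- length(lines) %/% 4L
    for (i in seq_len(n)) {
        at <- (i - 1L) * 4L
        if (!startsWith(lines[at + 1L], "@"))
            stop(sprintf("malformed FASTQ '%s': record %d lacks '@' header",
                         path, i))
        if (!startsWith(lines[at + 3L], "+"))
            stop(sprintf("malformed FASTQ '%s': record %d lacks '+' separator",
                         path, i))
        if (nchar(lines[at + 2L]) != nchar(lines[at + 4L]))
            stop(sprintf(
                "malformed FASTQ '%s': record %d sequence/quality lengths differ (%d vs %d)",
                path, i, nchar(lines[at + 2L]), nchar(lines[at + 4L])))
    }
    invisible(TRUE)
}

#' Write reads to FASTQ
#'
#' @param reads a [Biostrings::QualityScaledDNAStringSet].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFastq <- function(reads, path) {
    withCallingHandlers(
        Biostrings::writeQualityScaledXStringSet(reads, path),
        warning = function(w) {
            if (grepl("metadata columns", conditionMessage(w)))
                invokeRestart("muffleWarning")
        })
    invisible(path)
}

#' Write genomes to FASTA
#'
#' @param genomes a [Biostrings::DNAStringSet].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(genomes, path) {
    Biostrings::writeXStringSet(genomes, path)
    invisible(path)
}

.manifest <- function(dir, stage, params, inputs, outputs) {
    paramList <- lapply(params, function(p) {
        sl <- methods::slotNames(class(p))
        stats::setNames(lapply(sl, function(s) methods::slot(p, s)), sl)
    })
    man <- list(stage = stage,
                package = as.character(utils::packageVersion("PileupScrub")),
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                params = paramList,
                inputs = lapply(inputs, function(f)
                    list(path = f, md5 = unname(tools::md5sum(f)))),
                outputs = outputs)
    jsonlite::write_json(man, file.path(dir, paste0(stage, ".manifest.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

.needInput <- function(dir, file, upstream) {
    p <- file.path(dir, file)
    if (!file.exists(p))
        stop(sprintf("missing input '%s': run the '%s' stage first", file,
                     upstream), call. = FALSE)
    p
}

#' Run one pipeline stage file-to-file
#'
#' Stages operate on conventional file names inside `dir` and are
#' composable: `simulate` writes `genomes.fasta` / `reads.fastq` /
#' `truth.tsv`; `overlap` writes `overlaps.tsv`; `pileup` writes
#' `segments.rds`; `label` writes `labels.tsv` (from the truth track);
#' `train` writes `model.rds`; `predict` writes `predictions.tsv`; `scrub`
#' writes `scrubbed.fastq` and `scrub_stats.json`; `evaluate` writes
#' `evaluation.json`. Every stage also writes a `<stage>.manifest.json`
#' run manifest (parameters, package version, input checksums).
#'
#' @param stage one of `simulate`, `overlap`, `pileup`, `label`, `train`,
#'   `predict`, `scrub`, `evaluate`.
#' @param dir working directory for the pipeline artifacts.
#' @param minimizerParam,overlapParam,pileupParam,trainParam,scrubParam,simParam
#'   parameter objects for the stages that use them.
#' @param verbose print per-stage progress at INFO level.
#' @return The stage's main result, invisibly.
#' @export
runPipeline <- function(stage = c("simulate", "overlap", "pileup", "label",
                                  "train", "predict", "scrub", "evaluate"),
                        dir = ".",
                        minimizerParam = MinimizerParam(),
                        overlapParam = OverlapParam(),
                        pileupParam = PileupParam(),
                        trainParam = TrainParam(),
                        scrubParam = ScrubParam(),
                        simParam = SimParam(),
                        verbose = TRUE) {
    stage <- match.arg(stage)
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    say <- function(fmt, ...) {
        if (verbose) message(sprintf(paste0("[%s] ", fmt), stage, ...))
    }
    t0 <- Sys.time()
    res <- switch(stage,
    simulate = {
        genomes <- simulateGenome(simParam)
        sim <- simulateReads(genomes, simParam)
        writeFasta(genomes, file.path(dir, "genomes.fasta"))
        writeFastq(sim$reads, file.path(dir, "reads.fastq"))
        writeTruthTsv(sim$truth, file.path(dir, "truth.tsv"))
        say("%d genome(s), %d reads, %d bases", length(genomes),
            length(sim$reads), sum(Biostrings::width(sim$reads)))
        .manifest(dir, stage, list(sim = simParam), character(),
                  c("genomes.fasta", "reads.fastq", "truth.tsv"))
        sim
    },
    overlap = {
        fq <- .needInput(dir, "reads.fastq", "simulate")
        reads <- readFastq(fq)
        ov <- findReadOverlaps(reads, minimizerParam, overlapParam)
        writeOverlaps(ov, file.path(dir, "overlaps.tsv"), minimizerParam)
        say("%d reads -> %d overlap records", length(reads), nrow(ov))
        .manifest(dir, stage,
                  list(minimizer = minimizerParam, overlap = overlapParam),
                  fq, "overlaps.tsv")
        ov
    },
    pileup = {
        fq <- .needInput(dir, "reads.fastq", "simulate")
        ovf <- .needInput(dir, "overlaps.tsv", "overlap")
        reads <- readFastq(fq)
        sketches <- readSketches(reads, minimizerParam)
        ov <- readOverlaps(ovf, sketches)
        segs <- bindSegments(lapply(names(reads), function(id) {
            segmentPileup(encodePileup(id, ov, reads, pileupParam,
                                       minimizerParam, sketches),
                          pileupParam)
        }))
        saveRDS(segs, file.path(dir, "segments.rds"))
        say("%d segments from %d reads", length(segs), length(reads))
        .manifest(dir, stage,
                  list(minimizer = minimizerParam, pileup = pileupParam),
                  c(fq, ovf), "segments.rds")
        segs
    },
    label = {
        tf <- .needInput(dir, "truth.tsv", "simulate")
        sf <- .needInput(dir, "segments.rds", "pileup")
        truth <- readTruthTsv(tf)
        segs <- readRDS(sf)
        labels <- truthLabels(truth, segs)
        writeLabelsTsv(labels, file.path(dir, "labels.tsv"))
        say("%d labels, mean identity %.3f", nrow(labels),
            mean(labels$identity))
        .manifest(dir, stage, list(), c(tf, sf), "labels.tsv")
        labels
    },
    train = {
        sf <- .needInput(dir, "segments.rds", "pileup")
        lf <- .needInput(dir, "labels.tsv", "label")
        segs <- readRDS(sf)
        ltab <- utils::read.table(lf, header = TRUE, sep = "\t",
                                  stringsAsFactors = FALSE)
        labels <- data.frame(refId = ltab$ref_id,
                             segmentIndex = ltab$segment_index,
                             baseStart = ltab$base_start,
                             baseEnd = ltab$base_end,
                             identity = ltab$identity)
        model <- trainScrubModel(segs, labels, trainParam, minimizerParam,
                                 pileupParam)
        saveScrubModel(model, file.path(dir, "model.rds"))
        say("trained %s for %d epochs, final loss %.5f", trainParam@variant,
            trainParam@epochs, utils::tail(lossHistory(model), 1L))
        .manifest(dir, stage,
                  list(train = trainParam, pileup = pileupParam,
                       minimizer = minimizerParam), c(sf, lf), "model.rds")
        model
    },
    predict = {
        mf <- .needInput(dir, "model.rds", "train")
        sf <- .needInput(dir, "segments.rds", "pileup")
        model <- loadScrubModel(mf)
        segs <- readRDS(sf)
        ptab <- predictionTable(model, segs)
        writePredictionsTsv(ptab, file.path(dir, "predictions.tsv"))
        say("%d predictions, mean %.3f", nrow(ptab), mean(ptab$prediction))
        .manifest(dir, stage, list(), c(mf, sf), "predictions.tsv")
        ptab
    },
    scrub = {
        fq <- .needInput(dir, "reads.fastq", "simulate")
        pf <- .needInput(dir, "predictions.tsv", "predict")
        stats <- scrubFastq(fq, pf, scrubParam,
                            file.path(dir, "scrubbed.fastq"))
        jsonlite::write_json(stats, file.path(dir, "scrub_stats.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
        say("%d/%d bases kept, %d reads -> %d fragments", stats$basesOut,
            stats$basesIn, stats$readsIn, stats$readsOut)
        .manifest(dir, stage, list(scrub = scrubParam), c(fq, pf),
                  c("scrubbed.fastq", "scrub_stats.json"))
        stats
    },
    evaluate = {
        pf <- .needInput(dir, "predictions.tsv", "predict")
        lf <- .needInput(dir, "labels.tsv", "label")
        preds <- readPredictionsTsv(pf)
        ltab <- utils::read.table(lf, header = TRUE, sep = "\t",
                                  stringsAsFactors = FALSE)
        key <- paste(preds$refId, preds$segmentIndex)
        lkey <- paste(ltab$ref_id, ltab$segment_index)
        rep <- evaluatePredictions(preds$prediction,
                                   ltab$identity[match(key, lkey)],
                                   cutoff = scrubParam@threshold)
        jsonlite::write_json(as.list(evalMetrics(rep)),
                             file.path(dir, "evaluation.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
        say("MSE %.5f, Spearman %.3f", rep@mse, rep@spearman)
        .manifest(dir, stage, list(scrub = scrubParam), c(pf, lf),
                  "evaluation.json")
        rep
    })
    say("done in %.1fs", as.numeric(difftime(Sys.time(), t0, units = "secs")))
    invisible(res)
}
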