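#' @describeIn nFrames frame count of a FrameStack
#' @export
setMethod("nFrames", "FrameStack", function(x) length(x@frames))

#' @describeIn fps fps of a FrameStack
#' @export
setMethod("fps", "FrameStack", function(x) x@fps)

#' @describeIn fps fps of the recording behind a WormTracks
#' @export
setMethod("fps", "WormTracks", function(x) x@fps)

#' @describeIn getFrame extract frame i (1-based)
#' @export
setMethod("getFrame", "FrameStack", function(x, i) {
    stopifnot(i >= 1, i <= length(x@frames))
    x@frames[[i]]
})

setMethod("show", "FrameStack", function(object) {
    d <- if (length(object@frames)) dim(object@frames[[1]]) else c(0L, 0L)
    cat(sprintf("FrameStack: %d frames of %d x %d px at %g fps\n",
        length(object@frames), d[2], d[1], object@fps))
})

setMethod("show", "WormRecording", function(object) {
    show(object@stack)
    nw <- length(unique(object@truth$worm_id))
    cf <- trueCoilFraction(object)
    cat(sprintf("  %d worms; true coil fraction %.4f\n", nw, cf))
})

#' @describeIn corpusDocs document table of a Corpus
#' @export
setMethod("corpusDocs", "Corpus", function(x) x@docs)

#' @describeIn entityRoles entity -> role map of a Corpus
#' @export
setMethod("entityRoles", "Corpus", function(x) {
    u <- unique(x@docs[, c("entity", "role")])
    structure(u$role, names = u$entity)
})

setMethod("show", "Corpus", function(object) {
    r <- entityRoles(object)
    cat(sprintf(
        "Corpus: %d documents, %d known + %d candidate entities\n",
        nrow(object@docs), sum(r == "known"), sum(r == "candidate")))
})

#' @describeIn plateTimes read times (hours) of a plate
#' @export
setMethod("plateTimes", "RtQuicPlate",
    function(x) SummarizedExperiment::colData(x)$time_h)

#' @describeIn plateTimes read times (hours) behind a calls object
#' @export
setMethod("plateTimes", "RtQuicCalls", function(x) x@times)

setMethod("show", "RtQuicPlate", function(object) {
    rd <- SummarizedExperiment::rowData(object)
    tm <- plateTimes(object)
    cat(sprintf(
        "RtQuicPlate: %d wells (%d background) x %d reads, %.2f-%.2f h\n",
        nrow(object), sum(rd$is_background), length(tm), min(tm), max(tm)))
    cat(sprintf("  %d samples, %d replicates each\n",
        length(unique(rd$sample[!rd$is_background])),
        if (any(!rd$is_background))
            as.integer(table(rd$sample[!rd$is_background])[1]) else 0L))
})

#' @describeIn trackDetections detections of a WormTracks
#' @export
setMethod("trackDetections", "WormTracks", function(x) x@detections)

#' @describeIn trackStats per-track duration, path length and speed
#' @export
setMethod("trackStats", "WormTracks", function(x) {
    d <- x@detections
    out <- lapply(split(d, d$track_id), function(td) {
        td <- td[order(td$frame), ]
        dur <- (td$frame[nrow(td)] - td$frame[1]) / x@fps
        pl <- if (nrow(td) > 1)
            sum(sqrt(diff(td$x)^2 + diff(td$y)^2)) else 0
        data.frame(track_id = td$track_id[1], n_detections = nrow(td),
            duration_s = dur, path_length_px = pl,
            speed_px_s = if (dur > 0) pl / dur else NA_real_)
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
})

setMethod("show", "WormTracks", function(object) {
    cat(sprintf(
        "WormTracks: %d tracks, %d detections over %d frames (%g fps)\n",
        length(unique(object@detections$track_id)),
        nrow(object@detections), object@nFramesTotal, object@fps))
    if (object@framesDropped > 0)
        cat(sprintf("  %d oversized (collision) blobs dropped upstream\n",
            object@framesDropped))
})

#' @describeIn diffusionScores scores of a RankedList
#' @export
setMethod("diffusionScores", "RankedList", function(x) x@scores)

#' @describeIn candidateRanking ranking table of a RankedList
#' @export
setMethod("candidateRanking", "RankedList", function(x) x@ranking)

setMethod("show", "RankedList", function(object) {
    cat(sprintf(
        "RankedList: %d candidates ranked against %d known entities\n",
        nrow(object@ranking), length(object@known)))
    print(head(object@ranking, 5))
})

#' @describeIn sampleCalls sample calls of an RtQuicCalls
#' @export
setMethod("sampleCalls", "RtQuicCalls", function(x) x@sampleCalls)

#' @describeIn replicateCalls replicate calls of an RtQuicCalls
#' @export
setMethod("replicateCalls", "RtQuicCalls", function(x) x@replicateCalls)

setMethod("show", "RtQuicCalls", function(object) {
    sc <- object@sampleCalls
    cat(sprintf(
        "RtQuicCalls: threshold %.1f rfu; %d/%d samples positive\n",
        object@threshold, sum(sc$positive), nrow(sc)))
})
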