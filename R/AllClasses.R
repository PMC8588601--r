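#' @import methods
#' @importFrom stats rnorm runif sd quantile pnorm rbinom
#' @importFrom utils read.csv write.csv head
NULL

#' FrameStack: an ordered sequence of grayscale frames
#'
#' Container for a timed image sequence (one video of crawling worms).
#' Frames are numeric matrices in [0, 1] sharing dimensions; pixel values
#' follow the dark-on-light convention of agar-plate recordings.
#'
#' @slot frames list of numeric matrices (row = y, column = x).
#' @slot fps frames per second (> 0).
#' @slot pxScale optional pixels-per-millimetre factor (NA when
#'   uncalibrated; all shape metrics are reported in pixel units).
#' @export
setClass("FrameStack",
    representation(frames = "list", fps = "numeric", pxScale = "numeric"),
    prototype(frames = list(), fps = 2, pxScale = NA_real_))

setValidity("FrameStack", function(object) {
    if (length(object@fps) != 1L || !is.finite(object@fps) || object@fps <= 0)
        return("fps must be a single positive number")
    if (length(object@frames)) {
        dims <- vapply(object@frames, function(f) {
            if (!is.matrix(f)) return(c(NA_integer_, NA_integer_))
            dim(f)
        }, integer(2))
        if (anyNA(dims)) return("all frames must be 2-D matrices")
        if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
            return("all frames must share dimensions")
    }
    TRUE
})

#' FrameStack constructor
#'
#' @param frames list of numeric matrices sharing dimensions.
#' @param fps frames per second.
#' @param pxScale optional pixels per millimetre.
#' @return A \linkS4class{FrameStack}.
#' @examples
#' fs <- FrameStack(list(matrix(0.9, 20, 30)), fps = 2)
#' nFrames(fs)
#' @export
FrameStack <- function(frames, fps = 2, pxScale = NA_real_) {
    new("FrameStack", frames = frames, fps = as.numeric(fps),
        pxScale = as.numeric(pxScale))
}

#' Simulated worm recording with ground truth
#'
#' @slot stack the rendered \linkS4class{FrameStack}.
#' @slot truth data.frame with one row per worm per frame: \code{frame}
#'   (0-based), \code{worm_id}, \code{posture} (sinusoidal/turn/coil),
#'   \code{x}, \code{y} (midline centroid, 0-based pixel coordinates).
#' @slot config the generating configuration (list).
#' @export
setClass("WormRecording",
    representation(stack = "FrameStack", truth = "data.frame",
        config = "list"))

#' Literature corpus of entity-tagged documents
#'
#' One row per document: a document id, the entity (compound) the document
#' is about, the entity's role (\code{"known"} or \code{"candidate"}), and
#' whitespace-tokenizable text.
#'
#' @slot docs data.frame with columns doc_id, entity, role, text.
#' @export
setClass("Corpus", representation(docs = "data.frame"))

setValidity("Corpus", function(object) {
    d <- object@docs
    need <- c("doc_id", "entity", "role", "text")
    if (!all(need %in% names(d)))
        return(paste("docs must have columns", paste(need, collapse = ", ")))
    if (!all(d$role %in% c("known", "candidate")))
        return("role must be 'known' or 'candidate'")
    if (anyDuplicated(d$doc_id)) return("doc_id values must be unique")
    byrole <- unique(d[, c("entity", "role")])
    if (anyDuplicated(byrole$entity))
        return("each entity must have exactly one role")
    TRUE
})

#' Corpus constructor
#' @param docs data.frame with columns doc_id, entity, role, text.
#' @return A \linkS4class{Corpus}.
#' @export
Corpus <- function(docs) {
    docs <- as.data.frame(docs, stringsAsFactors = FALSE)
    docs$doc_id <- as.character(docs$doc_id)
    docs$entity <- as.character(docs$entity)
    docs$role <- as.character(docs$role)
    docs$text <- as.character(docs$text)
    new("Corpus", docs = docs)
}

#' RT-QuIC kinetic fluorescence plate
#'
#' Wells-by-timepoints ThT fluorescence readings (rfu) with the well map
#' (sample, replicate, background flag, optional treatment group) in
#' \code{rowData} and the read times in hours in \code{colData}. Extends
#' \link[SummarizedExperiment]{SummarizedExperiment}, so all its accessors
#' apply.
#'
#' @export
#' @import SummarizedExperiment
setClass("RtQuicPlate", contains = "SummarizedExperiment")

setValidity("RtQuicPlate", function(object) {
    rd <- SummarizedExperiment::rowData(object)
    need <- c("sample", "replicate", "is_background")
    if (!all(need %in% names(rd)))
        return(paste("rowData must have columns",
            paste(need, collapse = ", ")))
    tm <- plateTimes(object)
    if (any(diff(tm) <= 0)) return("times must be strictly increasing")
    if (sum(rd$is_background) < 2L)
        return("at least 2 background wells are required")
    reps <- table(rd$sample[!rd$is_background])
    if (length(reps) && length(unique(as.integer(reps))) != 1L)
        return("every sample must have the same replicate count")
    TRUE
})

#' RtQuicPlate constructor
#'
#' @param readings numeric matrix, wells x timepoints, rfu. Row names are
#'   well ids (generated when absent).
#' @param times numeric vector of read times in hours, strictly
#'   increasing, one per column.
#' @param wellMap data.frame with one row per well: columns
#'   \code{sample}, \code{replicate}, \code{is_background}, and
#'   optionally \code{group}.
#' @return An \linkS4class{RtQuicPlate}.
#' @export
RtQuicPlate <- function(readings, times, wellMap) {
    readings <- as.matrix(readings)
    if (is.null(rownames(readings)))
        rownames(readings) <- sprintf("W%03d", seq_len(nrow(readings)))
    if (ncol(readings) != length(times))
        stop("length(times) must equal ncol(readings)")
    wellMap <- as.data.frame(wellMap, stringsAsFactors = FALSE)
    if (nrow(wellMap) != nrow(readings))
        stop("wellMap must have one row per well")
    if (is.null(wellMap$group)) wellMap$group <- NA_character_
    rd <- S4Vectors::DataFrame(wellMap)
    rownames(rd) <- rownames(readings)
    cd <- S4Vectors::DataFrame(time_h = as.numeric(times))
    colnames(readings) <- sprintf("t_%.2f", as.numeric(times))
    rownames(cd) <- colnames(readings)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(rfu = readings), rowData = rd, colData = cd)
    new("RtQuicPlate", se)
}

#' Seeding-positivity calls for an RT-QuIC plate
#'
#' @slot threshold positivity threshold in rfu (background mean + 5 SD).
#' @slot replicateCalls data.frame: well, sample, replicate, endpoint rfu,
#'   positive (logical).
#' @slot sampleCalls data.frame: sample, group, n_positive_replicates,
#'   n_replicates, positive (logical).
#' @slot meanCurves matrix samples x timepoints: per sample, the mean over
#'   its positive replicates when the sample is positive, else over its
#'   negative replicates.
#' @slot times read times in hours.
#' @export
setClass("RtQuicCalls",
    representation(threshold = "numeric", replicateCalls = "data.frame",
        sampleCalls = "data.frame", meanCurves = "matrix",
        times = "numeric"))

#' Linked per-animal worm tracks
#'
#' @slot detections data.frame of track-assigned detections: frame
#'   (0-based), track_id, area, perimeter, circularity, x, y, posture.
#' @slot fps frames per second of the source recording.
#' @slot nFramesTotal total frames in the source recording.
#' @slot framesDropped number of detections discarded upstream (oversized
#'   collision blobs).
#' @export
setClass("WormTracks",
    representation(detections = "data.frame", fps = "numeric",
        nFramesTotal = "integer", framesDropped = "integer"))

#' Diffusion-ranked candidate list
#'
#' @slot scores named numeric vector of stationary random-walk-with-
#'   restart scores over all entities (sums to 1).
#' @slot ranking data.frame over candidate entities: rank, entity, score,
#'   ordered by score descending with lexicographic tie-break.
#' @slot known character vector of known (seed) entities.
#' @slot iterations iterations used by the power method.
#' @export
setClass("RankedList",
    representation(scores = "numeric", ranking = "data.frame",
        known = "character", iterations = "integer"))
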