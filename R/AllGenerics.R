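#' Number of frames in a stack
#' @param x a \linkS4class{FrameStack}.
#' @return integer frame count.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Frames-per-second accessor
#' @param x a \linkS4class{FrameStack} or \linkS4class{WormTracks}.
#' @return numeric fps.
#' @export
setGeneric("fps", function(x) standardGeneric("fps"))

#' Extract one frame
#' @param x a \linkS4class{FrameStack}.
#' @param i frame number (1-based).
#' @return numeric matrix.
#' @export
setGeneric("getFrame", function(x, i) standardGeneric("getFrame"))

#' Corpus document table accessor
#' @param x a \linkS4class{Corpus}.
#' @return data.frame with doc_id, entity, role, text.
#' @export
setGeneric("corpusDocs", function(x) standardGeneric("corpusDocs"))

#' Entity roles of a corpus
#' @param x a \linkS4class{Corpus}.
#' @return named character vector entity -> role.
#' @export
setGeneric("entityRoles", function(x) standardGeneric("entityRoles"))

#' Read times of an RT-QuIC plate
#' @param x an \linkS4class{RtQuicPlate} or \linkS4class{RtQuicCalls}.
#' @return numeric vector of hours.
#' @export
setGeneric("plateTimes", function(x) standardGeneric("plateTimes"))

#' Track-assigned detections accessor
#' @param x a \linkS4class{WormTracks}.
#' @return data.frame of detections with track ids.
#' @export
setGeneric("trackDetections", function(x) standardGeneric("trackDetections"))

#' Per-track summary statistics
#'
#' Duration is (last - first frame)/fps; path length is the sum of
#' consecutive centroid distances; speed is path_length/duration.
#'
#' @param x a \linkS4class{WormTracks}.
#' @return data.frame: track_id, n_detections, duration_s, path_length_px,
#'   speed_px_s.
#' @export
setGeneric("trackStats", function(x) standardGeneric("trackStats"))

#' Diffusion scores accessor
#' @param x a \linkS4class{RankedList}.
#' @return named numeric vector over all entities (sums to 1).
#' @export
setGeneric("diffusionScores", function(x) standardGeneric("diffusionScores"))

#' Candidate ranking table accessor
#' @param x a \linkS4class{RankedList}.
#' @return data.frame: rank, entity, score.
#' @export
setGeneric("candidateRanking",
    function(x) standardGeneric("candidateRanking"))

#' Per-sample positivity calls accessor
#' @param x an \linkS4class{RtQuicCalls}.
#' @return data.frame: sample, group, n_positive_replicates, n_replicates,
#'   positive.
#' @export
setGeneric("sampleCalls", function(x) standardGeneric("sampleCalls"))

#' Per-replicate (well) positivity calls accessor
#' @param x an \linkS4class{RtQuicCalls}.
#' @return data.frame: well, sample, replicate, endpoint, positive.
#' @export
setGeneric("replicateCalls", function(x) standardGeneric("replicateCalls"))
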