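#' Link per-frame detections into worm tracks
#'
#' Greedy nearest-neighbour frame-to-frame assignment: matches are
#' accepted in order of increasing distance, only within \code{maxDisp};
#' unmatched detections seed new tracks; a track unmatched for more than
#' \code{maxGap} frames is closed. Each detection joins at most one
#' track. Identity swaps during close encounters are tolerated because
#' the population endpoints (pooled coiler score, duration-weighted
#' speed) are swap-invariant.
#'
#' @param detections data.frame from \code{\link{segmentStack}} (columns
#'   frame, x, y at minimum; extra columns are carried through).
#' @param maxDisp maximum per-link displacement in px.
#' @param maxGap maximum number of consecutive missed frames before a
#'   track is closed (default 2).
#' @param fps frames per second of the recording (used by downstream
#'   summaries; taken from the detections attribute when absent).
#' @return a \linkS4class{WormTracks}.
#' @export
linkTracks <- function(detections, maxDisp, maxGap = 2, fps = 2) {
    stopifnot(maxDisp > 0, maxGap >= 0)
    det <- as.data.frame(detections)
    nTotal <- attr(detections, "nFramesTotal") %||%
        (if (nrow(det)) max(det$frame) + 1L else 0L)
    dropped <- attr(detections, "framesDropped") %||% 0L
    det$track_id <- rep(NA_integer_, nrow(det))
    if (nrow(det)) {
        det <- det[order(det$frame), ]
        frames <- sort(unique(det$frame))
        rowsByFrame <- split(seq_len(nrow(det)), det$frame)
        # active tracks: id, last x/y, last frame
        act <- data.frame(id = integer(), x = numeric(), y = numeric(),
            last = integer())
        nextId <- 1L
        for (f in frames) {
            rows <- rowsByFrame[[as.character(f)]]
            act <- act[f - act$last <= maxGap + 1L, , drop = FALSE]
            assigned <- rep(NA_integer_, length(rows))
            if (nrow(act)) {
                dx <- outer(act$x, det$x[rows], "-")
                dy <- outer(act$y, det$y[rows], "-")
                dist <- sqrt(dx^2 + dy^2)
                dist[dist > maxDisp] <- NA
                while (any(is.finite(dist))) {
                    k <- arrayInd(which.min(dist), dim(dist))
                    assigned[k[2]] <- act$id[k[1]]
                    act$x[k[1]] <- det$x[rows[k[2]]]
                    act$y[k[1]] <- det$y[rows[k[2]]]
                    act$last[k[1]] <- f
                    dist[k[1], ] <- NA
                    dist[, k[2]] <- NA
                }
            }
            if (anyNA(assigned)) {
                newIdx <- which(is.na(assigned))
                ids <- nextId + seq_along(newIdx) - 1L
                nextId <- nextId + length(newIdx)
                assigned[newIdx] <- ids
                act <- rbind(act, data.frame(id = ids,
                    x = det$x[rows[newIdx]], y = det$y[rows[newIdx]],
                    last = f))
            }
            det$track_id[rows] <- assigned
        }
    }
    rownames(det) <- NULL
    new("WormTracks", detections = det, fps = as.numeric(fps),
        nFramesTotal = as.integer(nTotal),
        framesDropped = as.integer(dropped))
}

#' Population coiler score
#'
#' Percentage of tracked frames whose circularity exceeds the coiling
#' threshold (strict), pooled over all tracks in the population. A
#' per-animal mode averages each track's own percentage instead (whether
#' the original scoring pooled frames or averaged animals is not
#' documented; pooling is the default here).
#'
#' @param tracks a \linkS4class{WormTracks} (or a data.frame of
#'   detections with a circularity column).
#' @param coilThreshold coiling cut-off (default 0.6).
#' @param perAnimal average per-track percentages instead of pooling
#'   frames (default FALSE).
#' @return coiler score in percent (0-100).
#' @examples
#' d <- data.frame(frame = 0:3, track_id = 1,
#'                 circularity = c(0.2, 0.7, 0.9, 0.5))
#' coilerScore(d)  # 50
#' @export
coilerScore <- function(tracks, coilThreshold = 0.6, perAnimal = FALSE) {
    d <- if (is(tracks, "WormTracks")) tracks@detections else
        as.data.frame(tracks)
    if (!nrow(d)) stop("no tracked frames: coiler score undefined")
    coil <- d$circularity > coilThreshold
    if (!perAnimal) return(100 * mean(coil))
    mean(vapply(split(coil, d$track_id), function(z) 100 * mean(z),
        numeric(1)))
}

#' Duration-weighted average population speed
#'
#' Per-track speed is path length over tracked time; the population
#' speed is the duration-weighted mean of track speeds, identically
#' total path length / total tracked time.
#'
#' @param tracks a \linkS4class{WormTracks}.
#' @return speed in px/s.
#' @export
averageSpeed <- function(tracks) {
    stopifnot(is(tracks, "WormTracks"))
    st <- trackStats(tracks)
    st <- st[st$duration_s > 0, , drop = FALSE]
    if (!nrow(st)) stop("no track with positive duration")
    sum(st$path_length_px) / sum(st$duration_s)
}

#' Population-level result summary
#'
#' @param tracks a \linkS4class{WormTracks}.
#' @param coilThreshold coiling cut-off (default 0.6).
#' @return data.frame: n_tracks, coiler_score_pct, mean_speed_px_s,
#'   frames_used, frames_dropped.
#' @export
populationResult <- function(tracks, coilThreshold = 0.6) {
    stopifnot(is(tracks, "WormTracks"))
    d <- tracks@detections
    data.frame(
        n_tracks = length(unique(d$track_id)),
        coiler_score_pct = coilerScore(tracks, coilThreshold),
        mean_speed_px_s = averageSpeed(tracks),
        frames_used = nrow(d),
        frames_dropped = tracks@framesDropped)
}

#' Normalize scores to a control group
#'
#' Fold-of-control normalization: each test score divided by the mean of
#' the control scores (a severe coiler reaching a normalized score above
#' 100 is only consistent with a ratio, not a difference).
#'
#' @param testScores numeric vector of raw scores (percent).
#' @param controlScores numeric vector of control-group raw scores;
#'   nonempty with positive mean.
#' @return data.frame: raw, control_mean, normalized.
#' @examples
#' normalizeToControl(c(10, 20), c(4, 6))$normalized  # 2, 4
#' @export
normalizeToControl <- function(testScores, controlScores) {
    if (!length(controlScores))
        stop("control scores must be nonempty")
    cm <- mean(controlScores)
    if (!is.finite(cm) || cm <= 0)
        stop("control mean is not positive; report raw scores instead")
    data.frame(raw = testScores, control_mean = cm,
        normalized = testScores / cm)
}
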