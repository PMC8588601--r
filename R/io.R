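# Format plumbing: every writer's output is readable by its reader with
# lossless field values (within float formatting at 1e-9). CSV dialect:
# comma-separated, UTF-8, header row, '.' decimal.

#' Write a frame stack as multipage TIFF
#'
#' 8-bit grayscale; an optional ground-truth table is written alongside
#' as CSV (frame, worm_id, posture, x, y).
#'
#' @param stack a \linkS4class{FrameStack} (or a
#'   \linkS4class{WormRecording}, in which case the ground truth is
#'   written next to the TIFF as \code{<path>.truth.csv}).
#' @param path output .tif path.
#' @return invisibly, the path.
#' @export
writeFrameStack <- function(stack, path) {
    truth <- NULL
    if (is(stack, "WormRecording")) {
        truth <- stack@truth
        stack <- stack@stack
    }
    tiff::writeTIFF(stack@frames, path, bits.per.sample = 8L)
    if (!is.null(truth))
        write.csv(truth, paste0(path, ".truth.csv"), row.names = FALSE)
    invisible(path)
}

#' Read a frame stack from multipage TIFF or a PNG directory
#'
#' @param path a multipage .tif file, or a directory of numbered .png
#'   frames (sorted by filename).
#' @param fps frames per second to attach (default 2).
#' @return a \linkS4class{FrameStack}.
#' @export
readFrameStack <- function(path, fps = 2) {
    if (dir.exists(path)) {
        files <- sort(list.files(path, pattern = "\\.png$",
            full.names = TRUE))
        if (!length(files)) stop("no .png frames in ", path)
        frames <- lapply(files, function(f) {
            img <- EBImage::readImage(f)
            m <- as.matrix(img)
            if (length(dim(img)) > 2) m <- as.matrix(img[, , 1])
            t(m)  # EBImage stores x-major; frames are row = y
        })
    } else {
        frames <- tiff::readTIFF(path, all = TRUE)
        frames <- lapply(frames, function(f)
            if (length(dim(f)) == 3) f[, , 1] else f)
    }
    FrameStack(frames, fps = fps)
}

#' Write / read a detection table
#'
#' CSV columns: frame, object_id, area_px2, perimeter_px, circularity,
#' x, y, posture.
#'
#' @param detections data.frame from \code{\link{segmentStack}}.
#' @param path .csv path.
#' @return invisibly the path / the detections data.frame (with
#'   \code{nFramesTotal} and \code{framesDropped} attributes restored
#'   from the companion columns when present).
#' @export
writeDetections <- function(detections, path) {
    d <- as.data.frame(detections)
    write.csv(d, path, row.names = FALSE)
    meta <- data.frame(
        nFramesTotal = attr(detections, "nFramesTotal") %||% NA,
        framesDropped = attr(detections, "framesDropped") %||% NA)
    write.csv(meta, paste0(path, ".meta.csv"), row.names = FALSE)
    invisible(path)
}

#' @rdname writeDetections
#' @export
readDetections <- function(path) {
    d <- read.csv(path, stringsAsFactors = FALSE)
    metaPath <- paste0(path, ".meta.csv")
    if (file.exists(metaPath)) {
        meta <- read.csv(metaPath)
        attr(d, "nFramesTotal") <- as.integer(meta$nFramesTotal)
        attr(d, "framesDropped") <- as.integer(meta$framesDropped)
    }
    d
}

#' Write / read a corpus as JSON-lines
#'
#' One JSON object per line: doc_id, entity, role, text.
#'
#' @param corpus a \linkS4class{Corpus}.
#' @param path .jsonl path.
#' @return invisibly the path / the \linkS4class{Corpus}.
#' @export
writeCorpus <- function(corpus, path) {
    stopifnot(is(corpus, "Corpus"))
    lines <- vapply(seq_len(nrow(corpus@docs)), function(i)
        jsonlite::toJSON(as.list(corpus@docs[i, ]), auto_unbox = TRUE),
        character(1))
    writeLines(lines, path, useBytes = TRUE)
    invisible(path)
}

#' @rdname writeCorpus
#' @export
readCorpus <- function(path) {
    lines <- readLines(path, encoding = "UTF-8")
    rows <- lapply(lines, function(l)
        as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE))
    Corpus(do.call(rbind, rows))
}

#' Write / read an RT-QuIC plate as CSV
#'
#' Columns: well, sample, replicate, is_background, group, then one
#' column per timepoint (\code{t_<hours>} with 2-decimal hours).
#'
#' @param plate an \linkS4class{RtQuicPlate}.
#' @param path .csv path.
#' @return invisibly the path / the \linkS4class{RtQuicPlate}.
#' @export
writeRtQuicPlate <- function(plate, path) {
    stopifnot(is(plate, "RtQuicPlate"))
    rd <- as.data.frame(SummarizedExperiment::rowData(plate))
    rfu <- SummarizedExperiment::assay(plate, "rfu")
    out <- cbind(data.frame(well = rownames(rfu)), rd,
        as.data.frame(rfu, check.names = FALSE))
    write.csv(out, path, row.names = FALSE)
    invisible(path)
}

#' @rdname writeRtQuicPlate
#' @export
readRtQuicPlate <- function(path) {
    d <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    tcols <- grep("^t_", names(d), value = TRUE)
    times <- as.numeric(sub("^t_", "", tcols))
    readings <- as.matrix(d[, tcols])
    rownames(readings) <- d$well
    RtQuicPlate(readings, times,
        d[, c("sample", "replicate", "is_background", "group")])
}

#' Write population and per-track results as CSV
#'
#' Writes \code{population_<id>.csv} (population_id, n_tracks,
#' coiler_score_pct, mean_speed_px_s, frames_used, frames_dropped) and
#' \code{tracks_<id>.csv} (per-track duration, path length, speed) into
#' a directory; \code{\link{screenReport}} picks the former up.
#'
#' @param tracks a \linkS4class{WormTracks}.
#' @param populationId identifier written into the tables.
#' @param dir output directory (created if missing).
#' @return invisibly, the population CSV path.
#' @export
writeTrackResults <- function(tracks, populationId, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    pop <- cbind(population_id = populationId,
        populationResult(tracks))
    popPath <- file.path(dir,
        sprintf("population_%s.csv", populationId))
    write.csv(pop, popPath, row.names = FALSE)
    st <- cbind(population_id = populationId, trackStats(tracks))
    write.csv(st, file.path(dir,
        sprintf("tracks_%s.csv", populationId)), row.names = FALSE)
    invisible(popPath)
}

#' Write a ranked candidate list as CSV
#'
#' Columns: rank, entity, score.
#'
#' @param rankedList a \linkS4class{RankedList}.
#' @param path .csv path.
#' @return invisibly the path.
#' @export
writeRankedList <- function(rankedList, path) {
    write.csv(candidateRanking(rankedList), path, row.names = FALSE)
    invisible(path)
}

#' Write leave-one-out validation results as JSON (+ curve CSVs)
#'
#' @param loo result of \code{\link{looValidate}}.
#' @param path .json path; ROC and PR curves go to \code{<path>.roc.csv}
#'   and \code{<path>.pr.csv}.
#' @return invisibly the path.
#' @export
writeLooValidation <- function(loo, path) {
    jsonlite::write_json(list(auc = loo$auc,
        average_precision = loo$averagePrecision,
        ranksum_p = loo$ranksumP,
        holdout_ranks = loo$holdouts$rank,
        holdout_entities = loo$holdouts$entity),
        path, auto_unbox = TRUE, digits = NA)
    write.csv(loo$roc, paste0(path, ".roc.csv"), row.names = FALSE)
    write.csv(loo$pr, paste0(path, ".pr.csv"), row.names = FALSE)
    invisible(path)
}

#' Write a run manifest
#'
#' Records inputs, configuration, seed and package version so any result
#' can be reproduced from the manifest alone.
#'
#' @param path .json path.
#' @param config the configuration list used.
#' @param inputs character vector of input paths (empty for simulated
#'   inputs).
#' @param seed the seed used.
#' @return invisibly the path.
#' @export
writeRunManifest <- function(path, config, inputs = character(),
        seed = NULL) {
    cfg <- unclass(config)
    jsonlite::write_json(list(
        package = "SynScreen",
        version = as.character(utils::packageVersion("SynScreen")),
        r_version = as.character(getRversion()),
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
        seed = seed, inputs = inputs, config = cfg,
        config_hash = sum(utf8ToInt(paste(deparse(cfg),
            collapse = "")))),
        path, auto_unbox = TRUE, digits = NA, null = "null")
    invisible(path)
}

#' Plain-text screen report
#'
#' Summarizes whatever stage outputs are present in a directory --
#' population coiler-score CSVs, ranking CSVs, RT-QuIC call CSVs -- into
#' one human-readable document mirroring the screen funnel (behavioural
#' scoring, in silico ranking, RT-QuIC validation). Missing or
#' malformed sections are skipped with a warning.
#'
#' @param dir directory of stage outputs.
#' @param path output .txt path.
#' @return invisibly the path.
#' @export
screenReport <- function(dir, path = file.path(dir, "report.txt")) {
    lines <- c("SynScreen report", strrep("=", 16), "")
    readOr <- function(f) tryCatch(read.csv(f, stringsAsFactors = FALSE),
        error = function(e) {
            warning("skipping malformed ", basename(f)); NULL
        })
    section <- function(title, files, fmt) {
        if (!length(files)) return(character())
        out <- c(title, strrep("-", nchar(title)))
        for (f in files) {
            d <- readOr(f)
            if (!is.null(d)) out <- c(out, fmt(basename(f), d))
        }
        c(out, "")
    }
    lines <- c(lines,
        section("Coiler scores",
            list.files(dir, "population.*\\.csv$", full.names = TRUE),
            function(n, d) {
                if (!all(c("coiler_score_pct") %in% names(d))) {
                    warning("skipping malformed ", n,
                        ": unrecognized schema")
                    return(character())
                }
                sprintf("%s: coiler score %.2f%% (%d tracks, %d frames)",
                    n, d$coiler_score_pct[1], d$n_tracks[1],
                    d$frames_used[1])
            }),
        section("Candidate ranking",
            list.files(dir, "rank.*\\.csv$", full.names = TRUE),
            function(n, d) {
                if (!all(c("rank", "entity") %in% names(d))) {
                    warning("skipping malformed ", n,
                        ": unrecognized schema")
                    return(character())
                }
                c(sprintf("%s: top candidates", n),
                    sprintf("  %2d. %s (%.4g)", head(d$rank, 5),
                        head(d$entity, 5), head(d$score, 5)))
            }),
        section("RT-QuIC calls",
            list.files(dir, "calls.*\\.csv$", full.names = TRUE),
            function(n, d) {
                if (!all(c("sample", "positive") %in% names(d))) {
                    warning("skipping malformed ", n,
                        ": unrecognized schema")
                    return(character())
                }
                sprintf("%s: %d/%d samples positive", n,
                    sum(d$positive), nrow(d))
            }))
    writeLines(lines, path)
    invisible(path)
}
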