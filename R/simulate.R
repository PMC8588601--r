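#' Worm-recording simulation configuration
#'
#' Defaults follow the population-recording design the pipeline targets:
#' 10 adult animals per recording, 2 frames/s, a 1936 x 1456 px arena
#' (the recording area inside the chemorepellent ring), and a nominal
#' adult silhouette of 100 x 10 px.
#'
#' @param nWorms worms per recording (default 10).
#' @param nFrames frames to simulate.
#' @param fps frames per second (2 or 10 in the source design; any
#'   positive value accepted).
#' @param arena c(width, height) in px (default 1936 x 1456).
#' @param wormLength,wormWidth body dimensions in px (length > width).
#' @param coilProb per-frame probability a worm is coiled.
#' @param turnProb per-frame probability of an omega turn.
#' @param meanSpeed crawling speed in px/s (default 20).
#' @param headingSd per-frame heading noise, radians (default 0.3).
#' @param dwell mean posture holding time in frames (geometric; default
#'   1 = independent per-frame draws).
#' @param noiseSd Gaussian pixel noise SD on rendered frames (default
#'   0.02; worms are rendered at intensity 0.2 on a 0.9 background).
#' @param seed RNG seed.
#' @return validated list of class \code{wormSimConfig}.
#' @export
wormSimConfig <- function(nWorms = 10, nFrames = 120, fps = 2,
        arena = c(1936, 1456), wormLength = 100, wormWidth = 10,
        coilProb = 0.02, turnProb = 0.05, meanSpeed = 20,
        headingSd = 0.3, dwell = 1, noiseSd = 0.02, seed = 1) {
    checkScalar(nWorms, "nWorms"); checkScalar(nFrames, "nFrames")
    checkScalar(fps, "fps"); checkScalar(wormLength, "wormLength")
    checkScalar(wormWidth, "wormWidth")
    checkScalar(meanSpeed, "meanSpeed", positive = FALSE)
    if (length(arena) != 2 || any(arena <= 0))
        stop("arena must be c(width, height) in px")
    if (coilProb < 0 || turnProb < 0 || coilProb + turnProb > 1)
        stop("need coilProb, turnProb >= 0 and coilProb + turnProb <= 1")
    if (wormLength <= wormWidth)
        stop("wormLength must exceed wormWidth")
    if (dwell < 1) stop("dwell must be >= 1 frame")
    structure(list(nWorms = as.integer(nWorms),
        nFrames = as.integer(nFrames), fps = fps, arena = arena,
        wormLength = wormLength, wormWidth = wormWidth,
        coilProb = coilProb, turnProb = turnProb, meanSpeed = meanSpeed,
        headingSd = headingSd, dwell = dwell, noiseSd = noiseSd,
        seed = seed), class = "wormSimConfig")
}

# Posture-specific midline in local coordinates (before heading rotation),
# re-centred so the point centroid sits at the origin. Arc-length step ds.
wormMidline <- function(posture, L, W, phase, ds) {
    if (posture == "sinusoidal") {
        amp <- L / 12
        u <- seq(0, 1.4 * L, by = ds)
        y <- amp * sin(2 * pi * 2 * u / L + phase)
        arc <- c(0, cumsum(sqrt(diff(u)^2 + diff(y)^2)))
        keep <- arc <= L
        pts <- cbind(u[keep], y[keep])
    } else if (posture == "turn") {
        # omega: 70% of the body as a closed-ish loop, tail tangent
        fLoop <- 0.7
        r <- fLoop * L / (2 * pi)
        s <- seq(0, L, by = ds)
        loop <- s <= fLoop * L
        phi <- s[loop] / r
        pts <- cbind(r * sin(phi), r - r * cos(phi))
        phiEnd <- fLoop * L / r
        tangent <- c(cos(phiEnd), sin(phiEnd))
        tail_s <- s[!loop] - fLoop * L
        if (length(tail_s))
            pts <- rbind(pts, cbind(
                pts[nrow(pts), 1] + tangent[1] * tail_s,
                pts[nrow(pts), 2] + tangent[2] * tail_s))
    } else {  # coil: slightly over-wrapped closed loop
        wrap <- 1.1
        r <- L / (2 * pi * wrap)
        phi <- seq(0, L, by = ds) / r
        pts <- cbind(r * sin(phi), r - r * cos(phi))
    }
    sweep(pts, 2, colMeans(pts))
}

# Trajectory + posture sampling for a whole recording; no rendering.
# Returns per-frame-per-worm positions, headings, phases, postures.
simulateWormStates <- function(config) {
    nW <- config$nWorms; nF <- config$nFrames
    L <- config$wormLength
    margin <- L / 2 + config$wormWidth
    lim <- config$arena - margin
    if (any(lim <= margin))
        stop("arena too small for wormLength")
    # non-overlapping initial placement, bounded retries
    pos0 <- matrix(NA_real_, nW, 2)
    for (w in seq_len(nW)) {
        ok <- FALSE
        for (try in 1:200) {
            p <- c(runif(1, margin, lim[1]), runif(1, margin, lim[2]))
            if (w == 1 || all(sqrt(rowSums(sweep(pos0[seq_len(w - 1), ,
                drop = FALSE], 2, p)^2)) > L)) {
                pos0[w, ] <- p; ok <- TRUE; break
            }
        }
        if (!ok) stop("could not place worms without overlap ",
            "(arena too crowded)")
    }
    heading <- matrix(0, nF, nW); posx <- matrix(0, nF, nW)
    posy <- matrix(0, nF, nW); phase <- matrix(0, nF, nW)
    posture <- matrix("sinusoidal", nF, nW)
    step <- config$meanSpeed / config$fps
    h <- runif(nW, 0, 2 * pi)
    ph <- runif(nW, 0, 2 * pi)
    p <- pos0
    pc <- config$coilProb; pt <- config$turnProb
    hold <- integer(nW); state <- rep("sinusoidal", nW)
    for (f in seq_len(nF)) {
        h <- h + rnorm(nW, 0, config$headingSd)
        p <- p + step * cbind(cos(h), sin(h))
        # reflecting boundary (chemorepellent ring)
        for (d in 1:2) {
            low <- p[, d] < margin; hi <- p[, d] > lim[d]
            p[low, d] <- 2 * margin - p[low, d]
            p[hi, d] <- 2 * lim[d] - p[hi, d]
            h[low | hi] <- if (d == 1) pi - h[low | hi] else -h[low | hi]
        }
        # mutual avoidance: worms closer than one body length are
        # pushed apart and deflect away, so silhouettes stay disjoint
        # as in the non-overlapping placement rule
        if (nW > 1) {
            for (rep_ in 1:2) {
                dx <- outer(p[, 1], p[, 1], "-")
                dy <- outer(p[, 2], p[, 2], "-")
                dd <- sqrt(dx^2 + dy^2)
                close_ <- which(dd < L & upper.tri(dd), arr.ind = TRUE)
                if (!nrow(close_)) break
                for (k in seq_len(nrow(close_))) {
                    i <- close_[k, 2]; j <- close_[k, 1]
                    v <- p[i, ] - p[j, ]
                    d0 <- sqrt(sum(v^2))
                    u <- if (d0 > 1e-9) v / d0 else
                        c(cos(h[i]), sin(h[i]))
                    shift <- (L - d0) / 2 + 0.5
                    p[i, ] <- pmin(pmax(p[i, ] + u * shift, margin), lim)
                    p[j, ] <- pmin(pmax(p[j, ] - u * shift, margin), lim)
                    h[i] <- atan2(u[2], u[1])
                    h[j] <- atan2(-u[2], -u[1])
                }
            }
        }
        ph <- ph + pi / 3
        redraw <- hold <= 0L
        if (any(redraw)) {
            u <- runif(sum(redraw))
            state[redraw] <- ifelse(u < pc, "coil",
                ifelse(u < pc + pt, "turn", "sinusoidal"))
            hold[redraw] <- if (config$dwell > 1)
                stats::rgeom(sum(redraw), 1 / config$dwell) + 1L else 1L
        }
        hold <- hold - 1L
        posture[f, ] <- state
        heading[f, ] <- h; posx[f, ] <- p[, 1]; posy[f, ] <- p[, 2]
        phase[f, ] <- ph
    }
    list(posx = posx, posy = posy, heading = heading, phase = phase,
        posture = posture)
}

# Render frame f of a simulated state: dark worms (0.2) on a light
# background (0.9) plus Gaussian pixel noise.
# Midlines are cached per posture (turn/coil are phase-independent;
# sinusoidal phase is quantized to 2*pi/64, well below rendering
# resolution) to keep per-frame cost down.
cachedMidline <- function(cache, posture, L, W, phase, ds) {
    if (is.null(cache))
        return(wormMidline(posture, L, W, phase, ds))
    key <- if (posture == "sinusoidal")
        sprintf("s%d", as.integer((phase %% (2 * pi)) * 64 / (2 * pi)))
        else posture
    pts <- cache[[key]]
    if (is.null(pts)) {
        phq <- if (posture == "sinusoidal")
            floor((phase %% (2 * pi)) * 64 / (2 * pi)) * 2 * pi / 64
            else phase
        pts <- wormMidline(posture, L, W, phq, ds)
        assign(key, pts, envir = cache)
    }
    pts
}

renderWormFrame <- function(states, f, config, discOffsets,
        cache = NULL) {
    wpx <- config$arena[1]; hpx <- config$arena[2]
    ds <- max(0.5, config$wormWidth / 4)
    nOff <- nrow(discOffsets)
    allx <- vector("list", config$nWorms)
    ally <- vector("list", config$nWorms)
    for (w in seq_len(config$nWorms)) {
        pts <- cachedMidline(cache, states$posture[f, w],
            config$wormLength, config$wormWidth, states$phase[f, w],
            ds)
        a <- states$heading[f, w]
        cx <- round(pts[, 1] * cos(a) - pts[, 2] * sin(a) +
            states$posx[f, w]) + 1L
        cy <- round(pts[, 1] * sin(a) + pts[, 2] * cos(a) +
            states$posy[f, w]) + 1L
        allx[[w]] <- rep(cx, each = nOff) + discOffsets[, 1]
        ally[[w]] <- rep(cy, each = nOff) + discOffsets[, 2]
    }
    .renderFrameCpp(hpx, wpx, 0.9, 0.2, config$noiseSd,
        as.integer(unlist(allx, use.names = FALSE)),
        as.integer(unlist(ally, use.names = FALSE)))
}

discMask <- function(radius) {
    r <- max(1L, ceiling(radius))
    g <- expand.grid(dx = -r:r, dy = -r:r)
    as.matrix(g[g$dx^2 + g$dy^2 <= radius^2, , drop = FALSE])
}

statesToTruth <- function(states, config) {
    nF <- config$nFrames; nW <- config$nWorms
    data.frame(frame = rep(seq_len(nF) - 1L, nW),
        worm_id = rep(seq_len(nW), each = nF),
        posture = as.vector(states$posture),
        x = as.vector(states$posx), y = as.vector(states$posy))
}

#' Simulate a multi-worm recording with ground truth
#'
#' Renders each worm as a filled band of width \code{wormWidth} around a
#' posture-specific midline: an undulating open curve (sinusoidal), a
#' horseshoe with a tangent tail (omega turn), or a slightly over-wrapped
#' closed loop (coil). The rendered regimes reproduce the circularity
#' bands of real recordings (~0.2 sinusoidal, ~0.5 turn, > 0.6 coil).
#' Worms advance at \code{meanSpeed} with heading noise and reflect at
#' the arena edge; worms closer than one body length deflect away from
#' each other, so silhouettes stay disjoint (as with the
#' non-overlapping initial placement); posture is drawn per frame per
#' worm from (coilProb, turnProb), optionally with geometric dwell.
#'
#' @param config a \code{\link{wormSimConfig}}.
#' @return a \linkS4class{WormRecording} (frame stack + ground truth).
#' @examples
#' rec <- simulateWormRecording(wormSimConfig(nWorms = 2, nFrames = 4,
#'     arena = c(300, 300), wormLength = 50, wormWidth = 6, seed = 7))
#' trueCoilFraction(rec)
#' @export
simulateWormRecording <- function(config) {
    stopifnot(inherits(config, "wormSimConfig"))
    withSeed(config$seed, {
        states <- simulateWormStates(config)
        offs <- discMask(config$wormWidth / 2)
        cache <- new.env(parent = emptyenv())
        frames <- lapply(seq_len(config$nFrames), function(f)
            renderWormFrame(states, f, config, offs, cache))
        new("WormRecording",
            stack = FrameStack(frames, fps = config$fps),
            truth = statesToTruth(states, config),
            config = unclass(config))
    })
}

#' Simulate a recording and segment it frame by frame
#'
#' Streaming variant of \code{\link{simulateWormRecording}} +
#' \code{\link{segmentStack}} that never holds the full frame stack in
#' memory -- intended for long parameter-recovery runs. Results are
#' identical to rendering the full stack and segmenting it.
#'
#' @param config a \code{\link{wormSimConfig}}.
#' @param seg a \code{\link{segConfig}}; defaults derive the area filter
#'   from the configured worm geometry.
#' @param coilThreshold coiling cut-off (default 0.6).
#' @return list: \code{detections} (as from \code{\link{segmentStack}})
#'   and \code{truth} (ground-truth data.frame).
#' @export
simulateAndSegment <- function(config, seg = NULL, coilThreshold = 0.6) {
    stopifnot(inherits(config, "wormSimConfig"))
    seg <- seg %||% segConfig(wormLength = config$wormLength,
        wormWidth = config$wormWidth,
        input = if (config$noiseSd > 0) "gray" else "auto")
    withSeed(config$seed, {
        states <- simulateWormStates(config)
        offs <- discMask(config$wormWidth / 2)
        cache <- new.env(parent = emptyenv())
        res <- vector("list", config$nFrames)
        dropped <- 0L
        for (f in seq_len(config$nFrames)) {
            img <- renderWormFrame(states, f, config, offs, cache)
            core <- segmentCore(img, seg)
            dropped <- dropped + core$nDropped
            if (length(core$object_id)) {
                core$nDropped <- NULL
                core$frame <- rep(f - 1L, length(core$object_id))
                res[[f]] <- core
            }
        }
        res <- res[!vapply(res, is.null, logical(1))]
        cols <- c("frame", "object_id", "area_px2", "perimeter_px",
            "circularity", "x", "y")
        out <- if (length(res)) {
            as.data.frame(lapply(stats::setNames(cols, cols),
                function(cn) unlist(lapply(res, `[[`, cn),
                    use.names = FALSE)))
        } else {
            data.frame(frame = integer(), object_id = integer(),
                area_px2 = numeric(), perimeter_px = numeric(),
                circularity = numeric(), x = numeric(), y = numeric())
        }
        out$posture <- if (nrow(out))
            classifyPosture(out$circularity, coilThreshold) else
            character()
        attr(out, "framesDropped") <- dropped
        attr(out, "nFramesTotal") <- config$nFrames
        list(detections = out, truth = statesToTruth(states, config))
    })
}

#' Ground-truth coil fraction
#'
#' @param x a \linkS4class{WormRecording} or a ground-truth data.frame
#'   with a posture column.
#' @return proportion of worm-frames in the coil posture.
#' @export
trueCoilFraction <- function(x) {
    truth <- if (is(x, "WormRecording")) x@truth else x
    mean(truth$posture == "coil")
}

#' Corpus simulation configuration
#'
#' Emulates the known/candidate design of a literature-ranking screen:
#' known entities and a planted subset of candidates draw tokens from a
#' shared topic distribution mixed into a background distribution at
#' weight \code{topicSeparation}; all other candidates draw from the
#' background alone. Default scale mirrors a screen of 15 known
#' molecules against 620 candidate compounds.
#'
#' @param nKnown known entities (default 15).
#' @param nCandidates candidate entities (default 620).
#' @param docsPerEntity documents per entity (default 5).
#' @param vocabSize vocabulary size (>= 10; default 1000). The topic
#'   occupies the first tenth of the vocabulary.
#' @param topicSeparation mixing weight in [0, 1] of the shared topic
#'   for known/planted entities (0 = indistinguishable from background).
#' @param nPlantedPositives candidates sharing the known topic (their
#'   entity ids carry the prefix \code{"candP_"}).
#' @param docLength tokens per document (default 100).
#' @param seed RNG seed.
#' @return validated list of class \code{corpusSimConfig}.
#' @export
corpusSimConfig <- function(nKnown = 15, nCandidates = 620,
        docsPerEntity = 5, vocabSize = 1000, topicSeparation = 0.7,
        nPlantedPositives = 25, docLength = 100, seed = 1) {
    checkScalar(nKnown, "nKnown"); checkScalar(nCandidates, "nCandidates")
    checkScalar(docsPerEntity, "docsPerEntity")
    checkScalar(docLength, "docLength")
    if (vocabSize < 10) stop("vocabSize must be >= 10")
    if (topicSeparation < 0 || topicSeparation > 1)
        stop("topicSeparation must lie in [0, 1]")
    if (nPlantedPositives > nCandidates)
        stop("nPlantedPositives must be <= nCandidates")
    structure(list(nKnown = as.integer(nKnown),
        nCandidates = as.integer(nCandidates),
        docsPerEntity = as.integer(docsPerEntity),
        vocabSize = as.integer(vocabSize),
        topicSeparation = topicSeparation,
        nPlantedPositives = as.integer(nPlantedPositives),
        docLength = as.integer(docLength), seed = seed),
        class = "corpusSimConfig")
}

#' Simulate a topic-structured corpus
#'
#' @param config a \code{\link{corpusSimConfig}}.
#' @return a \linkS4class{Corpus}; entities named \code{known_*},
#'   \code{candP_*} (planted positives) and \code{cand_*}.
#' @examples
#' simulateCorpus(corpusSimConfig(nKnown = 3, nCandidates = 6,
#'     docsPerEntity = 2, vocabSize = 50, nPlantedPositives = 1,
#'     seed = 2))
#' @export
simulateCorpus <- function(config) {
    stopifnot(inherits(config, "corpusSimConfig"))
    withSeed(config$seed, {
        V <- config$vocabSize
        terms <- sprintf("w%05d", seq_len(V))
        topicSize <- max(10L, V %/% 10L)
        topicP <- c(rep(1 / topicSize, topicSize), rep(0, V - topicSize))
        bgP <- rep(1 / V, V)
        mix <- config$topicSeparation * topicP +
            (1 - config$topicSeparation) * bgP
        entities <- c(sprintf("known_%02d", seq_len(config$nKnown)),
            if (config$nPlantedPositives > 0)
                sprintf("candP_%02d", seq_len(config$nPlantedPositives)),
            if (config$nCandidates > config$nPlantedPositives)
                sprintf("cand_%03d", seq_len(
                    config$nCandidates - config$nPlantedPositives)))
        roles <- c(rep("known", config$nKnown),
            rep("candidate", config$nCandidates))
        onTopic <- grepl("^known_|^candP_", entities)
        docs <- lapply(seq_along(entities), function(i) {
            p <- if (onTopic[i]) mix else bgP
            vapply(seq_len(config$docsPerEntity), function(j)
                paste(sample(terms, config$docLength, replace = TRUE,
                    prob = p), collapse = " "), character(1))
        })
        Corpus(data.frame(
            doc_id = sprintf("d%05d", seq_len(
                length(entities) * config$docsPerEntity)),
            entity = rep(entities, each = config$docsPerEntity),
            role = rep(roles, each = config$docsPerEntity),
            text = unlist(docs), stringsAsFactors = FALSE))
    })
}

#' RT-QuIC plate simulation configuration
#'
#' Flat Gaussian background wells and sigmoidal (logistic) seeded wells
#' read every \code{readInterval} minutes for \code{duration} hours.
#' Default background statistics (mean 1200, SD 400 rfu) put the
#' mean-plus-5-SD threshold near 3200 rfu.
#'
#' @param nSamplesPerGroup samples per group; a named vector defines the
#'   groups (e.g. \code{c(vehicle = 7, treated = 8)}).
#' @param replicatesPerSample replicate wells per sample (default 4).
#' @param nBackgroundWells diluent wells (default 8).
#' @param backgroundMean,backgroundSd background rfu model.
#' @param seededAmplitude plateau rfu gain of seeded reactions (default
#'   30000).
#' @param lagTime seeding lag in hours before the rise (default 20).
#' @param riseRate logistic rate in 1/h (default 0.5).
#' @param readInterval minutes between reads (default 45).
#' @param duration total assay time in hours (default 60).
#' @param fracSeeded per-group proportion of truly seeding samples
#'   (recycled across groups; the first \code{round(frac * n)} samples
#'   of each group seed).
#' @param seed RNG seed.
#' @return validated list of class \code{rtquicSimConfig}.
#' @export
rtquicSimConfig <- function(nSamplesPerGroup = 8,
        replicatesPerSample = 4, nBackgroundWells = 8,
        backgroundMean = 1200, backgroundSd = 400,
        seededAmplitude = 30000, lagTime = 20, riseRate = 0.5,
        readInterval = 45, duration = 60, fracSeeded = 1, seed = 1) {
    if (any(nSamplesPerGroup < 1)) stop("need >= 1 sample per group")
    if (replicatesPerSample < 1) stop("replicatesPerSample must be >= 1")
    if (nBackgroundWells < 2) stop("need >= 2 background wells")
    if (backgroundSd < 0) stop("backgroundSd must be >= 0")
    if (duration <= 0 || readInterval <= 0)
        stop("duration and readInterval must be positive")
    if (any(fracSeeded < 0) || any(fracSeeded > 1))
        stop("fracSeeded must lie in [0, 1]")
    structure(list(nSamplesPerGroup = nSamplesPerGroup,
        replicatesPerSample = as.integer(replicatesPerSample),
        nBackgroundWells = as.integer(nBackgroundWells),
        backgroundMean = backgroundMean, backgroundSd = backgroundSd,
        seededAmplitude = seededAmplitude, lagTime = lagTime,
        riseRate = riseRate, readInterval = readInterval,
        duration = duration, fracSeeded = fracSeeded, seed = seed),
        class = "rtquicSimConfig")
}

#' Simulate an RT-QuIC plate
#'
#' @param config an \code{\link{rtquicSimConfig}}.
#' @return an \linkS4class{RtQuicPlate}.
#' @examples
#' plate <- simulateRtQuicPlate(rtquicSimConfig(
#'     nSamplesPerGroup = c(vehicle = 7, treated = 8),
#'     fracSeeded = c(4 / 7, 0), seed = 3))
#' sampleCalls(rtquicCall(plate))
#' @export
simulateRtQuicPlate <- function(config) {
    stopifnot(inherits(config, "rtquicSimConfig"))
    withSeed(config$seed, {
        times <- seq(0, config$duration, by = config$readInterval / 60)
        nT <- length(times)
        groups <- names(config$nSamplesPerGroup) %||%
            if (length(config$nSamplesPerGroup) == 1) "group1" else
                paste0("group", seq_along(config$nSamplesPerGroup))
        if (is.null(names(config$nSamplesPerGroup)))
            names(config$nSamplesPerGroup) <- groups
        frac <- rep(config$fracSeeded,
            length.out = length(config$nSamplesPerGroup))
        wellMap <- data.frame(sample = character(), replicate = integer(),
            is_background = logical(), group = character())
        rows <- list()
        bgNoise <- function(n) matrix(rnorm(n * nT, config$backgroundMean,
            config$backgroundSd), n, nT)
        # diluent wells
        rows$bg <- bgNoise(config$nBackgroundWells)
        wellMap <- rbind(wellMap, data.frame(sample = "diluent",
            replicate = seq_len(config$nBackgroundWells),
            is_background = TRUE, group = NA_character_))
        for (gi in seq_along(groups)) {
            n <- config$nSamplesPerGroup[gi]
            nSeed <- round(frac[gi] * n)
            for (si in seq_len(n)) {
                sname <- sprintf("%s_s%02d", groups[gi], si)
                m <- bgNoise(config$replicatesPerSample)
                if (si <= nSeed && config$seededAmplitude > 0) {
                    t50 <- config$lagTime + 3 / config$riseRate
                    for (ri in seq_len(config$replicatesPerSample)) {
                        amp <- config$seededAmplitude *
                            exp(rnorm(1, 0, 0.1))
                        m[ri, ] <- m[ri, ] + amp /
                            (1 + exp(-config$riseRate * (times - t50)))
                    }
                }
                rows[[sname]] <- m
                wellMap <- rbind(wellMap, data.frame(sample = sname,
                    replicate = seq_len(config$replicatesPerSample),
                    is_background = FALSE, group = groups[gi]))
            }
        }
        readings <- do.call(rbind, rows)
        rownames(readings) <- sprintf("W%03d", seq_len(nrow(readings)))
        RtQuicPlate(readings, times, wellMap)
    })
}
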