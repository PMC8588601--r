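test_that("worm-sim configuration validates its invariants", {
    expect_error(wormSimConfig(coilProb = 0.7, turnProb = 0.5),
        "coilProb")
    expect_error(wormSimConfig(coilProb = -0.1), "coilProb")
    expect_error(wormSimConfig(wormLength = 5, wormWidth = 6),
        "exceed")
    expect_error(wormSimConfig(fps = 0), "fps")
    expect_error(simulateWormRecording(wormSimConfig(nWorms = 1,
        nFrames = 1, arena = c(50, 50), wormLength = 60,
        wormWidth = 6)), "arena too small")
})

test_that("posture ground truth follows the configured probabilities", {
    # degenerate probabilities pin the posture
    cfg0 <- wormSimConfig(nWorms = 2, nFrames = 10, arena = c(300, 300),
        wormLength = 50, wormWidth = 6, coilProb = 0, turnProb = 0,
        seed = 1)
    expect_equal(trueCoilFraction(simulateWormRecording(cfg0)), 0)
    cfg1 <- wormSimConfig(nWorms = 2, nFrames = 10, arena = c(300, 300),
        wormLength = 50, wormWidth = 6, coilProb = 1, turnProb = 0,
        seed = 1)
    expect_equal(trueCoilFraction(simulateWormRecording(cfg1)), 1)
    # binomial sampling bound at coil_prob = 0.05 over 7200 draws
    cfg <- wormSimConfig(nWorms = 10, nFrames = 720,
        arena = c(1000, 800), wormLength = 60, wormWidth = 6,
        coilProb = 0.05, turnProb = 0, noiseSd = 0, seed = 77)
    states <- SynScreen:::withSeed(cfg$seed,
        SynScreen:::simulateWormStates(cfg))
    truth <- SynScreen:::statesToTruth(states, cfg)
    cf <- trueCoilFraction(truth)
    expect_lt(abs(cf - 0.05), 3 * sqrt(0.05 * 0.95 / 7200))
})

test_that("true coil fraction is an unbiased estimator of coil_prob", {
    fracs <- vapply(1:20, function(s) {
        cfg <- wormSimConfig(nWorms = 5, nFrames = 100,
            arena = c(400, 300), wormLength = 50, wormWidth = 6,
            coilProb = 0.1, turnProb = 0, seed = 300 + s)
        states <- SynScreen:::withSeed(cfg$seed,
            SynScreen:::simulateWormStates(cfg))
        trueCoilFraction(SynScreen:::statesToTruth(states, cfg))
    }, numeric(1))
    se <- sqrt(0.1 * 0.9 / (20 * 500))
    expect_lt(abs(mean(fracs) - 0.1), 3 * se)
})

test_that("same seed gives identical recordings, corpora and plates", {
    cfg <- wormSimConfig(nWorms = 3, nFrames = 4, arena = c(300, 250),
        wormLength = 50, wormWidth = 6, coilProb = 0.2, seed = 12)
    r1 <- simulateWormRecording(cfg)
    r2 <- simulateWormRecording(cfg)
    expect_identical(r1@stack@frames, r2@stack@frames)
    expect_identical(r1@truth, r2@truth)
    cc <- corpusSimConfig(nKnown = 3, nCandidates = 5,
        docsPerEntity = 2, vocabSize = 60, nPlantedPositives = 1,
        docLength = 30, seed = 8)
    expect_identical(corpusDocs(simulateCorpus(cc)),
        corpusDocs(simulateCorpus(cc)))
    rc <- rtquicSimConfig(nSamplesPerGroup = 3, seed = 4)
    expect_identical(
        SummarizedExperiment::assay(simulateRtQuicPlate(rc), "rfu"),
        SummarizedExperiment::assay(simulateRtQuicPlate(rc), "rfu"))
})

test_that("rendered postures land in their circularity bands", {
    # >= 100 random frames across postures
    seg <- segConfig(wormLength = 60, wormWidth = 6)
    vals <- list(sinusoidal = c(), turn = c(), coil = c())
    for (i in 1:36) {
        for (post in names(vals)) {
            cfg <- wormSimConfig(nWorms = 1, nFrames = 1,
                arena = c(250, 250), wormLength = 60, wormWidth = 6,
                coilProb = as.numeric(post == "coil"),
                turnProb = as.numeric(post == "turn"),
                seed = 5000 + i)
            d <- simulateAndSegment(cfg, seg)$detections
            if (nrow(d)) vals[[post]] <- c(vals[[post]],
                d$circularity[1])
        }
    }
    expect_gt(length(unlist(vals)), 100)
    expect_true(all(vals$sinusoidal < 0.4))
    expect_true(all(vals$coil > 0.6))
    expect_true(all(vals$turn > 0.4 & vals$turn <= 0.6))
})

test_that("corpus generator separates topics as configured", {
    # separation 1: known documents use only the topic block
    co1 <- simulateCorpus(corpusSimConfig(nKnown = 2, nCandidates = 3,
        docsPerEntity = 2, vocabSize = 100, topicSeparation = 1,
        nPlantedPositives = 1, docLength = 50, seed = 3))
    d <- corpusDocs(co1)
    topicTerms <- sprintf("w%05d", 1:10)
    knownToks <- unlist(strsplit(d$text[d$role == "known"], " "))
    expect_true(all(knownToks %in% topicTerms))
    # planted positives share the topic; plain candidates do not
    plantToks <- unlist(strsplit(d$text[grepl("^candP_", d$entity)],
        " "))
    expect_true(all(plantToks %in% topicTerms))
    plainToks <- unlist(strsplit(d$text[grepl("^cand_", d$entity)],
        " "))
    expect_gt(length(setdiff(plainToks, topicTerms)), 0)
    # separation 0: known and candidate term distributions coincide
    co0 <- simulateCorpus(corpusSimConfig(nKnown = 20,
        nCandidates = 20, docsPerEntity = 4, vocabSize = 50,
        topicSeparation = 0, nPlantedPositives = 0, docLength = 200,
        seed = 6))
    d0 <- corpusDocs(co0)
    fracTopic <- function(rows) {
        toks <- unlist(strsplit(d0$text[rows], " "))
        mean(toks %in% sprintf("w%05d", 1:10))
    }
    expect_lt(abs(fracTopic(d0$role == "known") -
        fracTopic(d0$role == "candidate")), 0.03)
})

test_that("plate generator: flat nulls, saturated seeded wells, exact zeros", {
    # amplitude 0: no well mean strays 5 SD above background
    pl <- simulateRtQuicPlate(rtquicSimConfig(nSamplesPerGroup = 8,
        seededAmplitude = 0, seed = 10))
    rfu <- SummarizedExperiment::assay(pl, "rfu")
    wellMeans <- rowMeans(rfu)
    expect_lt(max(wellMeans) - 1200, 5 * 400)
    # all seeded, huge amplitude: every sample has a positive replicate
    pl2 <- simulateRtQuicPlate(rtquicSimConfig(nSamplesPerGroup = 4,
        fracSeeded = 1, seededAmplitude = 50000, seed = 11))
    expect_true(all(sampleCalls(rtquicCall(pl2))$positive))
    # noiseless null: endpoints are exactly the background mean
    pl3 <- simulateRtQuicPlate(rtquicSimConfig(nSamplesPerGroup = 3,
        backgroundSd = 0, seededAmplitude = 0, seed = 12))
    expect_true(all(SummarizedExperiment::assay(pl3, "rfu") == 1200))
    # timing grid: every 45 min to 60 h
    expect_equal(plateTimes(pl3)[1:3], c(0, 0.75, 1.5))
    expect_equal(max(plateTimes(pl3)), 60)
})

test_that("streamed segmentation equals stack rendering + segmentation", {
    cfg <- wormSimConfig(nWorms = 3, nFrames = 6, arena = c(300, 250),
        wormLength = 50, wormWidth = 6, coilProb = 0.3, turnProb = 0.2,
        seed = 44)
    seg <- segConfig(wormLength = 50, wormWidth = 6, input = "gray")
    streamed <- simulateAndSegment(cfg, seg)
    rec <- simulateWormRecording(cfg)
    stacked <- segmentStack(rec@stack, seg)
    expect_equal(streamed$detections, stacked, ignore_attr = TRUE)
    expect_identical(streamed$truth, rec@truth)
})
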