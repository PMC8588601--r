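test_that("threshold is pooled background mean + 5 SD", {
    # two wells at constant 100 and 200 rfu: mean 150, SD 70.71...
    pl <- tinyPlate(bgReadings = c(100, 200), sampleEndpoints = 1000,
        times = 0.75)
    expect_equal(computeThreshold(pl), 150 + 5 * sd(c(100, 200)))
    # constant background: threshold equals the background level
    pl0 <- tinyPlate(c(120, 120, 120), 1000, times = 0.75)
    expect_equal(computeThreshold(pl0), 120)
    # per-timepoint mode returns one threshold per read
    pl2 <- tinyPlate(c(100, 200), 1000, times = c(0, 0.75))
    expect_length(computeThreshold(pl2, perTimepoint = TRUE), 2)
    # simulated plate with the default background model lands near 3200
    plate <- simulateRtQuicPlate(rtquicSimConfig(nSamplesPerGroup = 4,
        seededAmplitude = 0, seed = 5))
    expect_lt(abs(computeThreshold(plate) - 3200), 200)
})

test_that("replicate calls use the 60 h endpoint with a strict inequality", {
    pl <- tinyPlate(c(100, 100), c(150, 149.9999, 150.0001),
        times = c(30, 60))
    rc <- callReplicates(pl, threshold = 150)
    sm <- rc[!rc$is_background, ]
    expect_identical(sm$positive, c(FALSE, FALSE, TRUE))
    # flat background well is negative
    expect_true(all(!rc$positive[rc$is_background]))
    # reads after 60 h are ignored for the endpoint call
    pl2 <- tinyPlate(c(100, 100), 100, times = c(59.25, 60, 60.75))
    rfu <- SummarizedExperiment::assay(pl2, "rfu")
    rfu[3, ] <- c(100, 100, 9000)   # rises only after 60 h
    pl3 <- RtQuicPlate(rfu, plateTimes(pl2),
        as.data.frame(SummarizedExperiment::rowData(pl2)))
    rc3 <- callReplicates(pl3, threshold = 150, endpointH = 60)
    expect_false(rc3$positive[3])
})

test_that("sample rule: positive iff at least one replicate is positive", {
    mk <- function(reps) {
        pl <- tinyPlate(c(100, 100), reps, times = 0.75)
        callSamples(callReplicates(pl, threshold = 150))
    }
    expect_false(mk(c(100, 100, 100, 100))$positive)
    expect_true(mk(c(1000, 100, 100, 100))$positive)
    expect_identical(mk(c(1000, 100, 100, 100))$n_positive_replicates,
        1L)
})

test_that("group contingency reproduces the 4/7 vs 0/8 comparison", {
    plate <- simulateRtQuicPlate(rtquicSimConfig(
        nSamplesPerGroup = c(vehicle = 7, treated = 8),
        fracSeeded = c(4 / 7, 0), seed = 42))
    calls <- rtquicCall(plate)
    sc <- sampleCalls(calls)
    ct <- groupContingency(sc)
    expect_equal(sort(ct$table[, "positive"]), c(0, 4),
        ignore_attr = TRUE)
    expect_equal(ct$fisherP, 0.0256410256, tolerance = 1e-6)
})

test_that("mean curves average positive replicates for positive samples", {
    pl <- tinyPlate(c(100, 100), c(1000, 2000, 100, 100),
        times = c(0, 0.75))
    rc <- callReplicates(pl, threshold = 500)
    mc <- meanCurves(pl, rc)
    expect_equal(unname(mc["s1", ]), c(1500, 1500))
    # all-negative sample: mean of all (negative) replicates
    rcNeg <- callReplicates(pl, threshold = 5000)
    mcNeg <- meanCurves(pl, rcNeg)
    expect_equal(unname(mcNeg["s1", ]), rep(mean(c(1000, 2000, 100,
        100)), 2))
    # one positive replicate: the curve is that replicate
    pl1 <- tinyPlate(c(100, 100), c(1000, 100), times = c(0, 0.75))
    mc1 <- meanCurves(pl1, callReplicates(pl1, threshold = 500))
    expect_equal(unname(mc1["s1", ]), c(1000, 1000))
})

test_that("calls are invariant to well order and to a constant rfu shift", {
    plate <- simulateRtQuicPlate(rtquicSimConfig(nSamplesPerGroup = 5,
        fracSeeded = 0.6, seed = 9))
    calls <- rtquicCall(plate)
    # permute wells
    perm <- sample(nrow(plate))
    rfu <- SummarizedExperiment::assay(plate, "rfu")[perm, ]
    rd <- as.data.frame(SummarizedExperiment::rowData(plate))[perm, ]
    plPerm <- RtQuicPlate(rfu, plateTimes(plate), rd)
    scPerm <- sampleCalls(rtquicCall(plPerm))
    sc <- sampleCalls(calls)
    expect_equal(scPerm[order(scPerm$sample), "positive"],
        sc[order(sc$sample), "positive"])
    # shift every reading (and hence the background) by a constant
    plShift <- RtQuicPlate(
        SummarizedExperiment::assay(plate, "rfu") + 500,
        plateTimes(plate),
        as.data.frame(SummarizedExperiment::rowData(plate)))
    callsShift <- rtquicCall(plShift)
    expect_equal(callsShift@threshold, calls@threshold + 500)
    expect_identical(sampleCalls(callsShift)$positive,
        sc$positive)
})

test_that("plate validity: increasing times, >= 2 background wells, equal replicates", {
    expect_error(tinyPlate(c(100, 100), 100, times = c(1, 1)),
        "increasing")
    expect_error(RtQuicPlate(matrix(100, 2, 1), 0,
        data.frame(sample = c("diluent", "s1"), replicate = c(1, 1),
            is_background = c(TRUE, FALSE))), "background")
})
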