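test_that("circularity closed forms: circle, square, elongated rectangle", {
    r <- 7.3
    expect_identical(circularity(pi * r^2, 2 * pi * r), 1)
    expect_equal(circularity(4, 8), pi / 4)
    expect_equal(circularity(10, 22), 40 * pi / 484)
    expect_error(circularity(-1, 5), "positive")
    expect_error(circularity(5, 0), "positive")
})

test_that("continuous circularity is scale-invariant and monotone in aspect ratio", {
    # dilation (A, P) -> (k^2 A, k P) leaves the value unchanged
    for (k in c(0.5, 2, 7)) {
        expect_equal(circularity(3 * k^2, 8 * k), circularity(3, 8))
    }
    # rectangles of fixed area, growing aspect ratio: strictly decreasing
    area <- 36
    sides <- c(6, 9, 12, 18, 36)
    circ <- vapply(sides, function(w)
        circularity(area, 2 * (w + area / w)), numeric(1))
    expect_true(all(diff(circ) < 0))
})

test_that("posture classification bands and strict coil inequality", {
    expect_identical(classifyPosture(0.2), "sinusoidal")
    expect_identical(classifyPosture(0.5), "turn")
    expect_identical(classifyPosture(0.61), "coil")
    expect_identical(classifyPosture(0.6), "turn")   # not coil at 0.6
    expect_identical(classifyPosture(0.4), "sinusoidal")
    expect_error(classifyPosture(0), "0, 1")
    expect_error(classifyPosture(1.2), "0, 1")
})

test_that("Crofton perimeter is accurate on rasterized discs", {
    # frozen agreement with an independent implementation
    expect_equal(croftonPerimeter(discMatrix(15)), 96.45567771584422,
        tolerance = 1e-9)
    expect_equal(croftonPerimeter(discMatrix(30)), 190.22983837035395,
        tolerance = 1e-9)
    # discs of radius >= 15 px give circularity in [0.95, 1]
    for (r in c(15, 20, 30, 45)) {
        m <- discMatrix(r)
        circ <- circularity(sum(m), croftonPerimeter(m))
        expect_gte(circ, 0.95)
        expect_lte(circ, 1)
    }
})

test_that("discrete circularity is scale-invariant within 2% across dilations", {
    # base disc inside the estimator's accuracy regime (raster bias
    # ~0.65/r, so the 1x-4x spread stays under 2% from r = 30 up)
    base <- circularity(sum(discMatrix(30)),
        croftonPerimeter(discMatrix(30)))
    for (k in 2:4) {
        m <- discMatrix(30 * k)
        circ <- circularity(sum(m), croftonPerimeter(m))
        expect_lt(abs(circ - base) / base, 0.02)
    }
})

test_that("outer-contour convention: the hole of an annulus is excluded from P", {
    # annulus: disc radius 20 minus disc radius 12
    outer_ <- discMatrix(20)
    inner <- discMatrix(12, pad = 5 + 8)
    ann <- outer_ - inner
    pOuter <- croftonPerimeter(discMatrix(20))
    expect_equal(croftonPerimeter(ann, fillHoles = TRUE), pOuter,
        tolerance = 1e-9)
    # without filling, both contours count
    expect_gt(croftonPerimeter(ann, fillHoles = FALSE), 1.4 * pOuter)
})

test_that("segmentFrame finds worms, drops oversized blobs, handles empties", {
    expect_identical(nrow(segmentFrame(matrix(0.9, 40, 40))), 0L)
    expect_error(segmentFrame(array(0, c(3, 3, 3))), "2-D")
    # one rendered worm -> exactly one detection with sane metrics
    cfg <- wormSimConfig(nWorms = 1, nFrames = 1, arena = c(200, 200),
        wormLength = 60, wormWidth = 6, coilProb = 0, turnProb = 0,
        seed = 13)
    img <- getFrame(simulateWormRecording(cfg)@stack, 1)
    det <- segmentFrame(img, segConfig(wormLength = 60, wormWidth = 6))
    expect_identical(nrow(det), 1L)
    expect_gt(det$area_px2, 100)
    expect_lt(det$circularity, 0.4)
    # an oversized blob is treated as a collision and dropped
    big <- matrix(0.9, 120, 120)
    big[20:100, 20:100] <- 0.2
    det2 <- segmentFrame(big, segConfig(minArea = 10, maxArea = 500,
        input = "gray"))
    expect_identical(nrow(det2), 0L)
    expect_identical(attr(det2, "nDroppedOversize"), 1L)
})

test_that("binary masks are segmented with the foreground = 1 convention", {
    m <- matrix(0, 60, 60)
    m[20:40, 25:35] <- 1
    det <- segmentFrame(m, segConfig(minArea = 10, maxArea = 1e4))
    expect_identical(nrow(det), 1L)
    expect_equal(det$area_px2, 21 * 11)
    expect_equal(det$x, 29)   # 0-based column centroid
    expect_equal(det$y, 29)
})

test_that("own Otsu threshold agrees with EBImage on bimodal frames", {
    set.seed(2)
    img <- matrix(c(stats::rnorm(4000, 0.25, 0.04),
        stats::rnorm(8000, 0.8, 0.05)), 120, 100)
    img[img < 0] <- 0; img[img > 1] <- 1
    own <- otsuThreshold(img)
    ref <- EBImage::otsu(EBImage::Image(img), range = c(0, 1),
        levels = 256)
    expect_lt(abs(own - ref), 0.01)
    expect_gt(own, 0.3); expect_lt(own, 0.75)
})

test_that("segmentStack classifies posture per detection and keeps bookkeeping", {
    cfg <- wormSimConfig(nWorms = 2, nFrames = 5, arena = c(300, 250),
        wormLength = 60, wormWidth = 6, coilProb = 1, turnProb = 0,
        seed = 19)
    rec <- simulateWormRecording(cfg)
    det <- segmentStack(rec@stack, segConfig(wormLength = 60,
        wormWidth = 6))
    expect_true(all(det$posture == "coil"))
    expect_identical(attr(det, "nFramesTotal"), 5L)
    expect_true(all(det$circularity > 0.6))
})
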