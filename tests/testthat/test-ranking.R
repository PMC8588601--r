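test_that("vocabulary: top-K by count with lexicographic tie-break", {
    co <- Corpus(data.frame(doc_id = c("d1", "d2"),
        entity = c("e1", "e2"), role = c("known", "candidate"),
        text = c("c c b b a", "c z"), stringsAsFactors = FALSE))
    v <- buildVocabulary(co, K = 2)
    expect_identical(v$term, c("c", "b"))
    expect_identical(v$df, c(2L, 1L))
    # ties broken lexicographically: a and z both count 1
    v4 <- buildVocabulary(co, K = 4)
    expect_identical(v4$term, c("c", "b", "a", "z"))
    # K beyond the distinct terms keeps everything
    expect_identical(nrow(buildVocabulary(co, K = 100)), 4L)
    expect_error(buildVocabulary(co, K = 0), "K")
})

test_that("TF-IDF weights match the stated formula by hand", {
    co <- tinyCorpus()   # d1 = "a a b", d2 = "b"
    v <- buildVocabulary(co, 10)
    M <- tfidfVectors(co, v)
    expect_equal(M["d1", "a"], (2 / 3) * log(3 / 2))
    # a term present in every document has idf = ln((1+N)/(1+N)) = 0
    expect_equal(M["d1", "b"], 0)
    expect_equal(M["d2", "b"], 0)
    # out-of-vocabulary-only documents give zero vectors, with warning
    co2 <- Corpus(data.frame(doc_id = c("d1", "d2", "d3"),
        entity = c("e1", "e2", "e3"),
        role = c("known", "candidate", "candidate"),
        text = c("a a b", "b", ""), stringsAsFactors = FALSE))
    expect_warning(M2 <- tfidfVectors(co2, buildVocabulary(co2, 10)),
        "empty")
    expect_true(all(M2["d3", ] == 0))
})

test_that("entity centroids are arithmetic means of document vectors", {
    co <- Corpus(data.frame(doc_id = paste0("d", 1:3),
        entity = c("e1", "e2", "e2"),
        role = c("known", "candidate", "candidate"),
        text = c("a b", "a a", "b b"), stringsAsFactors = FALSE))
    M <- tfidfVectors(co, buildVocabulary(co, 10))
    cen <- entityCentroids(M, co)
    expect_equal(cen["e1", ], M["d1", ])
    expect_equal(cen["e2", ], (M["d2", ] + M["d3", ]) / 2)
    # symmetric toy vectors: mean of unit axes
    cen2 <- entityCentroids(
        matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE,
            dimnames = list(c("da", "db"), c("t1", "t2"))),
        Corpus(data.frame(doc_id = c("da", "db"),
            entity = c("e", "e"), role = c("known", "known"),
            text = c("x", "x"), stringsAsFactors = FALSE)))
    expect_equal(unname(cen2["e", ]), c(0.5, 0.5))
})

test_that("cosine similarity graph: identical, orthogonal, zero centroids", {
    cen <- rbind(a = c(2, 2, 0), b = c(1, 1, 0), c = c(0, 0, 3),
        z = c(0, 0, 0))
    g <- similarityGraph(cen)
    expect_equal(g$S["a", "b"], 1)
    expect_equal(g$S["a", "c"], 0)
    expect_equal(g$S["a", "a"], 1)
    expect_equal(g$S["z", "z"], 0)     # zero centroid: diagonal 0
    expect_true(all(g$S["z", ] == 0))
    expect_equal(similarityGraph(rbind(x = c(1, 1, 0),
        y = c(1, 0, 0)))$S["x", "y"], 1 / sqrt(2))
    expect_true(isSymmetric(g$S))
    expect_error(similarityGraph(cen[1, , drop = FALSE]), "2 entities")
})

test_that("diffusion ranking: fixed points, conservation, monotone candidates", {
    cen <- rbind(k1 = c(1, 0, 0, 1), k2 = c(0.9, 0.1, 0, 1),
        cGood = c(1, 0, 0, 1), cBad = c(0, 1, 1, 0))
    g <- similarityGraph(cen)
    rl <- diffusionRank(g, c("k1", "k2"))
    expect_equal(sum(diffusionScores(rl)), 1, tolerance = 1e-9)
    expect_true(all(diffusionScores(rl) >= 0))
    # the candidate identical to a known outranks the dissimilar one
    rk <- candidateRanking(rl)
    expect_identical(rk$entity[1], "cGood")
    # alpha = 1 reproduces the seed distribution exactly
    rl1 <- diffusionRank(g, c("k1", "k2"), alpha = 1)
    expect_equal(unname(diffusionScores(rl1)[c("k1", "k2")]),
        c(0.5, 0.5))
    expect_equal(unname(diffusionScores(rl1)[c("cGood", "cBad")]),
        c(0, 0))
    # a single candidate is rank 1 whatever its score
    rlOne <- diffusionRank(similarityGraph(cen[c(1, 4), ]), "k1")
    expect_identical(candidateRanking(rlOne)$rank, 1L)
    expect_error(diffusionRank(g, character()), "nonempty")
    expect_error(diffusionRank(g, "nope"), "absent")
})

test_that("iterative RWR agrees with the direct linear solve on random graphs", {
    set.seed(14)
    for (n in c(5, 20, 50)) {
        C <- matrix(stats::runif(n * 30), n)
        rownames(C) <- paste0("e", seq_len(n))
        g <- similarityGraph(C)
        known <- paste0("e", 1:3)
        it <- diffusionScores(diffusionRank(g, known, tol = 1e-12))
        ds <- SynScreen:::diffusionSolve(g, known)
        expect_lt(max(abs(it - ds)), 1e-8)
        expect_equal(sum(it), 1, tolerance = 1e-9)
    }
})

test_that("raising a candidate's similarity to the knowns never lowers its rank", {
    set.seed(23)
    base <- matrix(stats::runif(6 * 8, 0.1, 0.9), 6)
    rownames(base) <- c("k1", "k2", "c1", "c2", "c3", "c4")
    g0 <- similarityGraph(base)
    rank0 <- candidateRanking(diffusionRank(g0, c("k1", "k2")))
    pos0 <- match("c2", rank0$entity)
    # move c2 toward the known centroids stepwise
    for (lam in c(0.3, 0.7, 1)) {
        C <- base
        C["c2", ] <- (1 - lam) * base["c2", ] +
            lam * colMeans(base[1:2, ])
        rk <- candidateRanking(diffusionRank(similarityGraph(C),
            c("k1", "k2")))
        pos <- match("c2", rk$entity)
        expect_lte(pos, pos0)
        pos0 <- pos
    }
})

test_that("label permutation permutes scores without changing them", {
    set.seed(4)
    C <- matrix(stats::runif(5 * 10), 5)
    rownames(C) <- paste0("e", 1:5)
    g <- similarityGraph(C)
    s1 <- diffusionScores(diffusionRank(g, c("e1", "e2")))
    perm <- c(3, 1, 5, 2, 4)
    Cp <- C[perm, ]
    gp <- similarityGraph(Cp)
    s2 <- diffusionScores(diffusionRank(gp, c("e1", "e2")))
    expect_equal(s2[names(s1)], s1, tolerance = 1e-10)
})

test_that("LOO validation: boundary case and holdout bookkeeping", {
    # 2 knowns, 1 candidate: ROC defined on 2 positives / 1 negative
    co <- Corpus(data.frame(doc_id = paste0("d", 1:3),
        entity = c("k1", "k2", "c1"),
        role = c("known", "known", "candidate"),
        text = c("a b c", "a b d", "x y z"), stringsAsFactors = FALSE))
    loo <- looValidate(co, K = 50)
    expect_identical(nrow(loo$holdouts), 2L)
    expect_true(all(is.finite(c(loo$auc, loo$averagePrecision,
        loo$ranksumP))))
    expect_error(looValidate(Corpus(data.frame(doc_id = "d1",
        entity = "k1", role = "known", text = "a",
        stringsAsFactors = FALSE)), K = 10), "2 known")
})
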