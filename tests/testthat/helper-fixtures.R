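# Fixtures built in code: rasterized shapes, micro-corpora, tiny plates.

# Binary disc of radius r (matrix of 0/1), padded border.
discMatrix <- function(r, pad = 5) {
    n <- 2 * ceiling(r) + 2 * pad + 1
    ctr <- (n + 1) / 2
    outer(seq_len(n), seq_len(n),
        function(i, j) as.integer((i - ctr)^2 + (j - ctr)^2 <= r^2))
}

# Axis-aligned filled rectangle mask.
rectMatrix <- function(h, w, pad = 3) {
    m <- matrix(0L, h + 2 * pad, w + 2 * pad)
    m[pad + seq_len(h), pad + seq_len(w)] <- 1L
    m
}

# Two-document corpus used for the hand-evaluated TF-IDF example.
tinyCorpus <- function() {
    Corpus(data.frame(
        doc_id = c("d1", "d2"), entity = c("e1", "e2"),
        role = c("known", "candidate"),
        text = c("a a b", "b"), stringsAsFactors = FALSE))
}

# Minimal plate: nBg background wells with given readings (one row per
# well), one sample of nRep replicate wells at the given endpoint rfu.
tinyPlate <- function(bgReadings, sampleEndpoints, times = c(0, 0.75)) {
    nT <- length(times)
    bg <- matrix(rep(bgReadings, each = nT), ncol = nT, byrow = TRUE)
    sm <- matrix(rep(sampleEndpoints, each = nT), ncol = nT,
        byrow = TRUE)
    RtQuicPlate(rbind(bg, sm), times, data.frame(
        sample = c(rep("diluent", length(bgReadings)),
            rep("s1", length(sampleEndpoints))),
        replicate = c(seq_along(bgReadings),
            seq_along(sampleEndpoints)),
        is_background = rep(c(TRUE, FALSE),
            c(length(bgReadings), length(sampleEndpoints)))))
}

# Brute-force two-sided Fisher p: enumerate all tables with the observed
# margins and sum probabilities <= that of the observed table.
fisherBruteForce <- function(tab) {
    r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
    c1 <- sum(tab[, 1]); n <- sum(tab)
    support <- max(0, c1 - r2):min(r1, c1)
    probs <- vapply(support, function(a) {
        b <- r1 - a; cc <- c1 - a; d <- r2 - cc
        exp(lchoose(r1, a) + lchoose(r2, cc) - lchoose(n, c1))
    }, numeric(1))
    pObs <- probs[match(tab[1, 1], support)]
    sum(probs[probs <= pObs * (1 + 1e-7)])
}

# Exact one-tailed rank-sum p by enumeration (oracle for the normal
# approximation).
ranksumBruteForce <- function(x, y) {
    r <- rank(c(x, y))
    W <- sum(r[seq_along(x)])
    combos <- utils::combn(length(x) + length(y), length(x))
    sums <- colSums(matrix(r[combos], nrow = length(x)))
    mean(sums >= W - 1e-9)
}
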