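#' Tokenize text
#'
#' Lowercase whitespace splitting; optional bigrams appended as
#' underscore-joined phrases.
#'
#' @param text character vector.
#' @param bigrams also emit adjacent-word bigrams (default FALSE).
#' @return list of character token vectors, one per input string.
#' @export
tokenize <- function(text, bigrams = FALSE) {
    toks <- strsplit(tolower(trimws(text)), "\\s+")
    toks <- lapply(toks, function(t) t[nzchar(t)])
    if (bigrams)
        toks <- lapply(toks, function(t) {
            if (length(t) < 2) return(t)
            c(t, paste(t[-length(t)], t[-1], sep = "_"))
        })
    toks
}

#' Build a bounded vocabulary from a corpus
#'
#' The top-K terms by total corpus count (ties broken lexicographically),
#' with per-term document frequency.
#'
#' @param corpus a \linkS4class{Corpus}.
#' @param K vocabulary size bound (default 20000, mirroring ranking
#'   against the most common words and phrases of the lexicon).
#' @param bigrams include adjacent-word bigrams (default FALSE).
#' @return data.frame: term, count, df; ordered by count descending then
#'   term.
#' @export
buildVocabulary <- function(corpus, K = 20000, bigrams = FALSE) {
    stopifnot(is(corpus, "Corpus"))
    if (K < 1) stop("K must be >= 1")
    toks <- tokenize(corpus@docs$text, bigrams = bigrams)
    if (!length(unlist(toks, use.names = FALSE)))
        stop("corpus has no tokens")
    counts <- table(unlist(toks, use.names = FALSE))
    dfreq <- table(unlist(lapply(toks, unique), use.names = FALSE))
    out <- data.frame(term = names(counts),
        count = as.integer(counts),
        df = as.integer(dfreq[names(counts)]))
    out <- out[order(-out$count, out$term), ]
    out <- head(out, K)
    rownames(out) <- NULL
    out
}

#' TF-IDF document vectors
#'
#' weight(t, d) = tf * idf with tf = count(t, d)/len(d) (length-
#' normalized) and idf = ln((1 + N)/(1 + df(t))) (add-one smoothed),
#' N = number of documents. Out-of-vocabulary tokens are ignored;
#' \code{len(d)} counts all tokens of the document. Raw-count tf and
#' unsmoothed idf are available as switches.
#'
#' @param corpus a \linkS4class{Corpus}.
#' @param vocab vocabulary from \code{\link{buildVocabulary}}.
#' @param tf "lengthnorm" (default) or "raw".
#' @param smoothIdf add-one smoothing (default TRUE).
#' @param bigrams tokenize with bigrams (must match the vocabulary).
#' @return numeric matrix, documents x terms, dimnames (doc_id, term).
#'   Empty documents give zero rows (with a warning).
#' @export
tfidfVectors <- function(corpus, vocab, tf = c("lengthnorm", "raw"),
        smoothIdf = TRUE, bigrams = FALSE) {
    stopifnot(is(corpus, "Corpus"))
    tf <- match.arg(tf)
    toks <- tokenize(corpus@docs$text, bigrams = bigrams)
    N <- length(toks)
    terms <- vocab$term
    idf <- if (smoothIdf) log((1 + N) / (1 + vocab$df)) else
        log(N / vocab$df)
    M <- matrix(0, N, length(terms),
        dimnames = list(corpus@docs$doc_id, terms))
    empty <- lengths(toks) == 0L
    if (any(empty))
        warning(sum(empty), " empty document(s): zero vectors")
    for (i in seq_len(N)) {
        t_i <- toks[[i]]
        if (!length(t_i)) next
        tab <- table(t_i)
        hit <- intersect(names(tab), terms)
        if (!length(hit)) next
        w <- as.numeric(tab[hit])
        if (tf == "lengthnorm") w <- w / length(t_i)
        M[i, hit] <- w * idf[match(hit, terms)]
    }
    M
}

#' Entity centroids of document vectors
#'
#' The centroid of an entity is the element-wise arithmetic mean of the
#' TF-IDF vectors of all documents associated with that entity.
#'
#' @param docVectors documents x terms matrix from
#'   \code{\link{tfidfVectors}}.
#' @param corpus the \linkS4class{Corpus} the vectors came from.
#' @return numeric matrix, entities x terms.
#' @export
entityCentroids <- function(docVectors, corpus) {
    stopifnot(is(corpus, "Corpus"))
    ent <- corpus@docs$entity[match(rownames(docVectors),
        corpus@docs$doc_id)]
    grp <- rowsum(docVectors, ent)
    grp / as.integer(table(ent)[rownames(grp)])
}

#' Pairwise entity similarity graph
#'
#' Cosine similarity between entity centroids, truncated at 0 (TF-IDF
#' centroids are nonnegative so negative cosines cannot arise, but the
#' guard keeps the matrix in [0, 1] for any input). A zero centroid has
#' similarity 0 to everything, including itself; nonzero centroids have
#' unit diagonal.
#'
#' @param centroids entities x terms matrix from
#'   \code{\link{entityCentroids}}.
#' @return list with \code{entities} (character) and \code{S} (symmetric
#'   similarity matrix in [0, 1]).
#' @export
similarityGraph <- function(centroids) {
    if (nrow(centroids) < 2) stop("need at least 2 entities")
    nrm <- sqrt(rowSums(centroids^2))
    Z <- centroids / ifelse(nrm > 0, nrm, 1)
    S <- tcrossprod(Z)
    S[nrm == 0, ] <- 0
    S[, nrm == 0] <- 0
    S <- pmax(S, 0)
    S <- pmin(S, 1)
    S <- (S + t(S)) / 2
    list(entities = rownames(centroids), S = S)
}

#' Rank candidates by graph diffusion (random walk with restart)
#'
#' Scores every entity by the stationary distribution of a random walk
#' on the row-normalized similarity matrix W that restarts, with
#' probability \code{alpha}, at a uniform distribution e over the known
#' set: s <- alpha e + (1 - alpha) W' s, iterated from s = e until the
#' L1 change falls below \code{tol}. Candidates are ordered by score
#' descending, ties broken lexicographically. Scores are conserved (sum
#' to 1). Rows of W with no similarity mass are given a self-loop.
#'
#' @param graph list from \code{\link{similarityGraph}}.
#' @param known character vector of known (seed) entities, nonempty and
#'   present in the graph.
#' @param alpha restart probability (default 0.15).
#' @param tol L1 convergence tolerance (default 1e-10).
#' @param maxIter iteration cap (default 10000); non-convergence is an
#'   error reporting the residual.
#' @return a \linkS4class{RankedList}.
#' @export
diffusionRank <- function(graph, known, alpha = 0.15, tol = 1e-10,
        maxIter = 10000) {
    entities <- graph$entities
    if (!length(known)) stop("known set must be nonempty")
    if (!all(known %in% entities))
        stop("known entities absent from graph: ",
            paste(setdiff(known, entities), collapse = ", "))
    if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
    S <- graph$S
    n <- length(entities)
    rs <- rowSums(S)
    W <- S / ifelse(rs > 0, rs, 1)
    if (any(rs == 0))
        W[cbind(which(rs == 0), which(rs == 0))] <- 1  # self-loop
    e <- numeric(n)
    e[match(known, entities)] <- 1 / length(known)
    s <- e
    iter <- 0L
    if (alpha < 1) {
        Wt <- t(W)
        repeat {
            iter <- iter + 1L
            sNew <- alpha * e + (1 - alpha) * as.vector(Wt %*% s)
            delta <- sum(abs(sNew - s))
            s <- sNew
            if (delta < tol) break
            if (iter >= maxIter)
                stop(sprintf(
                    "no convergence in %d iterations (L1 residual %.3g)",
                    maxIter, delta))
        }
    }
    names(s) <- entities
    cand <- setdiff(entities, known)
    if (length(cand)) {
        ord <- order(-s[cand], cand)
        ranking <- data.frame(rank = seq_along(cand),
            entity = cand[ord], score = unname(s[cand][ord]))
        if (alpha < 1 && length(cand) > 1 &&
            max(s[cand]) - min(s[cand]) < 1e-15)
            warning("candidate scores are tied ",
                "(known set may be isolated from the graph)")
    } else {
        ranking <- data.frame(rank = integer(), entity = character(),
            score = numeric())
    }
    new("RankedList", scores = s, ranking = ranking,
        known = as.character(known), iterations = iter)
}

# Direct linear-solve equivalent of diffusionRank; the test oracle.
diffusionSolve <- function(graph, known, alpha = 0.15) {
    entities <- graph$entities
    S <- graph$S
    n <- length(entities)
    rs <- rowSums(S)
    W <- S / ifelse(rs > 0, rs, 1)
    if (any(rs == 0)) W[cbind(which(rs == 0), which(rs == 0))] <- 1
    e <- numeric(n)
    e[match(known, entities)] <- 1 / length(known)
    s <- solve(diag(n) - (1 - alpha) * t(W), alpha * e)
    names(s) <- entities
    s
}

#' Leave-one-out validation of diffusion ranking
#'
#' Each known entity is held out in turn: it is moved to the candidate
#' set and re-ranked against the remaining knowns; its score and rank
#' among candidates are recorded. ROC and precision-recall curves treat
#' the held-out knowns as positives and the never-known candidates
#' (scored under the full known set) as negatives; a one-tailed rank-sum
#' test asks whether known scores exceed candidate scores.
#'
#' @param corpus a \linkS4class{Corpus} with >= 2 known entities.
#' @param K vocabulary size (default 20000).
#' @param alpha restart probability (default 0.15).
#' @param ... further arguments to \code{\link{diffusionRank}}.
#' @return list: \code{holdouts} (data.frame entity, score, rank,
#'   n_candidates), \code{auc}, \code{roc} (curve data.frame),
#'   \code{averagePrecision}, \code{pr} (curve data.frame),
#'   \code{ranksumP}, \code{fullRanking} (the full-known-set
#'   \linkS4class{RankedList}).
#' @export
looValidate <- function(corpus, K = 20000, alpha = 0.15, ...) {
    stopifnot(is(corpus, "Corpus"))
    roles <- entityRoles(corpus)
    known <- names(roles)[roles == "known"]
    if (length(known) < 2) stop("need >= 2 known entities")
    vocab <- buildVocabulary(corpus, K)
    dv <- tfidfVectors(corpus, vocab)
    cen <- entityCentroids(dv, corpus)
    graph <- similarityGraph(cen)
    full <- diffusionRank(graph, known, alpha = alpha, ...)
    holdouts <- do.call(rbind, lapply(known, function(k) {
        rl <- diffusionRank(graph, setdiff(known, k), alpha = alpha, ...)
        tab <- candidateRanking(rl)
        i <- match(k, tab$entity)
        data.frame(entity = k, score = tab$score[i], rank = tab$rank[i],
            n_candidates = nrow(tab))
    }))
    negScores <- candidateRanking(full)$score
    scores <- c(holdouts$score, negScores)
    labels <- c(rep(1, nrow(holdouts)), rep(0, length(negScores)))
    roc <- rocAuc(scores, labels)
    pr <- precisionRecall(scores, labels)
    p <- wilcoxonRankSumGreater(holdouts$score, negScores)
    list(holdouts = holdouts, auc = roc$auc, roc = roc$curve,
        averagePrecision = pr$averagePrecision, pr = pr$curve,
        ranksumP = p, fullRanking = full)
}
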