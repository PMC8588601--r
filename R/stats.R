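#' Two-sided Fisher exact test for a 2x2 table
#'
#' Point-probability (Fisher) definition: with both margins fixed, the
#' p-value is the sum of hypergeometric probabilities of every table whose
#' probability does not exceed that of the observed table. This is the
#' convention of mainstream statistical software and reproduces, e.g.,
#' p = 0.026 for a 4/3 vs 0/8 split of positives.
#'
#' @param table 2x2 matrix of nonnegative counts (rows = groups, columns
#'   = positive/negative), or four counts \code{c(a, b, c, d)} read
#'   row-wise.
#' @return the two-sided p-value in (0, 1].
#' @examples
#' fisherExactTwoSided(matrix(c(4, 0, 3, 8), 2))  # 0.02564
#' @export
fisherExactTwoSided <- function(table) {
    if (!is.matrix(table)) {
        if (length(table) != 4L) stop("need a 2x2 table")
        table <- matrix(table, 2, 2, byrow = TRUE)
    }
    if (!all(dim(table) == c(2L, 2L))) stop("need a 2x2 table")
    if (any(table < 0) || any(table != round(table)))
        stop("counts must be nonnegative integers")
    n <- sum(table)
    if (n == 0) stop("table total must be positive")
    r1 <- sum(table[1, ]); c1 <- sum(table[, 1])
    if (r1 == 0 || r1 == n || c1 == 0 || c1 == n) {
        warning("degenerate margin: p = 1")
        return(1.0)
    }
    a <- table[1, 1]
    support <- max(0, r1 + c1 - n):min(r1, c1)
    probs <- stats::dhyper(support, c1, n - c1, r1)
    pObs <- stats::dhyper(a, c1, n - c1, r1)
    # relative tolerance guards against FP noise when probabilities tie
    min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
}

#' One-tailed Wilcoxon rank-sum test (x stochastically greater than y)
#'
#' Exact permutation p-value by enumeration of all rank assignments when
#' n + m <= \code{exactLimit}; otherwise a normal approximation to the
#' Mann-Whitney U statistic with tie correction and a 0.5 continuity
#' correction. The alternative is one-sided: values in \code{x} tend to
#' exceed values in \code{y}.
#'
#' @param x,y numeric score vectors (both nonempty).
#' @param exactLimit switch to the normal approximation when
#'   \code{length(x) + length(y)} exceeds this (default 12).
#' @return the one-tailed p-value.
#' @examples
#' wilcoxonRankSumGreater(c(4, 5, 6), c(1, 2, 3))  # 1/20 = 0.05
#' @export
wilcoxonRankSumGreater <- function(x, y, exactLimit = 12) {
    if (!length(x) || !length(y)) stop("both samples must be nonempty")
    n <- length(x); m <- length(y)
    pooled <- c(x, y)
    if (length(unique(pooled)) == 1L) {
        warning("all values tied across both samples: p = 1")
        return(1.0)
    }
    r <- rank(pooled)
    W <- sum(r[seq_len(n)])
    if (n + m <= exactLimit) {
        combos <- utils::combn(n + m, n)
        sums <- colSums(matrix(r[combos], nrow = n))
        # >= observed, with tolerance for tied fractional ranks
        return(mean(sums >= W - 1e-9))
    }
    U <- W - n * (n + 1) / 2
    mu <- n * m / 2
    tie <- table(pooled)
    sigma2 <- n * m / 12 *
        (n + m + 1 - sum(tie^3 - tie) / ((n + m) * (n + m - 1)))
    z <- (U - mu - 0.5) / sqrt(sigma2)
    stats::pnorm(z, lower.tail = FALSE)
}

# Shared threshold sweep: descending unique scores, cumulative TP/FP with
# tied scores grouped into one step.
scoreSteps <- function(scores, labels) {
    stopifnot(length(scores) == length(labels))
    labels <- as.integer(labels != 0)
    P <- sum(labels == 1L); N <- sum(labels == 0L)
    if (P < 1L || N < 1L)
        stop("need at least one positive and one negative")
    ord <- order(scores, decreasing = TRUE)
    s <- scores[ord]; l <- labels[ord]
    grp <- cumsum(!duplicated(s))
    tp <- cumsum(l); fp <- cumsum(1L - l)
    last <- !duplicated(grp, fromLast = TRUE)   # end of each tie group
    list(threshold = s[last], tp = tp[last], fp = fp[last], P = P, N = N)
}

#' ROC curve and AUC
#'
#' Threshold sweep over unique scores with tied scores grouped into one
#' step; AUC by the trapezoidal rule, equivalent to the Mann-Whitney
#' statistic with 0.5 credit for score ties.
#'
#' @param scores numeric scores, larger = more positive-like.
#' @param labels binary labels (1/TRUE = positive); at least one positive
#'   and one negative.
#' @return list with \code{curve} (data.frame threshold, fpr, tpr,
#'   starting at (0, 0)) and \code{auc}.
#' @examples
#' rocAuc(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0))$auc  # 0.75
#' @export
rocAuc <- function(scores, labels) {
    st <- scoreSteps(scores, labels)
    tpr <- c(0, st$tp / st$P); fpr <- c(0, st$fp / st$N)
    auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
    list(curve = data.frame(threshold = c(Inf, st$threshold),
        fpr = fpr, tpr = tpr), auc = auc)
}

#' Precision-recall curve and average precision
#'
#' Average precision is the step-sum \eqn{\sum_k (R_k - R_{k-1}) P_k}
#' over descending-score threshold steps (tied scores grouped).
#'
#' @inheritParams rocAuc
#' @return list with \code{curve} (data.frame threshold, recall,
#'   precision) and \code{averagePrecision}.
#' @examples
#' precisionRecall(c(0.9, 0.4, 0.6, 0.1),
#'                 c(1, 1, 0, 0))$averagePrecision  # 0.8333
#' @export
precisionRecall <- function(scores, labels) {
    st <- scoreSteps(scores, labels)
    recall <- st$tp / st$P
    precision <- st$tp / (st$tp + st$fp)
    ap <- sum(diff(c(0, recall)) * precision)
    list(curve = data.frame(threshold = st$threshold, recall = recall,
        precision = precision), averagePrecision = ap)
}

#' Group summary table (mean, SD, SEM)
#'
#' Thin descriptive summary used in screen report tables.
#'
#' @param values numeric vector.
#' @param groups grouping factor/character of the same length.
#' @return data.frame: group, n, mean, sd, sem.
#' @export
groupSummary <- function(values, groups) {
    stopifnot(length(values) == length(groups))
    out <- lapply(split(values, groups), function(v) {
        data.frame(n = length(v), mean = mean(v), sd = stats::sd(v),
            sem = stats::sd(v) / sqrt(length(v)))
    })
    res <- do.call(rbind, out)
    data.frame(group = names(out), res, row.names = NULL)
}
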