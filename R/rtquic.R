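#' RT-QuIC positivity threshold
#'
#' Mean background (diluent) fluorescence plus 5 standard deviations.
#' By default the statistics pool every timepoint of every background
#' well (sample SD, divisor n-1); a per-timepoint mode computes a
#' threshold vector instead.
#'
#' @param plate an \linkS4class{RtQuicPlate} with >= 2 background wells.
#' @param nSd number of SDs above the background mean (default 5).
#' @param perTimepoint return one threshold per read time instead of a
#'   single pooled value (default FALSE).
#' @return threshold in rfu (scalar, or vector when
#'   \code{perTimepoint = TRUE}).
#' @export
computeThreshold <- function(plate, nSd = 5, perTimepoint = FALSE) {
    stopifnot(is(plate, "RtQuicPlate"))
    rd <- SummarizedExperiment::rowData(plate)
    bg <- SummarizedExperiment::assay(plate, "rfu")[rd$is_background, ,
        drop = FALSE]
    if (nrow(bg) < 2) stop("need >= 2 background wells")
    if (perTimepoint)
        return(apply(bg, 2, mean) + nSd * apply(bg, 2, stats::sd))
    v <- as.vector(bg)
    mean(v) + nSd * stats::sd(v)
}

#' Call replicate (well) positivity
#'
#' A replicate is positive iff its fluorescence at the endpoint -- the
#' last recorded timepoint at or before \code{endpointH} -- strictly
#' exceeds the threshold. A max-over-time mode (any read above
#' threshold) is available but non-default.
#'
#' @param plate an \linkS4class{RtQuicPlate}.
#' @param threshold rfu threshold from \code{\link{computeThreshold}}.
#' @param endpointH endpoint in hours (default 60).
#' @param mode "endpoint" (default) or "max" (max over reads up to the
#'   endpoint).
#' @return data.frame: well, sample, replicate, is_background, endpoint
#'   (rfu used for the call), positive.
#' @export
callReplicates <- function(plate, threshold, endpointH = 60,
        mode = c("endpoint", "max")) {
    stopifnot(is(plate, "RtQuicPlate"))
    mode <- match.arg(mode)
    tm <- plateTimes(plate)
    upto <- which(tm <= endpointH + 1e-9)
    if (!length(upto)) stop("no timepoint at or before the endpoint")
    rfu <- SummarizedExperiment::assay(plate, "rfu")
    val <- if (mode == "endpoint") rfu[, max(upto)] else
        apply(rfu[, upto, drop = FALSE], 1, max)
    rd <- as.data.frame(SummarizedExperiment::rowData(plate))
    data.frame(well = rownames(rfu), sample = rd$sample,
        replicate = rd$replicate, is_background = rd$is_background,
        group = if (!is.null(rd$group)) rd$group else NA_character_,
        endpoint = unname(val), positive = unname(val > threshold))
}

#' Call sample positivity and group counts
#'
#' A sample is positive when at least one of its replicates is positive.
#'
#' @param repCalls replicate calls from \code{\link{callReplicates}}.
#' @return data.frame: sample, group, n_positive_replicates,
#'   n_replicates, positive. Groups (when present in the plate map) are
#'   carried through; see \code{\link{groupContingency}}.
#' @export
callSamples <- function(repCalls) {
    sc <- repCalls[!repCalls$is_background, , drop = FALSE]
    if (!nrow(sc)) stop("no sample wells to call")
    grp <- if (!is.null(sc$group)) sc$group else rep(NA_character_,
        nrow(sc))
    out <- do.call(rbind, lapply(split(seq_len(nrow(sc)), sc$sample),
        function(i) data.frame(sample = sc$sample[i[1]],
            group = grp[i[1]],
            n_positive_replicates = sum(sc$positive[i]),
            n_replicates = length(i),
            positive = any(sc$positive[i]))))
    rownames(out) <- NULL
    out
}

#' Per-group 2x2 contingency table of sample positivity
#'
#' @param sampleCalls data.frame from \code{\link{callSamples}} with a
#'   group column (two groups).
#' @return list: \code{table} (2x2 matrix, rows = groups, columns =
#'   positive/negative) and \code{fisherP} (two-sided Fisher exact
#'   p-value).
#' @export
groupContingency <- function(sampleCalls) {
    g <- unique(sampleCalls$group)
    if (length(g) != 2) stop("need exactly 2 groups")
    tab <- t(vapply(g, function(gi) {
        p <- sampleCalls$positive[sampleCalls$group == gi]
        c(positive = sum(p), negative = sum(!p))
    }, numeric(2)))
    rownames(tab) <- g
    list(table = tab, fisherP = fisherExactTwoSided(tab))
}

#' Mean kinetic curves per sample
#'
#' For a positive sample, the mean fluorescence over its positive
#' replicates at each timepoint; for a negative sample, the mean over
#' its negative replicates.
#'
#' @param plate the \linkS4class{RtQuicPlate}.
#' @param repCalls replicate calls from \code{\link{callReplicates}}.
#' @return matrix, samples x timepoints.
#' @export
meanCurves <- function(plate, repCalls) {
    stopifnot(is(plate, "RtQuicPlate"))
    rfu <- SummarizedExperiment::assay(plate, "rfu")
    sc <- repCalls[!repCalls$is_background, , drop = FALSE]
    samples <- unique(sc$sample)
    out <- t(vapply(samples, function(s) {
        rows <- sc[sc$sample == s, , drop = FALSE]
        use <- if (any(rows$positive)) rows$well[rows$positive] else
            rows$well[!rows$positive]
        colMeans(rfu[use, , drop = FALSE])
    }, numeric(ncol(rfu))))
    rownames(out) <- samples
    out
}

#' Full RT-QuIC positivity calling
#'
#' Convenience wrapper: threshold, replicate calls at the 60 h endpoint,
#' sample calls (>= 1-of-4 replicate rule), and mean curves.
#'
#' @inheritParams computeThreshold
#' @inheritParams callReplicates
#' @return an \linkS4class{RtQuicCalls}.
#' @export
rtquicCall <- function(plate, nSd = 5, endpointH = 60,
        mode = c("endpoint", "max")) {
    thr <- computeThreshold(plate, nSd = nSd)
    rc <- callReplicates(plate, thr, endpointH = endpointH,
        mode = match.arg(mode))
    sc <- callSamples(rc)
    mc <- meanCurves(plate, rc)
    new("RtQuicCalls", threshold = thr,
        replicateCalls = rc[!rc$is_background,
            c("well", "sample", "replicate", "endpoint", "positive")],
        sampleCalls = sc, meanCurves = mc, times = plateTimes(plate))
}
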