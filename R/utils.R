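# Internal helpers shared across modules.

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", envir = globalenv()))
            get(".Random.seed", envir = globalenv()) else NULL
        on.exit({
            if (is.null(old)) {
                if (exists(".Random.seed", envir = globalenv()))
                    rm(".Random.seed", envir = globalenv())
            } else assign(".Random.seed", old, envir = globalenv())
        })
        set.seed(as.integer(seed))
    }
    force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Single positive finite scalar check
checkScalar <- function(x, name, positive = TRUE) {
    if (length(x) != 1L || !is.finite(x) || (positive && x <= 0))
        stop(sprintf("'%s' must be a single %s number", name,
            if (positive) "positive finite" else "finite"), call. = FALSE)
    invisible(x)
}
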