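# Internal helpers: seeded evaluation and classed conditions.

## Evaluate `expr` under a fixed RNG seed without disturbing the caller's
## RNG stream.
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
        set.seed(seed)
    }
    force(expr)
}

mpStop <- function(class, fmt, ...) {
    stop(structure(class = c(class, "error", "condition"),
                   list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

mpWarn <- function(class, fmt, ...) {
    warning(structure(class = c(class, "warning", "condition"),
                      list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

logMsg <- function(fmt, ...) {
    message(sprintf(fmt, ...))
}
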