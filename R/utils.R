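# Evaluate `expr` under set.seed(seed), restoring the caller's RNG state.
# Every stochastic operation in the package takes an explicit seed and
# routes through this, so generators are pure functions of (config, seed).
.withSeed <- function(seed, expr) {
    if (missing(seed) || is.null(seed))
        stop("a seed is mandatory for stochastic operations")
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        stats::runif(1)
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    expr
}
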