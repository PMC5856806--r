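# Internal helpers shared across modules.

# Derive a child seed from a master seed and a stage counter so stages are
# individually reproducible. Kept strictly below 2^31 - 1.
childSeed <- function(seed, k) {
    as.integer((as.double(seed) * 48271 + 1009 * as.double(k)) %%
               2147483646) + 1L
}

# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
    expr
}

# n uniform random unit vectors (rows), via normalized Gaussian triples.
runifDirections <- function(n) {
    m <- matrix(stats::rnorm(3 * n), ncol = 3)
    m / sqrt(rowSums(m^2))
}

# Population SD (divide by n): image statistics are moments of a fixed pixel
# grid, not estimates from a sample.
popSD <- function(x) {
    sqrt(mean((x - mean(x))^2))
}

stopIfNot3D <- function(stack) {
    stopifnot(is(stack, "ImageStack"))
    invisible(stack)
}
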