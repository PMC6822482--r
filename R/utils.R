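`%||%` <- function(a, b) if (is.null(a)) b else a

# All internal randomness is routed through withr so that user RNG state is
# never disturbed and every stochastic step is reproducible from its seed.
.withSeed <- function(seed, code) {
    withr::with_seed(as.integer(seed), code)
}

# Derive a child seed from a parent seed and a stream index, staying well
# inside 32-bit integer range.
.childSeed <- function(seed, stream) {
    as.integer((as.double(seed) * 1103L + as.double(stream) * 7919L) %% 2147483291)
}

.hashObject <- function(x) {
    f <- tempfile()
    on.exit(unlink(f))
    writeBin(serialize(x, NULL, version = 3L, xdr = TRUE), f)
    unname(tools::md5sum(f))
}

.assertScalarString <- function(x, what) {
    if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x))
        stop(what, " must be a single non-empty string", call. = FALSE)
    x
}
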