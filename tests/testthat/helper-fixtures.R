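# Shared, lazily built and memoised fixtures. All are generated in code under
# fixed seeds; the canonical study-like fixture (8 imbalanced cities, 200 ECs,
# effect 8, seed 42) is the package's reference condition and the two
# leave-one-out runs on it are reused by several test files.

.cache <- new.env(parent = emptyenv())

.memo <- function(key, expr) {
    if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
    .cache[[key]]
}

# -- small cheap set for unit tests ----------------------------------------
smallConfig <- function() {
    syntheticConfig(nCities = 3L, samplesPerCity = c(8L, 20L, 12L),
                    nEcs = 60L, nSignatureEcsPerCity = 6L, seed = 7L)
}
smallKnown <- function() .memo("smallKnown", simulateKnownSet(smallConfig()))
smallCV <- function() .memo("smallCV",
    looCrossval(smallKnown(), "raw-select",
                params = list(kFeatures = 10L), seed = 3L))
smallSuite <- function() .memo("smallSuite",
    fitFinalSuite(smallKnown(), "final",
                  params = list(kFeatures = 10L, perCity = 20L,
                                perClass = 60L), seed = 5L))
smallRandom <- function() .memo("smallRandom",
    generateRandomMetagenomeSet(smallKnown(), nPoolPerCity = 5L,
                                nOut = 300L, seed = 11L))

# -- harder imbalanced set where balancing/prevalence effects are visible --
hardConfig <- function() {
    syntheticConfig(nCities = 3L, samplesPerCity = c(5L, 50L, 50L),
                    nEcs = 120L, nSignatureEcsPerCity = 10L,
                    effectSize = 3, sparsity = 0.3, seed = 23L)
}
hardKnown <- function() .memo("hardKnown", simulateKnownSet(hardConfig()))
hardCV <- function() .memo("hardCV",
    looCrossval(hardKnown(), "raw-select",
                params = list(kFeatures = 10L), seed = 7L))

# -- canonical study-like fixture ------------------------------------------
fixtureParams <- function() {
    list(kFeatures = 20L, perCity = 30L, perClass = 100L)
}
fixtureKnown <- function() .memo("fixtureKnown",
    simulateKnownSet(syntheticConfig()))
fixtureCV <- function(variant = c("raw-select", "balance-select")) {
    variant <- match.arg(variant)
    .memo(paste0("fixtureCV_", variant),
          looCrossval(fixtureKnown(), variant, params = fixtureParams(),
                      seed = 101L))
}
# final suites are cheap enough to fit at the published balancing scale
fixtureSuite <- function(variant = c("final", "final-unbalanced")) {
    variant <- match.arg(variant)
    .memo(paste0("fixtureSuite_", variant),
          fitFinalSuite(fixtureKnown(), variant,
                        params = list(kFeatures = 20L, perCity = 150L,
                                      perClass = 5000L),
                        seed = 202L))
}
fixtureRandom <- function(replicate = 1L, nOut = 1000L) {
    .memo(paste0("fixtureRandom_", replicate, "_", nOut),
          generateRandomMetagenomeSet(fixtureKnown(), nPoolPerCity = 10L,
                                      nOut = nOut, seed = 300L + replicate))
}

# write a tiny profile file for the parser tests
writeProfileFile <- function(lines) {
    f <- tempfile(fileext = ".tsv")
    writeLines(lines, f)
    f
}
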