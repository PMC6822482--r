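#' Configuration of the synthetic city-profile generator
#'
#' Declares the generative model used to emulate city-structured EC profiles:
#' a single log-normal baseline abundance vector shared by all cities, with
#' each city's planted signature ECs multiplied (enriched) or divided
#' (depleted) by `effectSize`; per-sample log-normal noise on the expected
#' composition; multinomial read sampling at the configured depth; and
#' Bernoulli dropout that zeroes each EC count independently with probability
#' `sparsity`.
#'
#' Defaults describe the canonical study-like condition: 8 cities with
#' deliberately imbalanced sample counts dominated by two large cities, a
#' 200-EC universe, 20 signature ECs per city, an 8-fold signature effect,
#' 20% dropout, and 1e5 reads per sample.
#'
#' @param nCities number of cities.
#' @param samplesPerCity integer vector of per-city sample counts.
#' @param nEcs size of the EC universe (at most 1257).
#' @param nSignatureEcsPerCity planted signature ECs per city (disjoint
#'   across cities).
#' @param effectSize multiplicative enrichment/depletion factor (> 1).
#' @param sparsity probability an EC count is zeroed in a sample, in [0, 1).
#' @param depth simulated total reads per sample.
#' @param seed integer seed driving every draw.
#' @param baselineSdLog sd of the log-normal baseline EC means.
#' @param sampleNoiseSd sd of per-sample log-normal composition noise.
#' @return a `SyntheticConfig`.
#' @aliases SyntheticConfig-class
#' @export
syntheticConfig <- function(nCities = 8L,
                            samplesPerCity = c(5L, 8L, 100L, 10L, 60L, 10L, 15L, 20L),
                            nEcs = 200L,
                            nSignatureEcsPerCity = 20L,
                            effectSize = 8,
                            sparsity = 0.2,
                            depth = 100000L,
                            seed = 42L,
                            baselineSdLog = 1.25,
                            sampleNoiseSd = 0.3) {
    new("SyntheticConfig",
        nCities = as.integer(nCities),
        samplesPerCity = as.integer(samplesPerCity),
        nEcs = as.integer(nEcs),
        nSignatureEcsPerCity = as.integer(nSignatureEcsPerCity),
        effectSize = as.numeric(effectSize),
        sparsity = as.numeric(sparsity),
        depth = as.integer(depth),
        seed = as.integer(seed),
        baselineSdLog = as.numeric(baselineSdLog),
        sampleNoiseSd = as.numeric(sampleNoiseSd))
}

setMethod("show", "SyntheticConfig", function(object) {
    cat("SyntheticConfig: ", object@nCities, " cities (",
        paste(object@samplesPerCity, collapse = ","), " samples), ",
        object@nEcs, " ECs, ", object@nSignatureEcsPerCity,
        " signature ECs/city, effect ", object@effectSize,
        ", sparsity ", object@sparsity, ", depth ", object@depth,
        ", seed ", object@seed, "\n", sep = "")
})

# Deterministic EC universe for a config: a seeded draw of unique dotted
# four-field identifiers, shared by the known and outgroup generators so that
# both live in the same feature space.
.ecNamesForConfig <- function(config) {
    .withSeed(.childSeed(config@seed, 1L), {
        n <- config@nEcs
        ecs <- character(0)
        while (length(ecs) < n) {
            cand <- sprintf("%d.%d.%d.%d",
                            sample.int(6L, 2L * n, replace = TRUE),
                            sample.int(20L, 2L * n, replace = TRUE),
                            sample.int(30L, 2L * n, replace = TRUE),
                            sample.int(200L, 2L * n, replace = TRUE))
            ecs <- unique(c(ecs, cand))
        }
        sort(ecs[seq_len(n)], method = "radix")
    })
}

.cityNames <- function(n) sprintf("city%02d", seq_len(n))

# Draw one set of samples given per-sample expected weights (ECs x samples),
# applying multinomial sampling and dropout. Returns counts matrix.
.drawCounts <- function(weights, depth, sparsity) {
    counts <- apply(weights, 2L, function(w) {
        stats::rmultinom(1L, size = depth, prob = w / sum(w))[, 1L]
    })
    if (sparsity > 0) {
        drop <- matrix(stats::runif(length(counts)) < sparsity, nrow = nrow(counts))
        counts[drop] <- 0L
    }
    counts
}

#' Generate a city-structured synthetic sample set
#'
#' Emulates a labeled training ("known") set: all cities share one log-normal
#' baseline composition; each city's planted signature ECs are enriched or
#' depleted by the configured effect size; per-sample counts come from
#' multinomial sampling at the configured depth with per-sample log-normal
#' composition noise and Bernoulli dropout. The planted ground truth is stored
#' in `metadata(x)$signatures` as a per-city data.frame of (ec, direction).
#'
#' @param config a [syntheticConfig()].
#' @return an [ECProfileSet] tagged `"known"`, with `metadata()` entries
#'   `signatures`, `baselineLogMean`, and `config`.
#' @export
simulateKnownSet <- function(config) {
    stopifnot(is(config, "SyntheticConfig"))
    validObject(config)
    ecs <- .ecNamesForConfig(config)
    cities <- .cityNames(config@nCities)
    .withSeed(.childSeed(config@seed, 2L), {
        baseLog <- stats::rnorm(config@nEcs, mean = 0, sd = config@baselineSdLog)
        names(baseLog) <- ecs
        # disjoint signature EC sets, random direction per EC
        sigPool <- sample(ecs, config@nSignatureEcsPerCity * config@nCities)
        signatures <- vector("list", config@nCities)
        names(signatures) <- cities
        cityWeights <- matrix(rep(exp(baseLog), config@nCities),
                              nrow = config@nEcs,
                              dimnames = list(ecs, cities))
        for (i in seq_len(config@nCities)) {
            idx <- seq.int((i - 1L) * config@nSignatureEcsPerCity + 1L,
                           i * config@nSignatureEcsPerCity)
            sig <- sigPool[idx]
            dir <- sample(c("enriched", "depleted"), length(sig), replace = TRUE)
            fac <- ifelse(dir == "enriched", config@effectSize, 1 / config@effectSize)
            cityWeights[sig, i] <- cityWeights[sig, i] * fac
            signatures[[i]] <- data.frame(ec = sig, direction = dir,
                                          stringsAsFactors = FALSE)
        }
        ncol_total <- sum(config@samplesPerCity)
        labels <- rep(cities, config@samplesPerCity)
        ids <- sprintf("%s_s%03d", labels,
                       unlist(lapply(config@samplesPerCity, seq_len)))
        noise <- matrix(exp(stats::rnorm(config@nEcs * ncol_total,
                                         sd = config@sampleNoiseSd)),
                        nrow = config@nEcs)
        weights <- cityWeights[, labels, drop = FALSE] * noise
        counts <- .drawCounts(weights, config@depth, config@sparsity)
        dimnames(counts) <- list(ecs, ids)
        ab <- counts / config@depth
        ECProfileSet(ab, city = labels, totalReads = config@depth,
                     setTag = "known", counts = counts,
                     metadata = list(signatures = signatures,
                                     baselineLogMean = baseLog,
                                     config = config))
    })
}

#' Construct the random-metagenome null set
#'
#' Builds artificial metagenomes from a labeled sample set: a pool is formed
#' by drawing `nPoolPerCity` samples from each city (with replacement when a
#' city is smaller than that); each output sample's value for each EC is then
#' drawn independently and uniformly from the pool's values for that EC. The
#' construction preserves per-EC marginal abundance distributions while
#' destroying the inter-EC correlation that makes real profiles city-like,
#' which is what makes it a usable null for novelty calibration.
#'
#' @param known an [ECProfileSet] with city labels.
#' @param nPoolPerCity samples drawn per city into the pool (default 10).
#' @param nOut number of artificial samples (default 1000).
#' @param seed integer seed.
#' @return an [ECProfileSet] tagged `"random"`, city `"unknown"`.
#' @export
generateRandomMetagenomeSet <- function(known, nPoolPerCity = 10L,
                                        nOut = 1000L, seed = 1L) {
    stopifnot(is(known, "ECProfileSet"))
    if (ncol(known) == 0L) stop("empty known set", call. = FALSE)
    labels <- cityLabels(known)
    cities <- sort(unique(labels))
    a <- abundanceMatrix(known)          # ECs x samples
    .withSeed(seed, {
        poolIdx <- unlist(lapply(cities, function(cc) {
            idx <- which(labels == cc)
            sample(idx, nPoolPerCity, replace = length(idx) < nPoolPerCity)
        }))
        pool <- a[, poolIdx, drop = FALSE]     # ECs x poolN
        poolN <- ncol(pool)
        nEcs <- nrow(pool)
        pick <- matrix(sample.int(poolN, nEcs * nOut, replace = TRUE),
                       nrow = nEcs)
        out <- matrix(pool[cbind(rep(seq_len(nEcs), nOut), as.vector(pick))],
                      nrow = nEcs)
        dimnames(out) <- list(rownames(a), sprintf("random_%04d", seq_len(nOut)))
        ECProfileSet(out, city = "unknown", totalReads = NA_real_,
                     setTag = "random",
                     metadata = list(nPoolPerCity = nPoolPerCity,
                                     poolSamples = colnames(a)[poolIdx],
                                     seed = as.integer(seed)))
    })
}

#' Random-label baseline label vectors
#'
#' Produces label-shuffle replicates: each replicate is a uniform random
#' permutation of the original city label vector, so per-city label counts
#' are preserved within every replicate.
#'
#' @param known an [ECProfileSet] (or a character label vector).
#' @param nReplicates number of permutations (the study used 1000).
#' @param seed integer seed.
#' @return list of `nReplicates` character label vectors.
#' @export
shuffleLabels <- function(known, nReplicates = 1000L, seed = 1L) {
    labels <- if (is(known, "ECProfileSet")) as.character(cityLabels(known))
              else as.character(known)
    .withSeed(seed, {
        lapply(seq_len(nReplicates), function(i) sample(labels))
    })
}

#' Generate an unrelated outgroup sample set
#'
#' Emulates a negative-control metagenome set unrelated to any training city:
#' the baseline EC composition is redrawn independently of the known-set
#' baseline and additionally perturbed by the factor `shift` (a seeded random
#' half of the ECs is multiplied by `shift`, the other half divided), moving
#' the outgroup composition far from every city centroid. Sampling noise,
#' depth, and dropout follow the config.
#'
#' @param config the [syntheticConfig()] whose EC universe to share.
#' @param shift positive multiplicative perturbation factor.
#' @param nSamples number of outgroup samples.
#' @param seed integer seed (defaults to a stream derived from the config
#'   seed, independent of the known-set stream).
#' @return an [ECProfileSet] tagged `"outgroup"`, city `"unknown"`.
#' @export
generateOutgroupSet <- function(config, shift = 8, nSamples = 50L,
                                seed = .childSeed(config@seed, 99L)) {
    stopifnot(is(config, "SyntheticConfig"))
    if (shift <= 0) stop("shift must be positive", call. = FALSE)
    ecs <- .ecNamesForConfig(config)
    .withSeed(seed, {
        logw <- stats::rnorm(config@nEcs, mean = 0, sd = config@baselineSdLog)
        half <- sample.int(config@nEcs, floor(config@nEcs / 2))
        w <- exp(logw)
        w[half] <- w[half] * shift
        w[-half] <- w[-half] / shift
        noise <- matrix(exp(stats::rnorm(config@nEcs * nSamples,
                                         sd = config@sampleNoiseSd)),
                        nrow = config@nEcs)
        weights <- matrix(w, nrow = config@nEcs, ncol = nSamples) * noise
        counts <- .drawCounts(weights, config@depth, config@sparsity)
        dimnames(counts) <- list(ecs, sprintf("outgroup_s%03d", seq_len(nSamples)))
        ab <- counts / config@depth
        ECProfileSet(ab, city = "unknown", totalReads = config@depth,
                     setTag = "outgroup", counts = counts,
                     metadata = list(shift = shift, seed = as.integer(seed),
                                     config = config))
    })
}

#' Planted ground-truth signatures of a synthetic set
#'
#' @param x an [ECProfileSet] produced by [simulateKnownSet()].
#' @return named list: per city a data.frame of `ec` and `direction`.
#' @export
plantedSignatures <- function(x) {
    sig <- S4Vectors::metadata(x)$signatures
    if (is.null(sig))
        stop("no planted signatures recorded in this set", call. = FALSE)
    sig
}

#' Write a synthetic sample set to disk in the package's exchange formats
#'
#' Writes one two-column TSV profile per sample (EC, annotated count),
#' a metadata CSV (`sample_id,city,total_reads,set_tag`), and a ground-truth
#' JSON (planted signatures and the generator configuration).
#'
#' @param x an [ECProfileSet] carrying a `counts` assay.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSyntheticSet <- function(x, dir) {
    stopifnot(is(x, "ECProfileSet"))
    if (!"counts" %in% names(SummarizedExperiment::assays(x)))
        stop("set has no counts assay to export", call. = FALSE)
    dir.create(file.path(dir, "profiles"), recursive = TRUE, showWarnings = FALSE)
    cnt <- SummarizedExperiment::assay(x, "counts")
    for (j in seq_len(ncol(x))) {
        keep <- cnt[, j] > 0L
        writeLines(c("# EC\tannotated_reads",
                     sprintf("%s\t%d", rownames(cnt)[keep], cnt[keep, j])),
                   file.path(dir, "profiles", paste0(colnames(x)[j], ".tsv")))
    }
    meta <- data.frame(sample_id = colnames(x),
                       city = as.character(cityLabels(x)),
                       total_reads = as.numeric(totalReads(x)),
                       set_tag = as.character(setTags(x)))
    utils::write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
    md <- S4Vectors::metadata(x)
    truth <- list(signatures = md$signatures)
    if (!is.null(md$config)) {
        cf <- md$config
        truth$config <- list(nCities = cf@nCities,
                             samplesPerCity = cf@samplesPerCity,
                             nEcs = cf@nEcs,
                             nSignatureEcsPerCity = cf@nSignatureEcsPerCity,
                             effectSize = cf@effectSize,
                             sparsity = cf@sparsity,
                             depth = cf@depth,
                             seed = cf@seed)
    }
    jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    invisible(dir)
}
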