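#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#' @importFrom S4Vectors DataFrame metadata
NULL

.EC_REGEX <- "^[0-9]+\\.[0-9]+\\.[0-9]+\\.[0-9]+$"

#' Maximum number of annotatable enzyme functions
#'
#' The upstream read-to-function annotator can assign reads to at most 1257
#' distinct EC numbers, which bounds the width of any feature matrix built
#' from its output.
#' @export
MAX_ANNOTATABLE_ECS <- 1257L

# ---------------------------------------------------------------------------
# FunctionalProfile: one sample's EC -> annotated-read-count map, optionally
# normalized to relative abundances by the sample's total read count.
# ---------------------------------------------------------------------------

#' @rdname FunctionalProfile
#' @export
setClass("FunctionalProfile",
    representation(
        sampleID   = "character",
        counts     = "integer",
        totalReads = "integer",
        abundances = "numeric"
    ),
    prototype(totalReads = NA_integer_, abundances = numeric(0))
)

setValidity("FunctionalProfile", function(object) {
    msg <- character(0)
    if (length(object@sampleID) != 1L || is.na(object@sampleID) ||
        !nzchar(object@sampleID))
        msg <- c(msg, "sampleID must be a single non-empty string")
    ecs <- names(object@counts)
    if (length(object@counts) > 0L) {
        if (is.null(ecs) || anyNA(ecs))
            msg <- c(msg, "counts must be named by EC number")
        else {
            bad <- ecs[!grepl(.EC_REGEX, ecs)]
            if (length(bad))
                msg <- c(msg, paste0("malformed EC identifier(s): ",
                                     paste(utils::head(bad, 3L), collapse = ", ")))
            if (anyDuplicated(ecs))
                msg <- c(msg, "duplicate EC keys in counts")
        }
        if (anyNA(object@counts) || any(object@counts < 0L))
            msg <- c(msg, "counts must be non-negative integers")
    }
    if (length(object@abundances) > 0L) {
        if (is.na(object@totalReads) || object@totalReads <= 0L)
            msg <- c(msg, "normalized profile requires a positive totalReads")
        else {
            if (!identical(names(object@abundances), names(object@counts)))
                msg <- c(msg, "abundances must be aligned with counts")
            expected <- as.numeric(object@counts) / as.numeric(object@totalReads)
            if (length(expected) && max(abs(object@abundances - expected)) > 1e-12)
                msg <- c(msg, "abundances must equal counts / totalReads")
            if (sum(object@abundances) > 1 + 1e-9)
                msg <- c(msg, "abundances must sum to at most 1")
        }
    }
    if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# ECProfileSet: samples x union-of-ECs feature container. Extends
# SummarizedExperiment with ECs as rows and samples as columns; the "abundance"
# assay holds relative abundances (zero exactly where an EC was absent).
# ---------------------------------------------------------------------------

#' @rdname ECProfileSet
#' @export
setClass("ECProfileSet", contains = "SummarizedExperiment")

setValidity("ECProfileSet", function(object) {
    msg <- character(0)
    if (!"abundance" %in% names(SummarizedExperiment::assays(object)))
        return("ECProfileSet requires an 'abundance' assay")
    a <- SummarizedExperiment::assay(object, "abundance")
    ecs <- rownames(object)
    if (is.null(ecs) || anyDuplicated(ecs))
        msg <- c(msg, "EC row names must be present and unique")
    else {
        if (!identical(ecs, sort(ecs, method = "radix")))
            msg <- c(msg, "EC rows must be in lexicographic order")
        bad <- ecs[!grepl(.EC_REGEX, ecs)]
        if (length(bad))
            msg <- c(msg, paste0("malformed EC identifier(s): ",
                                 paste(utils::head(bad, 3L), collapse = ", ")))
    }
    if (nrow(object) > MAX_ANNOTATABLE_ECS)
        msg <- c(msg, sprintf("more ECs (%d) than the %d annotatable maximum",
                              nrow(object), MAX_ANNOTATABLE_ECS))
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample (column) names must be present and unique")
    if (length(a) && (anyNA(a) || min(a) < 0))
        msg <- c(msg, "abundances must be non-negative and non-missing")
    needed <- c("city", "total_reads", "set_tag")
    missing <- setdiff(needed, colnames(SummarizedExperiment::colData(object)))
    if (length(missing))
        msg <- c(msg, paste0("colData lacks column(s): ",
                             paste(missing, collapse = ", ")))
    if (!length(missing) && ncol(object) && length(a)) {
        # artificial random metagenomes draw each EC independently, so their
        # sums are compositional only in expectation; all real or simulated
        # profiles must respect sum(abundance) <= 1
        real <- SummarizedExperiment::colData(object)$set_tag != "random"
        if (any(real) && max(colSums(a[, real, drop = FALSE])) > 1 + 1e-6)
            msg <- c(msg, "per-sample abundance sums must not exceed 1")
    }
    if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# SyntheticConfig: the declared generative model for city-structured profiles.
# ---------------------------------------------------------------------------

#' @rdname syntheticConfig
#' @export
setClass("SyntheticConfig",
    representation(
        nCities              = "integer",
        samplesPerCity       = "integer",
        nEcs                 = "integer",
        nSignatureEcsPerCity = "integer",
        effectSize           = "numeric",
        sparsity             = "numeric",
        depth                = "integer",
        seed                 = "integer",
        baselineSdLog        = "numeric",
        sampleNoiseSd        = "numeric"
    )
)

setValidity("SyntheticConfig", function(object) {
    msg <- character(0)
    if (object@nCities < 1L) msg <- c(msg, "nCities must be >= 1")
    if (length(object@samplesPerCity) != object@nCities)
        msg <- c(msg, "samplesPerCity must have one entry per city")
    if (any(object@samplesPerCity < 1L))
        msg <- c(msg, "samplesPerCity entries must be >= 1")
    if (object@nEcs < 1L || object@nEcs > MAX_ANNOTATABLE_ECS)
        msg <- c(msg, sprintf("nEcs must be in [1, %d]", MAX_ANNOTATABLE_ECS))
    if (object@nSignatureEcsPerCity * object@nCities > object@nEcs)
        msg <- c(msg, "total planted signature ECs exceed the EC universe")
    if (object@effectSize < 1)
        msg <- c(msg, "effectSize must be >= 1 (1 plants no signal, for null checks)")
    if (object@sparsity < 0 || object@sparsity >= 1)
        msg <- c(msg, "sparsity must be in [0, 1)")
    if (object@depth < 1L) msg <- c(msg, "depth must be positive")
    if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# FeatureRanking: DKM gains for every EC of one city-vs-rest task plus the
# selected top-k under the declared tie-break.
# ---------------------------------------------------------------------------

#' @rdname selectTopFeatures
#' @export
setClass("FeatureRanking",
    representation(
        city     = "character",
        scores   = "numeric",
        selected = "character",
        k        = "integer"
    )
)

setValidity("FeatureRanking", function(object) {
    msg <- character(0)
    if (is.null(names(object@scores)))
        msg <- c(msg, "scores must be named by EC")
    if (length(object@selected) != object@k)
        msg <- c(msg, "selected must contain exactly k ECs")
    if (!all(object@selected %in% names(object@scores)))
        msg <- c(msg, "selected ECs must be scored ECs")
    if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# CityModel: one city's one-vs-rest classifier with its feature-scaling
# statistics and the training score range used for standardization.
# ---------------------------------------------------------------------------

#' @rdname trainCityModel
#' @export
setClass("CityModel",
    representation(
        city         = "character",
        selectedECs  = "character",
        fit          = "ANY",
        featureCenter = "numeric",
        featureScale  = "numeric",
        decisionSign  = "numeric",
        scoreRange    = "numeric",
        params        = "list"
    )
)

setValidity("CityModel", function(object) {
    msg <- character(0)
    if (length(object@scoreRange) != 2L || anyNA(object@scoreRange))
        msg <- c(msg, "scoreRange must be two finite numbers")
    else if (object@scoreRange[1L] > object@scoreRange[2L])
        msg <- c(msg, "scoreRange must satisfy min <= max")
    if (length(object@featureCenter) != length(object@selectedECs) ||
        length(object@featureScale) != length(object@selectedECs))
        msg <- c(msg, "feature scaling stats must match selectedECs")
    if (!object@decisionSign %in% c(-1, 1))
        msg <- c(msg, "decisionSign must be +1 or -1")
    if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# ModelSuite: one CityModel per training city plus the frozen EC universe.
# ---------------------------------------------------------------------------

.VARIANTS_CV    <- c("raw-full", "raw-select", "balance-select")
.VARIANTS_FINAL <- c("final", "final-unbalanced")
.VARIANTS       <- c(.VARIANTS_CV, .VARIANTS_FINAL)

#' @rdname fitFinalSuite
#' @export
setClass("ModelSuite",
    representation(
        variant    = "character",
        cityModels = "list",
        ecUniverse = "character",
        params     = "list",
        seed       = "integer"
    )
)

setValidity("ModelSuite", function(object) {
    msg <- character(0)
    if (!object@variant %in% .VARIANTS)
        msg <- c(msg, paste0("variant must be one of: ",
                             paste(.VARIANTS, collapse = ", ")))
    if (length(object@cityModels) == 0L)
        msg <- c(msg, "suite must contain at least one city model")
    if (!all(vapply(object@cityModels, is, logical(1L), "CityModel")))
        msg <- c(msg, "cityModels must all be CityModel objects")
    cities <- unname(vapply(object@cityModels, function(m) m@city,
                            character(1L)))
    if (!identical(names(object@cityModels), cities))
        msg <- c(msg, "cityModels must be named by their city")
    if (anyDuplicated(cities))
        msg <- c(msg, "one model per city")
    ok <- vapply(object@cityModels,
                 function(m) all(m@selectedECs %in% object@ecUniverse),
                 logical(1L))
    if (!all(ok))
        msg <- c(msg, "selected ECs must lie in the training EC universe")
    if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# CityAssignment: standardized per-sample city scores, ranking, novelty.
# ---------------------------------------------------------------------------

#' @rdname assignCities
#' @export
setClass("CityAssignment",
    representation(
        scores  = "matrix",   # samples x cities, standardized
        novelty = "logical"   # NA until judged against a calibration
    )
)

setValidity("CityAssignment", function(object) {
    msg <- character(0)
    if (is.null(rownames(object@scores)) || is.null(colnames(object@scores)))
        msg <- c(msg, "scores must have sample row names and city column names")
    if (ncol(object@scores) < 1L)
        msg <- c(msg, "at least one city score column required")
    if (length(object@novelty) != nrow(object@scores))
        msg <- c(msg, "novelty must have one entry per sample")
    if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# NoveltyCalibration: the random-set score threshold.
# ---------------------------------------------------------------------------

#' @rdname calibrateThreshold
#' @export
setClass("NoveltyCalibration",
    representation(
        threshold = "numeric",
        quantile  = "numeric",
        nRandom   = "integer",
        exceedance = "numeric",
        seed      = "integer"
    ),
    prototype(seed = NA_integer_)
)

setValidity("NoveltyCalibration", function(object) {
    msg <- character(0)
    if (length(object@threshold) != 1L || is.na(object@threshold))
        msg <- c(msg, "threshold must be a single number")
    if (object@quantile <= 0 || object@quantile >= 1)
        msg <- c(msg, "quantile must be in (0, 1)")
    if (object@nRandom < 1L)
        msg <- c(msg, "calibration requires a non-empty random set")
    if (!is.na(object@exceedance) &&
        object@exceedance > (1 - object@quantile) + 1e-12)
        msg <- c(msg, "calibration exceedance exceeds 1 - quantile")
    if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# CrossValResult: everything a leave-one-out run produces.
# ---------------------------------------------------------------------------

#' @rdname looCrossval
#' @export
setClass("CrossValResult",
    representation(
        variant     = "character",
        assignments = "CityAssignment",
        rawScores   = "matrix",
        trueCity    = "character",
        rankings    = "list",   # city -> list of per-iteration FeatureRanking
        params      = "list",
        seed        = "integer"
    )
)

setValidity("CrossValResult", function(object) {
    msg <- character(0)
    if (!object@variant %in% .VARIANTS_CV)
        msg <- c(msg, "variant must be a cross-validation variant")
    if (length(object@trueCity) != nrow(object@rawScores))
        msg <- c(msg, "trueCity must have one entry per sample")
    if (!identical(dim(object@rawScores), dim(object@assignments@scores)))
        msg <- c(msg, "raw and standardized score matrices must align")
    if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# ExperimentConfig: declarative description of one of the five model variants.
# ---------------------------------------------------------------------------

#' @rdname experimentConfig
#' @export
setClass("ExperimentConfig",
    representation(
        variant   = "character",
        kFeatures = "integer",
        perCity   = "integer",
        perClass  = "integer",
        quantile  = "numeric",
        svmParams = "list",
        seed      = "integer",
        retrainShuffles = "logical"
    )
)

setValidity("ExperimentConfig", function(object) {
    msg <- character(0)
    if (!object@variant %in% .VARIANTS)
        msg <- c(msg, paste0("variant must be one of: ",
                             paste(.VARIANTS, collapse = ", ")))
    if (object@kFeatures < 1L) msg <- c(msg, "kFeatures must be >= 1")
    if (object@perCity < 1L || object@perClass < 1L)
        msg <- c(msg, "perCity and perClass must be positive")
    if (object@quantile <= 0 || object@quantile >= 1)
        msg <- c(msg, "quantile must be in (0, 1)")
    if (length(msg)) msg else TRUE
})
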