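#' Fit the final model suite on the complete labeled set
#'
#' Runs one pass of the cross-validation training procedure on the full
#' sample set -- without leaving anything out -- producing one model per
#' city. `"final"` applies two-stage balancing before DKM feature selection
#' and training (selection and training on the balanced multiset);
#' `"final-unbalanced"` selects and trains on the raw set. Either way, each
#' model's standardization range is the range of raw scores of the distinct
#' training samples under that model, so any later test sample is standardized
#' against the training cohort.
#'
#' @param x a labeled [ECProfileSet].
#' @param variant `"final"` (balanced) or `"final-unbalanced"`.
#' @param params list: `kFeatures` (default 20), `perCity` (150), `perClass`
#'   (5000), `svmParams`.
#' @param seed integer seed for the balancing draws.
#' @return a `ModelSuite`.
#' @aliases ModelSuite-class
#' @export
fitFinalSuite <- function(x, variant = c("final", "final-unbalanced"),
                          params = list(), seed = 1L) {
    stopifnot(is(x, "ECProfileSet"))
    variant <- match.arg(variant)
    labels <- as.character(cityLabels(x))
    if (length(unique(labels)) < 2L)
        stop("need at least two cities", call. = FALSE)
    m <- abundanceMatrix(x, samplesAsRows = TRUE)
    tr <- .trainVariantModels(m, labels, variant, params, seed = seed)
    new("ModelSuite", variant = variant, cityModels = tr$models,
        ecUniverse = ecUniverse(x), params = params, seed = as.integer(seed))
}

#' @rdname fitFinalSuite
#' @param x a `ModelSuite`.
#' @export
trainingCities <- function(x) {
    stopifnot(is(x, "ModelSuite"))
    names(x@cityModels)
}

#' @rdname fitFinalSuite
#' @param city a training city name.
#' @export
cityModel <- function(x, city) {
    stopifnot(is(x, "ModelSuite"))
    if (!city %in% names(x@cityModels))
        stop("no model for city '", city, "'", call. = FALSE)
    x@cityModels[[city]]
}

setMethod("show", "ModelSuite", function(object) {
    cat("ModelSuite (", object@variant, "): ", length(object@cityModels),
        " city models over ", length(object@ecUniverse), " ECs; cities: ",
        paste(names(object@cityModels), collapse = ", "), "\n", sep = "")
})

#' Score and assign samples with a model suite
#'
#' Scores every sample with every city model, standardizes each raw margin by
#' the corresponding model's training score range, and ranks cities by
#' standardized score.
#'
#' @param suite a [fitFinalSuite()] `ModelSuite`.
#' @param x an [ECProfileSet] or samples-x-ECs matrix (projected onto the
#'   training EC universe automatically).
#' @param calibration optional [calibrateThreshold()] result; when given, the
#'   novelty verdict is set on the returned assignment.
#' @return a `CityAssignment` of standardized scores; use [rawScores()] on a
#'   [cityModel()] for the underlying raw margins.
#' @export
predictSuite <- function(suite, x, calibration = NULL) {
    stopifnot(is(suite, "ModelSuite"))
    sc <- .scoreWithModels(suite@cityModels, x)
    res <- assignCities(sc$std)
    if (!is.null(calibration)) res <- judgeOrigin(res, calibration)
    res
}

#' JSON-serializable description of a model suite
#'
#' Captures the reproducibility metadata of a suite: variant, per-city
#' selected ECs and training score ranges, classifier parameters, seed, and
#' EC universe hash. The fitted kernel classifiers themselves are R objects;
#' persist them with `saveRDS` if needed.
#'
#' @param suite a `ModelSuite`.
#' @param path optional path; when given the manifest is written as JSON.
#' @return the manifest list, invisibly when written.
#' @export
suiteManifest <- function(suite, path = NULL) {
    stopifnot(is(suite, "ModelSuite"))
    man <- list(
        variant = suite@variant,
        seed = suite@seed,
        nEcUniverse = length(suite@ecUniverse),
        ecUniverseHash = .hashObject(suite@ecUniverse),
        params = suite@params,
        cities = lapply(suite@cityModels, function(mm) {
            list(city = mm@city,
                 selectedECs = mm@selectedECs,
                 scoreRange = mm@scoreRange,
                 svm = mm@params)
        })
    )
    if (!is.null(path)) {
        jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                             pretty = TRUE)
        return(invisible(man))
    }
    man
}
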