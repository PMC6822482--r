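#' Declarative experiment configuration
#'
#' Describes one of the five model variants end to end. Balancing parameters
#' are validated against the variant: supplying non-default `perCity` /
#' `perClass` for a variant that never balances raises a warning and the
#' values are ignored.
#'
#' @param variant one of `"raw-full"`, `"raw-select"`, `"balance-select"`,
#'   `"final"`, `"final-unbalanced"`.
#' @param kFeatures DKM features per city (default 20).
#' @param perCity stage-1 balancing size (default 150).
#' @param perClass stage-2 per-class size (default 5000).
#' @param quantile novelty calibration quantile (default 0.95).
#' @param svmParams list of classifier parameters (`kernel`, `cost`,
#'   `gamma`).
#' @param seed integer master seed.
#' @param retrainShuffles whether random-label baselines retrain per shuffle.
#' @return an `ExperimentConfig`.
#' @aliases ExperimentConfig-class
#' @export
experimentConfig <- function(variant, kFeatures = 20L, perCity = 150L,
                             perClass = 5000L, quantile = 0.95,
                             svmParams = list(), seed = 1L,
                             retrainShuffles = FALSE) {
    balancing <- variant %in% c("balance-select", "final")
    if (!balancing && (perCity != 150L || perClass != 5000L))
        warning("variant '", variant, "' never balances; perCity/perClass ",
                "are ignored", call. = FALSE)
    cfg <- new("ExperimentConfig", variant = variant,
               kFeatures = as.integer(kFeatures),
               perCity = as.integer(perCity), perClass = as.integer(perClass),
               quantile = as.numeric(quantile),
               svmParams = svmParams, seed = as.integer(seed),
               retrainShuffles = isTRUE(retrainShuffles))
    validObject(cfg)
    cfg
}

setMethod("show", "ExperimentConfig", function(object) {
    cat("ExperimentConfig: variant '", object@variant, "', k=",
        object@kFeatures,
        if (object@variant %in% c("balance-select", "final"))
            sprintf(", balancing %d/city then %d/class",
                    object@perCity, object@perClass) else "",
        ", seed ", object@seed, "\n", sep = "")
})

.configAsList <- function(config) {
    list(variant = config@variant, kFeatures = config@kFeatures,
         perCity = config@perCity, perClass = config@perClass,
         quantile = config@quantile, svmParams = config@svmParams,
         seed = config@seed, retrainShuffles = config@retrainShuffles)
}

#' Run one experiment variant end to end
#'
#' Dispatches the configured variant: the three cross-validation variants run
#' [looCrossval()], the two final variants fit a [fitFinalSuite()]
#' `ModelSuite`. When `outDir` is given, the standard artifacts are written:
#' a manifest JSON (config echo, seed, input hash), and either the per-sample
#' assignment table plus per-city AUCs (cross-validation) or the suite
#' manifest (final variants), all as TSV/JSON.
#'
#' @param config an [experimentConfig()].
#' @param x a labeled [ECProfileSet].
#' @param outDir optional artifact directory.
#' @return a `CrossValResult` or `ModelSuite`, per the variant.
#' @export
runExperiment <- function(config, x, outDir = NULL) {
    stopifnot(is(config, "ExperimentConfig"), is(x, "ECProfileSet"))
    validObject(config)
    params <- list(kFeatures = config@kFeatures, perCity = config@perCity,
                   perClass = config@perClass, svmParams = config@svmParams)
    res <- if (config@variant %in% .VARIANTS_CV)
        looCrossval(x, config@variant, params = params, seed = config@seed)
    else
        fitFinalSuite(x, config@variant, params = params, seed = config@seed)
    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        manifest <- list(config = .configAsList(config),
                         nSamples = ncol(x), nEcs = nrow(x),
                         inputHash = .hashObject(abundanceMatrix(x)),
                         cities = sort(unique(as.character(cityLabels(x)))))
        jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
        if (is(res, "CrossValResult")) {
            utils::write.table(as.data.frame(assignments(res)),
                               file.path(outDir, "assignments.tsv"),
                               sep = "\t", quote = FALSE, row.names = FALSE)
            utils::write.table(assignmentTable(res),
                               file.path(outDir, "assignment_table.tsv"),
                               sep = "\t", quote = FALSE, row.names = FALSE)
            utils::write.table(cityAUCs(res),
                               file.path(outDir, "city_aucs.tsv"),
                               sep = "\t", quote = FALSE, row.names = FALSE)
        } else {
            suiteManifest(res, file.path(outDir, "suite.json"))
        }
    }
    res
}
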