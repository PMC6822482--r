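#' Calibrate the not-from-any-training-city threshold
#'
#' Scores a constructed random-metagenome null set with the trained suite and
#' takes the nearest-rank empirical quantile of the top-hit standardized
#' scores as the novelty threshold: by construction at most a
#' `1 - quantile` fraction of the calibration set exceeds it. On the study's
#' data this construction put the threshold at 0.65 for the 95% quantile; the
#' threshold is always recalibrated, never hard-coded.
#'
#' @param suite a trained [fitFinalSuite()] `ModelSuite`.
#' @param randomSet the null [ECProfileSet] from
#'   [generateRandomMetagenomeSet()].
#' @param quantile confidence quantile (default 0.95).
#' @param seed optional seed recorded for provenance.
#' @return a `NoveltyCalibration`.
#' @aliases NoveltyCalibration-class noveltyThreshold
#' @export
calibrateThreshold <- function(suite, randomSet, quantile = 0.95,
                               seed = NA_integer_) {
    stopifnot(is(suite, "ModelSuite"))
    if (is(randomSet, "ECProfileSet") && ncol(randomSet) == 0L)
        stop("empty random set", call. = FALSE)
    tops <- topHitScores(predictSuite(suite, randomSet))
    n <- length(tops)
    if (n == 0L) stop("empty random set", call. = FALSE)
    s <- sort(tops)
    thr <- s[ceiling(quantile * n)]        # nearest-rank quantile
    new("NoveltyCalibration", threshold = unname(thr),
        quantile = quantile, nRandom = as.integer(n),
        exceedance = mean(tops > thr), seed = as.integer(seed))
}

#' @rdname calibrateThreshold
#' @export
setMethod("noveltyThreshold", "NoveltyCalibration", function(x) x@threshold)

setMethod("show", "NoveltyCalibration", function(object) {
    cat("NoveltyCalibration: threshold ", signif(object@threshold, 4L),
        " at the ", object@quantile * 100, "% quantile of ", object@nRandom,
        " random-set top-hit scores (calibration exceedance ",
        sprintf("%.2f%%", 100 * object@exceedance), ")\n", sep = "")
})

#' Judge whether samples come from any training city
#'
#' A sample is judged novel -- not from any training city -- when its top-hit
#' standardized score is at or below the calibrated threshold; confidence of
#' a known-city origin applies only to scores strictly above it.
#'
#' @param result a [assignCities()] / [predictSuite()] `CityAssignment`.
#' @param calibration a [calibrateThreshold()] `NoveltyCalibration`.
#' @return the assignment with its novelty verdict set; ranking untouched.
#' @aliases noveltyFlags
#' @export
judgeOrigin <- function(result, calibration) {
    stopifnot(is(result, "CityAssignment"),
              is(calibration, "NoveltyCalibration"))
    result@novelty <- unname(topHitScores(result) <= calibration@threshold)
    result
}
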