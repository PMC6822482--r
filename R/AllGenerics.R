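#' @rdname ECProfileSet
#' @export
setGeneric("ecUniverse", function(x) standardGeneric("ecUniverse"))

#' @rdname ECProfileSet
#' @export
setGeneric("cityLabels", function(x) standardGeneric("cityLabels"))

#' @rdname ECProfileSet
#' @export
setGeneric("setTags", function(x) standardGeneric("setTags"))

#' @rdname ECProfileSet
#' @export
setGeneric("totalReads", function(x) standardGeneric("totalReads"))

#' @rdname ECProfileSet
#' @export
setGeneric("abundanceMatrix", function(x, ...) standardGeneric("abundanceMatrix"))

#' @rdname FunctionalProfile
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' @rdname trainCityModel
#' @export
setGeneric("trainScoreRange", function(x) standardGeneric("trainScoreRange"))

#' @rdname selectTopFeatures
#' @export
setGeneric("selectedECs", function(x) standardGeneric("selectedECs"))

#' @rdname assignCities
#' @export
setGeneric("standardizedScores", function(x) standardGeneric("standardizedScores"))

#' @rdname assignCities
#' @export
setGeneric("topHitScores", function(x) standardGeneric("topHitScores"))

#' @rdname assignCities
#' @export
setGeneric("topCity", function(x) standardGeneric("topCity"))

#' @rdname assignCities
#' @export
setGeneric("cityRanking", function(x) standardGeneric("cityRanking"))

#' @rdname judgeOrigin
#' @export
setGeneric("noveltyFlags", function(x) standardGeneric("noveltyFlags"))

#' @rdname calibrateThreshold
#' @export
setGeneric("noveltyThreshold", function(x) standardGeneric("noveltyThreshold"))

#' @rdname looCrossval
#' @export
setGeneric("assignments", function(x) standardGeneric("assignments"))

#' @rdname looCrossval
#' @export
setGeneric("iterationRankings", function(x, city) standardGeneric("iterationRankings"))
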