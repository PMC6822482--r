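.defaultSvmParams <- function(params = list(), nFeatures) {
    list(kernel = params$kernel %||% "radial",
         cost   = params$cost %||% 1,
         gamma  = params$gamma %||% (1 / nFeatures))
}

#' Train one city's one-vs-rest classifier
#'
#' Fits a soft-margin kernel SVM (radial basis kernel, cost 1, kernel width
#' 1/n_features by default) to separate "this city" (positive) from all other
#' cities (negative). Features are z-scored by training-set mean and standard
#' deviation (zero-variance features get scale 1), and the same statistics are
#' applied to any sample scored later. The raw score of a sample is the signed
#' kernel margin, oriented so that larger means more city-like. The range of
#' raw scores over a reference sample set (by default the training samples) is
#' recorded for score standardization.
#'
#' @param x an [ECProfileSet] or samples-x-ECs matrix of training samples.
#' @param city positive-class city name.
#' @param positives optional logical vector of positive samples (defaults to
#'   `cityLabels(x) == city`).
#' @param selected ECs to train on (default: all columns of `x`).
#' @param params list of SVM parameters (`kernel`, `cost`, `gamma`).
#' @param rangeReference optional [ECProfileSet] or samples-x-ECs matrix whose
#'   scores define the standardization range; defaults to the training
#'   samples. When training is a balanced multiset, pass the distinct source
#'   samples here so the range describes the actual training cohort.
#' @return a `CityModel`.
#' @aliases CityModel-class trainScoreRange
#' @export
trainCityModel <- function(x, city, positives = NULL, selected = NULL,
                           params = list(), rangeReference = NULL) {
    if (is(x, "ECProfileSet")) {
        positives <- positives %||% (cityLabels(x) == city)
        m <- abundanceMatrix(x, samplesAsRows = TRUE)
    } else m <- as.matrix(x)
    if (is.null(positives))
        stop("positives must be given for matrix input", call. = FALSE)
    positives <- as.logical(positives)
    if (all(positives) || !any(positives))
        stop("both classes must be present to train '", city, "'",
             call. = FALSE)
    if (!is.null(selected)) m <- m[, selected, drop = FALSE]
    if (is.null(colnames(m)))
        stop("training matrix must have EC column names", call. = FALSE)
    selected <- colnames(m)
    params <- .defaultSvmParams(params, ncol(m))

    center <- colMeans(m)
    scl <- apply(m, 2L, stats::sd)
    scl[!is.finite(scl) | scl == 0] <- 1
    ms <- scale(m, center = center, scale = scl)
    y <- factor(ifelse(positives, "pos", "neg"), levels = c("pos", "neg"))
    fit <- e1071::svm(ms, y, kernel = params$kernel, cost = params$cost,
                      gamma = params$gamma, scale = FALSE)
    d <- attr(stats::predict(fit, ms, decision.values = TRUE),
              "decision.values")
    sign <- if (startsWith(colnames(d)[1L], "pos")) 1 else -1
    model <- new("CityModel", city = city, selectedECs = selected, fit = fit,
                 featureCenter = center, featureScale = scl,
                 decisionSign = sign, scoreRange = range(sign * d[, 1L]),
                 params = params)
    if (!is.null(rangeReference))
        model@scoreRange <- range(rawScores(model, rangeReference))
    model
}

#' @rdname trainCityModel
#' @export
setMethod("trainScoreRange", "CityModel", function(x) x@scoreRange)

setMethod("show", "CityModel", function(object) {
    cat("CityModel '", object@city, "': ", length(object@selectedECs),
        " ECs, ", object@params$kernel, " kernel (cost ", object@params$cost,
        ", gamma ", signif(object@params$gamma, 3L), "), score range [",
        signif(object@scoreRange[1L], 4L), ", ",
        signif(object@scoreRange[2L], 4L), "]\n", sep = "")
})

#' Raw city-model scores of samples
#'
#' Projects samples onto the model's selected ECs (unseen ECs dropped,
#' missing ECs zero), applies the training feature scaling, and returns the
#' signed kernel margin of each sample, oriented city-positive.
#'
#' @param model a [trainCityModel()] `CityModel`.
#' @param x an [ECProfileSet] or samples-x-ECs matrix.
#' @return named numeric vector of raw scores.
#' @export
rawScores <- function(model, x) {
    stopifnot(is(model, "CityModel"))
    m <- .projectMatrix(x, model@selectedECs)
    ms <- scale(m, center = model@featureCenter, scale = model@featureScale)
    d <- attr(stats::predict(model@fit, ms, decision.values = TRUE),
              "decision.values")
    stats::setNames(model@decisionSign * d[, 1L], rownames(m))
}

#' Standardize raw scores to a model's training score range
#'
#' Standardized score = (raw - min) / (max - min), where min and max are the
#' model's training score range. Scores outside the training range map outside
#' [0, 1] (no clamping, so ordering is preserved); a degenerate range maps
#' every score to 0.5.
#'
#' @param raw numeric vector of raw scores, or a named `city -> raw` map when
#'   `model` is a `ModelSuite`.
#' @param model a `CityModel`, or a `ModelSuite` whose per-city ranges are
#'   applied to the correspondingly named entries of `raw`.
#' @return numeric vector of standardized scores.
#' @export
standardizeScores <- function(raw, model) {
    if (is(model, "ModelSuite")) {
        if (is.null(names(raw)))
            stop("raw scores must be named by city", call. = FALSE)
        unknown <- setdiff(names(raw), names(model@cityModels))
        if (length(unknown))
            stop("no model for city: ", paste(unknown, collapse = ", "),
                 call. = FALSE)
        return(vapply(names(raw),
                      function(cc) standardizeScores(raw[[cc]],
                                                     model@cityModels[[cc]]),
                      numeric(1L)))
    }
    stopifnot(is(model, "CityModel"))
    r <- model@scoreRange
    if (r[2L] - r[1L] <= 0) return(rep(0.5, length(raw)))
    (raw - r[1L]) / (r[2L] - r[1L])
}

#' City assignment from standardized scores
#'
#' Ranks cities by descending standardized score (ties broken
#' lexicographically by city name); the top-ranked city is the assignment and
#' the top score is the sample's top-hit score. A sample is counted correct
#' under the top-2 criterion when its true city is among the first two ranks.
#'
#' @param scores numeric matrix (samples x cities) of standardized scores,
#'   with dimnames; or a named numeric vector for a single sample.
#' @return a `CityAssignment`.
#' @aliases CityAssignment-class standardizedScores topHitScores topCity
#'   cityRanking
#' @export
assignCities <- function(scores) {
    if (is.null(dim(scores))) {
        if (is.null(names(scores)) || !length(scores))
            stop("need a non-empty named city -> score map", call. = FALSE)
        scores <- matrix(scores, nrow = 1L,
                         dimnames = list("sample", names(scores)))
    }
    new("CityAssignment", scores = as.matrix(scores),
        novelty = rep(NA, nrow(scores)))
}

#' @rdname assignCities
#' @export
setMethod("standardizedScores", "CityAssignment", function(x) x@scores)

#' @rdname assignCities
#' @export
setMethod("cityRanking", "CityAssignment", function(x) {
    cities <- colnames(x@scores)
    t(apply(x@scores, 1L, function(s) {
        cities[order(-s, cities, method = "radix")]
    }))
})

#' @rdname assignCities
#' @export
setMethod("topCity", "CityAssignment", function(x) {
    stats::setNames(cityRanking(x)[, 1L], rownames(x@scores))
})

#' @rdname assignCities
#' @export
setMethod("topHitScores", "CityAssignment", function(x) {
    stats::setNames(apply(x@scores, 1L, max), rownames(x@scores))
})

#' @rdname judgeOrigin
#' @export
setMethod("noveltyFlags", "CityAssignment", function(x) {
    stats::setNames(x@novelty, rownames(x@scores))
})

setMethod("show", "CityAssignment", function(object) {
    cat("CityAssignment: ", nrow(object@scores), " samples x ",
        ncol(object@scores), " cities",
        if (!anyNA(object@novelty))
            sprintf("; %d flagged novel", sum(object@novelty)) else "",
        "\n", sep = "")
})

#' @rdname assignCities
#' @param x a `CityAssignment`.
#' @param ... unused.
#' @export
setMethod("as.data.frame", "CityAssignment", function(x, ...) {
    rk <- cityRanking(x)
    data.frame(sample_id = rownames(x@scores),
               top_city = rk[, 1L],
               second_city = if (ncol(rk) > 1L) rk[, 2L] else NA_character_,
               top_hit_score = as.numeric(topHitScores(x)),
               novelty = x@novelty,
               x@scores,
               check.names = FALSE, stringsAsFactors = FALSE,
               row.names = NULL)
})

#' Two-stage with-replacement class balancing
#'
#' Balances a city-vs-rest training set: first every city is resampled with
#' replacement to exactly `perCity` samples (up- or down-sampling as needed);
#' then the positive class (the target city's `perCity` samples) and the
#' negative class (the pooled other cities' samples) are each resampled with
#' replacement to `perClass` samples. The study used `perCity = 150`,
#' `perClass = 5000`. Balancing changes sample multiplicities only, never the
#' set of distinct samples available.
#'
#' @param labels character vector of city labels (or an [ECProfileSet]).
#' @param city target (positive) city; must be present in `labels`.
#' @param perCity stage-1 per-city size (default 150).
#' @param perClass stage-2 per-class size (default 5000).
#' @param seed integer seed.
#' @return list with `idx` (integer indices into the input samples, length
#'   `2 * perClass`), `positive` (logical, same length), and `stage1` (the
#'   stage-1 indices, named by city).
#' @export
balanceResample <- function(labels, city, perCity = 150L, perClass = 5000L,
                            seed = 1L) {
    if (is(labels, "ECProfileSet")) labels <- as.character(cityLabels(labels))
    perCity <- as.integer(perCity); perClass <- as.integer(perClass)
    if (perCity <= 0L || perClass <= 0L)
        stop("perCity and perClass must be positive", call. = FALSE)
    cities <- sort(unique(labels))
    if (!city %in% cities)
        stop("city '", city, "' absent from the sample set", call. = FALSE)
    if (length(cities) < 2L)
        stop("balancing needs at least two cities", call. = FALSE)
    .withSeed(seed, {
        stage1 <- lapply(cities, function(cc) {
            sample(which(labels == cc), perCity, replace = TRUE)
        })
        names(stage1) <- cities
        pos <- sample(stage1[[city]], perClass, replace = TRUE)
        negPool <- unlist(stage1[setdiff(cities, city)], use.names = FALSE)
        neg <- sample(negPool, perClass, replace = TRUE)
        list(idx = c(pos, neg),
             positive = rep(c(TRUE, FALSE), each = perClass),
             stage1 = stage1)
    })
}
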